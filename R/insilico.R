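#' Simulated PCR of a primer pair against template sequences
#'
#' A binary amplification model built on the 3'-terminal mismatch effect: a
#' single mismatch under the primer's 3' end cripples the polymerase (up to
#' ~100-fold), so a site only supports extension when its final
#' `terminal_exact` 3' bases match the template exactly; internal
#' mismatches are tolerated up to `max_internal_mm` in total. Every binding
#' site of either primer on either strand with at most
#' `max_internal_mm + terminal_exact` mismatches is found by exhaustive
#' scan, and an amplicon is called for every convergent site pair whose
#' product is at most `max_product` bases.
#'
#' @param pair One row of a pair table, or a list with `f_sequence` and
#'   `r_sequence` (both 5'->3').
#' @param templates Named character vector of template sequences.
#' @param max_internal_mm Maximum tolerated internal mismatches per site
#'   pair (summed over both primers).
#' @param terminal_exact Number of 3'-terminal bases that must match
#'   exactly.
#' @param max_product Maximum simulated product size (bases).
#' @return Data frame of amplicon calls: `template_label`, `orientation`
#'   (`"+"` = forward primer on the plus strand), `forward_site`,
#'   `reverse_site` (0-based starts of the two binding sites on the plus
#'   strand), `product_size`, `forward_3prime_match`,
#'   `reverse_3prime_match`, `internal_mismatches`, `amplifies`.
#' @export
simulate_pcr <- function(pair, templates, max_internal_mm = 3,
                         terminal_exact = 1, max_product = 10000) {
  stopifnot(length(templates) > 0)
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  f <- toupper(pair$f_sequence[[1L]])
  r <- toupper(pair$r_sequence[[1L]])
  mm_cap <- max_internal_mm + terminal_exact

  # binding sites of `oligo` laid along the plus strand (possibly as its
  # reverse complement), with per-site mismatch positions
  site_info <- function(oligo, tmpl_dna, as_revcomp) {
    probe <- if (as_revcomp) revcomp(oligo) else oligo
    m <- Biostrings::matchPattern(Biostrings::DNAString(probe), tmpl_dna,
                                  max.mismatch = mm_cap)
    starts <- IRanges::start(m)
    if (length(starts) == 0L)
      return(list(start = integer(), internal = integer(),
                  term_ok = logical()))
    L <- nchar(probe)
    pc <- strsplit(probe, "", fixed = TRUE)[[1L]]
    internal <- integer(length(starts))
    term_ok <- logical(length(starts))
    # 3'-terminal bases of the oligo sit at probe positions L..L-k+1 when
    # laid forward, or 1..k when laid as its reverse complement.
    term_idx <- if (as_revcomp) seq_len(terminal_exact) else
      seq(L, L - terminal_exact + 1L)
    for (i in seq_along(starts)) {
      tc <- strsplit(as.character(
        Biostrings::subseq(tmpl_dna, starts[i], starts[i] + L - 1L)),
        "", fixed = TRUE)[[1L]]
      mm <- which(tc != pc)
      term_ok[i] <- !any(mm %in% term_idx)
      internal[i] <- sum(!mm %in% term_idx)
    }
    list(start = starts - 1L, internal = internal, term_ok = term_ok,
         len = L)
  }

  out <- list()
  emit <- function(label, orientation, fs, rs) {
    # fs: site of the left (plus-strand) primer, rs: site of the right
    # (minus-strand) primer; both 0-based starts on the plus strand
    combos <- expand.grid(a = seq_along(fs$start), b = seq_along(rs$start))
    for (k in seq_len(nrow(combos))) {
      a <- combos$a[k]; b <- combos$b[k]
      i <- fs$start[a]; j <- rs$start[b]
      if (j < i + fs$len) next                    # not convergent
      size <- j + rs$len - i
      if (size > max_product) next
      internal <- fs$internal[a] + rs$internal[b]
      amp <- fs$term_ok[a] && rs$term_ok[b] && internal <= max_internal_mm
      out[[length(out) + 1L]] <<- data.frame(
        template_label = label, orientation = orientation,
        forward_site = if (orientation == "+") i else j,
        reverse_site = if (orientation == "+") j else i,
        product_size = size,
        forward_3prime_match = if (orientation == "+") fs$term_ok[a]
                               else rs$term_ok[b],
        reverse_3prime_match = if (orientation == "+") rs$term_ok[b]
                               else fs$term_ok[a],
        internal_mismatches = internal, amplifies = amp)
    }
  }

  for (label in names(templates)) {
    tmpl_dna <- Biostrings::DNAString(toupper(templates[[label]]))
    f_plus <- site_info(f, tmpl_dna, as_revcomp = FALSE)
    r_minus <- site_info(r, tmpl_dna, as_revcomp = TRUE)
    r_plus <- site_info(r, tmpl_dna, as_revcomp = FALSE)
    f_minus <- site_info(f, tmpl_dna, as_revcomp = TRUE)
    if (length(f_plus$start) && length(r_minus$start))
      emit(label, "+", f_plus, r_minus)
    if (length(r_plus$start) && length(f_minus$start))
      emit(label, "-", r_plus, f_minus)
  }
  if (length(out) == 0L)
    return(data.frame(template_label = character(),
                      orientation = character(), forward_site = integer(),
                      reverse_site = integer(), product_size = integer(),
                      forward_3prime_match = logical(),
                      reverse_3prime_match = logical(),
                      internal_mismatches = integer(),
                      amplifies = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specificity report of a tiling solution against the extracted loci
#'
#' Runs [simulate_pcr()] for every selected pair against the target locus
#' and every homologue. A pair passes when exactly the target amplifies;
#' with no homologues the pass is trivial and flagged with a warning.
#'
#' @param solution A `tiling_solution`.
#' @param templates Named character vector of templates; the first element
#'   must be the target locus. (Alternatively a list of
#'   `extracted_sequence` objects, target first.)
#' @param ... Passed to [simulate_pcr()].
#' @return A list of class `specificity_report`: `table` (per-pair summary
#'   with `pass`), `calls` (all amplicon calls), `all_pass`, `warning`.
#' @export
specificity_report <- function(solution, templates, ...) {
  if (is.list(templates) && inherits(templates[[1L]], "extracted_sequence"))
    templates <- stats::setNames(
      vapply(templates, `[[`, "", "residues"),
      vapply(templates, `[[`, "", "label"))
  target_label <- names(templates)[[1L]]
  warn <- if (length(templates) == 1L)
    "no homologues available: specificity passes trivially" else NULL
  rows <- list()
  calls <- list()
  pairs <- solution$pairs
  for (i in seq_len(nrow(pairs))) {
    cc <- simulate_pcr(pairs[i, , drop = FALSE], templates, ...)
    amp <- unique(cc$template_label[cc$amplifies])
    pass <- identical(sort(amp), sort(target_label))
    rows[[length(rows) + 1L]] <- data.frame(
      product_start = pairs$product_start[i],
      product_end = pairs$product_end[i],
      n_templates = length(templates),
      target_amplifies = target_label %in% amp,
      off_targets = paste(setdiff(amp, target_label), collapse = ","),
      pass = pass)
    calls[[length(calls) + 1L]] <- cc
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(product_start = integer(), product_end = integer(),
               n_templates = integer(), target_amplifies = logical(),
               off_targets = character(), pass = logical())
  structure(list(table = tab,
                 calls = if (length(calls)) do.call(rbind, calls) else NULL,
                 all_pass = all(tab$pass), warning = warn),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("<specificity_report> ", nrow(x$table), " pair(s): ",
      if (isTRUE(x$all_pass)) "all PASS" else "FAILURES present", "\n",
      sep = "")
  if (nrow(x$table)) {
    for (i in seq_len(nrow(x$table)))
      cat(sprintf("  %d-%d: %s%s\n", x$table$product_start[i],
                  x$table$product_end[i],
                  if (x$table$pass[i]) "PASS" else "FAIL",
                  if (nzchar(x$table$off_targets[i]))
                    paste0(" (off-target: ", x$table$off_targets[i], ")")
                  else ""))
  }
  if (!is.null(x$warning)) cat("  note: ", x$warning, "\n", sep = "")
  invisible(x)
}
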