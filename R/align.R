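#' Pairwise alignment with the pipeline's nucleotide scoring
#'
#' Affine-gap alignment with match +5, mismatch -4, gap open 10 and gap
#' extend 0.5 (a gap of length L costs `10 + 0.5 * L`). Local alignments
#' are used when building the multiple alignment so that partial homologues
#' and non-homologous flanks are left unaligned rather than forced together.
#'
#' @param pattern,subject Character scalars (DNA).
#' @param type `"global"` or `"local"`.
#' @param gap_opening,gap_extension Affine gap costs (a gap of length L
#'   costs `gap_opening + L * gap_extension`).
#' @return List with `score`, gapped `pattern` and `subject` strings, and
#'   the 1-based aligned ranges `p_start`, `p_end`, `s_start`, `s_end`.
#' @export
pairwise_align <- function(pattern, subject, type = c("global", "local"),
                           gap_opening = 10, gap_extension = 0.5) {
  type <- match.arg(type)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 5, mismatch = -4, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pattern),
    subject = Biostrings::DNAString(subject),
    type = type, substitutionMatrix = submat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  list(score = Biostrings::score(al),
       pattern = as.character(Biostrings::alignedPattern(al)),
       subject = as.character(Biostrings::alignedSubject(al)),
       p_start = IRanges::start(Biostrings::pattern(al)),
       p_end = IRanges::end(Biostrings::pattern(al)),
       s_start = IRanges::start(Biostrings::subject(al)),
       s_end = IRanges::end(Biostrings::subject(al)))
}

# Insertion profile of one pairwise alignment relative to the centre:
# slot p (0..n) counts pattern characters inserted between centre position p
# and p+1. Returns list(ins, pos_chr, slot_str): per-slot inserted strings
# and the aligned pattern character at each covered centre position.
.alignment_profile <- function(al, n) {
  P <- strsplit(al$pattern, "", fixed = TRUE)[[1L]]
  S <- strsplit(al$subject, "", fixed = TRUE)[[1L]]
  ins <- integer(n + 1L)
  slot_str <- character(n + 1L)
  slot_str[] <- ""
  pos_chr <- rep("-", n)
  cons <- al$s_start - 1L
  buf <- character(0)
  for (col in seq_along(S)) {
    if (S[col] == "-") {
      buf <- c(buf, P[col])
    } else {
      cons <- cons + 1L
      if (length(buf)) {
        ins[cons] <- length(buf)            # slot index cons == slot cons-1
        slot_str[cons] <- paste(buf, collapse = "")
        buf <- character(0)
      }
      pos_chr[cons] <- P[col]
    }
  }
  if (length(buf)) {                        # trailing insertion (rare)
    ins[cons + 1L] <- length(buf)
    slot_str[cons + 1L] <- paste(buf, collapse = "")
  }
  list(ins = ins, slot_str = slot_str, pos_chr = pos_chr)
}

.render_row <- function(slot_str, pos_chr, M) {
  n <- length(pos_chr)
  pads <- vapply(seq_len(n + 1L), function(i)
    paste0(slot_str[i], strrep("-", M[i] - nchar(slot_str[i]))), "")
  v <- character(2L * n + 1L)
  v[seq(1L, 2L * n + 1L, by = 2L)] <- pads
  v[seq(2L, 2L * n, by = 2L)] <- pos_chr
  paste(v, collapse = "")
}

#' Build the multiple sequence alignment of target and homologues
#'
#' The internal backend is a centre-star progressive alignment with the
#' target as centre: every other sequence is aligned to the target with a
#' local affine-gap alignment (see [pairwise_align()]) and the pairwise gap
#' patterns are merged, inserting the union of target-relative insertions.
#' Sequence regions a local alignment leaves unaligned (non-homologous
#' flanks, the missing ends of partial homologues) appear as leading or
#' trailing gap runs in that row. External backends (`"muscle"`,
#' `"dialign"`, `"mafft"`) shell out to the named binary when it is on the
#' PATH and fail with a clear error when it is not; row order is restored
#' to the input order.
#'
#' @param seqs A list of `extracted_sequence` objects (target first) or a
#'   named character vector (first element treated as the target).
#' @param backend `"internal"`, `"muscle"`, `"dialign"` or `"mafft"`.
#' @return An object of class `msa`: list with `rows` (named gapped
#'   character vector), `labels`, `roles`, `target_row` (index, always 1),
#'   `n_columns`.
#' @export
align_sequences <- function(seqs, backend = c("internal", "muscle",
                                              "dialign", "mafft")) {
  backend <- match.arg(backend)
  if (inherits(seqs, "extracted_sequence")) seqs <- list(seqs)
  if (is.character(seqs)) {
    labels <- names(seqs)
    roles <- c("target_locus", rep("homologue", length(seqs) - 1L))
    resid <- unname(seqs)
  } else {
    labels <- vapply(seqs, `[[`, "", "label")
    roles <- vapply(seqs, `[[`, "", "role")
    resid <- vapply(seqs, `[[`, "", "residues")
  }
  if (length(resid) == 0L) stop("no sequences to align")
  if (any(!nzchar(resid))) stop("cannot align empty sequences")
  if (roles[[1L]] != "target_locus")
    stop("the first sequence must be the target locus")
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = "#")

  if (length(resid) == 1L) {
    rows <- stats::setNames(resid, labels)
  } else if (backend == "internal") {
    target <- resid[[1L]]
    n <- nchar(target)
    # stiffer gap costs for the star legs: with cheap extension a local
    # alignment chains non-homologous flank DNA through long gaps (aligning
    # only chance matches), which poisons downstream SNP evidence
    alns <- lapply(resid[-1L], pairwise_align, subject = target,
                   type = "local", gap_opening = 15, gap_extension = 2.5)
    profs <- lapply(alns, .alignment_profile, n = n)
    M <- Reduce(pmax, lapply(profs, `[[`, "ins"), integer(n + 1L))
    tchars <- strsplit(target, "", fixed = TRUE)[[1L]]
    rows <- c(.render_row(character(n + 1L), tchars, M),
              vapply(profs, function(p)
                .render_row(p$slot_str, p$pos_chr, M), ""))
    names(rows) <- labels
  } else {
    rows <- .external_align(stats::setNames(resid, labels), backend)
    rows <- rows[labels]
  }
  structure(list(rows = rows, labels = labels, roles = roles,
                 target_row = 1L, n_columns = nchar(rows[[1L]])),
            class = "msa")
}

.external_align <- function(seqs, backend) {
  bin <- switch(backend, muscle = "muscle", mafft = "mafft",
                dialign = "dialign2-2")
  if (!nzchar(Sys.which(bin)))
    stop("alignment backend unavailable: '", bin, "' not found on PATH; ",
         "use backend = \"internal\" or install the binary")
  fin <- tempfile(fileext = ".fa")
  fout <- tempfile(fileext = ".fa")
  write_fasta(seqs, fin)
  status <- switch(backend,
    muscle = system2(bin, c("-align", fin, "-output", fout),
                     stdout = FALSE, stderr = FALSE),
    mafft = {
      out <- system2(bin, c("--auto", "--quiet", fin), stdout = TRUE)
      writeLines(out, fout); 0L
    },
    dialign = system2(bin, c("-fa", "-fn", sub("\\.fa$", "", fout), fin),
                      stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) && !file.exists(fout))
    stop("alignment backend '", bin, "' failed")
  read_alignment(fout)
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$rows), " rows x ", x$n_columns, " columns\n",
      sep = "")
  for (i in seq_along(x$rows))
    cat(sprintf("  [%d] %-12s %s\n", i, x$roles[i], x$labels[i]))
  invisible(x)
}

#' Ungapped content of an alignment row
#' @param msa An `msa` object.
#' @param row Row index.
#' @return Character scalar with gaps removed.
#' @export
ungapped_row <- function(msa, row = 1L) {
  gsub("-", "", msa$rows[[row]], fixed = TRUE)
}

#' Locate the bare input sequence inside the aligned flanked target
#'
#' The flank buffers mean that alignment columns cover more than the input
#' sequence; primer products, however, must cover the input itself. This
#' maps the bare input to both the target-coordinate interval and the
#' alignment-column interval it occupies.
#'
#' @param msa An `msa` object.
#' @param bare_input Character scalar: the original input sequence.
#' @return List with `target` (0-based half-open interval on the ungapped
#'   target) and `columns` (0-based half-open alignment-column interval).
#' @export
locate_input_region <- function(msa, bare_input) {
  target <- ungapped_row(msa, msa$target_row)
  bare <- toupper(gsub("-", "", bare_input, fixed = TRUE))
  hitpos <- gregexpr(bare, target, fixed = TRUE)[[1L]]
  if (identical(as.integer(hitpos), -1L))
    stop("input sequence not found in the extracted target locus; ",
         "the wrong locus may have been selected")
  if (length(hitpos) > 1L)
    stop("input sequence occurs ", length(hitpos),
         " times in the extracted target locus")
  t0 <- as.integer(hitpos) - 1L
  t1 <- t0 + nchar(bare)
  trow <- strsplit(msa$rows[[msa$target_row]], "", fixed = TRUE)[[1L]]
  colpos <- which(trow != "-")          # column (1-based) of target char i
  list(target = c(t0, t1),
       columns = c(colpos[t0 + 1L] - 1L, colpos[t1]))
}
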