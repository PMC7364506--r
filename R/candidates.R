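#' Generate SNP-anchored primer candidates
#'
#' For every usable discriminating SNP and every length in
#' `[len_min, len_max]`, emits one forward candidate whose 3' base sits on
#' the SNP and one reverse candidate whose 3' end sits on the SNP on the
#' reverse strand. Candidates that would run off the sequence or contain N
#' are dropped; the rest are scored (Tm, GC, self-complementarity, hairpin,
#' penalty).
#'
#' @param snps SNP table from [scan_snps()]; only rows with
#'   `discriminating = TRUE` and `varietal_conflict = FALSE` are used.
#' @param target Character scalar: the flanked target sequence the SNP
#'   `target_pos` coordinates refer to, or an `extracted_sequence`.
#' @param params A `design_parameters` object.
#' @return A data frame of candidates: `direction` (`F`/`R`), `anchor_pos`
#'   (0-based target position of the SNP), `anchor_col`, `gap_discriminated`,
#'   `start`, `end` (0-based half-open on the forward strand), `length`,
#'   `sequence` (5'->3'), `tm`, `gc`, `self_any`, `self_end`, `hairpin`,
#'   `penalty`.
#' @export
generate_candidates <- function(snps, target, params = design_parameters()) {
  if (inherits(target, "extracted_sequence")) target <- target$residues
  n <- nchar(target)
  use <- snps[snps$discriminating & !snps$varietal_conflict, , drop = FALSE]
  rows <- list()
  lens <- seq(params$len_min, params$len_max)
  for (i in seq_len(nrow(use))) {
    p <- use$target_pos[[i]]
    col <- use$column[[i]]
    gd <- use$gap_discriminated[[i]]
    for (L in lens) {
      # forward: occupies [p - L + 1, p + 1), 3' base at p
      if (p - L + 1L >= 0L) {
        seqF <- substr(target, p - L + 2L, p + 1L)
        rows[[length(rows) + 1L]] <- list(direction = "F", anchor_pos = p,
                                          anchor_col = col,
                                          gap_discriminated = gd,
                                          start = p - L + 1L, end = p + 1L,
                                          length = L, sequence = seqF)
      }
      # reverse: occupies [p, p + L) on the forward strand, 3' base at p
      if (p + L <= n) {
        seqR <- revcomp(substr(target, p + 1L, p + L))
        rows[[length(rows) + 1L]] <- list(direction = "R", anchor_pos = p,
                                          anchor_col = col,
                                          gap_discriminated = gd,
                                          start = p, end = p + L,
                                          length = L, sequence = seqR)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_candidates())
  cand <- do.call(rbind, lapply(rows, as.data.frame))
  cand <- cand[!grepl("N", cand$sequence, fixed = TRUE), , drop = FALSE]
  if (nrow(cand) == 0L) return(.empty_candidates())
  score_candidates(cand, params)
}

.empty_candidates <- function() {
  data.frame(direction = character(), anchor_pos = integer(),
             anchor_col = integer(), gap_discriminated = logical(),
             start = integer(), end = integer(), length = integer(),
             sequence = character(), tm = numeric(), gc = numeric(),
             self_any = numeric(), self_end = numeric(), hairpin = numeric(),
             penalty = numeric())
}

#' Score a table of primer candidates
#'
#' Adds `tm`, `gc`, `self_any`, `self_end`, `hairpin` and `penalty` columns.
#'
#' @param cand Data frame with at least `sequence`, `length` and (optional)
#'   `gap_discriminated` columns.
#' @param params A `design_parameters` object.
#' @return The scored data frame.
#' @export
score_candidates <- function(cand, params = design_parameters()) {
  cand$tm <- vapply(cand$sequence, melting_temperature, 0,
                    monovalent_mM = params$monovalent_mM,
                    primer_nM = params$primer_nM, USE.NAMES = FALSE)
  cand$gc <- vapply(cand$sequence, gc_percent, 0, USE.NAMES = FALSE)
  comp <- t(vapply(cand$sequence, complementarity_scores,
                   c(self_any = 0, self_end = 0, hairpin = 0),
                   USE.NAMES = FALSE))
  cand$self_any <- comp[, 1L]
  cand$self_end <- comp[, 2L]
  cand$hairpin <- comp[, 3L]
  gd <- if ("gap_discriminated" %in% names(cand)) cand$gap_discriminated
        else FALSE
  cand$penalty <- primer_penalty(cand$tm, cand$length, cand$gc,
                                 cand$self_any, cand$self_end, cand$hairpin,
                                 gd, params)
  rownames(cand) <- NULL
  cand
}
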