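#' Classify alignment columns as discriminating SNPs
#'
#' A column is a usable specificity anchor only when the target base differs
#' from the base of *every* homologue row with evidence at that column: a
#' single matching homologue would still be extended by the polymerase, so a
#' 3'-anchored primer there would not be homologue-specific.
#'
#' Evidence handling:
#' * Columns inside a homologue's leading or trailing gap run (before its
#'   first or after its last aligned base) carry no evidence from that row --
#'   a partial homologue neither confirms nor denies a SNP outside its
#'   aligned extent, and the unaligned copy can still amplify elsewhere.
#'   Columns where *no* homologue has evidence are not discriminating.
#' * An internal gap in a homologue counts as a difference but the column is
#'   flagged `gap_discriminated`; indel-anchored 3' ends behave less
#'   predictably and are deprioritised by a penalty bonus downstream.
#' * Any homologue showing N makes the column non-discriminating.
#' * Rows extracted from an additional variety of the same species are
#'   compared separately: a difference there is a varietal SNP, flagged
#'   `varietal_conflict` and never used as an anchor, because the variety
#'   being cloned may not carry it.
#'
#' Evidence is further restricted to columns where the row is credibly
#' homologous to the target: a sliding window of `evidence_window` columns
#' must show at least `evidence_identity` identity to the target row.
#' Cheap affine gap extension lets a local alignment chain non-homologous
#' flank sequence (e.g. the random neighbourhood of a partial homologue)
#' through long gaps; without the identity mask such junk regions would
#' both claim spurious discrimination and, by chance matches, veto genuine
#' anchors.
#'
#' @param msa An `msa` object (roles `target_locus`, `homologue`,
#'   `extra_genome`).
#' @param evidence_window Width (columns) of the identity window.
#' @param evidence_identity Minimum window identity for a row to count as
#'   evidence at a column.
#' @return A data frame with one row per alignment column whose target base
#'   is A/C/G/T: `column` (0-based), `target_pos` (0-based position on the
#'   ungapped target), `target_base`, `homologue_bases` (comma-separated
#'   evidence), `n_evidence`, `discriminating`, `gap_discriminated`,
#'   `varietal_conflict`.
#' @export
scan_snps <- function(msa, evidence_window = 61L, evidence_identity = 0.5) {
  mat <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  tgt <- mat[msa$target_row, ]
  hom_rows <- which(msa$roles == "homologue")
  extra_rows <- which(msa$roles == "extra_genome")
  if (length(hom_rows) == 0L)
    warning("alignment has no homologue rows; no column can discriminate")

  nc <- ncol(mat)
  hw <- evidence_window %/% 2L
  covers <- function(i) {
    nz <- which(mat[i, ] != "-")
    if (length(nz) == 0L) return(rep(FALSE, nc))
    ext <- seq_len(nc) >= nz[1L] & seq_len(nc) <= nz[length(nz)]
    # pair columns of this row vs the target: ignore columns where both
    # are gaps (they belong to other rows' insertions)
    pcols <- which(mat[i, ] != "-" | tgt != "-")
    np <- length(pcols)
    if (np == 0L) return(rep(FALSE, nc))
    mt <- as.numeric(mat[i, pcols] == tgt[pcols] & mat[i, pcols] != "-")
    cs <- c(0, cumsum(mt))
    lo <- pmax(1L, seq_len(np) - hw)
    hi <- pmin(nc, pmin(np, seq_len(np) + hw))
    ident_p <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    ident <- rep(FALSE, nc)
    ident[pcols] <- ident_p >= evidence_identity
    ext & ident
  }

  keep <- tgt %in% c("A", "C", "G", "T")
  cols <- which(keep)
  tpos <- cumsum(tgt != "-") - 1L          # 0-based ungapped target position

  n_ev <- integer(ncol(mat))
  all_diff <- rep(TRUE, ncol(mat))
  any_n <- rep(FALSE, ncol(mat))
  any_gap <- rep(FALSE, ncol(mat))
  ev_base <- matrix("", nrow = length(hom_rows), ncol = ncol(mat))
  for (k in seq_along(hom_rows)) {
    i <- hom_rows[k]
    cv <- covers(i)
    b <- mat[i, ]
    n_ev <- n_ev + cv
    all_diff <- all_diff & (!cv | b != tgt)
    any_n <- any_n | (cv & b == "N")
    any_gap <- any_gap | (cv & b == "-")
    ev_base[k, cv] <- b[cv]
  }
  discriminating <- keep & n_ev > 0L & all_diff & !any_n

  varietal <- rep(FALSE, ncol(mat))
  for (i in extra_rows) {
    cv <- covers(i)
    varietal <- varietal | (cv & mat[i, ] != tgt)
  }

  hb <- apply(ev_base, 2L, function(col) paste(col[nzchar(col)],
                                               collapse = ","))
  data.frame(column = cols - 1L,
             target_pos = tpos[cols],
             target_base = tgt[cols],
             homologue_bases = hb[cols],
             n_evidence = n_ev[cols],
             discriminating = discriminating[cols],
             gap_discriminated = discriminating[cols] & any_gap[cols],
             varietal_conflict = varietal[cols],
             row.names = NULL)
}
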