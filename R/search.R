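#' Internal seed-and-extend homology search
#'
#' A self-contained similarity search used when no precomputed tabular
#' report is supplied: exact seed words of the query are matched against
#' each genome record on both strands, seed matches are clustered along the
#' subject, and each cluster is resolved by a local alignment
#' (match +2, mismatch -3, gap open 5, gap extend 2). Scores are mapped to
#' bitscores with fixed Karlin-Altschul-style constants
#' (lambda = 0.625, K = 0.41): `bits = (lambda * S - ln K) / ln 2`. The
#' search reliably reports regions of >= 85% identity and >= 200 bases;
#' fidelity to any external tool's scores is not a goal -- only the ranking
#' behaviour of the resulting hit groups matters.
#'
#' @param query Named character scalar (name = query id) or a plain string.
#' @param index A `genome_index`.
#' @param word_size Seed word size.
#' @param min_seeds Minimum seed matches for a cluster to be aligned.
#' @param cluster_gap Maximum subject gap between seeds in one cluster.
#' @param min_aln_length,min_bitscore Reporting thresholds.
#' @return A hit table in the 12-column tabular layout (1-based inclusive
#'   coordinates; minus-strand hits have `s_start > s_end`).
#' @export
internal_search <- function(query, index, word_size = 11, min_seeds = 2,
                            cluster_gap = 1000, min_aln_length = 30,
                            min_bitscore = 50) {
  qid <- if (!is.null(names(query))) names(query)[[1L]] else "query"
  qseq <- toupper(unname(query[[1L]]))
  qlen <- nchar(qseq)
  if (qlen < word_size) stop("query shorter than word size")
  lambda <- 0.625; K <- 0.41
  genome_len <- sum(as.numeric(index$lengths))
  tiles <- Biostrings::DNAStringSet(
    vapply(seq_len(qlen - word_size + 1L),
           function(i) substr(qseq, i, i + word_size - 1L), ""))
  pd <- Biostrings::PDict(tiles)
  qdna <- Biostrings::DNAString(qseq)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = TRUE)
  rows <- list()

  scan_strand <- function(chrom, seq_fwd, strand) {
    L <- nchar(seq_fwd)
    subj <- if (strand == "+") Biostrings::DNAString(seq_fwd) else
      Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd))
    mi <- Biostrings::matchPDict(pd, subj)
    spos <- sort(unlist(IRanges::start(mi), use.names = FALSE))
    if (length(spos) < min_seeds) return()
    brk <- c(TRUE, diff(spos) > cluster_gap)
    cl <- cumsum(brk)
    for (idx in split(spos, cl)) {
      if (length(idx) < min_seeds) next
      w0 <- max(1L, min(idx) - 300L)
      w1 <- min(L, max(idx) + word_size + 300L)
      win <- Biostrings::subseq(subj, w0, w1)
      al <- Biostrings::pairwiseAlignment(
        pattern = qdna, subject = win, type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(al)
      bits <- (lambda * sc - log(K)) / log(2)
      alen <- nchar(as.character(Biostrings::alignedPattern(al)))
      if (alen < min_aln_length || bits < min_bitscore) next
      nmm <- Biostrings::nmismatch(al)
      nmatch <- Biostrings::nmatch(al)
      ins <- Biostrings::insertion(al)[[1L]]
      del <- Biostrings::deletion(al)[[1L]]
      gapo <- length(ins) + length(del)
      qs <- IRanges::start(Biostrings::pattern(al))
      qe <- IRanges::end(Biostrings::pattern(al))
      ss <- IRanges::start(Biostrings::subject(al)) + w0 - 1L
      se <- IRanges::end(Biostrings::subject(al)) + w0 - 1L
      if (strand == "-") {  # map coordinates on the reverse strand back
        tmp <- ss
        ss <- L - ss + 1L
        se <- L - se + 1L   # ss > se encodes minus strand
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        query_id = qid, subject_id = chrom,
        pct_identity = round(100 * nmatch / alen, 3),
        aln_length = alen, mismatches = nmm, gap_opens = gapo,
        q_start = qs, q_end = qe, s_start = ss, s_end = se,
        e_value = K * qlen * genome_len * 2^(-bits),
        bitscore = round(bits, 1))
    }
  }

  for (chrom in names(index$lengths)) {
    seq_fwd <- as.character(
      slice_genome(index, chrom, 0L, unname(index$lengths[[chrom]])))
    scan_strand(chrom, seq_fwd, "+")
    scan_strand(chrom, seq_fwd, "-")
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits[!duplicated(hits[, c("subject_id", "q_start", "q_end",
                            "s_start", "s_end")]), , drop = FALSE]
}
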