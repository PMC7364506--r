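#' Chain tabular hits into candidate-locus groups
#'
#' A similarity search reports a locus as several local-alignment fragments
#' (HSPs). Hits sharing the query, subject and strand are chained into one
#' group when, after sorting by subject position, the gap between consecutive
#' subject intervals (end of one to start of the next) is at most
#' `max_group_gap` bases. Each group carries summary statistics used for
#' ranking and homologue selection.
#'
#' @param hits Hit table (one query); see [parse_blast_tabular()].
#' @param max_group_gap Maximum chaining gap in bases (default 1000).
#' @param query_length Query length used for coverage; defaults to
#'   `max(q_end)` over all hits.
#' @return A list of `hit_group` objects, each with elements `subject_id`,
#'   `strand`, `hits` (the member rows), `s_min`, `s_max` (0-based half-open
#'   subject span), `mean_bitscore`, `total_bitscore`, `query_coverage`.
#' @export
group_hits <- function(hits, max_group_gap = 1000, query_length = NULL) {
  if (nrow(hits) == 0L) return(list())
  if (length(unique(hits$query_id)) != 1L)
    stop("group_hits expects hits from a single query")
  h <- normalize_hits(hits)
  qlen <- if (is.null(query_length)) max(h$q_max) else query_length
  out <- list()
  for (key in split(seq_len(nrow(h)),
                    list(h$subject_id, h$strand), drop = TRUE)) {
    sub <- h[key, , drop = FALSE]
    sub <- sub[order(sub$s_min, sub$s_max), , drop = FALSE]
    run_max <- cummax(sub$s_max)
    newgrp <- c(TRUE, sub$s_min[-1L] - run_max[-nrow(sub)] > max_group_gap)
    gid <- cumsum(newgrp)
    for (g in split(seq_len(nrow(sub)), gid)) {
      rows <- sub[g, , drop = FALSE]
      qiv <- IRanges::reduce(IRanges::IRanges(rows$q_min + 1L, rows$q_max))
      out[[length(out) + 1L]] <- structure(list(
        subject_id = rows$subject_id[[1L]],
        strand = rows$strand[[1L]],
        hits = rows,
        s_min = min(rows$s_min),
        s_max = max(rows$s_max),
        mean_bitscore = mean(rows$bitscore),
        total_bitscore = sum(rows$bitscore),
        query_coverage = sum(IRanges::width(qiv)) / qlen),
        class = "hit_group")
    }
  }
  out
}

#' @export
print.hit_group <- function(x, ...) {
  cat(sprintf("<hit_group> %s:%d-%d (%s)  %d hit(s)  total bitscore %.1f  mean %.1f  coverage %.2f\n",
              x$subject_id, x$s_min, x$s_max, x$strand, nrow(x$hits),
              x$total_bitscore, x$mean_bitscore, x$query_coverage))
  invisible(x)
}

#' Rank hit groups by relatedness to the query
#'
#' Groups are ordered by descending total bitscore -- the group most closely
#' related to the input over its full length is taken as the genomic
#' representation of the query. Ties fall back to query coverage, then to
#' `(subject_id, s_min)` lexicographically so the order is deterministic.
#'
#' @param groups List of `hit_group` objects.
#' @return The same list, ranked.
#' @export
rank_groups <- function(groups) {
  if (length(groups) == 0L) return(groups)
  tot <- vapply(groups, `[[`, 0, "total_bitscore")
  cov <- vapply(groups, `[[`, 0, "query_coverage")
  subj <- vapply(groups, `[[`, "", "subject_id")
  smin <- vapply(groups, `[[`, 0, "s_min")
  groups[order(-tot, -cov, subj, smin)]
}

#' Select the target-locus group and homologue groups
#'
#' The top-ranked group becomes the target locus. Up to
#' `n_homologue_groups` further groups are retained as homologues provided
#' their within-group mean bitscore exceeds `bitscore_floor`; the rest are
#' recorded with a discard reason.
#'
#' @param ranked Ranked list of `hit_group` objects (see [rank_groups()]).
#' @param n_homologue_groups Maximum homologue groups to keep.
#' @param bitscore_floor Mean-bitscore threshold homologues must exceed.
#' @return A list with elements `target` (a `hit_group`), `homologues`
#'   (list of `hit_group`) and `discarded` (list of `list(group, reason)`).
#' @export
select_loci <- function(ranked, n_homologue_groups = 3, bitscore_floor = 200) {
  if (length(ranked) == 0L) stop("no hit groups: query not found in genome")
  target <- ranked[[1L]]
  homologues <- list()
  discarded <- list()
  for (g in ranked[-1L]) {
    if (length(homologues) >= n_homologue_groups) {
      discarded[[length(discarded) + 1L]] <-
        list(group = g, reason = "rank beyond requested homologue count")
    } else if (g$mean_bitscore <= bitscore_floor) {
      discarded[[length(discarded) + 1L]] <-
        list(group = g, reason = sprintf(
          "mean bitscore %.1f does not exceed floor %.0f",
          g$mean_bitscore, bitscore_floor))
    } else {
      homologues[[length(homologues) + 1L]] <- g
    }
  }
  if (length(homologues) == 0L)
    warning("no homologues found: every non-target group was discarded")
  list(target = target, homologues = homologues, discarded = discarded)
}

#' Extract the flanked genomic sequence of a hit group
#'
#' The subject span of the group is widened by the start and end buffers,
#' clamped to the chromosome, and fetched. Minus-strand groups are
#' reverse-complemented (and the buffers swapped) so the returned residues
#' read in query orientation, with "start" meaning the query-5' side.
#'
#' @param group A `hit_group`.
#' @param index A `genome_index` containing the group's subject.
#' @param start_buffer,end_buffer Flank sizes in bases (query orientation).
#' @param label Sequence label; defaults to `subject:span(strand)`.
#' @param genome_label Label of the source genome.
#' @param role One of `"target_locus"`, `"homologue"`, `"extra_genome"`.
#' @return An `extracted_sequence`: list with `label`, `genome_label`,
#'   `chrom`, `start`, `end` (0-based half-open on the forward strand),
#'   `strand`, `residues` (query orientation), `role`, `clamped`.
#' @export
extract_flanked <- function(group, index, start_buffer = 1000,
                            end_buffer = 1000, label = NULL,
                            genome_label = "genome",
                            role = c("homologue", "target_locus",
                                     "extra_genome")) {
  role <- match.arg(role)
  if (!group$subject_id %in% names(index$lengths))
    stop("subject '", group$subject_id, "' absent from genome ", index$path)
  if (group$strand == "+") {
    a <- group$s_min - start_buffer
    b <- group$s_max + end_buffer
  } else {
    a <- group$s_min - end_buffer
    b <- group$s_max + start_buffer
  }
  sl <- slice_genome(index, group$subject_id, a, b)
  res <- as.character(sl)
  if (group$strand == "-") res <- revcomp(res)
  if (is.null(label))
    label <- sprintf("%s:%d-%d(%s)", group$subject_id,
                     attr(sl, "start"), attr(sl, "end"), group$strand)
  structure(list(label = label, genome_label = genome_label,
                 chrom = group$subject_id,
                 start = attr(sl, "start"), end = attr(sl, "end"),
                 strand = group$strand, residues = res, role = role,
                 clamped = attr(sl, "clamped")),
            class = "extracted_sequence")
}

#' @export
print.extracted_sequence <- function(x, ...) {
  cat(sprintf("<extracted_sequence> %s [%s] %s:%d-%d(%s) %d bases%s\n",
              x$label, x$role, x$chrom, x$start, x$end, x$strand,
              nchar(x$residues), if (isTRUE(x$clamped)) " (clamped)" else ""))
  invisible(x)
}
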