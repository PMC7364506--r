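#' Enumerate admissible primer pairs
#'
#' Combines forward and reverse candidates into pairs whose product size
#' (`reverse end - forward start`, half-open) lies within
#' `[product_min, product_max]`, scoring each with [pair_penalty()]. With
#' `cap_per_anchor = TRUE` (the default used by the pipeline) only the
#' best-penalty candidate per (direction, anchor) enters the enumeration,
#' so each SNP pair contributes a single pair -- the full quadratic-by-length
#' combination space is otherwise prohibitively large, and the complete
#' candidate table is still reported to the user separately.
#'
#' @param candidates Scored candidate table from [generate_candidates()].
#' @param params A `design_parameters` object.
#' @param cap_per_anchor Keep only the best length per (direction, anchor)
#'   before pairing.
#' @return Data frame of pairs: forward/reverse fields (`f_*`, `r_*`),
#'   `product_start`, `product_end`, `product_size`, `cross_dimer`,
#'   `pair_penalty`, sorted by `(product_start, product_size, f_sequence)`.
#' @export
enumerate_pairs <- function(candidates, params = design_parameters(),
                            cap_per_anchor = TRUE) {
  fw <- candidates[candidates$direction == "F", , drop = FALSE]
  rv <- candidates[candidates$direction == "R", , drop = FALSE]
  pick_best <- function(d) {
    if (nrow(d) == 0L) return(d)
    d <- d[order(d$anchor_pos, d$penalty, d$length, d$sequence), ,
           drop = FALSE]
    d[!duplicated(d$anchor_pos), , drop = FALSE]
  }
  if (cap_per_anchor) {
    fw <- pick_best(fw)
    rv <- pick_best(rv)
  }
  if (nrow(fw) == 0L || nrow(rv) == 0L) return(.empty_pairs())
  out <- list()
  for (i in seq_len(nrow(fw))) {
    size <- rv$end - fw$start[[i]]
    ok <- which(size >= params$product_min & size <= params$product_max &
                  rv$start >= fw$end[[i]])
    if (length(ok) == 0L) next
    f <- fw[i, , drop = FALSE]
    r <- rv[ok, , drop = FALSE]
    cross <- vapply(r$sequence, cross_dimer_score, 0, a = f$sequence,
                    USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      f_sequence = f$sequence, f_start = f$start, f_end = f$end,
      f_anchor = f$anchor_pos, f_tm = f$tm, f_gc = f$gc,
      f_penalty = f$penalty,
      r_sequence = r$sequence, r_start = r$start, r_end = r$end,
      r_anchor = r$anchor_pos, r_tm = r$tm, r_gc = r$gc,
      r_penalty = r$penalty,
      product_start = f$start, product_end = r$end,
      product_size = size[ok], cross_dimer = cross,
      pair_penalty = pair_penalty(f$penalty, r$penalty, f$tm, r$tm,
                                  cross, params))
  }
  if (length(out) == 0L) return(.empty_pairs())
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$product_start, pairs$product_size,
                       pairs$f_sequence), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

.empty_pairs <- function() {
  data.frame(f_sequence = character(), f_start = integer(),
             f_end = integer(), f_anchor = integer(), f_tm = numeric(),
             f_gc = numeric(), f_penalty = numeric(),
             r_sequence = character(), r_start = integer(),
             r_end = integer(), r_anchor = integer(), r_tm = numeric(),
             r_gc = numeric(), r_penalty = numeric(),
             product_start = integer(), product_end = integer(),
             product_size = integer(), cross_dimer = numeric(),
             pair_penalty = numeric())
}

#' Choose the minimal-penalty set of overlapping products covering the input
#'
#' Interval-cover optimisation over the enumerated pairs: pick products so
#' that the first starts at or before the input region, the last ends at or
#' after it, and consecutive products overlap by at least `min_overlap`
#' bases, minimising the total pair penalty. Solved exactly as a shortest
#' path over the DAG whose nodes are products (sorted by start) and whose
#' edges are admissible successions; ties are broken by the deterministic
#' `(product_start, product_size, forward sequence)` node order. When no
#' full cover exists, a greedy rightmost-reach partial cover is returned
#' with `covered = FALSE` and the uncovered intervals listed.
#'
#' @param pairs Pair table from [enumerate_pairs()].
#' @param input_region Length-2 integer vector: 0-based half-open interval
#'   of the bare input on the (flanked) target.
#' @param params A `design_parameters` object.
#' @return An object of class `tiling_solution`: list with `pairs` (selected
#'   rows in product order), `sequencing` (filled by
#'   [place_sequencing_primers()]), `covered`, `coverage_gaps` (data frame
#'   `start`/`end`), `total_penalty`, `input_region`.
#' @export
select_tiling <- function(pairs, input_region, params = design_parameters()) {
  in_start <- input_region[[1L]]
  in_end <- input_region[[2L]]
  sol <- function(sel, covered, gaps, total) {
    structure(list(pairs = sel, sequencing = NULL, covered = covered,
                   coverage_gaps = gaps, total_penalty = total,
                   input_region = c(in_start, in_end), params = params),
              class = "tiling_solution")
  }
  no_gaps <- data.frame(start = integer(), end = integer())
  if (nrow(pairs) == 0L)
    return(sol(pairs, FALSE,
               data.frame(start = in_start, end = in_end), Inf))
  ps <- pairs$product_start
  pe <- pairs$product_end
  pen <- pairs$pair_penalty
  n <- nrow(pairs)
  start_ok <- ps <= in_start & pe > in_start
  end_ok <- pe >= in_end
  dist <- ifelse(start_ok, pen, Inf)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    preds <- which(ps < ps[i] & pe - ps[i] >= params$min_overlap &
                     pe < pe[i] & is.finite(dist))
    if (length(preds)) {
      cand <- dist[preds] + pen[i]
      best <- which.min(cand)
      if (cand[best] < dist[i]) {
        dist[i] <- cand[best]
        parent[i] <- preds[best]
      }
    }
  }
  feas <- which(end_ok & is.finite(dist))
  if (length(feas)) {
    node <- feas[which.min(dist[feas])]
    chain <- integer(0)
    while (!is.na(node)) {
      chain <- c(node, chain)
      node <- parent[node]
    }
    return(sol(pairs[chain, , drop = FALSE], TRUE, no_gaps,
               sum(pen[chain])))
  }
  # greedy rightmost-reach partial cover
  chain <- integer(0)
  reach <- in_start
  gaps <- list()
  first <- TRUE
  repeat {
    lim <- if (first) in_start else reach - params$min_overlap
    cand <- which(ps <= lim & pe > reach)
    if (length(cand) == 0L) {
      nxt <- which(ps > lim & pe > reach)
      if (length(nxt) == 0L) break
      j <- nxt[order(ps[nxt], -pe[nxt], pen[nxt])][1L]
      gaps[[length(gaps) + 1L]] <-
        data.frame(start = max(reach, in_start), end = ps[j])
    } else {
      j <- cand[order(-pe[cand], pen[cand])][1L]
    }
    chain <- c(chain, j)
    reach <- pe[j]
    first <- FALSE
    if (reach >= in_end) break
  }
  if (reach < in_end)
    gaps[[length(gaps) + 1L]] <- data.frame(start = max(reach, in_start),
                                            end = in_end)
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(start = in_start, end = in_end)
  sel <- pairs[chain, , drop = FALSE]
  sol(sel, FALSE, gaps, sum(pen[chain]))
}

#' @export
print.tiling_solution <- function(x, ...) {
  cat("<tiling_solution> ", nrow(x$pairs), " product(s), ",
      if (isTRUE(x$covered)) "input fully covered"
      else sprintf("NOT covered (%d gap(s))", nrow(x$coverage_gaps)),
      sprintf(", total penalty %.2f\n", x$total_penalty), sep = "")
  if (nrow(x$pairs)) {
    for (i in seq_len(nrow(x$pairs)))
      cat(sprintf("  [%d] %d-%d (%d bases, penalty %.2f)\n", i,
                  x$pairs$product_start[i], x$pairs$product_end[i],
                  x$pairs$product_size[i], x$pairs$pair_penalty[i]))
  }
  if (!is.null(x$sequencing) && nrow(x$sequencing))
    cat("  +", nrow(x$sequencing), "internal sequencing primer(s)\n")
  invisible(x)
}

#' Place internal Sanger sequencing primers within a product
#'
#' A Sanger read is nominally `sanger_read` bases, of which the final
#' `sanger_trim` bases are discounted as low-quality, leaving
#' `usable = sanger_read - sanger_trim` trusted bases per read. The PCR
#' forward primer provides the first read; one internal forward primer is
#' placed near each subsequent multiple of `usable` so that
#' `ceiling(size / usable) - 1` internal primers give trusted, overlapping
#' reads across the whole product (consecutive read starts stay within
#' `sanger_read` of each other). Each primer is the lowest-penalty
#' unanchored forward candidate within `sanger_window` bases of its ideal
#' position; the amplicon is already allele-pure, so no SNP anchor is
#' needed, and all sequencing primers are forward primers. An empty window
#' is widened once (doubled); if still empty a warning is recorded.
#'
#' @param pair One row of a pair table (or a list with `product_start`,
#'   `product_end`).
#' @param target Flanked target sequence (character or
#'   `extracted_sequence`).
#' @param params A `design_parameters` object.
#' @return Data frame of sequencing primers: `split_index` (2, 3, ...),
#'   `sequence`, `start`, `end`, `length`, `tm`, `gc`, `penalty`,
#'   `product_start`, `product_end`, plus a `"warnings"` attribute.
#' @export
place_sequencing_primers <- function(pair, target,
                                     params = design_parameters()) {
  if (inherits(target, "extracted_sequence")) target <- target$residues
  ps <- pair$product_start[[1L]]
  pe <- pair$product_end[[1L]]
  size <- pe - ps
  usable <- params$sanger_read - params$sanger_trim
  k <- ceiling(size / usable) - 1L
  empty <- data.frame(split_index = integer(), sequence = character(),
                      start = integer(), end = integer(),
                      length = integer(), tm = numeric(), gc = numeric(),
                      penalty = numeric(), product_start = integer(),
                      product_end = integer())
  if (k <= 0L) return(empty)
  warns <- character(0)
  rows <- list()
  lens <- seq(params$len_min, params$len_max)
  for (i in seq_len(k)) {
    ideal <- ps + i * usable
    half <- params$sanger_window
    best <- NULL
    for (attempt in 1:2) {
      w0 <- max(ps, ideal - half)
      w1 <- min(pe - params$len_min, ideal + half)
      if (w1 >= w0) {
        grid <- expand.grid(start = w0:w1, length = lens)
        grid$end <- grid$start + grid$length
        grid <- grid[grid$end <= pe, , drop = FALSE]
        if (nrow(grid)) {
          grid$sequence <- substr(rep(target, nrow(grid)), grid$start + 1L,
                                  grid$end)
          grid <- grid[nchar(grid$sequence) == grid$length &
                         !grepl("N", grid$sequence, fixed = TRUE), ,
                       drop = FALSE]
        }
        if (nrow(grid)) {
          grid <- score_candidates(grid, params)
          grid <- grid[order(grid$penalty, grid$start, grid$length), ,
                       drop = FALSE]
          best <- grid[1L, , drop = FALSE]
          break
        }
      }
      half <- half * 2L   # widen once
    }
    if (is.null(best)) {
      warns <- c(warns, sprintf(
        "no acceptable sequencing primer near position %d of product %d-%d",
        ideal, ps, pe))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      split_index = i + 1L, sequence = best$sequence, start = best$start,
      end = best$end, length = best$length, tm = best$tm, gc = best$gc,
      penalty = best$penalty, product_start = ps, product_end = pe)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "warnings") <- warns
  out
}
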