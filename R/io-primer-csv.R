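#' Oligo names for a PCR product
#'
#' Names follow the convention `{prefix}.{product_start}-{product_end}.{F|R}`
#' for PCR primers and `{prefix}.{product_start}-{product_end}.split{k}.F`
#' for internal sequencing primers. The embedded coordinates behave as a
#' 0-based half-open interval, so the product size can be read directly off
#' the name as `product_end - product_start`.
#'
#' @param prefix Name prefix.
#' @param product_start,product_end Product interval (0-based half-open).
#' @param split `NULL` for the PCR pair, or the split index (2, 3, ...) of a
#'   sequencing primer.
#' @return For `split = NULL` a named character vector `c(F = , R = )`;
#'   otherwise the single sequencing-primer name.
#' @export
oligo_names <- function(prefix, product_start, product_end, split = NULL) {
  stem <- sprintf("%s.%d-%d", prefix, product_start, product_end)
  if (is.null(split))
    c(F = paste0(stem, ".F"), R = paste0(stem, ".R"))
  else
    paste0(stem, ".split", split, ".F")
}

#' Write a tiling solution as a primer CSV
#'
#' One row per oligo: both PCR primers of every selected pair followed by
#' the internal Sanger sequencing primers, with thermodynamic attributes.
#'
#' @param solution A `tiling_solution`.
#' @param path Output CSV path.
#' @param prefix Oligo name prefix.
#' @return The data frame written, invisibly.
#' @export
write_primer_csv <- function(solution, path, prefix = "target") {
  rows <- list()
  pr <- solution$pairs
  for (i in seq_len(nrow(pr))) {
    nm <- oligo_names(prefix, pr$product_start[i], pr$product_end[i])
    rows[[length(rows) + 1L]] <- data.frame(
      oligo_name = nm[["F"]], sequence_5to3 = pr$f_sequence[i],
      type = "PCR", direction = "F",
      product_start = pr$product_start[i], product_end = pr$product_end[i],
      product_size = pr$product_size[i],
      tm_celsius = round(pr$f_tm[i], 2), gc_percent = round(pr$f_gc[i], 2),
      penalty = round(pr$pair_penalty[i], 4))
    rows[[length(rows) + 1L]] <- data.frame(
      oligo_name = nm[["R"]], sequence_5to3 = pr$r_sequence[i],
      type = "PCR", direction = "R",
      product_start = pr$product_start[i], product_end = pr$product_end[i],
      product_size = pr$product_size[i],
      tm_celsius = round(pr$r_tm[i], 2), gc_percent = round(pr$r_gc[i], 2),
      penalty = round(pr$pair_penalty[i], 4))
  }
  sq <- solution$sequencing
  for (i in seq_len(NROW(sq))) {
    rows[[length(rows) + 1L]] <- data.frame(
      oligo_name = oligo_names(prefix, sq$product_start[i],
                               sq$product_end[i], sq$split_index[i]),
      sequence_5to3 = sq$sequence[i], type = "Sanger", direction = "F",
      product_start = sq$product_start[i], product_end = sq$product_end[i],
      product_size = sq$product_end[i] - sq$product_start[i],
      tm_celsius = round(sq$tm[i], 2), gc_percent = round(sq$gc[i], 2),
      penalty = round(sq$penalty[i], 4))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(oligo_name = character(), sequence_5to3 = character(),
               type = character(), direction = character(),
               product_start = integer(), product_end = integer(),
               product_size = integer(), tm_celsius = numeric(),
               gc_percent = numeric(), penalty = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
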