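BLAST_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end", "e_value", "bitscore")

#' Parse a 12-column tabular homology report
#'
#' Reads the standard 12-column tab-separated BLAST tabular dialect
#' (outfmt 6). A subject start greater than the subject end encodes a
#' minus-strand hit; [normalize_hits()] derives strand and 0-based
#' half-open subject spans from the printed 1-based inclusive coordinates.
#'
#' @param path Path to a tabular file; an empty file yields an empty table.
#' @return A data frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `e_value`, `bitscore`.
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("tabular hit file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("line ", which(nf != 12L)[1L], " of ", path, " has ",
         nf[nf != 12L][1L], " columns; expected the 12-column tabular format")
  m <- do.call(rbind, parts)
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     pct_identity = as.numeric(m[, 3L]),
                     aln_length = as.integer(m[, 4L]),
                     mismatches = as.integer(m[, 5L]),
                     gap_opens = as.integer(m[, 6L]),
                     q_start = as.integer(m[, 7L]),
                     q_end = as.integer(m[, 8L]),
                     s_start = as.integer(m[, 9L]),
                     s_end = as.integer(m[, 10L]),
                     e_value = as.numeric(m[, 11L]),
                     bitscore = as.numeric(m[, 12L]))
  stopifnot(all(hits$q_start <= hits$q_end), all(hits$bitscore >= 0))
  hits
}

empty_hits <- function() {
  stats::setNames(data.frame(character(), character(), numeric(), integer(),
                             integer(), integer(), integer(), integer(),
                             integer(), integer(), numeric(), numeric()),
                  BLAST_COLS)
}

#' Write hits in the 12-column tabular dialect
#'
#' @param hits A hit table as returned by [parse_blast_tabular()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  h <- hits[, BLAST_COLS]
  h$pct_identity <- sprintf("%.3f", h$pct_identity)
  utils::write.table(h, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Derive strand and 0-based half-open subject spans for tabular hits
#'
#' @param hits A hit table.
#' @return The table with added columns `strand` (`"+"`/`"-"`), `s_min` and
#'   `s_max` (0-based half-open subject span) and `q_min`/`q_max` (0-based
#'   half-open query span).
#' @export
normalize_hits <- function(hits) {
  minus <- hits$s_start > hits$s_end
  hits$strand <- ifelse(minus, "-", "+")
  hits$s_min <- as.integer(ifelse(minus, hits$s_end, hits$s_start)) - 1L
  hits$s_max <- as.integer(ifelse(minus, hits$s_start, hits$s_end))
  hits$q_min <- as.integer(hits$q_start) - 1L
  hits$q_max <- as.integer(hits$q_end)
  hits
}
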