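#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet DNAString
#'   DNAStringSet reverseComplement
NULL

DNA_BASES_N <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over A/C/G/T/N (case-insensitive).
#' @return Character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC content of a DNA string, in percent
#'
#' @param x Character scalar.
#' @return Numeric percent of G or C bases.
#' @export
gc_percent <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  100 * mean(ch %in% c("G", "C"))
}

# Locate the first line of a FASTA file satisfying a predicate on body lines,
# used only to point error messages at the offending line.
.fasta_offending_line <- function(path, pred) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">") || !nzchar(ln)) next
    if (pred(ln)) return(i)
  }
  NA_integer_
}

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased on read; record order is preserved and wrapped
#' record bodies are concatenated. Only A, C, G, T and N are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase DNA strings; names are the
#'   first whitespace-delimited token of each header, with the full header
#'   kept in the `"descriptions"` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  full <- names(set)
  ids <- vapply(strsplit(full, "[ \t]+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id '", dup, "' in ", path)
  }
  seqs <- toupper(as.character(set))
  bad <- grepl(sprintf("[^%s]", paste(DNA_BASES_N, collapse = "")), seqs)
  if (any(bad)) {
    line <- .fasta_offending_line(path, function(ln)
      grepl("[^ACGTNacgtn]", ln))
    stop("non-IUPAC character (outside A/C/G/T/N) in record '",
         ids[bad][1L], "' of ", path,
         if (!is.na(line)) paste0(" (line ", line, ")") else "")
  }
  if (any(!nzchar(seqs))) stop("empty sequence record '",
                               ids[!nzchar(seqs)][1L], "' in ", path)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- full
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width of record bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gapped multiple alignment in FASTA format
#'
#' Gaps written as "." are normalised to "-"; all rows must have equal
#' gapped length.
#'
#' @param path Path to a gapped FASTA file.
#' @return Named character vector of equal-length gapped rows (uppercase).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  rows <- chartr(".", "-", toupper(as.character(set)))
  names(rows) <- vapply(strsplit(names(set), "[ \t]+"), `[[`, "", 1L)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows in ", path, " have unequal gapped lengths")
  rows
}

#' Write a multiple alignment in FASTA or Clustal format
#'
#' @param rows Named character vector of equal-length gapped rows.
#' @param path Output path.
#' @param dialect `"fasta"` or `"clustal"`; the clustal dialect uses 60-column
#'   blocks.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(rows, path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows have unequal gapped lengths")
  stopifnot(!is.null(names(rows)))
  if (dialect == "fasta") return(write_fasta(rows, path))
  ncols <- nchar(rows[[1L]])
  nm <- names(rows)
  pad <- max(nchar(nm)) + 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL W multiple sequence alignment", con)
  writeLines("", con)
  starts <- seq(1L, ncols, by = 60L)
  for (s in starts) {
    e <- min(s + 59L, ncols)
    for (i in seq_along(rows)) {
      writeLines(sprintf("%-*s%s", pad, nm[i], substr(rows[[i]], s, e)), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
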