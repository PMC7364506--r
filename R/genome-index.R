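#' Build (or reuse) a faidx index of a genome FASTA
#'
#' Creates a samtools-style `.fai` index beside the FASTA so chromosome
#' slices can be fetched without loading the whole assembly. An existing
#' index is reused when it is newer than its FASTA.
#'
#' @param fasta_path Path to a genome FASTA (uniform line width per record
#'   body, as faidx requires).
#' @return An object of class `genome_index` with elements `path` and
#'   `lengths` (named integer vector of record lengths).
#' @export
build_genome_index <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("genome FASTA not found: ", fasta_path)
  fai <- paste0(fasta_path, ".fai")
  if (!file.exists(fai) || file.mtime(fai) < file.mtime(fasta_path)) {
    tryCatch(Rsamtools::indexFa(fasta_path),
             error = function(e)
               stop("cannot index '", fasta_path, "' (", conditionMessage(e),
                    "); faidx requires a uniform line width within each ",
                    "record body - reformat the FASTA and retry"))
  }
  gr <- Rsamtools::scanFaIndex(fasta_path)
  lens <- stats::setNames(GenomicRanges::width(gr),
                          as.character(GenomicRanges::seqnames(gr)))
  structure(list(path = fasta_path, lengths = lens), class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", x$path, "\n  ", length(x$lengths), " sequence(s), ",
      sum(as.numeric(x$lengths)), " bases total\n", sep = "")
  invisible(x)
}

#' Fetch a genomic slice through a faidx index
#'
#' Coordinates are 0-based half-open on the forward strand. Out-of-range
#' requests are clamped to `[0, record length]` and flagged rather than
#' erroring, because flank buffers routinely overrun chromosome ends.
#'
#' @param index A `genome_index`.
#' @param chrom Record name.
#' @param start,end 0-based half-open interval.
#' @return Character scalar of exactly `end - start` residues after clamping,
#'   with attributes `clamped` (logical), `start` and `end` (the clamped
#'   0-based half-open interval actually fetched).
#' @export
slice_genome <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "genome_index"))
  if (!chrom %in% names(index$lengths))
    stop("sequence '", chrom, "' not present in genome ", index$path)
  len <- unname(index$lengths[[chrom]])
  if (start > end) stop("slice start ", start, " exceeds end ", end)
  cs <- as.integer(max(0L, min(start, len)))
  ce <- as.integer(max(cs, min(end, len)))
  clamped <- (cs != start) || (ce != end)
  if (ce == cs) {
    out <- ""
  } else {
    fa <- Rsamtools::FaFile(index$path)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cs + 1L, ce))
    out <- toupper(as.character(Rsamtools::scanFa(fa, gr)[[1L]]))
  }
  attr(out, "clamped") <- clamped
  attr(out, "start") <- cs
  attr(out, "end") <- ce
  out
}
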