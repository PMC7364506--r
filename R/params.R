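#' Design parameters for the primer-design pipeline
#'
#' Bundles every tunable of the pipeline into a validated list. The defaults
#' follow long-standing primer-design conventions (primer length 18--27 with
#' an optimum of 20, melting temperature 57--63 degC with an optimum of 60,
#' GC content 30--70%) together with the pipeline-level defaults: 1000-base
#' flank buffers, hit groups chained at a maximum gap of 1000 bases, a
#' within-group mean bitscore floor of 200 for homologue selection, and
#' products of 500--2000 bases.
#'
#' @param len_min,len_opt,len_max Primer length bounds and optimum (bases).
#' @param tm_min,tm_opt,tm_max Melting temperature bounds and optimum (degC).
#' @param gc_min,gc_opt,gc_max GC content bounds and optimum (percent).
#' @param product_min,product_max Allowed PCR product size range (bases).
#' @param start_buffer,end_buffer Flanking sequence extracted upstream /
#'   downstream of the located gene (bases).
#' @param n_homologue_groups Maximum number of homologue hit groups retained.
#' @param bitscore_floor Within-group mean bitscore a homologue group must
#'   exceed to be retained.
#' @param max_group_gap Maximum subject-coordinate gap (bases) between
#'   consecutive hits chained into one group.
#' @param min_overlap Minimum overlap (bases) required between consecutive
#'   products in a tiling.
#' @param sanger_read Nominal Sanger read length (bases).
#' @param sanger_trim Bases trimmed from the end of a Sanger read when
#'   computing its trusted coverage; the usable read is
#'   `sanger_read - sanger_trim`.
#' @param sanger_window Half-width (bases) of the placement window around each
#'   ideal sequencing-primer start.
#' @param monovalent_mM Monovalent cation concentration (mM) for Tm.
#' @param primer_nM Primer concentration (nM) for Tm.
#' @param w_tm,w_len,w_gc,w_self,w_end,w_hp,w_gap Weights of the single-primer
#'   penalty terms (Tm deviation, length deviation, GC excess, self-annealing,
#'   3'-end self-annealing, hairpin, gap-discriminated anchor).
#' @param w_tmdiff,w_cross Weights of the pair penalty terms (Tm difference
#'   between the two primers, cross-dimer score).
#' @param word_size Seed word size of the internal homology search.
#'
#' @return A list of class `design_parameters`.
#' @export
design_parameters <- function(len_min = 18, len_opt = 20, len_max = 27,
                              tm_min = 57, tm_opt = 60, tm_max = 63,
                              gc_min = 30, gc_opt = 50, gc_max = 70,
                              product_min = 500, product_max = 2000,
                              start_buffer = 1000, end_buffer = 1000,
                              n_homologue_groups = 3, bitscore_floor = 200,
                              max_group_gap = 1000, min_overlap = 50,
                              sanger_read = 700, sanger_trim = 100,
                              sanger_window = 50,
                              monovalent_mM = 50, primer_nM = 500,
                              w_tm = 1.0, w_len = 1.0, w_gc = 0.5,
                              w_self = 0.1, w_end = 0.2, w_hp = 0.1,
                              w_gap = 2.0, w_tmdiff = 0.5, w_cross = 0.1,
                              word_size = 11) {
  p <- list(len_min = len_min, len_opt = len_opt, len_max = len_max,
            tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
            gc_min = gc_min, gc_opt = gc_opt, gc_max = gc_max,
            product_min = product_min, product_max = product_max,
            start_buffer = start_buffer, end_buffer = end_buffer,
            n_homologue_groups = n_homologue_groups,
            bitscore_floor = bitscore_floor,
            max_group_gap = max_group_gap, min_overlap = min_overlap,
            sanger_read = sanger_read, sanger_trim = sanger_trim,
            sanger_window = sanger_window,
            monovalent_mM = monovalent_mM, primer_nM = primer_nM,
            w_tm = w_tm, w_len = w_len, w_gc = w_gc, w_self = w_self,
            w_end = w_end, w_hp = w_hp, w_gap = w_gap,
            w_tmdiff = w_tmdiff, w_cross = w_cross, word_size = word_size)
  stopifnot(p$len_min <= p$len_opt, p$len_opt <= p$len_max,
            p$tm_min <= p$tm_opt, p$tm_opt <= p$tm_max,
            p$gc_min <= p$gc_opt, p$gc_opt <= p$gc_max,
            p$product_min <= p$product_max,
            p$product_min > p$len_min + p$len_max,
            p$min_overlap >= 0, p$sanger_trim < p$sanger_read,
            p$word_size >= 4)
  class(p) <- "design_parameters"
  p
}

#' Merge overrides into a design_parameters object
#'
#' @param params A `design_parameters` object.
#' @param overrides Named list of parameter values to replace.
#' @return A revalidated `design_parameters` object.
#' @export
update_parameters <- function(params, overrides) {
  if (length(overrides) == 0L) return(params)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown))
    stop("unknown design parameter(s): ", paste(unknown, collapse = ", "))
  args <- unclass(params)
  args[names(overrides)] <- overrides
  do.call(design_parameters, args)
}
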