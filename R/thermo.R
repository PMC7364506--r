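# Unified nearest-neighbour duplex parameters (SantaLucia 1998):
# enthalpy in kcal/mol, entropy in cal/(mol K), per 5'->3' dinucleotide stack.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(AT = 2.3, GC = 0.1)   # per terminal base pair
NN_INIT_DS <- c(AT = 4.1, GC = -2.8)

#' Nearest-neighbour melting temperature
#'
#' Duplex melting temperature from unified nearest-neighbour thermodynamics
#' with terminal initiation terms and an entropic monovalent-salt
#' correction:
#' `Tm = 1000 * dH / (dS + 0.368 * (L-1) * ln[Na+] + R * ln(C/4)) - 273.15`
#' with `dH` the summed stack and initiation enthalpies (kcal/mol), `dS`
#' the corresponding entropy (cal/mol/K), `R = 1.987` cal/mol/K, `[Na+]`
#' the monovalent cation concentration in mol/L and `C` the total primer
#' concentration in mol/L.
#'
#' @param sequence DNA string over A/C/G/T, length >= 8. Sequences
#'   containing N cannot be scored and raise an error.
#' @param monovalent_mM Monovalent cation concentration (mM).
#' @param primer_nM Primer concentration (nM).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(sequence, monovalent_mM = 50,
                                primer_nM = 500) {
  s <- toupper(sequence)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c("A", "C", "G", "T")))
    stop("melting_temperature: sequence contains bases outside A/C/G/T")
  n <- length(ch)
  if (n < 8L) stop("melting_temperature: sequence shorter than 8 bases")
  stacks <- paste0(ch[-n], ch[-1L])
  term <- ifelse(ch[c(1L, n)] %in% c("A", "T"), "AT", "GC")
  dH <- sum(NN_DH[stacks]) + sum(NN_INIT_DH[term])
  dS <- sum(NN_DS[stacks]) + sum(NN_INIT_DS[term])
  dS <- dS + 0.368 * (n - 1L) * log(monovalent_mM / 1000)
  R <- 1.987
  1000 * dH / (dS + R * log(primer_nM * 1e-9 / 4)) - 273.15
}

.encode_dna <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1L]],
        c("A", "C", "G", "T"))
}
# weight of a matched (i.e. complementary in the duplex) position:
# G/C pairs are worth 2, A/T pairs 1.
.pair_weight <- c(1, 2, 2, 1)

# Best weighted complementary run between oligo a and oligo b over all
# ungapped antiparallel offsets. Complementarity of a[i] with b[j] is
# equivalent to identity of a[i] with revcomp(b)[k]; runs are contiguous
# complementary stretches. `any` is the best run anywhere; `end` the best
# run that involves the 3'-terminal base of either oligo.
.dimer_scores <- function(a_codes, b_codes) {
  n <- length(a_codes)
  m <- length(b_codes)
  rcb <- rev(5L - b_codes)              # revcomp in code space (A<->T, C<->G)
  best_any <- 0
  best_end <- 0
  for (off in (-(m - 1L)):(n - 1L)) {
    i0 <- max(1L, 1L + off)
    i1 <- min(n, m + off)
    if (i1 < i0) next
    ai <- a_codes[i0:i1]
    bi <- rcb[(i0 - off):(i1 - off)]
    eq <- ai == bi
    if (!any(eq)) next
    w <- .pair_weight[ai] * eq
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cw <- cumsum(w)
    sc <- cw[ends] - c(0, cw)[starts]
    tr <- which(r$values)
    if (length(tr) == 0L) next
    best_any <- max(best_any, sc[tr])
    # positions in a: i0:i1 ; a's 3' base is index n; b's 3' base is b[m],
    # i.e. rcb[1], paired when (i - off) == 1  <=>  i == off + 1.
    apos_end <- starts + i0 - 1L        # run start index in a
    run_a <- cbind(apos_end, ends + i0 - 1L)
    for (k in tr) {
      covers_a3 <- run_a[k, 1L] <= n & run_a[k, 2L] >= n
      covers_b3 <- run_a[k, 1L] <= off + 1L & run_a[k, 2L] >= off + 1L
      if (covers_a3 || covers_b3) best_end <- max(best_end, sc[k])
    }
  }
  c(any = best_any, end = best_end)
}

.hairpin_score <- function(codes, min_loop = 3L) {
  n <- length(codes)
  best <- 0L
  if (n < min_loop + 2L) return(0L)
  for (i in 1L:(n - min_loop - 1L)) {
    for (j in (i + min_loop + 1L):n) {
      stem <- 0L
      while (i - stem >= 1L && j + stem <= n &&
             codes[i - stem] + codes[j + stem] == 5L) {
        stem <- stem + 1L
      }
      best <- max(best, stem)
    }
  }
  best
}

#' Self-complementarity and hairpin scores of an oligo
#'
#' `self_any` is the best weighted complementary run over all ungapped
#' antiparallel self-alignments of the oligo against a second copy of
#' itself (G/C pairs weigh 2, A/T pairs 1); `self_end` is the best such run
#' involving a 3'-terminal base; `hairpin` is the longest stem (consecutive
#' intramolecular base pairs) over all fold points with a loop of at least
#' 3 bases.
#'
#' @param sequence DNA string over A/C/G/T.
#' @return Named numeric vector `self_any`, `self_end`, `hairpin`.
#' @export
complementarity_scores <- function(sequence) {
  codes <- .encode_dna(sequence)
  if (anyNA(codes))
    stop("complementarity_scores: sequence contains bases outside A/C/G/T")
  d <- .dimer_scores(codes, codes)
  c(self_any = unname(d["any"]), self_end = unname(d["end"]),
    hairpin = .hairpin_score(codes))
}

#' Cross-dimer score of a primer pair
#'
#' Best weighted complementary run between the two oligos over all ungapped
#' antiparallel offsets (same scoring as [complementarity_scores()]).
#'
#' @param a,b DNA strings.
#' @return Numeric scalar.
#' @export
cross_dimer_score <- function(a, b) {
  unname(.dimer_scores(.encode_dna(a), .encode_dna(b))["any"])
}

#' Single-primer penalty
#'
#' Weighted sum of deviations from the design optima:
#' `w_tm*|tm - tm_opt| + w_len*|len - len_opt| +
#'  w_gc*max(0, gc_min - gc, gc - gc_max) + w_self*self_any +
#'  w_end*self_end + w_hp*hairpin + w_gap*[gap_discriminated]`.
#' Zero exactly at the documented optimum; the best primer is the one with
#' the lowest penalty.
#'
#' @param tm,len,gc,self_any,self_end,hairpin Primer attributes
#'   (vectorised).
#' @param gap_discriminated Logical: anchored on a gap-vs-base column.
#' @param params A `design_parameters` object.
#' @return Numeric penalty vector (>= 0).
#' @export
primer_penalty <- function(tm, len, gc, self_any, self_end, hairpin,
                           gap_discriminated = FALSE,
                           params = design_parameters()) {
  params$w_tm * abs(tm - params$tm_opt) +
    params$w_len * abs(len - params$len_opt) +
    params$w_gc * pmax(0, params$gc_min - gc, gc - params$gc_max) +
    params$w_self * self_any +
    params$w_end * self_end +
    params$w_hp * hairpin +
    params$w_gap * as.numeric(gap_discriminated)
}

#' Primer-pair penalty
#'
#' Sum of the two single-primer penalties plus a melting-temperature
#' mismatch term and a cross-dimer term:
#' `pen_f + pen_r + w_tmdiff*|tm_f - tm_r| + w_cross*cross`.
#' Symmetric in the two primers.
#'
#' @param pen_f,pen_r Single-primer penalties.
#' @param tm_f,tm_r Melting temperatures.
#' @param cross Cross-dimer score of the pair (see [cross_dimer_score()]).
#' @param params A `design_parameters` object.
#' @return Numeric penalty vector.
#' @export
pair_penalty <- function(pen_f, pen_r, tm_f, tm_r, cross,
                         params = design_parameters()) {
  pen_f + pen_r + params$w_tmdiff * abs(tm_f - tm_r) + params$w_cross * cross
}
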