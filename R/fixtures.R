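#' Specification of a synthetic polyploid fixture genome
#'
#' Describes a small polyploid genome with known ground truth for testing
#' the whole pipeline without downloads. An ancestral locus (gene plus
#' homologous flanks) is evolved along a star phylogeny: the target copy
#' accumulates its own substitutions (the planted discriminating sites),
#' and each homeologue accumulates private substitutions at disjoint
#' positions so that its pairwise identity to the target over the
#' homologous region is exactly the requested value. The defaults mirror a
#' documented wheat test locus: a 2.4 kb gene with homeologues at 93, 93
#' and 80% identity, the most diverged copy partial with homology starting
#' 325 bases into the gene and ending ~10 bases downstream of it, GC
#' content 49%, and a second variety of the target genome carrying a
#' handful of varietal SNPs.
#'
#' @param seed Integer seed governing all randomness of the generator.
#' @param gene_length Length of the gene (bases).
#' @param homeologue_identities Pairwise identities of the homeologues to
#'   the target over their homologous span.
#' @param partial_homologue `NULL`, or a list with `index` (which
#'   homeologue is partial), `offset` (homology starts this many bases into
#'   the gene) and `downstream` (homology extends this far past the gene).
#' @param chrom_length Length of each chromosome scaffold (bases).
#' @param gc_target GC fraction of generated sequence.
#' @param n_varieties Number of varieties of the target genome (>= 2 adds
#'   a second-variety genome carrying varietal SNPs).
#' @param varietal_snp_count Substitutions planted in the second variety.
#' @param target_divergence Fraction of the smallest target-homeologue
#'   divergence assigned to the target's own branch (these sites are the
#'   planted discriminating SNPs).
#' @param flank_homology How far the homologous region extends beyond each
#'   end of the gene (bases) for non-partial homeologues.
#' @param indel_rate Per-site indel rate in homeologues (0 disables;
#'   small values exercise gap-discriminated columns).
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, gene_length = 2400,
                         homeologue_identities = c(0.93, 0.93, 0.80),
                         partial_homologue = list(index = 3L, offset = 325L,
                                                  downstream = 10L),
                         chrom_length = 20000, gc_target = 0.49,
                         n_varieties = 2L, varietal_snp_count = 10L,
                         target_divergence = 0.5, flank_homology = 1000,
                         indel_rate = 0) {
  spec <- list(seed = as.integer(seed), gene_length = as.integer(gene_length),
               homeologue_identities = homeologue_identities,
               partial_homologue = partial_homologue,
               chrom_length = as.integer(chrom_length),
               gc_target = gc_target, n_varieties = as.integer(n_varieties),
               varietal_snp_count = as.integer(varietal_snp_count),
               target_divergence = target_divergence,
               flank_homology = as.integer(flank_homology),
               indel_rate = indel_rate)
  stopifnot(all(spec$homeologue_identities > 0.5),
            all(spec$homeologue_identities <= 1.0),
            spec$gene_length + 2L * spec$flank_homology + 2000L <=
              spec$chrom_length,
            spec$target_divergence >= 0, spec$target_divergence <= 1,
            spec$gc_target > 0, spec$gc_target < 1,
            spec$indel_rate >= 0, spec$indel_rate < 0.05)
  class(spec) <- "fixture_spec"
  spec
}

.random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.substitute <- function(chars, pos) {
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  chars
}

#' Generate a synthetic polyploid fixture genome with ground truth
#'
#' Writes one genome FASTA per variety plus the bare input gene FASTA and a
#' tab-separated truth table into `dir`, and returns everything needed by
#' tests: the planted target-branch substitutions (ground-truth
#' discriminating SNPs), each homeologue's private substitutions, the
#' varietal substitutions of the second variety, and the locus coordinates
#' of every embedded copy. Output is byte-identical for a given spec
#' (the generator seeds a private RNG stream and restores the caller's).
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return List with `genomes` (named FASTA paths, first = primary),
#'   `input` (bare gene FASTA path), `truth` (data frame: `kind`,
#'   `seq_label`, `region_pos`, `gene_pos`, `chrom`, `chrom_pos`,
#'   `ancestral`, `derived`), `truth_path`, `config` (YAML config path for
#'   the command-line driver), `loci` (data frame of embedded locus
#'   coordinates), `gene` (target gene sequence), `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fix")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  fl <- spec$flank_homology
  gl <- spec$gene_length
  region_len <- gl + 2L * fl
  ancestor <- strsplit(.random_dna(region_len, spec$gc_target), "",
                       fixed = TRUE)[[1L]]

  d <- 1 - spec$homeologue_identities
  m_t <- spec$target_divergence * min(d)
  # target branch: the planted discriminating sites
  t_sites <- which(stats::runif(region_len) < m_t)
  target_chars <- .substitute(ancestor, t_sites)
  truth <- list()
  add_truth <- function(kind, label, pos, anc, der) {
    truth[[length(truth) + 1L]] <<- data.frame(
      kind = kind, seq_label = label, region_pos = pos - 1L,
      gene_pos = ifelse(pos - 1L >= fl & pos - 1L < fl + gl,
                        pos - 1L - fl, NA_integer_),
      ancestral = anc, derived = der)
  }
  if (length(t_sites))
    add_truth("target_branch", "target", t_sites, ancestor[t_sites],
              target_chars[t_sites])

  hom_chroms <- c("chr4B", "chr4D", "chr5B",
                  paste0("chrH", seq_len(max(0, length(d) - 3L)) + 3L))
  hom_chroms <- hom_chroms[seq_along(d)]
  hom_seqs <- list()
  hom_spans <- list()   # 1-based region span embedded for each homeologue
  for (i in seq_along(d)) {
    m_i <- d[i] - m_t
    pool <- setdiff(seq_len(region_len), t_sites)
    h_sites <- pool[stats::runif(length(pool)) < m_i / (1 - m_t)]
    hchars <- .substitute(ancestor, h_sites)
    if (length(h_sites))
      add_truth("homologue_private", hom_chroms[i], h_sites,
                ancestor[h_sites], hchars[h_sites])
    if (spec$indel_rate > 0) {
      del <- setdiff(which(stats::runif(region_len) < spec$indel_rate),
                     c(t_sites, h_sites))
      if (length(del)) hchars[del] <- ""
    }
    span <- c(1L, region_len)
    if (!is.null(spec$partial_homologue) &&
        i == spec$partial_homologue$index) {
      span <- c(fl + spec$partial_homologue$offset + 1L,
                min(region_len, fl + gl + spec$partial_homologue$downstream))
    }
    hom_seqs[[i]] <- paste(hchars[span[1L]:span[2L]], collapse = "")
    hom_spans[[i]] <- span
  }

  target_region <- paste(target_chars, collapse = "")
  gene <- substr(target_region, fl + 1L, fl + gl)

  embed <- function(locus_seq, chrom_len) {
    margin <- 200L
    slack <- chrom_len - nchar(locus_seq) - 2L * margin
    at <- margin + sample.int(max(1L, slack), 1L)   # 0-based insert offset
    left <- .random_dna(at, spec$gc_target)
    right <- .random_dna(chrom_len - at - nchar(locus_seq), spec$gc_target)
    list(seq = paste0(left, locus_seq, right), at = at)
  }

  loci <- list()
  g1 <- list()
  emb_t <- embed(target_region, spec$chrom_length)
  g1[["chr5A"]] <- emb_t$seq
  loci[[length(loci) + 1L]] <- data.frame(
    genome = "variety1", chrom = "chr5A", label = "target",
    start = emb_t$at, end = emb_t$at + region_len)
  for (i in seq_along(hom_seqs)) {
    e <- embed(hom_seqs[[i]], spec$chrom_length)
    g1[[hom_chroms[i]]] <- e$seq
    loci[[length(loci) + 1L]] <- data.frame(
      genome = "variety1", chrom = hom_chroms[i],
      label = paste0("homologue", i),
      start = e$at, end = e$at + nchar(hom_seqs[[i]]))
  }
  paths <- character(0)
  p1 <- file.path(dir, "variety1.fa")
  write_fasta(unlist(g1), p1)
  paths["variety1"] <- p1

  if (spec$n_varieties >= 2L) {
    v_sites <- sort(sample.int(region_len, spec$varietal_snp_count))
    v_chars <- .substitute(target_chars, v_sites)
    add_truth("varietal", "variety2", v_sites, target_chars[v_sites],
              v_chars[v_sites])
    e2 <- embed(paste(v_chars, collapse = ""), spec$chrom_length)
    p2 <- file.path(dir, "variety2.fa")
    write_fasta(c(chr5A = e2$seq), p2)
    paths["variety2"] <- p2
    loci[[length(loci) + 1L]] <- data.frame(
      genome = "variety2", chrom = "chr5A", label = "target_variety2",
      start = e2$at, end = e2$at + region_len)
  }

  input_path <- file.path(dir, "input.fa")
  write_fasta(c(gene = gene), input_path)

  if (length(truth) == 0L)
    truth <- list(data.frame(kind = character(), seq_label = character(),
                             region_pos = integer(), gene_pos = integer(),
                             ancestral = character(),
                             derived = character()))
  truth <- do.call(rbind, truth)
  # chromosome coordinate of each truth site on its carrier
  locdf <- do.call(rbind, loci)
  t_at <- locdf$start[locdf$label == "target"]
  truth$chrom <- ifelse(truth$kind == "homologue_private", truth$seq_label,
                        "chr5A")
  truth$chrom_pos <- rep(NA_integer_, nrow(truth))
  is_hp <- truth$kind == "homologue_private"
  if (any(is_hp)) {
    hidx <- match(truth$seq_label[is_hp], hom_chroms)
    hstart <- locdf$start[match(paste0("homologue", hidx), locdf$label)]
    span1 <- vapply(hom_spans, `[[`, 0L, 1L)[hidx]
    span2 <- vapply(hom_spans, `[[`, 0L, 2L)[hidx]
    cp <- hstart + truth$region_pos[is_hp] - (span1 - 1L)
    inside <- truth$region_pos[is_hp] >= span1 - 1L &
      truth$region_pos[is_hp] <= span2 - 1L
    truth$chrom_pos[is_hp] <- ifelse(inside, cp, NA_integer_)
  }
  truth$chrom_pos[!is_hp] <- t_at + truth$region_pos[!is_hp]
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  config_path <- file.path(dir, "config.yaml")
  genomes_cfg <- lapply(names(paths), function(lbl)
    list(label = lbl, fasta = paths[[lbl]], primary = lbl == "variety1"))
  yaml::write_yaml(list(genomes = genomes_cfg), config_path)

  list(genomes = paths, input = input_path, truth = truth,
       truth_path = truth_path, config = config_path, loci = locdf,
       gene = gene, target_region = target_region, spec = spec)
}
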