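#' Read a genome configuration file
#'
#' YAML file with a `genomes` list; each entry has `label`, `fasta` and an
#' optional `primary` flag (exactly one genome must be primary; with a
#' single genome the flag may be omitted). Relative FASTA paths are
#' resolved against the config file's directory. An optional `params`
#' mapping overrides [design_parameters()] defaults.
#'
#' @param path Path to a YAML config file.
#' @return List with `genomes` (data frame: `label`, `fasta`, `primary`)
#'   and `params` (named list of overrides, possibly empty).
#' @export
read_genome_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$genomes) || length(cfg$genomes) == 0L)
    stop("config ", path, " lists no genomes")
  g <- data.frame(
    label = vapply(cfg$genomes, function(x) as.character(x$label), ""),
    fasta = vapply(cfg$genomes, function(x) as.character(x$fasta), ""),
    primary = vapply(cfg$genomes, function(x) isTRUE(x$primary), TRUE))
  rel <- !file.exists(g$fasta)
  g$fasta[rel] <- file.path(dirname(path), g$fasta[rel])
  if (nrow(g) == 1L) g$primary <- TRUE
  if (sum(g$primary) != 1L)
    stop("config must mark exactly one genome as primary")
  list(genomes = g, params = if (is.null(cfg$params)) list() else cfg$params)
}

#' Parse a user-supplied gapped alignment
#'
#' Expects the row order: the bare sequence to be cloned, the same sequence
#' with flanking regions included, then any homologues. Row 1 is
#' cross-validated against row 2 (its ungapped content must occur exactly
#' once in row 2's ungapped content).
#'
#' @param path Path to a gapped FASTA alignment.
#' @return List with `msa` (rows 2..n, roles target/homologue) and
#'   `bare_input` (ungapped row 1).
#' @export
read_user_alignment <- function(path) {
  rows <- read_alignment(path)
  if (length(rows) < 2L)
    stop("user alignment must contain at least two rows, in the order: ",
         "sequence to be cloned, same sequence with flanking regions ",
         "included, then any homologues")
  bare <- gsub("-", "", rows[[1L]], fixed = TRUE)
  flanked <- gsub("-", "", rows[[2L]], fixed = TRUE)
  npos <- gregexpr(bare, flanked, fixed = TRUE)[[1L]]
  if (identical(as.integer(npos), -1L) || length(npos) != 1L)
    stop("row 1 of the user alignment is not an ungapped substring of ",
         "row 2 (occurring exactly once); required row order: sequence to ",
         "be cloned, same sequence with flanking regions included, then ",
         "any homologues")
  keep <- rows[-1L]
  # rows named "<label>__extra" (as written by guided mode) are same-locus
  # sequences from an additional variety, kept for the varietal-SNP guard
  roles <- c("target_locus",
             ifelse(grepl("__extra$", names(keep)[-1L]),
                    "extra_genome", "homologue"))
  msa <- structure(list(rows = keep, labels = names(keep),
                        roles = roles,
                        target_row = 1L, n_columns = nchar(keep[[1L]])),
                   class = "msa")
  list(msa = msa, bare_input = bare)
}

.vmsg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

#' Run the full homologue-specific primer-design pipeline
#'
#' Locates the input sequence and its close homologues in the primary
#' genome (plus one locus from each additional variety genome), aligns the
#' flanked extractions, mines the alignment for discriminating SNPs,
#' generates 3'-anchored primer candidates, selects a minimal-penalty set
#' of overlapping products covering the whole input, places internal Sanger
#' sequencing primers, and validates the design by simulated PCR.
#'
#' @param input Path to a FASTA with the single sequence to clone, or a
#'   named character scalar.
#' @param genomes Genome table (`label`, `fasta`, `primary`) or path to a
#'   YAML config (see [read_genome_config()]). Ignored when `alignment` is
#'   given.
#' @param params A `design_parameters` object.
#' @param hits Optional precomputed 12-column tabular report (path or data
#'   frame) replacing the internal search against the primary genome.
#' @param alignment Optional user-supplied gapped alignment (path); skips
#'   search, extraction and alignment.
#' @param backend Alignment backend passed to [align_sequences()].
#' @param guided Stop after the alignment is built and return it, so rows
#'   can be inspected/curated before SNP calling; resume by passing the
#'   curated alignment via `alignment`.
#' @param prefix Oligo name prefix.
#' @param verbose Emit progress messages.
#' @return An object of class `primer_design`: list with `input_id`,
#'   `bare_input`, `selection` (target/homologues/extra/discarded),
#'   `hits`, `msa`, `snps`, `candidates`, `input_region`, `solution`
#'   (a `tiling_solution`), `specificity`, `params`, `prefix`, `guided`.
#' @export
design_primers <- function(input, genomes = NULL,
                           params = design_parameters(), hits = NULL,
                           alignment = NULL,
                           backend = c("internal", "muscle", "dialign",
                                       "mafft"),
                           guided = FALSE, prefix = "target",
                           verbose = FALSE) {
  backend <- match.arg(backend)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  selection <- NULL
  used_hits <- NULL
  if (is.null(alignment)) {
    if (is.character(input) && length(input) == 1L && file.exists(input)) {
      seqs <- stage("input", read_fasta(input))
      if (length(seqs) != 1L)
        stop("[input] expected exactly one record, found ", length(seqs))
      input_id <- names(seqs)[[1L]]
      bare <- unname(seqs[[1L]])
    } else {
      input_id <- if (!is.null(names(input))) names(input)[[1L]] else "query"
      bare <- toupper(unname(input[[1L]]))
    }
    if (is.character(genomes) && length(genomes) == 1L)
      genomes <- read_genome_config(genomes)$genomes
    if (is.null(genomes)) stop("[config] no genomes supplied")
    primary <- genomes[genomes$primary, , drop = FALSE]
    others <- genomes[!genomes$primary, , drop = FALSE]

    .vmsg(verbose, "indexing primary genome ", primary$fasta)
    idx <- stage("index", build_genome_index(primary$fasta))
    if (is.null(hits)) {
      .vmsg(verbose, "searching primary genome")
      used_hits <- stage("search", internal_search(
        stats::setNames(bare, input_id), idx, word_size = params$word_size))
    } else {
      used_hits <- if (is.character(hits))
        stage("hits", parse_blast_tabular(hits)) else hits
    }
    .vmsg(verbose, nrow(used_hits), " hit(s)")
    groups <- stage("grouping", group_hits(
      used_hits, params$max_group_gap, query_length = nchar(bare)))
    ranked <- rank_groups(groups)
    sel <- stage("selection", select_loci(
      ranked, params$n_homologue_groups, params$bitscore_floor))

    .vmsg(verbose, "extracting target + ", length(sel$homologues),
          " homologue(s)")
    target <- stage("extraction", extract_flanked(
      sel$target, idx, params$start_buffer, params$end_buffer,
      label = "target", genome_label = primary$label,
      role = "target_locus"))
    homologues <- lapply(sel$homologues, function(g)
      stage("extraction", extract_flanked(
        g, idx, params$start_buffer, params$end_buffer,
        genome_label = primary$label, role = "homologue")))

    extra <- list()
    for (j in seq_len(nrow(others))) {
      oidx <- stage("index", build_genome_index(others$fasta[j]))
      .vmsg(verbose, "searching additional genome ", others$label[j])
      oh <- stage("search", internal_search(
        stats::setNames(bare, input_id), oidx, word_size = params$word_size))
      og <- rank_groups(group_hits(oh, params$max_group_gap,
                                   query_length = nchar(bare)))
      if (length(og) == 0L) {
        warning("no locus found in additional genome ", others$label[j])
        next
      }
      extra[[length(extra) + 1L]] <- stage("extraction", extract_flanked(
        og[[1L]], oidx, params$start_buffer, params$end_buffer,
        label = paste0(others$label[j], ":", og[[1L]]$subject_id),
        genome_label = others$label[j], role = "extra_genome"))
    }
    selection <- list(target = target, homologues = homologues,
                      extra_variety = extra, discarded = sel$discarded)

    .vmsg(verbose, "aligning (", backend, " backend)")
    msa <- stage("alignment", align_sequences(
      c(list(target), homologues, extra), backend = backend))
  } else {
    ua <- stage("alignment", read_user_alignment(alignment))
    msa <- ua$msa
    bare <- ua$bare_input
    input_id <- names(msa$rows)[[1L]]
  }

  if (guided) {
    return(structure(list(input_id = input_id, bare_input = bare,
                          selection = selection, hits = used_hits,
                          msa = msa, snps = NULL, candidates = NULL,
                          input_region = NULL, solution = NULL,
                          specificity = NULL, params = params,
                          prefix = prefix, guided = TRUE),
                     class = "primer_design"))
  }

  region <- stage("region", locate_input_region(msa, bare))
  snps <- stage("snp_scan", scan_snps(msa))
  .vmsg(verbose, sum(snps$discriminating & !snps$varietal_conflict),
        " usable discriminating SNP column(s)")
  target_seq <- ungapped_row(msa, msa$target_row)
  candidates <- stage("candidates", generate_candidates(
    snps, target_seq, params))
  pairs <- stage("pairing", enumerate_pairs(candidates, params))
  .vmsg(verbose, nrow(pairs), " admissible pair(s)")
  solution <- stage("tiling", select_tiling(pairs, region$target, params))
  if (nrow(solution$pairs)) {
    sq <- lapply(seq_len(nrow(solution$pairs)), function(i)
      stage("sequencing", place_sequencing_primers(
        solution$pairs[i, , drop = FALSE], target_seq, params)))
    solution$sequencing <- do.call(rbind, sq)
  }
  templates <- c(target = target_seq)
  if (!is.null(selection)) {
    templates <- stats::setNames(
      c(selection$target$residues,
        vapply(selection$homologues, `[[`, "", "residues")),
      c("target", vapply(selection$homologues, `[[`, "", "label")))
  } else if (length(msa$rows) > 1L) {
    # off-target templates are the homologue rows; additional-variety rows
    # carry the same allele and legitimately amplify
    keep_rows <- c(msa$target_row, which(msa$roles == "homologue"))
    templates <- stats::setNames(
      vapply(keep_rows, function(i) ungapped_row(msa, i), ""),
      c("target", msa$labels[keep_rows[-1L]]))
  }
  specificity <- stage("validation", specificity_report(solution, templates))

  structure(list(input_id = input_id, bare_input = bare,
                 selection = selection, hits = used_hits, msa = msa,
                 snps = snps, candidates = candidates,
                 input_region = region, solution = solution,
                 specificity = specificity, params = params,
                 prefix = prefix, guided = FALSE),
            class = "primer_design")
}

#' @export
print.primer_design <- function(x, ...) {
  cat("<primer_design> input '", x$input_id, "' (", nchar(x$bare_input),
      " bases)\n", sep = "")
  if (isTRUE(x$guided)) {
    cat("  guided run: alignment built (", length(x$msa$rows),
        " rows); resume with the curated alignment\n", sep = "")
    return(invisible(x))
  }
  if (!is.null(x$selection))
    cat("  homologues: ", length(x$selection$homologues),
        "  additional varieties: ", length(x$selection$extra_variety),
        "  discarded groups: ", length(x$selection$discarded), "\n",
        sep = "")
  cat("  usable SNP anchors: ",
      sum(x$snps$discriminating & !x$snps$varietal_conflict), "\n", sep = "")
  print(x$solution)
  print(x$specificity)
  invisible(x)
}

#' Write the plain-text run report
#'
#' @param run A `primer_design` object.
#' @param path Output path.
#' @param seed Seed recorded in the report (or `NA`).
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("run report: homologue-specific primer design")
  w("input: %s (%d bases)", run$input_id, nchar(run$bare_input))
  if (!is.na(seed)) w("seed: %s", format(seed))
  if (!is.null(run$selection)) {
    w("homologues retained: %d", length(run$selection$homologues))
    for (h in run$selection$homologues) w("  %s", h$label)
    w("additional-variety loci: %d", length(run$selection$extra_variety))
    w("discarded groups: %d", length(run$selection$discarded))
    for (dg in run$selection$discarded)
      w("  %s:%d-%d(%s): %s", dg$group$subject_id, dg$group$s_min,
        dg$group$s_max, dg$group$strand, dg$reason)
  }
  if (!is.null(run$snps)) {
    w("SNP columns scanned: %d", nrow(run$snps))
    w("discriminating: %d", sum(run$snps$discriminating))
    w("varietal conflicts: %d", sum(run$snps$varietal_conflict))
    w("usable anchors: %d",
      sum(run$snps$discriminating & !run$snps$varietal_conflict))
  }
  if (!is.null(run$solution)) {
    w("coverage: %s",
      if (isTRUE(run$solution$covered)) "complete" else "PARTIAL")
    w("selected pairs: %d (total penalty %.2f)", nrow(run$solution$pairs),
      run$solution$total_penalty)
    if (nrow(run$solution$coverage_gaps))
      for (i in seq_len(nrow(run$solution$coverage_gaps)))
        w("  uncovered: %d-%d", run$solution$coverage_gaps$start[i],
          run$solution$coverage_gaps$end[i])
  }
  if (!is.null(run$specificity)) {
    w("specificity: %s",
      if (isTRUE(run$specificity$all_pass)) "all pairs PASS"
      else "FAILURES present")
  }
  invisible(path)
}
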