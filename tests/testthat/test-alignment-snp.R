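test_that("pairwise global scores equal an exhaustive affine-gap DP oracle", {
  set.seed(7)
  for (k in 1:60) {
    a <- random_dna(sample(3:12, 1))
    b <- random_dna(sample(3:12, 1))
    expect_equal(pairwise_align(a, b, "global")$score,
                 oracle_global_score(a, b), info = paste(a, b))
  }
  # the documented single-gap example
  al <- pairwise_align("ACGTACGT", "ACGACGT", "global")
  expect_equal(al$score, 7 * 5 - (10 + 0.5))
  expect_identical(nchar(al$pattern), 8L)
})

test_that("a single sequence aligns to itself without gaps", {
  msa <- align_sequences(c(target = "ACGTACGTAA"))
  expect_identical(length(msa$rows), 1L)
  expect_false(grepl("-", msa$rows[[1]], fixed = TRUE))
})

test_that("centre-star alignment conserves row content on homologous sequences", {
  set.seed(13)
  anc <- random_dna(1500)
  t_m <- mutate_seq(anc, 0.03)
  h1 <- mutate_seq(anc, 0.04)
  h2 <- mutate_seq(anc, 0.10)
  msa <- align_sequences(c(target = t_m$seq, hom1 = h1$seq, hom2 = h2$seq))
  expect_identical(length(unique(nchar(msa$rows))), 1L)
  # target row is never trimmed
  expect_identical(ungapped_row(msa, 1), t_m$seq)
  # homologue rows are contiguous substrings of the inputs covering
  # almost everything (local alignment may trim mismatching extremities)
  for (i in 2:3) {
    ug <- ungapped_row(msa, i)
    src <- c(h1$seq, h2$seq)[i - 1]
    expect_true(grepl(ug, src, fixed = TRUE))
    expect_gte(nchar(ug) / nchar(src), 0.98)
  }
})

test_that("locate_input_region maps flanks and gaps correctly", {
  set.seed(17)
  bare <- random_dna(300)
  flanked <- paste0(random_dna(100), bare, random_dna(100))
  msa <- align_sequences(c(target = flanked))
  reg <- locate_input_region(msa, bare)
  expect_identical(reg$target, c(100L, 400L))
  expect_identical(reg$columns, c(100L, 400L))

  # a gapped target row widens the column interval
  msa2 <- structure(list(
    rows = c(target = paste0(substr(flanked, 1, 150), "---",
                             substr(flanked, 151, 500)),
             hom = paste0(substr(flanked, 1, 150), "GGG",
                          substr(flanked, 151, 500))),
    labels = c("target", "hom"), roles = c("target_locus", "homologue"),
    target_row = 1L, n_columns = 503L), class = "msa")
  reg2 <- locate_input_region(msa2, bare)
  expect_identical(reg2$target, c(100L, 400L))
  expect_identical(reg2$columns[2] - reg2$columns[1], 303L)

  expect_error(locate_input_region(msa, random_dna(50)), "not found")
})

test_that("SNP columns discriminate only when every homologue with evidence differs", {
  mk <- function(rows, roles) {
    structure(list(rows = rows, labels = names(rows), roles = roles,
                   target_row = 1L, n_columns = nchar(rows[[1]])),
              class = "msa")
  }
  base <- strrep("ACGT", 5)
  # one differing column at position 10 (target A vs homologue G)
  t <- paste0(substr(base, 1, 9), "A", substr(base, 11, 20))
  hG <- paste0(substr(base, 1, 9), "G", substr(base, 11, 20))
  hA <- paste0(substr(base, 1, 9), "A", substr(base, 11, 20))
  hN <- paste0(substr(base, 1, 9), "N", substr(base, 11, 20))

  s <- scan_snps(mk(c(t = t, h1 = hG, h2 = hG),
                    c("target_locus", "homologue", "homologue")))
  expect_true(s$discriminating[s$target_pos == 9])

  # one homologue matching the target spoils the anchor
  s <- scan_snps(mk(c(t = t, h1 = hG, h2 = hA),
                    c("target_locus", "homologue", "homologue")))
  expect_false(s$discriminating[s$target_pos == 9])

  # N evidence disables the column
  s <- scan_snps(mk(c(t = t, h1 = hG, h2 = hN),
                    c("target_locus", "homologue", "homologue")))
  expect_false(s$discriminating[s$target_pos == 9])

  # an extra-variety difference marks a varietal conflict
  s <- scan_snps(mk(c(t = t, h1 = hG, v = paste0(substr(base, 1, 9), "T",
                                                 substr(base, 11, 20))),
                    c("target_locus", "homologue", "extra_genome")))
  expect_true(s$discriminating[s$target_pos == 9])
  expect_true(s$varietal_conflict[s$target_pos == 9])

  # internal gap discriminates but is flagged; leading/trailing gaps are
  # "no evidence", not discrimination
  hgap <- paste0(substr(base, 1, 9), "-", substr(base, 11, 20))
  s <- scan_snps(mk(c(t = t, h1 = hgap),
                    c("target_locus", "homologue")))
  expect_true(s$discriminating[s$target_pos == 9])
  expect_true(s$gap_discriminated[s$target_pos == 9])

  hpart <- paste0(strrep("-", 10), substr(base, 11, 20))
  s <- scan_snps(mk(c(t = t, h1 = hpart),
                    c("target_locus", "homologue")))
  expect_false(s$discriminating[s$target_pos == 9])   # no evidence there
  expect_identical(s$n_evidence[s$target_pos == 9], 0L)

  expect_warning(scan_snps(mk(c(t = t), "target_locus")), "no homologue")
})

test_that("scan_snps is invariant to homologue row order", {
  set.seed(23)
  anc <- random_dna(800)
  t_m <- mutate_seq(anc, 0.03)$seq
  h1 <- mutate_seq(anc, 0.05)$seq
  h2 <- mutate_seq(anc, 0.12)$seq
  m1 <- align_sequences(c(target = t_m, a = h1, b = h2))
  s1 <- scan_snps(m1)
  m2 <- align_sequences(c(target = t_m, b = h2, a = h1))
  s2 <- scan_snps(m2)
  expect_identical(s1$discriminating, s2$discriminating)
  expect_identical(s1$target_pos, s2$target_pos)
})

test_that("planted discriminating sites are recovered from a fixture alignment", {
  fx <- small_fixture()
  idx <- build_genome_index(fx$genomes[["variety1"]])
  sel <- select_loci(rank_groups(group_hits(
    internal_search(c(gene = fx$gene), idx),
    query_length = nchar(fx$gene))))
  tgt <- extract_flanked(sel$target, idx, label = "target",
                         role = "target_locus")
  homs <- lapply(sel$homologues, extract_flanked, index = idx)
  msa <- align_sequences(c(list(tgt), homs))
  snps <- scan_snps(msa)

  # ground truth in extracted-target coordinates
  planted <- fx$truth$chrom_pos[fx$truth$kind == "target_branch"] -
    tgt$start
  planted <- planted[planted >= 0 & planted < nchar(tgt$residues)]
  found <- snps$target_pos[snps$discriminating]
  recovery <- mean(planted %in% found)
  expect_gte(recovery, 0.90)
  # precision: discriminating columns are overwhelmingly planted sites
  expect_gte(mean(found %in% planted), 0.95)

  # every discriminating column re-checked against the raw aligned
  # sequences: over the 20 target-character columns ending at the anchor,
  # any homologue that is credibly homologous there (>= 10/20 identity to
  # the target, recomputed here from the matrix) must mismatch at the
  # terminal (anchor) column
  mat <- do.call(rbind, strsplit(unname(msa$rows), ""))
  tgt_row <- mat[1, ]
  colpos <- which(tgt_row != "-")
  check <- snps[snps$discriminating & snps$target_pos >= 19, ]
  set.seed(2)
  check <- check[sample(nrow(check), min(25, nrow(check))), ]
  for (i in seq_len(nrow(check))) {
    win <- colpos[(check$target_pos[i] - 18):(check$target_pos[i] + 1)]
    for (r in which(msa$roles == "homologue")) {
      kmer <- mat[r, win]
      if (sum(kmer == tgt_row[win]) >= 10)
        expect_true(kmer[20] != check$target_base[i],
                    info = paste("anchor", check$target_pos[i], "row", r))
    }
  }
})

test_that("user alignments must follow the documented row order", {
  bare <- "ACGTACGTAC"
  bare_row <- paste0("---", bare, "---")
  flanked <- paste0("GGG", bare, "TTT")
  p <- tempfile(fileext = ".fa")
  write_fasta(c(bare = bare_row, flanked = flanked,
                hom = "GGGACGTACGTACTTT"), p)
  ua <- read_user_alignment(p)
  expect_identical(ua$bare_input, bare)
  expect_identical(length(ua$msa$rows), 2L)
  expect_identical(ua$msa$roles, c("target_locus", "homologue"))

  write_fasta(c(flanked = flanked, bare = bare_row), p)
  expect_error(read_user_alignment(p), "order")
})

test_that("external alignment backends error clearly when the binary is absent", {
  expect_error(align_sequences(c(target = "ACGTACGT", h = "ACGTACGT"),
                               backend = "muscle"),
               "backend unavailable")
})
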