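mk_hit <- function(subject, s_min, s_max, bitscore = 500, q_min = 0,
                   q_max = 100, strand = "+", query = "q") {
  data.frame(query_id = query, subject_id = subject, pct_identity = 95,
             aln_length = q_max - q_min, mismatches = 5L, gap_opens = 0L,
             q_start = q_min + 1L, q_end = q_max,
             s_start = if (strand == "+") s_min + 1L else s_max,
             s_end = if (strand == "+") s_max else s_min + 1L,
             e_value = 0, bitscore = bitscore)
}

test_that("hits chain into one group within the gap and split beyond it", {
  h <- rbind(mk_hit("s", 100, 500), mk_hit("s", 1200, 1600))
  g <- group_hits(h, max_group_gap = 1000)
  expect_length(g, 1L)          # gap 700 <= 1000
  expect_identical(c(g[[1]]$s_min, g[[1]]$s_max), c(100L, 1600L))

  h2 <- rbind(mk_hit("s", 100, 500), mk_hit("s", 1600, 2000))
  expect_length(group_hits(h2, 1000), 2L)  # gap 1100 > 1000

  expect_length(group_hits(empty_hits <- parse_blast_tabular({
    p <- tempfile(); writeLines(character(0), p); p
  })), 0L)
})

test_that("grouping matches a brute-force transitive-closure chainer on random instances", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 50
    h <- do.call(rbind, lapply(seq_len(n), function(i) {
      s0 <- sample(0:20000, 1)
      mk_hit(sample(c("c1", "c2", "c3"), 1), s0,
             s0 + sample(50:800, 1),
             strand = sample(c("+", "-"), 1))
    }))
    g <- group_hits(h, 1000)
    # signature of the implementation's partition
    hn <- normalize_hits(h)
    key <- paste(hn$subject_id, hn$strand, hn$s_min, hn$s_max)
    impl <- lapply(g, function(gr)
      paste(gr$hits$subject_id, gr$hits$strand, gr$hits$s_min,
            gr$hits$s_max))
    comp <- oracle_group_hits(h, 1000)
    orac <- split(key, comp)
    expect_identical(partition_signature(impl), partition_signature(orac))
    # partition property: every hit in exactly one group
    expect_identical(sort(unlist(impl)), sort(key))
    # max-gap property within each group
    for (gr in g) {
      s <- gr$hits[order(gr$hits$s_min), ]
      if (nrow(s) > 1) {
        reach <- cummax(s$s_max)
        expect_true(all(s$s_min[-1] - reach[-nrow(s)] <= 1000))
      }
    }
  }
})

test_that("group ranking is by total bitscore with coverage tie-break, and is order-invariant", {
  h <- rbind(mk_hit("a", 0, 500, bitscore = 3500),
             mk_hit("b", 0, 500, bitscore = 2100),
             mk_hit("c", 0, 500, bitscore = 400))
  r <- rank_groups(group_hits(h))
  expect_identical(vapply(r, `[[`, "", "subject_id"), c("a", "b", "c"))

  # equal totals: higher query coverage first
  h2 <- rbind(mk_hit("a", 0, 500, bitscore = 1000, q_min = 0, q_max = 90),
              mk_hit("b", 0, 500, bitscore = 1000, q_min = 0, q_max = 60))
  r2 <- rank_groups(group_hits(h2, query_length = 100))
  expect_identical(r2[[1]]$subject_id, "a")
  expect_gt(r2[[1]]$query_coverage, r2[[2]]$query_coverage)

  set.seed(1)
  h3 <- h[sample(nrow(h)), ]
  r3 <- rank_groups(group_hits(h3))
  expect_identical(vapply(r3, `[[`, "", "subject_id"),
                   vapply(r, `[[`, "", "subject_id"))
})

test_that("locus selection applies the mean-bitscore floor to homologues", {
  scores <- c(3500, 900, 850, 150, 90)
  h <- do.call(rbind, lapply(seq_along(scores), function(i)
    mk_hit(paste0("s", i), 0, 500, bitscore = scores[i])))
  sel <- select_loci(rank_groups(group_hits(h)),
                     n_homologue_groups = 3, bitscore_floor = 200)
  expect_identical(sel$target$subject_id, "s1")
  expect_length(sel$homologues, 2L)
  expect_length(sel$discarded, 2L)
  expect_true(all(vapply(sel$homologues, `[[`, 0, "mean_bitscore") > 200))
  expect_match(sel$discarded[[1]]$reason, "bitscore")

  sel1 <- expect_warning(
    select_loci(rank_groups(group_hits(mk_hit("only", 0, 500)))),
    "no homologues")
  expect_length(sel1$homologues, 0L)
})

test_that("flanked extraction honours buffers, clamping and minus-strand orientation", {
  set.seed(21)
  chrom <- random_dna(10000)
  p <- write_temp_fasta(list(chr1 = chrom))
  idx <- build_genome_index(p)

  g <- group_hits(mk_hit("chr1", 5000, 7400))[[1]]
  ex <- extract_flanked(g, idx, 1000, 1000)
  expect_identical(c(ex$start, ex$end), c(4000L, 8400L))
  expect_identical(nchar(ex$residues), 4400L)
  expect_identical(ex$residues, substr(chrom, 4001, 8400))
  expect_false(ex$clamped)

  g2 <- group_hits(mk_hit("chr1", 300, 900))[[1]]
  ex2 <- extract_flanked(g2, idx, 1000, 1000)
  expect_identical(c(ex2$start, ex2$end), c(0L, 1900L))
  expect_true(ex2$clamped)

  g3 <- group_hits(mk_hit("chr1", 5000, 7400, strand = "-"))[[1]]
  ex3 <- extract_flanked(g3, idx, 1000, 500)
  # minus strand: buffers swapped on the forward strand, then revcomped
  expect_identical(c(ex3$start, ex3$end), c(4500L, 8400L))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA",
                                  substr(chrom, 4501, 8400)),
                           "")[[1]]), collapse = "")
  expect_identical(ex3$residues, rc)

  expect_error(extract_flanked(group_hits(mk_hit("chrX", 0, 10))[[1]], idx),
               "chrX")
})

test_that("internal search finds planted and diverged copies but not random DNA", {
  set.seed(31)
  query <- random_dna(600)
  genome <- paste0(random_dna(2000), query, random_dna(2000))
  idx <- build_genome_index(write_temp_fasta(list(chr1 = genome)))
  h <- internal_search(c(q = query), idx)
  expect_identical(nrow(h), 1L)
  expect_equal(h$pct_identity, 100)
  expect_identical(c(h$q_start, h$q_end), c(1L, 600L))
  expect_identical(c(h$s_start, h$s_end), c(2001L, 2600L))

  # 93%-identity copy: union of hit query spans covers >= 95% of the query
  mut <- mutate_seq(query, 0.07)
  genome2 <- paste0(random_dna(1500), mut$seq, random_dna(1500))
  idx2 <- build_genome_index(write_temp_fasta(list(chr1 = genome2)))
  h2 <- internal_search(c(q = query), idx2)
  expect_gt(nrow(h2), 0L)
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(h2$q_start, h2$q_end))))
  expect_gte(cov / 600, 0.95)

  # a reverse-complemented copy is reported on the minus strand
  rcg <- paste0(random_dna(1000), revcomp(query), random_dna(1000))
  idx3 <- build_genome_index(write_temp_fasta(list(chr1 = rcg)))
  h3 <- internal_search(c(q = query), idx3)
  expect_true(any(h3$s_start > h3$s_end))

  # random DNA of the same length never yields an alignment >= 50 bases
  for (s in 1:20) {
    set.seed(1000 + s)
    rnd <- random_dna(600)
    idxr <- build_genome_index(write_temp_fasta(list(chr1 = rnd)))
    hr <- internal_search(c(q = query), idxr)
    expect_true(nrow(hr) == 0L || all(hr$aln_length < 50))
  }
})

test_that("imported tabular hits and the internal search give the same selection", {
  fx <- small_fixture()
  idx <- build_genome_index(fx$genomes[["variety1"]])
  h <- internal_search(c(gene = fx$gene), idx)
  p <- tempfile()
  write_blast_tabular(h, p)
  h2 <- parse_blast_tabular(p)
  sel1 <- select_loci(rank_groups(group_hits(h, query_length = nchar(fx$gene))))
  sel2 <- select_loci(rank_groups(group_hits(h2, query_length = nchar(fx$gene))))
  expect_identical(sel1$target$subject_id, sel2$target$subject_id)
  expect_identical(vapply(sel1$homologues, `[[`, "", "subject_id"),
                   vapply(sel2$homologues, `[[`, "", "subject_id"))
  expect_identical(sel1$target$s_min, sel2$target$s_min)
})
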