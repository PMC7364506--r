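test_that("melting temperature matches a stack-sum oracle and duplex symmetry", {
  # independent oracle: loop over the 19 dinucleotide stacks of a 20-mer,
  # summing the published unified parameters
  dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
          TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
          GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          CC = -19.9)
  oracle_tm <- function(s, na_mM = 50, c_nM = 500) {
    ch <- strsplit(s, "")[[1]]
    H <- 0; S <- 0
    for (i in 1:(length(ch) - 1)) {
      st <- paste0(ch[i], ch[i + 1])
      H <- H + dh[[st]]
      S <- S + ds[[st]]
    }
    for (e in ch[c(1, length(ch))]) {
      if (e %in% c("A", "T")) { H <- H + 2.3; S <- S + 4.1 }
      else { H <- H + 0.1; S <- S - 2.8 }
    }
    S <- S + 0.368 * (length(ch) - 1) * log(na_mM / 1000)
    1000 * H / (S + 1.987 * log(c_nM * 1e-9 / 4)) - 273.15
  }
  set.seed(8)
  for (k in 1:40) {
    s <- random_dna(sample(15:27, 1))
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 1e-12)
    expect_equal(melting_temperature(revcomp(s)), melting_temperature(s),
                 tolerance = 1e-12)
  }
  expect_lt(melting_temperature(strrep("A", 20)),
            melting_temperature(strrep("GC", 10)))
  expect_error(melting_temperature("ACGTNACGTAA"), "A/C/G/T")
  expect_error(melting_temperature("ACGT"), "shorter")
})

test_that("complementarity scores equal exhaustive enumeration on random oligos", {
  set.seed(12)
  for (k in 1:100) {
    s <- random_dna(sample(18:27, 1))
    got <- complementarity_scores(s)
    od <- oracle_dimer(s, s)
    expect_identical(unname(got["self_any"]), unname(od["any"]),
                     info = s)
    expect_identical(unname(got["self_end"]), unname(od["end"]),
                     info = s)
    expect_identical(unname(got["hairpin"]), as.numeric(oracle_hairpin(s)),
                     info = s)
  }
  # cross-dimer against the same oracle
  for (k in 1:30) {
    a <- random_dna(20); b <- random_dna(22)
    expect_identical(cross_dimer_score(a, b),
                     unname(oracle_dimer(a, b)["any"]), info = paste(a, b))
  }
})

test_that("complementarity edge cases: poly-A inert, palindromic stem folds", {
  s <- complementarity_scores(strrep("A", 18))
  expect_identical(unname(s["self_any"]), 0)
  expect_identical(unname(s["hairpin"]), 0)
  # 8-pair stem around a 4-base loop
  expect_gte(complementarity_scores("GCGCGCGCATATGCGCGCGC")["hairpin"], 8)
})

test_that("primer penalty is zero at the optimum and monotone in each deviation", {
  p <- design_parameters()
  expect_identical(primer_penalty(tm = 60, len = 20, gc = 50, self_any = 0,
                                  self_end = 0, hairpin = 0, FALSE, p), 0)
  expect_lt(primer_penalty(61, 20, 50, 0, 0, 0, FALSE, p),
            primer_penalty(63, 20, 50, 0, 0, 0, FALSE, p))
  # hand-computed weighted sum for a fixed fixture candidate
  expect_equal(primer_penalty(tm = 58.5, len = 23, gc = 72, self_any = 6,
                              self_end = 2, hairpin = 3, TRUE, p),
               1.0 * 1.5 + 1.0 * 3 + 0.5 * 2 + 0.1 * 6 + 0.2 * 2 +
                 0.1 * 3 + 2.0)
  # gc below the window is penalised symmetrically to above
  expect_equal(primer_penalty(60, 20, 25, 0, 0, 0, FALSE, p), 0.5 * 5)
})

test_that("pair penalty is symmetric and hand-computable", {
  p <- design_parameters()
  expect_equal(pair_penalty(1.2, 0.8, 59, 61, 4, p),
               pair_penalty(0.8, 1.2, 61, 59, 4, p))
  expect_equal(pair_penalty(1.2, 0.8, 59, 61, 4, p),
               1.2 + 0.8 + 0.5 * 2 + 0.1 * 4)
  expect_equal(pair_penalty(0, 0, 60, 60, 0, p), 0)
})

test_that("candidate generation anchors every 3' terminus on its SNP", {
  set.seed(33)
  target <- random_dna(400)
  snps <- data.frame(column = c(5L, 200L, 396L),
                     target_pos = c(5L, 200L, 396L),
                     target_base = substring(target, c(6, 201, 397),
                                             c(6, 201, 397)),
                     homologue_bases = "G", n_evidence = 1L,
                     discriminating = TRUE, gap_discriminated = FALSE,
                     varietal_conflict = FALSE)
  cand <- generate_candidates(snps, target)
  p <- design_parameters()

  # counting: at most one forward and one reverse candidate per length
  mid <- cand[cand$anchor_pos == 200, ]
  expect_lte(sum(mid$direction == "F"), p$len_max - p$len_min + 1L)
  expect_identical(sum(mid$direction == "F"), 10L)
  expect_identical(sum(mid$direction == "R"), 10L)

  # a SNP too close to the 5' end yields no forward candidates
  near5 <- cand[cand$anchor_pos == 5, ]
  expect_identical(sum(near5$direction == "F"), 0L)
  expect_gt(sum(near5$direction == "R"), 0L)
  # and near the 3' end, no reverse candidates
  near3 <- cand[cand$anchor_pos == 396, ]
  expect_identical(sum(near3$direction == "R"), 0L)

  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    if (r$direction == "F") {
      expect_identical(substring(r$sequence, r$length, r$length),
                       substring(target, r$anchor_pos + 1, r$anchor_pos + 1))
      expect_identical(r$end - 1L, r$anchor_pos)
    } else {
      # reverse candidate: 3' base is the complement of the target base
      expect_identical(substring(r$sequence, r$length, r$length),
                       chartr("ACGT", "TGCA",
                              substring(target, r$anchor_pos + 1,
                                        r$anchor_pos + 1)))
      expect_identical(r$start, r$anchor_pos)
    }
  }

  # varietal-conflict SNPs are never used
  snps$varietal_conflict <- TRUE
  expect_identical(nrow(generate_candidates(snps, target)), 0L)

  # candidates spanning an N are dropped
  target_n <- paste0(substr(target, 1, 195), "N", substr(target, 197, 400))
  cand_n <- generate_candidates(snps[2, ], target_n)
  expect_identical(nrow(cand_n), 0L)
})
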