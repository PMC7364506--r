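# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation of a contract, kept
# separate from the implementation path it checks.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# mutate a sequence at a given per-site substitution rate; returns the
# mutated string and the 1-based positions changed
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  pos <- which(runif(length(ch)) < rate)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  list(seq = paste(ch, collapse = ""), positions = pos)
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    body <- seqs[[nm]]
    starts <- seq(1, nchar(body), by = 60)
    writeLines(substring(body, starts, pmin(starts + 59, nchar(body))), con)
  }
  close(con)
  path
}

# --- brute-force transitive-closure hit chainer ------------------------
# two hits connect when same (query, subject, strand) and their subject
# intervals are within `gap` bases; groups are connected components.
oracle_group_hits <- function(hits, gap = 1000) {
  h <- normalize_hits(hits)
  n <- nrow(h)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (h$query_id[i] == h$query_id[j] &&
        h$subject_id[i] == h$subject_id[j] &&
        h$strand[i] == h$strand[j]) {
      d <- max(h$s_min[i], h$s_min[j]) - min(h$s_max[i], h$s_max[j])
      if (d <= gap) adj[i, j] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# canonical signature of a hit partition: sorted member row-signatures per
# group, sorted across groups
partition_signature <- function(groups_members) {
  sig <- vapply(groups_members, function(m)
    paste(sort(m), collapse = ","), "")
  sort(unname(sig))
}

# --- exhaustive affine-gap global alignment score ----------------------
oracle_global_score <- function(a, b, match = 5, mismatch = -4,
                                go = 10, ge = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + i * ge)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + j * ge)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                           Y[i, j + 1] - go - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge,
                           X[i + 1, j] - go - ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exhaustive complementarity enumeration ----------------------------
comp_base <- c(A = "T", C = "G", G = "C", T = "A")
pair_w <- c(A = 1, C = 2, G = 2, T = 1)

oracle_dimer <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  best_any <- 0
  best_end <- 0
  # slide copy of b (3'->5', i.e. reversed) under a; a[i] pairs with b[j]
  for (off in -(m - 1):(n - 1)) {
    run <- 0
    run_has_end <- FALSE
    for (i in max(1, 1 + off):min(n, m + off)) {
      j <- m - (i - off) + 1          # antiparallel partner in b
      if (B[j] == comp_base[[A[i]]]) {
        run <- run + pair_w[[A[i]]]
        if (i == n || j == m) run_has_end <- TRUE
        best_any <- max(best_any, run)
        if (run_has_end) best_end <- max(best_end, run)
      } else {
        run <- 0
        run_has_end <- FALSE
      }
    }
  }
  c(any = best_any, end = best_end)
}

oracle_hairpin <- function(a, min_loop = 3) {
  A <- strsplit(a, "")[[1]]
  n <- length(A)
  best <- 0
  if (n < min_loop + 2) return(0)
  for (i in 1:(n - min_loop - 1)) for (j in (i + min_loop + 1):n) {
    stem <- 0
    while (i - stem >= 1 && j + stem <= n &&
           A[j + stem] == comp_base[[A[i - stem]]]) stem <- stem + 1
    best <- max(best, stem)
  }
  best
}

# --- naive in-silico PCR scan ------------------------------------------
oracle_pcr_sites <- function(primer, template, max_mm) {
  P <- strsplit(primer, "")[[1]]
  Tc <- strsplit(template, "")[[1]]
  L <- length(P)
  out <- list()
  for (i in seq_len(length(Tc) - L + 1)) {
    mm <- sum(Tc[i:(i + L - 1)] != P)
    if (mm <= max_mm) out[[length(out) + 1]] <- c(start = i - 1, mm = mm)
  }
  if (length(out)) do.call(rbind, out) else
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "mm")))
}

# --- exhaustive tiling subset search -----------------------------------
oracle_best_tiling <- function(pairs, input_region, min_overlap = 50) {
  n <- nrow(pairs)
  best <- Inf
  in0 <- input_region[1]
  in1 <- input_region[2]
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sel <- pairs[idx, , drop = FALSE]
    sel <- sel[order(sel$product_start, sel$product_size), , drop = FALSE]
    ok <- sel$product_start[1] <= in0 && sel$product_end[1] > in0 &&
      sel$product_end[nrow(sel)] >= in1
    if (ok && nrow(sel) > 1) {
      for (k in 2:nrow(sel)) {
        if (!(sel$product_start[k] > sel$product_start[k - 1] &&
              sel$product_end[k] > sel$product_end[k - 1] &&
              sel$product_end[k - 1] - sel$product_start[k] >= min_overlap)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) best <- min(best, sum(sel$pair_penalty))
  }
  best
}

# small shared end-to-end fixture (generated once per test run)
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixture(
        fixture_spec(seed = 11, gene_length = 1200, chrom_length = 12000),
        dir = file.path(tempdir(), "homeoprimer_small_fixture"))
    }
    cache
  }
})
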