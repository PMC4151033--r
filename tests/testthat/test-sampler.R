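# Fingerprint enumeration, candidate generation, the stopping bound, and the
# three Gibbs phases.

test_that("fingerprint enumeration is lexicographic and complete", {
  expect_identical(enumerate_fingerprints(1), "AAA")
  head6 <- enumerate_fingerprints(6)
  expect_identical(head6, c("AAA", "AAC", "AAD", "AAE", "AAF", "AAG"))
  fp <- enumerate_fingerprints(8000)
  only_ac <- fp[!grepl("[^AC]", fp)]
  expect_identical(length(only_ac), 8L)  # 2^3 triples over {A, C}
  # 1540 distinct multisets under unordered matching
  expect_identical(length(unique(gibbsmotif:::.sort_key(fp))), 1540L)
  expect_error(enumerate_fingerprints(0), "1..8000")
  expect_error(enumerate_fingerprints(8001), "1..8000")
})

test_that("seed candidate generation agrees with cubic brute force", {
  set.seed(41)
  s <- random_coil_structure(30, "cand")
  for (fp in c("AAC", paste(sort(sample(amino_alphabet(), 3)), collapse = ""),
               paste(s$symbols[1:3][order(s$symbols[1:3])], collapse = ""))) {
    got <- enumerate_seed_candidates(s, fp, radius = 10)
    want <- oracle_seed_triples(s, fp, radius = 10)
    expect_identical(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                     want[order(want[, 1], want[, 2], want[, 3]), ,
                          drop = FALSE])
  }
})

test_that("forced and empty candidate cases behave as specified", {
  # exactly one A,A,C clique within radius
  s1 <- cluster_structure(list(c(4, 5, 6)), "one")
  got <- enumerate_seed_candidates(s1, "AAC")
  expect_identical(got, matrix(1:3, 1, 3))
  # no C residue -> empty
  s2 <- calpha_structure("noC", c("A", "A", "G"),
                         rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)))
  expect_identical(nrow(enumerate_seed_candidates(s2, "AAC")), 0L)
  # ordered matching distinguishes arrangements
  ord <- enumerate_seed_candidates(s1, "AAC", ordered = TRUE)
  expect_true(all(apply(ord, 1, function(ix)
    identical(s1$symbols[ix], c("A", "A", "C")))))
  expect_identical(nrow(ord), 2L)  # two A positions permute
})

test_that("the stopping bound matches a brute-force scan", {
  expect_identical(gibbs_iterations_bound(6, 0.05), 16L)
  expect_identical(gibbs_iterations_bound(2, 0.25), 1L)
  expect_identical(gibbs_iterations_bound(2, 0.5), 0L)   # alpha >= (N-1)/N
  expect_identical(gibbs_iterations_bound(4, 0.9), 0L)
  for (n in c(2, 3, 7, 20)) {
    for (a in c(0.01, 0.05, 0.1, 0.3)) {
      r <- (n - 1) / n
      ks <- 1:2000
      brute <- suppressWarnings(max(0L, max(ks[r^ks > a])))
      expect_identical(gibbs_iterations_bound(n, a), as.integer(brute))
    }
  }
  expect_error(gibbs_iterations_bound(1, 0.05), "two structures")
  expect_error(gibbs_iterations_bound(4, 0), "alpha")
})

test_that("bootstrap returns the forced combination or NULL when starved", {
  set.seed(42)
  params <- motif_params(w = 3, rng_seed = 1)
  # every structure has exactly one candidate
  structures <- lapply(1:3, function(i)
    cluster_structure(list(c(4, 5, 6)), paste0("f", i)))
  rows <- bootstrap_phase(structures, "AAC", params)
  expect_identical(bare_rows(rows), matrix(rep(1:3, 3), 3, 3, byrow = TRUE))
  # one structure without candidates stops the fingerprint
  starved <- c(structures[1:2],
               list(calpha_structure("bare", c("G", "G", "G"),
                                     rbind(c(0, 0, 0), c(4, 0, 0),
                                           c(0, 4, 0)))))
  expect_null(bootstrap_phase(starved, "AAC", params))
})

test_that("the chain stalls at least the bound after its last change", {
  set.seed(43)
  fx <- make_seed_cluster_structures(4, 5)
  params <- motif_params(w = 3, alpha = 0.05, rng_seed = 1)
  rows <- bootstrap_phase(fx$structures, "AAC", params)
  k <- gibbs_iterations_bound(4, 0.05)
  expect_false(is.null(rows))
  if (attr(rows, "steps") < params$max_steps)
    expect_gte(attr(rows, "stall"), k)
})

test_that("bootstrap recovers a planted zero-distance seed combination", {
  set.seed(44)
  fx <- make_seed_cluster_structures(4, 5)
  params <- motif_params(w = 3, alpha = 0.05, rng_seed = 1)
  hits <- 0L
  for (run in 1:10) {
    rows <- bootstrap_phase(fx$structures, "AAC", params)
    if (!is.null(rows) && identical(bare_rows(rows), bare_rows(fx$planted)))
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("extension grows identical structures into zero-RMSD alignments", {
  set.seed(45)
  s <- random_coil_structure(40, "id")
  structures <- list(s, s, s)
  params <- motif_params(w = 8, rng_seed = 1)
  seed_rows <- matrix(rep(c(5L, 6L, 7L), each = 3), 3, 3)
  zero <- 0L
  for (run in 1:10) {
    rows <- extend_alignment(structures, seed_rows, params)
    if (!is.null(rows) && ncol(rows) == 8 &&
        average_pairwise_rmsd(rows, structures) < 1e-8 &&
        all(rows[1, ] == rows[2, ]) && all(rows[1, ] == rows[3, ]))
      zero <- zero + 1L
  }
  expect_gte(zero, 9L)
})

test_that("extension honours its gate, width, and starvation contracts", {
  set.seed(46)
  s <- random_coil_structure(40, "id")
  params <- motif_params(w = 8, rng_seed = 1)
  # width already w -> unchanged
  rows_w <- matrix(rep(1:8, each = 2), 2, 8)
  expect_identical(extend_alignment(list(s, s), rows_w, params), rows_w)
  # geometrically isolated row -> no candidates -> NULL
  iso <- cluster_structure(list(c(4, 5, 6)), "iso")
  got <- extend_alignment(list(iso, iso),
                          matrix(rep(1:3, each = 2), 2, 3),
                          motif_params(w = 4, rng_seed = 1))
  expect_null(got)
  # a seed failing the 1 A gate is rejected up front
  far <- calpha_structure("far", s$symbols, s$xyz + matrix(
    rnorm(120, sd = 3), 40, 3))
  bad_rows <- matrix(rep(c(5L, 6L, 7L), each = 2), 2, 3)
  gate <- average_pairwise_rmsd(bad_rows, list(s, far))
  if (gate > 1)
    expect_error(extend_alignment(list(s, far), bad_rows, params),
                 "seed gate")
})

test_that("refinement removes the worst column and preserves perfection", {
  set.seed(47)
  s <- random_coil_structure(40, "ref")
  structures <- list(s, s, s)
  params <- motif_params(w = 6, iter_refine = 1, rng_seed = 1)
  # corrupt one row entry of a perfect alignment: that column maximises
  # badness, and the brute-force oracle agrees
  rows <- matrix(rep(10:15, each = 3), 3, 6)
  rows[2, 4] <- 30L
  b <- vapply(1:6, function(k) badness(rows, structures, k), numeric(1))
  b_oracle <- vapply(1:6, function(k) oracle_badness(rows, structures, k),
                     numeric(1))
  expect_equal(b, b_oracle, tolerance = 1e-9)
  expect_identical(which.max(b), 4L)
  # iter_refine = 0 leaves the alignment untouched
  params0 <- motif_params(w = 6, iter_refine = 0, rng_seed = 1)
  expect_identical(refine_alignment(structures, rows, params0), rows)
  # a perfect alignment stays perfect through refinement
  perfect <- matrix(rep(10:15, each = 3), 3, 6)
  out <- refine_alignment(structures, perfect,
                          motif_params(w = 6, iter_refine = 2, rng_seed = 1))
  expect_identical(dim(out), c(3L, 6L))
  expect_lt(average_pairwise_rmsd(out, structures), 1e-8)
})

test_that("the driver is deterministic and tolerates empty searches", {
  fx <- generate_planted_motif_set(3, 6, 25, noise_sigma = 0.05,
                                   rng_seed = 48)
  fps <- planted_motif_fingerprints(fx)
  fit1 <- gibbsmotif(fx$structures, w = 6, rng_seed = 9, fingerprints = fps)
  fit2 <- gibbsmotif(fx$structures, w = 6, rng_seed = 9, fingerprints = fps)
  expect_identical(as.data.frame(fit1), as.data.frame(fit2))
  expect_s3_class(fit1, "gibbsmotif")
  # two structures sharing no symbol triple: empty result is legal
  set.seed(49)
  a <- calpha_structure("allA", rep("A", 12), random_coil_structure(12)$xyz)
  b <- calpha_structure("allC", rep("C", 12), random_coil_structure(12)$xyz)
  fit0 <- gibbsmotif(list(a, b), w = 3, rng_seed = 1, max_fingerprints = 200)
  expect_identical(length(fit0$alignments), 0L)
  expect_error(gibbsmotif(list(a), w = 3), "two structures")
  expect_error(gibbsmotif(list(a, b), w = 50), "shorter than w")
})

test_that("reported alignments satisfy the structural invariants", {
  fx <- generate_planted_motif_set(3, 8, 30, noise_sigma = 0.1, rng_seed = 50)
  fit <- gibbsmotif(fx$structures, w = 8, rng_seed = 2,
                    fingerprints = planted_motif_fingerprints(fx))
  expect_gt(length(fit$alignments), 0)
  for (al in fit$alignments) {
    expect_identical(dim(al$rows), c(3L, 8L))
    for (i in 1:3) {
      row <- al$rows[i, ]
      expect_identical(anyDuplicated(row), 0L)
      # residues pairwise-connected in the candidate-radius graph
      sub <- fx$structures[[i]]$dist[row, row] < 10
      reach <- sub
      for (step in 1:8) reach <- (reach %*% sub) > 0
      expect_true(all(reach))
    }
  }
})

test_that("longer chains recover the planted optimum at least as often", {
  set.seed(51)
  fx <- make_seed_cluster_structures(4, 5)
  rate <- function(alpha) {
    params <- motif_params(w = 3, alpha = alpha, rng_seed = 1)
    hits <- 0L
    for (run in 1:15) {
      rows <- bootstrap_phase(fx$structures, "AAC", params)
      if (!is.null(rows) && identical(bare_rows(rows), bare_rows(fx$planted)))
        hits <- hits + 1L
    }
    hits
  }
  r_short <- rate(0.3)
  r_long <- rate(0.05)
  expect_gte(r_long + 2L, r_short)  # monotone up to Monte-Carlo slack
})
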