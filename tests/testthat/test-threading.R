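test_that("residue profiles multiply density tables by structure weights", {
  # identity weights reduce to the density table
  dt <- c(A = 1, G = 0.5, W = 2)
  ws <- c(H = 1, E = 1, C = 1)
  p <- residue_profile("AGW", d_table = dt, w_ss = ws)
  expect_equal(p$A, c(1, 0.5, 2))

  # non-trivial structure weights scale per position
  ws2 <- c(H = 2, E = 1, C = 0.5)
  p2 <- residue_profile("AGW", ss = "HEC", d_table = dt, w_ss = ws2)
  expect_equal(p2$A, c(2, 0.5, 1))

  # default table orders residues by heavy-atom count
  pd <- residue_profile("GAW")
  expect_true(pd$A[1] < pd$A[2] && pd$A[2] < pd$A[3])

  # uniform sequence gives a constant profile
  expect_equal(length(unique(residue_profile("AAAA")$A)), 1L)

  expect_error(residue_profile("AXZ", d_table = dt, w_ss = ws), "unknown")
})

test_that("path profiles apply the printed Gaussian smoothing", {
  fx <- helix_fixture()
  ldps <- helix_ldps()

  # single LDP: V = v / sigma_path
  pp1 <- path_profile(ldps, 1L, fx$map, sigma_path = 1)
  expect_equal(pp1$V, pp1$v_raw)
  expect_equal(pp1$v_raw, sum(fx$map$values[ldps$members[[1]]]))

  # hand evaluation on a stubbed two-point path
  l2 <- stub_ldps(rbind(c(0, 0, 0), c(1, 0, 0)))
  g <- density_grid(array(c(1, 0), dim = c(2, 1, 1)))
  pp2 <- path_profile(l2, 1:2, g, sigma_path = 1)
  expect_equal(pp2$v_raw, c(1, 0))
  expect_equal(pp2$V, c(1, exp(-0.5)), tolerance = 1e-12)

  # constant v on an equally spaced path: interior values are constant
  l5 <- stub_ldps(cbind(0:4, 0, 0))
  g5 <- density_grid(array(1, dim = c(5, 1, 1)))
  pp5 <- path_profile(l5, 1:5, g5, sigma_path = 1)
  expect_equal(pp5$V[2], pp5$V[4], tolerance = 1e-12)
  expect_lt(pp5$V[1], pp5$V[3])  # edge effect at the termini
})

test_that("the Z-score similarity follows its closed form", {
  V <- c(1, 2, 3); A <- c(3, 2, 1)
  S <- zscore_similarity(V, A)
  zv <- (V - 2) / sqrt(2 / 3); za <- (A - 2) / sqrt(2 / 3)
  expect_equal(S, 1 - abs(outer(zv, za, "-")))
  expect_equal(S[2, 2], 1.0)          # equal Z-scores
  expect_equal(1 - abs(1.5 - 0.5), 0) # printed example values
  expect_equal(1 - abs(2.5), -1.5)    # scores can be negative
  # zero variance: Z = 0 for that string
  expect_equal(zscore_similarity(c(1, 1), c(0, 2)),
               matrix(1 - abs(outer(c(0, 0), c(-1, 1), "-")), 2, 2))
})

test_that("measure_d returns arc or chord distances between path points", {
  p <- stub_path(rbind(c(0, 0, 0), c(1.9, 0, 0), c(3.8, 0, 0)), V = 1:3)
  expect_equal(measure_d(p, 1, 2), 1.9)
  expect_equal(measure_d(p, 1, 3), 3.8)
  expect_equal(measure_d(p, 1, 3, metric = "euclidean"), 3.8)
  # on a bent path arc exceeds the chord
  pb <- stub_path(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)), V = 1:3)
  expect_gt(measure_d(pb, 1, 3), measure_d(pb, 1, 3, metric = "euclidean"))
  expect_error(measure_d(p, 2, 2))
})

test_that("threading scores match exhaustive alignment enumeration", {
  # base case: single residue on a single LDP scores SCO = 1
  p1 <- stub_path(c(0, 0, 0), V = 2)
  tm <- thread_sequence(stub_profile(1.5), p1)
  expect_equal(tm$score, 1.0)
  expect_equal(tm$assignments, 1L)

  # randomized instances, both distance metrics
  set.seed(21)
  for (rep in 1:60) {
    N <- sample(2:4, 1); L <- sample(2:7, 1)
    pos <- matrix(runif(L * 3, 0, 8), ncol = 3)
    pos <- pos[order(pos[, 1]), , drop = FALSE]
    V <- runif(L, 0, 5); A <- runif(N, 0.5, 2)
    pp <- stub_path(pos, V)
    for (metric in c("arc", "euclidean")) {
      tm <- thread_sequence(stub_profile(A), pp, gap = -0.7, w_ca = 0.9,
                            d_std = 3.8, d_metric = metric)
      bf <- brute_thread_score(V, A, pp$arc, pos, gap = -0.7, w_ca = 0.9,
                               d_std = 3.8, metric = metric)
      expect_equal(tm$score, bf, tolerance = 1e-9, info = metric)
    }
  }
})

test_that("alignments are monotone and shift-invariant in V", {
  set.seed(8)
  pos <- cbind(cumsum(runif(12, 1, 2)), 0, 0)
  V <- runif(12, 1, 4)
  pp <- stub_path(pos, V)
  A <- runif(6, 0.5, 1.5)
  tm <- thread_sequence(stub_profile(A), pp)
  idx <- tm$assignments[!is.na(tm$assignments)]
  expect_true(all(diff(idx) > 0))
  expect_true(all(is.finite(tm$ca_coords)))

  # adding a constant to V leaves the score unchanged (Z-scoring)
  pp2 <- stub_path(pos, V + 37)
  tm2 <- thread_sequence(stub_profile(A), pp2)
  expect_equal(tm2$score, tm$score, tolerance = 1e-9)

  # a palindromic profile threads identically in both directions
  Vp <- c(1, 2, 3, 2, 1)
  ppp <- stub_path(cbind(seq(0, 15.2, by = 3.8), 0, 0), Vp)
  Ap <- c(0.5, 1.5, 0.5)
  tf <- thread_sequence(stub_profile(Ap), ppp, direction = "forward")
  tr <- thread_sequence(stub_profile(Ap), ppp, direction = "reverse")
  expect_equal(tf$score, tr$score, tolerance = 1e-9)
})

test_that("gapped residues are interpolated and termini extrapolated", {
  pos <- cbind(seq(0, 38, by = 3.8), 0, 0)  # 11 points on a line
  V <- rep(1, 11)
  pp <- stub_path(pos, V)
  # profile with 5 residues, make ends unmatched by using short path piece
  A <- c(1, 1, 1, 1, 1)
  tm <- thread_sequence(stub_profile(A), pp, d_std = 3.8)
  expect_true(all(is.finite(tm$ca_coords)))
  # consecutive placed residues are near the standard spacing on a line
  dd <- sqrt(rowSums(diff(tm$ca_coords)^2))
  expect_true(all(dd > 2.5 & dd < 5))
})
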