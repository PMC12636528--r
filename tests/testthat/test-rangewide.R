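test_that("the species-wide matrix has the printed design size", {
  ds <- generate_study(seed = 61)
  sp <- build_component_spaces(ds, n_perm = 99, seed = 1)
  rw <- rangewide_analysis(sp)
  for (s in c("cluster", "edge", "visual")) {
    expect_equal(dim(rw$matrices[[s]]), c(52L, 309L))
    expect_equal(length(rw$matrices[[s]]), 16068L)
    expect_true(all(is.finite(rw$matrices[[s]])))
    expect_true(all(rw$matrices[[s]] >= 0))
    expect_equal(nrow(rw$location_means[[s]]), 364L)
  }
  expect_equal(nrow(rw$points3d), 364L)
})

test_that("distance matrix entries are exact Euclidean values", {
  L <- rbind(L1 = c(0, 0), L2 = c(1, 1))
  B <- rbind(B1 = c(3, 4), B2 = c(1, 1), B3 = c(-2, 0))
  D <- all_pairs_distances(L, B)
  expect_equal(D["L1", "B1"], 5)
  expect_equal(D["L2", "B2"], 0)
  expect_equal(D["L1", "B3"], 2)
  expect_error(all_pairs_distances(L, B[0, , drop = FALSE]), "empty")
})

test_that("location means agree with a brute-force loop oracle", {
  set.seed(67)
  D <- matrix(runif(5 * 12), 5, 12,
              dimnames = list(sprintf("L%d", 1:5), NULL))
  locs <- rep(c("x", "y", "z"), c(5, 4, 3))
  lm <- location_means(D, locs)
  expect_equal(nrow(lm), 15L)
  for (i in 1:5) {
    for (loc in c("x", "y", "z")) {
      v <- D[i, locs == loc]
      row <- lm[lm$lizard_id == rownames(D)[i] & lm$location == loc, ]
      expect_equal(row$mean, mean(v), tolerance = 1e-12)
      expect_equal(row$se, sd(v) / sqrt(length(v)), tolerance = 1e-12)
    }
  }
  # equal distances within a location give SE zero
  D2 <- matrix(1, 2, 4)
  lm2 <- location_means(D2, rep("a", 4))
  expect_equal(lm2$se, c(0, 0))
  # grand mean is reproduced when location counts are equal
  De <- matrix(runif(3 * 6), 3, 6)
  lme <- location_means(De, rep(c("u", "v"), each = 3))
  expect_equal(mean(lme$mean), mean(De), tolerance = 1e-12)
})

test_that("Hotelling T2 matches the squared pooled two-sample t in 1D", {
  ht <- hotelling_t2(cbind(c(1, 2, 3)), cbind(c(4, 5, 6)))
  expect_equal(ht$T2, 13.5, tolerance = 1e-12)
  expect_equal(ht$df, 1)
  # equals t^2 on random fixtures
  set.seed(71)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(11, mean = 0.5)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(hotelling_t2(cbind(a), cbind(b))$T2,
                 unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("Hotelling T2 is zero for identical groups, affine invariant", {
  set.seed(73)
  A <- matrix(rnorm(30), 10, 3)
  ht0 <- hotelling_t2(A, A)
  expect_equal(ht0$T2, 0, tolerance = 1e-10)
  B <- matrix(rnorm(36, 1), 12, 3)
  base <- hotelling_t2(A, B)$T2
  M <- matrix(c(2, 0.5, 0, 1, 1, 0, 0, -1, 3), 3, 3)
  shift <- c(5, -2, 1)
  At <- sweep(A %*% M, 2, shift, "+")
  Bt <- sweep(B %*% M, 2, shift, "+")
  expect_equal(hotelling_t2(At, Bt)$T2, base, tolerance = 1e-8)
  expect_error(hotelling_t2(A[1:2, ], B[1:2, ]), "few")
  # collinear coordinates produce a singular pooled covariance
  Ac <- cbind(A[, 1], A[, 1], A[, 2])
  Bc <- cbind(B[, 1], B[, 1], B[, 2])
  expect_error(hotelling_t2(Ac, Bc), "singular")
})

test_that("pairwise Hotelling tests cover all pairs and stay null-calibrated", {
  set.seed(79)
  X <- matrix(rnorm(70 * 3), 70, 3)
  g <- rep(letters[1:7], each = 10)
  pw <- pairwise_hotelling(X, g)
  expect_equal(nrow(pw$results), choose(7, 2))
  expect_true(isSymmetric(pw$chisq_matrix))
  expect_true(all(diag(pw$chisq_matrix) == 0))

  # two groups from one distribution rarely reject after adjustment
  rej <- 0
  for (r in 1:30) {
    set.seed(1000 + r)
    Y <- matrix(rnorm(100 * 3), 100, 3)
    gg <- rep(c("a", "b"), each = 50)
    pwr <- pairwise_hotelling(Y, gg)
    rej <- rej + (pwr$results$p_adj[1] < 0.05)
  }
  expect_lte(rej / 30, 0.10)

  # a strongly separated pair dominates the chi-square matrix
  Z <- rbind(matrix(rnorm(60), 20, 3),
             matrix(rnorm(60, mean = 8), 20, 3),
             matrix(rnorm(60, mean = 0.2), 20, 3))
  gz <- rep(c("near1", "far", "near2"), each = 20)
  pz <- pairwise_hotelling(Z, gz)
  mx <- max(pz$chisq_matrix, na.rm = TRUE)
  expect_equal(pz$chisq_matrix["near1", "far"] == mx ||
                 pz$chisq_matrix["near2", "far"] == mx, TRUE)

  # small groups are flagged untestable
  Xs <- matrix(rnorm(24), 8, 3)
  gs <- rep(c("a", "b"), c(4, 4))
  ps <- pairwise_hotelling(Xs, gs)
  expect_false(ps$results$testable[1])
})

test_that("within- vs between-location summaries match brute force", {
  set.seed(83)
  D <- matrix(runif(6 * 9), 6, 9)
  lloc <- rep(c("p", "q", "r"), each = 2)
  bloc <- rep(c("p", "q", "r"), each = 3)
  wb <- within_vs_between(D, lloc, bloc)
  for (loc in c("p", "q", "r")) {
    lr <- which(lloc == loc)
    expect_equal(wb$within_mean[wb$location == loc],
                 mean(D[lr, bloc == loc]), tolerance = 1e-12)
    expect_equal(wb$outside_mean[wb$location == loc],
                 mean(D[lr, bloc != loc]), tolerance = 1e-12)
  }
  # single location: outside undefined
  wb1 <- within_vs_between(D[1:2, 1:3], c("p", "p"), rep("p", 3))
  expect_true(is.na(wb1$outside_mean))

  # construction: lizards equal to their own location's background mean
  lizv <- rbind(c(0, 0), c(10, 10))
  bgv <- rbind(c(-1, 0), c(1, 0), c(9, 10), c(11, 10))
  Dc <- all_pairs_distances(lizv, bgv)
  wbc <- within_vs_between(Dc, c("u", "v"), c("u", "u", "v", "v"))
  expect_true(all(wbc$within_mean < wbc$outside_mean))
  expect_false(any(wbc$outside_lower))
})

test_that("a location shifted away from its lizards shows outside < within", {
  eff <- effect_spec(shifted_location = list(location = "Werrikimbe",
                                             shift = 4))
  ds <- generate_study(study_design(n_corrupted = 0L), eff, seed = 89)
  sp <- build_component_spaces(ds, n_perm = 99, seed = 1)
  rw <- rangewide_analysis(sp)
  for (s in c("cluster", "edge", "visual")) {
    wb <- rw$within_between[[s]]
    expect_true(wb$outside_lower[wb$location == "Werrikimbe"])
    expect_false(any(wb$outside_lower[wb$location != "Werrikimbe"]))
  }
})
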