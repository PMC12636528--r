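test_that("microhabitat distances are plain Euclidean norms", {
  r <- microhabitat_distances(c(0, 0), rbind(B1 = c(3, 4)))
  expect_equal(r$d, 5)
  r0 <- microhabitat_distances(c(1, 2, 3), rbind(B1 = c(1, 2, 3)))
  expect_equal(r0$d, 0)
  # permuting coordinate order of both vectors leaves d unchanged
  l <- c(0.3, -1, 2); B <- rbind(B1 = c(1, 0.5, -2), B2 = c(0, 0, 0))
  perm <- c(3, 1, 2)
  expect_equal(microhabitat_distances(l, B)$d,
               microhabitat_distances(l[perm], B[, perm])$d)
  expect_error(microhabitat_distances(c(0, 0), rbind(c(1, 2, 3))),
               "dimension")
})

test_that("optimal-background calls follow the argmin rule", {
  B <- rbind(P = c(0, 0.1), O1 = c(0, 0.5), O2 = c(0, 0.9))
  r <- microhabitat_distances(c(0, 0), B, is_perch = c(TRUE, FALSE, FALSE))
  oc <- find_optimal(r, B)
  expect_true(oc$on_optimal)
  expect_true(is.na(oc$d_perch_to_optimal))

  # hand-planted 2D fixture: perch at (0,0) -> d = 5, option at (1,1)
  B2 <- rbind(P = c(0, 0), O1 = c(1, 1), O2 = c(3, 4))
  liz <- c(1.9, 1.9)
  r2 <- microhabitat_distances(liz, B2, is_perch = c(TRUE, FALSE, FALSE))
  oc2 <- find_optimal(r2, B2)
  expect_false(oc2$on_optimal)
  expect_equal(oc2$optimal_background_id, "O1")
  expect_equal(oc2$d_perch_to_optimal, sqrt(2), tolerance = 1e-12)
  expect_equal(oc2$d_lizard_perch, sqrt(2 * 1.9^2))

  # ties broken by lowest background id and flagged
  B3 <- rbind(A = c(1, 0), B = c(-1, 0), P = c(0, 2))
  r3 <- microhabitat_distances(c(0, 0), B3,
                               is_perch = c(FALSE, FALSE, TRUE))
  oc3 <- find_optimal(r3, B3)
  expect_equal(oc3$optimal_background_id, "A")
  expect_true(oc3$tied)
})

test_that("d(L, optimal) <= d(L, perch) with equality iff on the optimal", {
  ds <- generate_study(seed = 31)
  sp <- build_component_spaces(ds, n_perm = 99, seed = 1)
  m <- matching_analysis(sp)
  expect_true(all(m$optimal$d_lizard_optimal <=
                    m$optimal$d_lizard_perch + 1e-12))
  eq <- abs(m$optimal$d_lizard_optimal - m$optimal$d_lizard_perch) < 1e-12
  expect_equal(eq, m$optimal$on_optimal | m$optimal$tied)
})

test_that("proportion test equals the Pearson chi-square oracle", {
  # field-count fixture
  res <- proportion_test_by_clade(c(A = 3, B = 2, C = 0, D = 0),
                                  c(A = 16, B = 6, C = 25, D = 5))
  expect_equal(res$df, 3)
  expect_equal(res$statistic, 8.611, tolerance = 1e-3)
  expect_equal(res$statistic,
               pearson_prop_chisq(c(3, 2, 0, 0), c(16, 6, 25, 5)),
               tolerance = 1e-10)
  # equal proportions: statistic exactly 0
  res0 <- proportion_test_by_clade(c(2, 2, 2), c(10, 10, 10))
  expect_equal(res0$statistic, 0)
  # exhaustive small-instance sweep over 2 x k tables with totals <= 30
  set.seed(99)
  for (k in 2:4) {
    for (rep in 1:25) {
      n <- sample(2:10, k, replace = TRUE)
      x <- vapply(n, function(ni) sample(0:ni, 1), numeric(1))
      if (sum(x) == 0 || sum(x) == sum(n)) next
      got <- suppressWarnings(proportion_test_by_clade(x, n))
      expect_equal(got$statistic, pearson_prop_chisq(x, n),
                   tolerance = 1e-10)
      expect_equal(got$df, k - 1)
    }
  }
  expect_warning(proportion_test_by_clade(c(1, 2, 0), c(5, 5, 0)), "zero")
})

sim_table <- function(n, seed, beta_svl = 0, dmale_shift = 0, sd = 1) {
  set.seed(seed)
  d <- data.frame(
    sex = sample(c("female", "male"), n, replace = TRUE),
    habitat = sample(c("coastal heath", "other"), n, replace = TRUE),
    clade = sample(LETTERS[1:4], n, replace = TRUE),
    svl = runif(n, 60, 120))
  d$y <- 10 + beta_svl * d$svl + rnorm(n, sd = sd)
  d$y[d$clade == "D" & d$sex == "male"] <-
    d$y[d$clade == "D" & d$sex == "male"] + dmale_shift
  d
}

test_that("GLM stage keeps the nominal type-I error on null data", {
  reps <- 40
  rej <- 0
  total <- 0
  for (r in seq_len(reps)) {
    d <- sim_table(200, seed = 500 + r)
    fit <- fit_matching_glm(d, "y")
    rej <- rej + sum(fit$term_table$p_value < 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(fit$term_table$p_value))
  }
  expect_lte(rej / total, 0.10)
})

test_that("GLM recovers a planted SVL slope with zero noise", {
  d <- sim_table(120, seed = 3)
  d$y <- 2 + 0.05 * d$svl
  fit <- fit_matching_glm(d, "y")
  tt <- fit$term_table
  svl_p <- tt$p_value[tt$term == "svl"]
  expect_lt(svl_p, 1e-10)
  expect_equal(unname(coef(fit$model)["svl"]), 0.05, tolerance = 1e-8)
})

test_that("Type I and Type II statistics agree on a balanced orthogonal design", {
  # fully crossed balanced design with SVL orthogonal to every factor:
  # sequential and marginal sums of squares coincide term by term
  g <- expand.grid(sex = c("female", "male"),
                   habitat = c("coastal heath", "other"),
                   clade = LETTERS[1:4], rep = 1:10)
  set.seed(7)
  g$svl <- ifelse(g$rep %% 2 == 0, 80, 100)
  g$y <- rnorm(nrow(g)) + ifelse(g$sex == "male", 0.5, 0) +
    ifelse(g$clade == "B", 0.3, 0)
  fit2 <- fit_matching_glm(g, "y")
  expect_equal(fit2$ss_type, 2L)
  m <- glm(y ~ sex + habitat + clade + svl, data = transform(
    g, sex = factor(sex), habitat = factor(habitat), clade = factor(clade)),
    family = gaussian())
  a1 <- anova(m, test = "Chisq")
  tt <- fit2$term_table
  for (tm in c("sex", "habitat", "clade", "svl")) {
    seqdev <- a1[tm, "Deviance"] / summary(m)$dispersion
    expect_equal(tt$statistic[tt$term == tm], seqdev, tolerance = 1e-6)
  }
})

test_that("interaction screen switches to Type III and flags the term", {
  d <- sim_table(400, seed = 11, dmale_shift = -3, sd = 0.8)
  fit <- fit_matching_glm(d, "y")
  expect_equal(fit$ss_type, 3L)
  expect_true("sex:clade" %in% fit$significant_interactions)
})

test_that("EMM contrasts recover a planted clade-D-male deficit", {
  d <- sim_table(400, seed = 13, dmale_shift = -3, sd = 0.8)
  fit <- fit_matching_glm(d, "y")
  emm <- emm_and_contrasts(fit, ~ clade | sex, adjust = "holm")
  ct <- emm$contrasts
  d_male <- ct[grepl("D", ct$contrast) & ct$sex == "male", ]
  d_female <- ct[grepl("D", ct$contrast) & ct$sex == "female", ]
  expect_true(all(d_male$p.value < 0.05))
  expect_true(all(d_female$p.value > 0.05))
  # the D-vs-other estimates within males carry the planted sign
  signs <- ifelse(grepl("^D", d_male$contrast), -1, 1)
  expect_true(all(signs * d_male$estimate > 0))
  # EMMs on null data stay near the grand mean
  d0 <- sim_table(300, seed = 17)
  f0 <- fit_matching_glm(d0, "y")
  e0 <- emm_and_contrasts(f0, ~ clade)$emmeans
  expect_true(all(abs(e0$emmean - mean(f0$data$.y)) <
                    4 * e0$SE + 0.5))
})
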