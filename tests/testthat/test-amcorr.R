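test_that("spousal correlation handles exact cases, missingness and small n", {
  x <- c(1.2, -0.5, 3.1, 0.4, 2.2)
  expect_equal(spousal_correlation(x, x, "pearson")$r, 1)
  # hand-computed Spearman: ranks identical, d = (-1,1,-1,1), sum d^2 = 4,
  # rho = 1 - 6*4/(4*15) = 0.6
  sp <- spousal_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3), "spearman")
  expect_equal(sp$r, 0.6)
  # pairs with a missing member are dropped (pairwise complete)
  pc <- spousal_correlation(c(x, NA), c(x, 99), "pearson")
  expect_equal(pc$n, 5L)
  expect_equal(pc$r, 1)
  expect_error(spousal_correlation(1:2, 2:1), "at least 3")
})

test_that("spousal correlation recovers the simulated trait-assortment parameter", {
  co <- simulate_cohort(sim_config(n_snps = 200, n_causal = 100,
                                   n_families = 2000, h2 = 0.5,
                                   rho_ancestry = 0, rho_trait = 0.3,
                                   n_generations = 1, seed = 71))
  ped <- co$pedigree
  tr <- setNames(co$traits$trait, co$traits$sample_id)
  r <- spousal_correlation(tr[ped$father_id], tr[ped$mother_id], "pearson")
  expect_gt(r$r, 0.25)
  expect_lt(r$r, 0.35)
})

test_that("Fisher z comparison matches the closed form and is antisymmetric", {
  c1 <- list(r = 0.5, n = 103)
  c2 <- list(r = 0.3, n = 103)
  cmp <- compare_correlations(c1, c2)
  expect_equal(cmp$z, (atanh(0.5) - atanh(0.3)) / sqrt(2 / 100),
               tolerance = 1e-12)
  expect_equal(cmp$z, 1.696, tolerance = 1e-3)
  expect_equal(cmp$p, 0.0899, tolerance = 1e-3)
  swp <- compare_correlations(c2, c1)
  expect_equal(swp$z, -cmp$z)
  expect_equal(swp$p, cmp$p)
  same <- compare_correlations(list(r = 0.3, n = 100), list(r = 0.3, n = 100))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(compare_correlations(list(r = 0.5, n = 3), c1), "n > 3")
})

test_that("Bonferroni threshold and the Fisher-z sample-size rule", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_equal(min_n_for_power(0.5, 0.05, 0.8), 30L)
  # lower detectable correlation needs more samples
  expect_gt(min_n_for_power(0.3, 0.05, 0.8), min_n_for_power(0.5, 0.05, 0.8))
  expect_error(min_n_for_power(1.2), "r must be")
})

test_that("variance explained reports adjusted R-squared per predictor block", {
  set.seed(72)
  n <- 5000
  d <- data.frame(y = rnorm(n), x_indep = rnorm(n))
  d$x_exact <- d$y
  ve <- suppressWarnings(  # the exact block triggers lm's perfect-fit note
    variance_explained(d, "y", list(exact = "x_exact", indep = "x_indep")))
  expect_equal(ve$adj_r_squared[ve$model == "exact"], 1, tolerance = 1e-12)
  expect_lt(abs(ve$adj_r_squared[ve$model == "indep"]), 0.002)
  # population R^2 = 0.25 recovered within Monte-Carlo slack
  n2 <- 1000
  x <- rnorm(n2)
  d2 <- data.frame(x = x, y = 0.5 * x + rnorm(n2, sd = sqrt(0.75)))
  ve2 <- variance_explained(d2, "y", list(x = "x"))
  expect_gt(ve2$adj_r_squared[1], 0.20)
  expect_lt(ve2$adj_r_squared[1], 0.30)
  expect_error(variance_explained(d2[1:2, ], "y", list(x = "x")), "too few")
})

test_that("residualized spousal correlation isolates the adjusted component", {
  set.seed(73)
  nf <- 2000
  shared <- rnorm(nf)                       # spousal-shared component
  make_parents <- function(role, values, covar) {
    data.frame(family_id = seq_len(nf), role = role, trait = values,
               covar = covar, stringsAsFactors = FALSE)
  }
  # (a) irrelevant covariate: correlation essentially unchanged
  tf <- shared + rnorm(nf); tm <- shared + rnorm(nf)
  d <- rbind(make_parents("father", tf, rnorm(nf)),
             make_parents("mother", tm, rnorm(nf)))
  out <- residualized_spousal_correlation(d, "trait", "covar", "pearson")
  expect_lt(abs(out$residual$r - out$raw$r), 0.02)
  # (b) adjusting by the true shared confounder removes the correlation
  d2 <- rbind(make_parents("father", tf, shared),
              make_parents("mother", tm, shared))
  out2 <- residualized_spousal_correlation(d2, "trait", "covar", "pearson")
  expect_gt(out2$raw$r, 0.3)
  expect_lt(abs(out2$residual$r), 0.07)
  expect_gt(out2$fractional_change, 0.8)
  # (c) adjusting the trait by itself is degenerate
  d3 <- rbind(make_parents("father", tf, tf), make_parents("mother", tm, tm))
  expect_error(residualized_spousal_correlation(d3, "trait", "covar", "pearson"),
               "constant")
})

test_that("Fisher-z confidence intervals achieve nominal coverage", {
  set.seed(74)
  n <- 200; rho <- 0.4; reps <- 1000
  x <- matrix(rnorm(n * reps), n)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * reps), n)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  r <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
  half <- qnorm(0.975) / sqrt(n - 3)
  covered <- tanh(atanh(r) - half) <= rho & rho <= tanh(atanh(r) + half)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
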