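test_that("LD pruning removes later correlated variants within the window only", {
  set.seed(81)
  x <- sample(0:2, 80, replace = TRUE)
  y <- sample(0:2, 80, replace = TRUE)
  # v1/v2 duplicates 1 kb apart; v3 independent nearby; v4 duplicates v1
  # but beyond the window
  d <- cbind(x, x, y, x)
  rownames(d) <- sprintf("s%02d", 1:80)
  g <- make_geno(d, chrom = rep("1", 4),
                 pos = c(1e5, 1e5 + 1e3, 2e5, 1e5 + 6e5))
  kept <- ld_prune(g, r2_threshold = 0.1, window_bp = 5e5)
  expect_identical(kept$id, c("v001", "v003", "v004"))
  # uncorrelated variants are both kept
  expect_true(all(c("v001", "v003") %in% kept$id))
})

test_that("distance thinning respects the minimum gap and the seed", {
  v <- data.frame(id = c("a", "b", "c"), chrom = "1",
                  pos = c(1, 1e5, 6e5), stringsAsFactors = FALSE)
  for (s in 1:20) {
    acc <- thin_by_distance(v, min_gap_bp = 5e5, seed = s)
    expect_false(all(c("a", "b") %in% acc$id))  # 1 and 1e5 conflict
    expect_equal(nrow(acc), 2L)                 # c is compatible with either
    expect_true("c" %in% acc$id)
  }
  # different chromosomes never conflict
  v2 <- data.frame(id = letters[1:4], chrom = as.character(1:4), pos = 1e5)
  expect_equal(nrow(thin_by_distance(v2, seed = 1)), 4L)
  expect_identical(thin_by_distance(v, seed = 9),
                   thin_by_distance(v, seed = 9))
})

test_that("Wright's F matches hand arithmetic", {
  expect_equal(wrights_f(25, 50, 25), 0)   # exact HWE proportions
  expect_equal(wrights_f(50, 0, 50), 1)    # no heterozygotes
  # p = 0.5, expected hets 50, observed 40 -> F = 0.2
  expect_equal(wrights_f(30, 40, 30), 0.2)
  expect_true(is.na(wrights_f(50, 0, 0)))  # monomorphic: undefined
  expect_equal(wrights_f(c(25, 30), c(50, 40), c(25, 30)), c(0, 0.2))
})

test_that("EM haplotype frequencies: exact cases, margins and monotone likelihood", {
  # phase-unambiguous: 50 (2,2) + 50 (0,0) -> p_AB = p_ab = 0.5 exactly
  h <- em_haplotype_freqs(c(rep(2, 50), rep(0, 50)),
                          c(rep(2, 50), rep(0, 50)))
  expect_equal(unname(h$p), c(0.5, 0, 0, 0.5))
  expect_true(h$converged)
  # all double heterozygotes from the LE start: fixed point at 0.25 each
  h2 <- em_haplotype_freqs(rep(1, 40), rep(1, 40))
  expect_equal(unname(h2$p), rep(0.25, 4))
  # implied allele frequencies match genotype-derived frequencies
  set.seed(82)
  for (i in 1:20) {
    g1 <- sample(0:2, 40, replace = TRUE)
    g2 <- sample(0:2, 40, replace = TRUE)
    hh <- em_haplotype_freqs(g1, g2)
    expect_equal(unname(hh$p["AB"] + hh$p["Ab"]), mean(g1) / 2,
                 tolerance = 1e-6)
    expect_equal(unname(hh$p["AB"] + hh$p["aB"]), mean(g2) / 2,
                 tolerance = 1e-6)
  }
  # log-likelihood is non-decreasing along the EM path
  set.seed(83)
  g1 <- sample(0:2, 30, replace = TRUE, prob = c(.3, .5, .2))
  g2 <- sample(0:2, 30, replace = TRUE, prob = c(.2, .5, .3))
  lls <- vapply(1:8, function(k)
    em_haplotype_freqs(g1, g2, max_iter = k)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-12))
  expect_error(em_haplotype_freqs(NA, NA), "observed")
})

test_that("EM attains the grid-search likelihood maximum on random tables", {
  set.seed(84)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    g1 <- sample(0:2, n, replace = TRUE)
    g2 <- sample(0:2, n, replace = TRUE)
    h <- em_haplotype_freqs(g1, g2)
    expect_equal(h$loglik, em_grid_oracle(count9(g1, g2)), tolerance = 1e-6)
  }
})

test_that("the C++ batch engine agrees with the R EM pair by pair", {
  set.seed(85)
  n <- 40; m <- 8
  d <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                     prob = c(.3, .35, .3, .05)), n, m)
  chrom <- as.integer(rep(1:2, each = 4))
  batch <- amstruct:::.mean_d2_cross_cpp(d, chrom, 1e-10, 1000L)
  ref <- c()
  for (j in 1:(m - 1)) for (k in (j + 1):m) {
    if (chrom[j] == chrom[k]) next
    ref <- c(ref, d_squared(em_haplotype_freqs(d[, j], d[, k])))
  }
  expect_equal(batch$n_pairs, 16)
  expect_equal(batch$mean_d2, mean(ref), tolerance = 1e-10)
})

test_that("D-squared matches hand arithmetic and is allele-label invariant", {
  expect_equal(d_squared(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(d_squared(c(0.5, 0, 0, 0.5)), 0.0625)   # D = 0.25
  # p_A = 0.5, p_B = 0.6, D = 0.4 - 0.30 = 0.1
  expect_equal(d_squared(c(0.4, 0.1, 0.2, 0.3)), 0.01)
  # swapping allele labels at the first locus: (AB,Ab,aB,ab)->(aB,ab,AB,Ab)
  p <- c(0.4, 0.1, 0.2, 0.3)
  expect_equal(d_squared(p), d_squared(p[c(3, 4, 1, 2)]))
  # and at the second locus
  expect_equal(d_squared(p), d_squared(p[c(2, 1, 4, 3)]))
})

test_that("pooling divergent subpopulations reproduces the Wahlund closed form", {
  set.seed(86)
  nsnp <- 1000; n <- 500
  p1 <- runif(nsnp, 0.05, 0.95)
  p2 <- runif(nsnp, 0.05, 0.95)
  g <- rbind(matrix(rbinom(n * nsnp, 2, rep(p1, each = n)), n),
             matrix(rbinom(n * nsnp, 2, rep(p2, each = n)), n))
  f <- wrights_f(colSums(g == 2), colSums(g == 1), colSums(g == 0))
  pb <- (p1 + p2) / 2
  wahlund <- (p1 - p2)^2 / (4 * pb * (1 - pb))
  expect_lt(abs(mean(f, na.rm = TRUE) - mean(wahlund)), 0.01)
})

test_that("cross-chromosome D-squared under panmixia sits at the sampling floor", {
  set.seed(87)
  n <- 200; m <- 40
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n)
  chrom <- as.integer(rep(1:4, each = 10))
  batch <- amstruct:::.mean_d2_cross_cpp(d, chrom, 1e-10, 1000L)
  pq <- p * (1 - p)
  floors <- outer(pq, pq)
  cross <- outer(chrom, chrom, "!=") & upper.tri(floors)
  floor_mean <- mean(floors[cross]) / (2 * n)
  expect_lt(batch$mean_d2, 3 * floor_mean)
  expect_gt(batch$mean_d2, floor_mean / 3)
})

test_that("the resampling comparison is deterministic given the seed", {
  co <- simulate_cohort(sim_config(n_snps = 200, n_families = 60,
                                   fst = 0.05, seed = 88))
  ped <- co$pedigree
  dv <- setNames(abs(co$freqs$p1 - co$freqs$p2), co$freqs$id)
  run <- function() resampling_comparison(co$geno, ped, dv, n_iter = 5,
                                          top_k = 20, seed = 99,
                                          roles = c("father", "mother"))
  expect_identical(run()$iterations, run()$iterations)
})

test_that("assortment in the ancestral generation attenuates in the offspring", {
  co <- simulate_cohort(sim_config(n_snps = 400, n_families = 400,
                                   fst = 0.08, rho_ancestry = 0.6,
                                   n_generations = 1, seed = 90))
  ped <- co$pedigree
  dv <- abs(co$freqs$p1 - co$freqs$p2)
  top <- order(-dv)[1:60]
  stat_for <- function(ids) {
    d <- co$geno$dosages[ids, top]
    f <- wrights_f(colSums(d == 2), colSums(d == 1), colSums(d == 0))
    d2 <- amstruct:::.mean_d2_cross_cpp(
      d, as.integer(co$geno$variants$chrom[top]), 1e-10, 1000L)
    c(f = mean(f, na.rm = TRUE), d2 = d2$mean_d2)
  }
  parents <- stat_for(c(ped$father_id, ped$mother_id))
  kids <- stat_for(c(ped$proband_id, ped$sibling_id))
  # offspring of rho = 0.6 couples have Var(alpha) reduced by (1+rho)/2
  expect_lt(kids["f"], parents["f"])
  expect_lt(kids["d2"], parents["d2"])
})

test_that("the top-vs-bottom D-squared gap grows with the assortment strength", {
  gap_at <- function(rho, seed) {
    co <- simulate_cohort(sim_config(n_snps = 600, n_families = 300,
                                     fst = 0.08, rho_ancestry = rho,
                                     seed = seed))
    ped <- co$pedigree
    dv <- setNames(abs(co$freqs$p1 - co$freqs$p2) /
                     sqrt(co$freqs$p * (1 - co$freqs$p)), co$freqs$id)
    lc <- resampling_comparison(co$geno, ped, dv, n_iter = 15, top_k = 50,
                                seed = seed, roles = "father")
    tst <- lc$tests[lc$tests$statistic == "d2", ]
    tst$mean_top - tst$mean_bottom
  }
  gaps <- vapply(c(0, 0.3, 0.6), gap_at, numeric(1), seed = 91)
  expect_true(all(diff(gaps) > 0))
})
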