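test_that("Balding-Nichols frequencies reproduce the target FST", {
  set.seed(21)
  fr <- draw_subpop_freqs(4000, fst = 0.1)
  # fst = 0 is the degenerate branch
  fr0 <- draw_subpop_freqs(50, fst = 0)
  expect_identical(fr0$p1, fr0$p)
  expect_identical(fr0$p2, fr0$p)
  # Hudson-style FST from two simulated subpopulation samples
  n <- 500
  x1 <- matrix(rbinom(n * nrow(fr), 2, rep(fr$p1, each = n)), n)
  x2 <- matrix(rbinom(n * nrow(fr), 2, rep(fr$p2, each = n)), n)
  q1 <- colMeans(x1) / 2
  q2 <- colMeans(x2) / 2
  hw <- q1 * (1 - q1) + q2 * (1 - q2)
  hb <- q1 * (1 - q2) + q2 * (1 - q1)
  fst_hat <- 1 - sum(hw) / sum(hb)
  expect_gt(fst_hat, 0.08)
  expect_lt(fst_hat, 0.12)
  # determinism under an explicit seed
  expect_identical(draw_subpop_freqs(100, 0.05, seed = 7),
                   draw_subpop_freqs(100, 0.05, seed = 7))
})

test_that("copula mating attains the target spousal ancestry correlation", {
  set.seed(22)
  founders <- data.frame(idx = 1:2000,
                         sex = rep(c("male", "female"), each = 1000),
                         alpha = rbeta(2000, 2, 2))
  for (rho in c(0, 0.5)) {
    pr <- mate_assortatively(founders, rho_ancestry = rho)
    r <- cor(founders$alpha[pr$father_idx], founders$alpha[pr$mother_idx])
    expect_lt(abs(r - rho), 0.06)
  }
  pr99 <- mate_assortatively(founders, rho_ancestry = 0.99)
  rs <- cor(founders$alpha[pr99$father_idx], founders$alpha[pr99$mother_idx],
            method = "spearman")
  expect_gte(rs, 0.95)
  expect_error(mate_assortatively(founders, rho_ancestry = 1.2), "rho")
})

test_that("Mendelian transmission is exact and segregates correctly", {
  set.seed(23)
  # forced genotypes
  f <- matrix(2L, 1, 5); m <- matrix(2L, 1, 5)
  expect_equal(simulate_offspring(f, m, 1)[[1]], matrix(2L, 1, 5))
  # het x het segregation over many children
  f1 <- matrix(1L, 1e4, 1); m1 <- matrix(1L, 1e4, 1)
  kid <- simulate_offspring(f1, m1, 1)[[1]]
  frac <- tabulate(kid + 1L, 3) / 1e4
  expect_equal(frac, c(0.25, 0.5, 0.25), tolerance = 0.05)
  # a simulated cohort has zero Mendelian errors before missingness
  co <- simulate_cohort(sim_config(n_snps = 300, n_families = 120,
                                   fst = 0.05, seed = 23))
  mer <- mendel_error_rate(co$geno, co$pedigree)
  expect_equal(sum(mer, na.rm = TRUE), 0)
  expect_error(simulate_offspring(matrix(NA_integer_, 1, 1), m[, 1, drop = FALSE]),
               "non-missing")
})

test_that("heritability scaling and liability ascertainment are recovered", {
  co <- simulate_cohort(sim_config(n_snps = 400, n_causal = 200,
                                   n_families = 1000, h2 = 0.5,
                                   rho_ancestry = 0, n_generations = 1,
                                   seed = 24))
  tr <- co$traits
  parents <- tr[tr$role %in% c("father", "mother"), ]
  ratio <- var(parents$genetic_value) / var(parents$trait)
  expect_gt(ratio, 0.42)
  expect_lt(ratio, 0.58)
  # h2 = 0: trait carries no genetic signal
  co0 <- simulate_cohort(sim_config(n_snps = 200, n_causal = 100,
                                    n_families = 1000, h2 = 0,
                                    rho_ancestry = 0, n_generations = 1,
                                    seed = 25))
  expect_true(all(co0$effects$beta == 0))
  # affected prevalence among children tracks the ascertainment quantile
  co2 <- simulate_cohort(sim_config(n_snps = 200, n_causal = 100,
                                    n_families = 3000, h2 = 0.5,
                                    rho_ancestry = 0,
                                    ascertainment_quantile = 0.02,
                                    n_generations = 1, seed = 26))
  prev <- mean(c(co2$pedigree$proband_affected, co2$pedigree$sibling_affected))
  expect_gt(prev, 0.012)
  expect_lt(prev, 0.028)
})

test_that("offspring ancestry equals midparent ancestry in expectation", {
  cfg <- sim_config(n_snps = 1000, n_families = 500, fst = 0.1,
                    rho_ancestry = 0.3, n_generations = 1, seed = 27)
  co <- simulate_cohort(cfg)
  ped <- co$pedigree
  # genotype-based least-squares ancestry estimate for each child
  delta <- 2 * (co$freqs$p1 - co$freqs$p2)
  base <- 2 * co$freqs$p2
  est <- function(ids) {
    d <- co$geno$dosages[ids, , drop = FALSE]
    (sweep(d, 2, base) %*% delta) / sum(delta^2)
  }
  mid <- (co$alpha[ped$father_id] + co$alpha[ped$mother_id]) / 2
  child_hat <- (est(ped$proband_id) + est(ped$sibling_id)) / 2
  slope <- coef(lm(child_hat ~ mid))[2]
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("emitted datasets are deterministic and loadable with zero integrity errors", {
  cfg <- sim_config(n_snps = 150, n_families = 60, missing_rate = 0.01,
                    seed = 28)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_dataset(cfg, d1)
  emit_dataset(cfg, d2)
  expect_identical(readBin(file.path(d1, "cohort.bed"), "raw", 1e6),
                   readBin(file.path(d2, "cohort.bed"), "raw", 1e6))
  back <- read_plink(file.path(d1, "cohort"))
  expect_equal(n_samples(back$geno), 240L)
  expect_equal(n_variants(back$geno), 150L)
  ped <- read.table(file.path(d1, "pedigree.tsv"), header = TRUE,
                    stringsAsFactors = FALSE)
  expect_true(all(ped$father_id %in% samples(back$geno)))
  ref <- read_plink(file.path(d1, "ref_panels"))
  expect_equal(n_variants(ref$geno), 150L)
  # missing_rate = 0 leaves nothing for the call-rate filter to remove
  cfg0 <- sim_config(n_snps = 100, n_families = 50, missing_rate = 0, seed = 29)
  co0 <- simulate_cohort(cfg0)
  expect_false(anyNA(co0$geno$dosages))
})

test_that("spousal PC1 correlation responds to the ancestry-assortment parameter", {
  corr_at <- function(rho, seed) {
    co <- simulate_cohort(sim_config(n_snps = 800, n_families = 500,
                                     fst = 0.05, rho_ancestry = rho,
                                     n_generations = 1, seed = seed))
    ped <- co$pedigree
    founders <- c(ped$father_id, ped$mother_id)
    gf <- subset_genotypes(co$geno, sample_ids = founders)
    m <- fit_reference_pca(gf, k = 2)
    cor(m$scores[ped$father_id, 1], m$scores[ped$mother_id, 1])
  }
  r0 <- corr_at(0, 31)
  r5 <- corr_at(0.5, 31)
  expect_gte(abs(r5) - abs(r0), 0.3)
  expect_gt(r5, 0)
})
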