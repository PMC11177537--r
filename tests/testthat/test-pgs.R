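test_that("the SD retention filter implements all four removal conditions", {
  mk <- function(se, n_case = 1e4, n_control = 1e4)
    data.frame(id = "rs1", effect_allele = "A", other_allele = "G",
               beta = 0.1, se = se, n_case = n_case, n_control = n_control,
               stringsAsFactors = FALSE)
  # se = 0.02, n_eff = 20000: SD_ss = 2/(0.02*sqrt(20000)) = 0.7071;
  # AF = 0.5: SD_test = sqrt(0.5) = 0.7071 -> kept
  keep <- sd_filter(mk(0.02), founder_freq = 0.5)
  expect_true(keep)
  det <- attr(keep, "detail")
  expect_equal(det$sd_ss, 2 / (0.02 * sqrt(2e4)), tolerance = 1e-12)
  expect_equal(det$sd_ss, 0.7071, tolerance = 1e-4)
  expect_equal(det$sd_test, 0.7071, tolerance = 1e-4)
  # SD_test = sqrt(2*0.0005*0.9995) = 0.0316 < 0.05 -> removed
  expect_false(sd_filter(mk(0.02), founder_freq = 0.0005))
  # huge se: SD_ss = 0.05 < 0.1 -> removed
  expect_false(sd_filter(mk(2 / (0.05 * sqrt(2e4))), founder_freq = 0.5))
  # SD_ss > 0.1 + SD_test -> removed (tiny se)
  expect_false(sd_filter(mk(1e-4), founder_freq = 0.5))
  # SD_ss < 0.5 * SD_test -> removed
  expect_false(sd_filter(mk(2 / (0.3 * sqrt(2e4))), founder_freq = 0.5))
  # quantitative branch: SD_ss = 1/(se*sqrt(n))
  sq <- data.frame(id = "rs1", effect_allele = "A", other_allele = "G",
                   beta = 0.1, se = 0.02, n = 1e4, stringsAsFactors = FALSE)
  kq <- sd_filter(sq, founder_freq = 0.5)
  expect_equal(attr(kq, "detail")$sd_ss, 1 / (0.02 * sqrt(1e4)))
  expect_true(kq)
})

test_that("scoring handles weights, mean imputation and founder standardization", {
  d <- matrix(c(0L, 1L, 2L, 2L,
                1L, NA, 0L, 2L), 4, 2,
              dimnames = list(paste0("s", 1:4), NULL))
  g <- make_geno(d, chrom = c("1", "2"), pos = c(1e6, 1e6))
  w0 <- data.frame(id = c("v001", "v002"), beta = c(0, 0))
  expect_true(all(score_pgs(g, w0)$raw == 0))
  w1 <- data.frame(id = "v001", beta = 1)
  expect_equal(score_pgs(g, w1)$raw, c(0, 1, 2, 2))
  # the missing dosage contributes the founder mean of its variant
  w2 <- data.frame(id = "v002", beta = 2)
  mu <- mean(c(1, 0, 2))   # founder mean dosage of v002 (non-missing)
  expect_equal(score_pgs(g, w2)$raw[2], mu * 2)
  # standardized scores have founder mean ~0 and sd ~1
  set.seed(61)
  dd <- matrix(sample(0:2, 50 * 20, replace = TRUE), 50, 20,
               dimnames = list(sprintf("f%02d", 1:50), NULL))
  gg <- make_geno(dd, chrom = rep("1", 20), pos = 1:20 * 1e6)
  ww <- data.frame(id = gg$variants$id, beta = rnorm(20))
  std <- score_pgs(gg, ww)$std
  expect_lt(abs(mean(std)), 1e-10)
  expect_lt(abs(sd(std) - 1), 1e-10)
  expect_error(score_pgs(g, data.frame(id = "absent", beta = 1)), "overlap")
})

test_that("pTDT reproduces hand-computed deviations and degenerate cases", {
  ped <- data.frame(family_id = paste0("f", 1:3),
                    father_id = paste0("fa", 1:3),
                    mother_id = paste0("mo", 1:3),
                    proband_id = paste0("ch", 1:3),
                    stringsAsFactors = FALSE)
  # midparent scores (0, 1, 2), children (1, 2, 4):
  # deviations (1, 1, 2)/sd(0,1,2)=1 -> mean 4/3, t = (4/3)/(sd/sqrt(3)) = 4
  sc <- c(fa1 = 0, fa2 = 2, fa3 = 2, mo1 = 0, mo2 = 0, mo3 = 2,
          ch1 = 1, ch2 = 2, ch3 = 4)
  res <- ptdt(sc, ped, "proband")
  expect_equal(res$mean_deviation, 4 / 3, tolerance = 1e-12)
  expect_equal(res$t, 4, tolerance = 1e-10)
  expect_equal(res$n, 3L)
  # children equal to midparent: zero deviation, t = 0
  sc0 <- sc
  sc0[c("ch1", "ch2", "ch3")] <- c(0, 1, 2)
  res0 <- ptdt(sc0, ped, "proband")
  expect_equal(res0$mean_deviation, 0)
  expect_equal(res0$t, 0)
  # constant midparent scores: undefined
  scc <- c(fa1 = 1, fa2 = 1, fa3 = 1, mo1 = 1, mo2 = 1, mo3 = 1,
           ch1 = 1, ch2 = 2, ch3 = 0)
  expect_error(ptdt(scc, ped, "proband"), "constant")
})

test_that("odd/even theta is exactly 1 for identical half-genome scores", {
  set.seed(62)
  n <- 120; m <- 40
  half <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  d <- cbind(half, half)   # even half duplicates the odd half
  rownames(d) <- sprintf("p%03d", 1:n)
  g <- make_geno(d,
                 chrom = c(rep(c("1", "3", "5", "7"), each = 10),
                           rep(c("2", "4", "6", "8"), each = 10)),
                 pos = rep(seq(1e6, by = 2e6, length.out = 10), 8))
  w <- data.frame(id = g$variants$id, beta = rep(rnorm(m), 2))
  th <- suppressWarnings(odd_even_theta(g, w, k = 3))  # perfect fit by design
  est <- th$estimates
  expect_equal(est$theta[est$regression == "odd_on_even"], 1, tolerance = 1e-10)
  expect_equal(est$theta[est$regression == "even_on_odd"], 1, tolerance = 1e-10)
})

test_that("odd/even theta is near zero for independent half-genome scores", {
  set.seed(63)
  null_theta <- function(seed) {
    co <- simulate_cohort(sim_config(n_snps = 600, n_causal = 600,
                                     n_families = 400, h2 = 1,
                                     rho_ancestry = 0, n_generations = 1,
                                     ascertainment_quantile = 0, seed = seed))
    kids <- c(co$pedigree$proband_id, co$pedigree$sibling_id)
    th <- odd_even_theta(subset_genotypes(co$geno, sample_ids = kids),
                         co$effects, k = 10)
    th$estimates[th$estimates$regression == "combined", ]
  }
  out <- do.call(rbind, lapply(64:68, null_theta))
  expect_true(all(abs(out$theta) < 0.15))
  expect_gte(sum(out$p > 0.05), 4)
})
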