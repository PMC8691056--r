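test_that("pseudo-R2 follows 1 - exp(-chisq/D)", {
  expect_equal(round(pseudo_r2(859, 1011), 2), 0.57)
  expect_equal(round(pseudo_r2(1358, 564), 2), 0.91)
  expect_equal(round(pseudo_r2(389, 1011), 2), 0.32)
  expect_equal(pseudo_r2(0, 100), 0)
  ## strictly increasing in chisq at fixed D
  grid <- seq(0, 2000, by = 50)
  expect_true(all(diff(pseudo_r2(grid, 1011)) > 0))
  expect_error(pseudo_r2(10, 0), "D must be positive")
})

test_that("genetic share and calibration coefficients are the printed ratios", {
  expect_equal(round(100 * genetic_share(389, 1043)), 27)
  expect_equal(round(100 * genetic_share(746, 1358)), 35)
  expect_equal(round(100 * genetic_share(680, 1776)), 28)
  expect_equal(genetic_share(0, 5), 0)
  expect_error(genetic_share(0, 0), "undefined")
  expect_equal(round(calibration_coefficients(0.86, 0.96), 2), 0.90)
  expect_equal(round(calibration_coefficients(0.26, 0.82), 2), 0.32)
  expect_equal(calibration_coefficients(0.7, 0.7), 1)
  expect_error(calibration_coefficients(1, 0), "zero")
})

test_that("cross-validated index tracks the full-fit index when folds are stable", {
  s <- sim_records(sim_config(n_subjects = 120, n_snps = 0, n_causal_snps = 0,
                              true_betas = c(t2_lesions = 0.5),
                              frailty_sd = 0, seed = 19))
  cv <- build_index(s$records, "t2_lesions", loo = TRUE, name = "CEPI")
  full <- build_index(s$records, "t2_lesions", loo = FALSE, name = "CEPI")
  expect_lt(max(abs(cv$values - full$values)), 0.2)
  expect_equal(mean(cv$values), 0, tolerance = 1e-10)
  expect_equal(cv$sd, sd(cv$values))
})

test_that("two-subject cross-validation exercises the fallback path", {
  set.seed(1)
  d <- data.frame(id = rep(1:2, each = 3),
                  start = rep(c(0, 1, 2), 2), stop = rep(c(1, 2, 3), 2),
                  status = c(0L, 0L, 0L, 0L, 1L, 1L), x = rnorm(6))
  ## the fold that trains on the event-free subject cannot fit and must fall
  ## back to the full-fit coefficients
  suppressWarnings(
    expect_message(idx <- build_index(d, "x", loo = TRUE), "fell back"))
  expect_length(idx$values, 6)
  expect_true(all(is.finite(idx$values)))
  expect_gte(idx$n_fallback, 1)
})

test_that("a well-calibrated cross-validated index has supermodel alpha near 1", {
  s <- sim_records(sim_config(n_subjects = 300, n_snps = 0, n_causal_snps = 0,
                              true_betas = c(t2_lesions = 0.45, female = 0.4),
                              frailty_sd = 0.2, seed = 29))
  set.seed(5)
  cepi <- build_index(s$records, c("t2_lesions", "female"), folds = 10,
                      name = "CEPI")
  m <- calibrate_supermodel(s$records, cepi)
  expect_lt(abs(unname(m$alpha) - 1), 2 * unname(m$alpha_se))
  expect_equal(m$metrics$pseudo_r2,
               1 - exp(-m$metrics$chisq / m$metrics$D))
})

test_that("CEGPI is the exact alpha-weighted combination and alpha3 is 1", {
  s <- sim_records(sim_config(n_subjects = 200, n_snps = 10, n_causal_snps = 3,
                              seed = 37))
  set.seed(2)
  cepi <- build_index(s$records, c("t2_lesions", "female"), folds = 8,
                      name = "CEPI")
  rec_g <- attach_genotypes(s$records, s$cohort$genotypes)
  gpi <- build_index(rec_g, paste0("snp_", 1:3), folds = 8, name = "GPI")
  m6 <- calibrate_supermodel(s$records, list(cepi, gpi))
  a <- m6$alpha
  ## machine-precision identity
  expect_equal(m6$cegpi$values,
               a[["CEPI"]] * (cepi$values - mean(cepi$values)) +
                 a[["GPI"]] * (gpi$values - mean(gpi$values)),
               tolerance = 1e-12)
  m7 <- calibrate_supermodel(s$records, m6$cegpi)
  expect_equal(unname(m7$alpha), 1, tolerance = 1e-6)
  expect_equal(m7$metrics$chisq, m6$metrics$chisq, tolerance = 1e-4)
  ## both robust and naive SEs are reported
  expect_true(is.finite(m7$alpha_se) && is.finite(m7$alpha_se_naive))
})

test_that("an uninformative genetic component gets alpha2 near 0", {
  s <- sim_records(sim_config(n_subjects = 250, n_snps = 0, n_causal_snps = 0,
                              true_betas = c(t2_lesions = 0.5),
                              frailty_sd = 0.2, seed = 43))
  set.seed(3)
  cepi <- build_index(s$records, "t2_lesions", folds = 10, name = "CEPI")
  noise <- cepi
  noise$name <- "GPI"
  noise$values <- sample(noise$values)  # independent of outcome
  m6 <- calibrate_supermodel(s$records, list(cepi, noise))
  expect_lt(abs(m6$alpha[["GPI"]]), 2 * m6$alpha_se[["GPI"]])
  expect_equal(m6$cegpi$values,
               m6$alpha[["CEPI"]] * (cepi$values - mean(cepi$values)) +
                 m6$alpha[["GPI"]] * (noise$values - mean(noise$values)),
               tolerance = 1e-12)
})

test_that("a many-small-SNP genetic index is approximately normal", {
  nsnp <- 60
  sb <- cbind(main = rep(0.08, nsnp), log_interattack = 0, z_latitude = 0,
              duration = 0)
  rownames(sb) <- paste0("snp_", seq_len(nsnp))
  s <- sim_records(sim_config(n_subjects = 300, n_snps = nsnp,
                              snp_betas = sb, seed = 47))
  rec_g <- attach_genotypes(s$records, s$cohort$genotypes)
  set.seed(4)
  gpi <- build_index(rec_g, paste0("snp_", seq_len(nsnp)), folds = 6,
                     name = "GPI")
  base <- gpi$values[!duplicated(gpi$id)]
  expect_gt(stats::shapiro.test(base)$p.value, 0.01)
})

test_that("index correlation is reported and near zero for independent drivers", {
  s <- sim_records(sim_config(n_subjects = 250, n_snps = 6, n_causal_snps = 3,
                              true_betas = c(t2_lesions = 0.5),
                              seed = 53))
  set.seed(6)
  cepi <- build_index(s$records, "t2_lesions", folds = 8, name = "CEPI")
  rec_g <- attach_genotypes(s$records, s$cohort$genotypes)
  gpi <- build_index(rec_g, paste0("snp_", 1:3), folds = 8, name = "GPI")
  rho <- index_correlation(cepi, gpi)
  expect_true(is.finite(rho))
  expect_lt(abs(rho), 0.3)  # t2 lesions and dosages are independent draws
})
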