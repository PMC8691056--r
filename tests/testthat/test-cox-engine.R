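test_that("beta matches brute-force maximization of the partial likelihood", {
  ## one covariate, 6 records, 3 events, no ties
  d <- toy_records()
  f <- ag_fit(d, "x")
  b_star <- oracle_cox_beta(d["x"], d$start, d$stop, d$status)
  expect_lt(abs(unname(f$beta) - b_star), 1e-6)
  ## several random small instances, one and two covariates, with strata
  for (s in 1:4) {
    set.seed(s)
    n <- 8
    d <- data.frame(id = 1:n, start = 0, stop = sort(runif(n, 0.5, 4)),
                    status = rep(c(1L, 0L), 4),
                    x = rnorm(n), z = rbinom(n, 1, 0.5))
    f1 <- ag_fit(d, "x")
    b1 <- oracle_cox_beta(d["x"], d$start, d$stop, d$status)
    expect_lt(abs(unname(f1$beta) - b1), 1e-4)
    f2 <- ag_fit(d, c("x", "z"))
    b2 <- oracle_cox_beta(d[c("x", "z")], d$start, d$stop, d$status)
    expect_lt(max(abs(unname(f2$beta) - b2)), 1e-4)
    g <- rep(c("a", "b"), each = 4)
    d$grp <- g
    f3 <- ag_fit(d, "x", strata = "grp")
    b3 <- oracle_cox_beta(d["x"], d$start, d$stop, d$status, strata = g)
    expect_lt(abs(unname(f3$beta) - b3), 1e-4)
  }
})

test_that("the internal partial likelihood agrees with the literal double loop", {
  s <- sim_records(sim_config(n_subjects = 30, n_snps = 0, n_causal_snps = 0,
                              seed = 21))
  d <- s$records
  X <- as.matrix(d[, c("t2_lesions", "bmi")])
  sf <- d$edss_stratum
  for (b in list(c(0, 0), c(0.3, -0.1), c(-1, 0.5))) {
    expect_equal(pll_breslow(as.numeric(X %*% b), d$start, d$stop, d$status, sf),
                 oracle_pll(b, X, d$start, d$stop, d$status, sf),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and penalized limits behave", {
  d <- toy_records()
  d$zero <- 0
  f0 <- suppressWarnings(ag_fit(d, "zero"))
  expect_equal(unname(f0$beta), 0)
  expect_equal(f0$model_chisq, 0, tolerance = 1e-8)
  ## very large L1 penalty: penalized coefficients vanish, forced stay free
  s <- sim_records(sim_config(n_subjects = 80, n_snps = 4, n_causal_snps = 2,
                              snp_betas = matrix(c(0.6, 0, 0, 0, 0.6, 0, 0, 0),
                                                 nrow = 2, byrow = TRUE,
                                                 dimnames = list(c("snp_1", "snp_2"),
                                                                 c("main", "log_interattack",
                                                                   "z_latitude", "duration"))),
                              true_betas = c(t2_lesions = 0.5), seed = 6))
  rec <- attach_genotypes(s$records, s$cohort$genotypes)
  fbig <- ag_fit(rec, c("t2_lesions", "snp_1", "snp_2"), penalty = 50,
                 forced = "t2_lesions")
  expect_equal(unname(fbig$beta[c("snp_1", "snp_2")]), c(0, 0))
  expect_gt(abs(fbig$beta[["t2_lesions"]]), 0)
})

test_that("linear predictor is the centered dot product", {
  d <- toy_records()
  f <- ag_fit(d, "x")
  expect_equal(linear_predictor(f, d),
               unname(f$beta) * (d$x - mean(d$x)))
  f$beta[] <- 0
  expect_equal(linear_predictor(f, d), rep(0, nrow(d)))
  ## hand computation on a 3-record toy with beta = 1
  f$beta[] <- 1
  nd <- data.frame(start = 0, stop = 1, x = c(2, 3, 4))
  expect_equal(linear_predictor(f, nd), c(2, 3, 4) - mean(d$x))
})

test_that("concordance matches exhaustive pair enumeration", {
  d <- data.frame(id = 1:4, start = 0, stop = c(1, 2, 3, 4),
                  status = c(1L, 1L, 0L, 1L), x = 0)
  risk <- c(4, 3, 2, 1)  # perfectly ordered
  expect_equal(concordance_index(risk, d), 1)
  for (s in 1:3) {
    set.seed(s)
    risk <- rnorm(4)
    expect_equal(concordance_index(risk, d),
                 oracle_concordance(risk, d$start, d$stop, d$status))
  }
  set.seed(99)
  big <- data.frame(id = 1:400, start = 0, stop = rexp(400), status = 1L)
  expect_lt(abs(concordance_index(rnorm(400), big) - 0.5), 0.06)
  none <- data.frame(id = 1, start = 0, stop = 1, status = 0L)
  expect_error(concordance_index(0, none), "no comparable pairs")
})

test_that("covariate location/scale changes transform beta as expected", {
  s <- sim_records(sim_config(n_subjects = 60, n_snps = 0, n_causal_snps = 0,
                              true_betas = c(t2_lesions = 0.4), seed = 13))
  d <- s$records
  f <- ag_fit(d, "t2_lesions")
  d2 <- d; d2$t2_lesions <- d2$t2_lesions + 100
  f2 <- ag_fit(d2, "t2_lesions")
  expect_equal(unname(f$beta), unname(f2$beta), tolerance = 1e-6)
  d3 <- d; d3$t2_lesions <- d3$t2_lesions * 4
  f3 <- ag_fit(d3, "t2_lesions")
  expect_equal(unname(f3$beta), unname(f$beta) / 4, tolerance = 1e-6)
})

test_that("sandwich variance approaches the naive one on independent records", {
  set.seed(7)
  n <- 2000
  x <- rnorm(n)
  t <- rexp(n, exp(0.5 * x))
  d <- data.frame(id = 1:n, start = 0, stop = t, status = 1L, x = x)
  f <- ag_fit(d, "x")
  ratio <- f$robust_cov[1, 1] / f$naive_cov[1, 1]
  expect_lt(abs(ratio - 1), 0.15)
})

test_that("model chi-square is invariant to stratum relabeling", {
  s <- sim_records(sim_config(n_subjects = 50, n_snps = 0, n_causal_snps = 0,
                              seed = 17))
  d <- s$records
  f1 <- suppressWarnings(ag_fit(d, "t2_lesions", strata = "edss_stratum"))
  d2 <- d
  d2$edss_stratum <- paste0("relabel_", d2$edss_stratum)
  f2 <- suppressWarnings(ag_fit(d2, "t2_lesions", strata = "edss_stratum"))
  expect_equal(f1$model_chisq, f2$model_chisq, tolerance = 1e-8)
})

test_that("Breslow baseline agrees with the survival package estimator", {
  d <- toy_records()
  f <- ag_fit(d, "x")
  bh <- survival::basehaz(f$cox, centered = FALSE)
  mine <- f$baseline
  at <- match(round(mine$time, 9), round(bh$time, 9))
  expect_equal(mine$cumhaz, bh$hazard[at], tolerance = 1e-8)
  expect_true(all(tapply(mine$cumhaz, mine$stratum,
                         function(z) all(diff(z) >= 0))))
})

test_that("LOO cross-validated partial log-likelihood matches a literal loop", {
  ## fixed toy chosen so every leave-one-out fold has an interior optimum
  d <- data.frame(id = rep(1:5, each = 2),
                  start = rep(c(0, 1), 5),
                  stop = rep(c(1.1, 2.2), 5) + 0.01 * (1:10),
                  status = c(1L, 0L, 0L, 1L, 1L, 1L, 0L, 1L, 1L, 0L),
                  x = c(0.5, -0.2, 0.3, 0.1, -0.4, 0.2, 0, -0.3, 0.25, -0.1))
  cv <- cv_partial_loglik(d, "x", penalty = 0, folds = "loo")
  ## literal leave-one-subject-out recomputation with independent pieces
  direct <- 0
  for (i in 1:5) {
    tr <- d$id != i
    cf <- survival::coxph(survival::Surv(start, stop, status) ~ x,
                          data = d[tr, ], ties = "breslow")
    b <- unname(coef(cf))
    direct <- direct +
      oracle_pll(b, d["x"], d$start, d$stop, d$status) -
      oracle_pll(b, d[tr, "x", drop = FALSE], d$start[tr], d$stop[tr],
                 d$status[tr])
  }
  expect_equal(unname(cv), direct, tolerance = 1e-6)
  ## infinite penalty: every fold contributes at beta = 0
  cvinf <- cv_partial_loglik(d, "x", penalty = Inf, folds = "loo")
  direct0 <- 0
  for (i in 1:5) {
    tr <- d$id != i
    direct0 <- direct0 +
      oracle_pll(0, d["x"], d$start, d$stop, d$status) -
      oracle_pll(0, d[tr, "x", drop = FALSE], d$start[tr], d$stop[tr],
                 d$status[tr])
  }
  expect_equal(unname(cvinf), direct0, tolerance = 1e-10)
})

test_that("cv penalty selection keeps signal SNPs in a sparse simulation", {
  s <- sim_records(sim_config(
    n_subjects = 250, n_snps = 30, n_causal_snps = 5,
    snp_betas = matrix(c(rep(0.45, 5), rep(0, 15)), nrow = 5,
                       dimnames = list(paste0("snp_", 1:5),
                                       c("main", "log_interattack",
                                         "z_latitude", "duration"))),
    true_betas = c(t2_lesions = 0.3), frailty_sd = 0.2, seed = 23))
  rec <- attach_genotypes(s$records, s$cohort$genotypes)
  snps <- colnames(s$cohort$genotypes)
  grid <- exp(seq(log(0.2), log(0.002), length.out = 10))
  set.seed(1)
  cv <- cv_partial_loglik(rec, c("t2_lesions", snps), penalty = grid,
                          folds = 6, forced = "t2_lesions")
  pen <- grid[which.max(cv)]
  f <- ag_fit(rec, c("t2_lesions", snps), penalty = pen, forced = "t2_lesions")
  kept <- names(f$beta)[f$beta != 0]
  expect_gte(sum(paste0("snp_", 1:5) %in% kept), 3)  # at least half the causal
})

test_that("time-varying terms are episode-split and shift the likelihood", {
  s <- sim_records(sim_config(n_subjects = 60, n_snps = 0, n_causal_snps = 0,
                              seed = 41))
  f <- ag_fit(s$records, list(term_spec("t2_lesions"),
                              term_spec("t2_lesions", "time")))
  expect_named(f$beta, c("t2_lesions", "t2_lesions:time"))
  expect_true(f$converged)
  expect_gte(f$model_chisq, 0)
})
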