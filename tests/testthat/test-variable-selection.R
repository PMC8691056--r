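sparse_config <- function(n, nsnp, ncausal, beta, seed, duration = 0) {
  sb <- if (ncausal > 0) {
    m <- cbind(main = rep(beta, ncausal), log_interattack = 0, z_latitude = 0,
               duration = duration)
    rownames(m) <- paste0("snp_", seq_len(ncausal))
    m
  } else matrix(0, 0, 4, dimnames = list(NULL, c("main", "log_interattack",
                                                 "z_latitude", "duration")))
  sim_config(n_subjects = n, n_snps = nsnp, snp_betas = sb,
             true_betas = c(t2_lesions = 0.3), frailty_sd = 0.2,
             follow_up_years = 6, visit_interval_mean = 0.9, seed = seed)
}

test_that("the global test detects strong genetic signal", {
  hits <- 0
  n_seed <- 12
  for (s in seq_len(n_seed)) {
    sim <- sim_records(sparse_config(300, 20, 5, 0.4, seed = 100 + s))
    gt <- global_test(sim$records, "t2_lesions", sim$cohort$genotypes,
                      n_perm = 199, seed = s)
    hits <- hits + (gt$p_value < 0.05)
  }
  expect_gte(hits, n_seed - 1)
})

test_that("the global test is calibrated when genotypes carry no information", {
  sim <- sim_records(sparse_config(150, 15, 0, 0, seed = 77))
  G <- sim$cohort$genotypes
  set.seed(8)
  pvals <- vapply(1:40, function(k) {
    Gp <- G[sample(nrow(G)), , drop = FALSE]  # break genotype-outcome link
    rownames(Gp) <- rownames(G)
    global_test(sim$records, "t2_lesions", Gp, n_perm = 99)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pvals > 0 & pvals <= 1))
})

test_that("the global statistic is monotone in a single SNP's score", {
  ## one binary SNP, no clinical covariates: the statistic must rank
  ## cohorts the same way as the squared univariate score
  stat_and_score <- function(seed) {
    sim <- sim_records(sim_config(n_subjects = 80, n_snps = 1,
                                  snp_betas = matrix(
                                    c(0.02 * seed, 0, 0, 0), 1,
                                    dimnames = list("snp_1",
                                                    c("main", "log_interattack",
                                                      "z_latitude", "duration"))),
                                  maf_range = c(0.4, 0.5),
                                  frailty_sd = 0, seed = 500 + seed))
    rec <- sim$records
    gt <- global_test(rec, NULL, sim$cohort$genotypes, n_perm = 100, seed = 1)
    g <- sim$cohort$genotypes[as.character(rec$id), 1]
    ## univariate score at beta = 0 (log-rank numerator), computed by hand
    sc <- 0
    for (i in which(rec$status == 1)) {
      t <- rec$stop[i]
      rs <- rec$start < t & rec$stop >= t
      sc <- sc + g[i] - mean(g[rs])
    }
    c(stat = gt$statistic, score2 = sc^2)
  }
  vals <- vapply(c(1, 10, 25), stat_and_score, c(stat = 0, score2 = 0))
  expect_equal(order(vals["stat", ]), order(vals["score2", ]))
})

test_that("Cox-LASSO with backfitting recovers causal SNPs with few false hits", {
  set.seed(9)
  recovered <- fp <- integer(0)
  for (s in 1:3) {
    sim <- sim_records(sparse_config(350, 60, 6, 0.45, seed = 200 + s))
    sel <- select_snps(sim$records, "t2_lesions", sim$cohort$genotypes,
                       interaction_menu = character(0), folds = 6)
    main_sel <- sel$selected_labels[!grepl(":", sel$selected_labels)]
    recovered <- c(recovered, sum(paste0("snp_", 1:6) %in% main_sel))
    fp <- c(fp, sum(!main_sel %in% paste0("snp_", 1:6)))
  }
  expect_gte(stats::median(recovered), 3)  # at least half the causal set
  expect_lte(stats::median(fp), 5)
})

test_that("under a global null the backfit filter keeps false positives near alpha", {
  set.seed(10)
  fps <- vapply(1:3, function(s) {
    sim <- sim_records(sparse_config(200, 40, 0, 0, seed = 300 + s))
    sel <- suppressWarnings(
      select_snps(sim$records, "t2_lesions", sim$cohort$genotypes,
                  interaction_menu = character(0), folds = 5))
    sum(!grepl(":", sel$selected_labels))
  }, numeric(1))
  expect_lte(mean(fps), 0.05 * 40)
})

test_that("a forced HLA-tag SNP survives selection even with no true effect", {
  sim <- sim_records(sparse_config(150, 12, 0, 0, seed = 88))
  sel <- suppressWarnings(
    select_snps(sim$records, "t2_lesions", sim$cohort$genotypes,
                forced_snp = "snp_1", interaction_menu = character(0),
                folds = 5))
  expect_true("snp_1" %in% sel$selected_labels)
  expect_true(all(sel$forced %in% sel$selected_labels))
})

test_that("backward elimination keeps signal, drops noise, honors forcing", {
  ## power: a strong effect is retained in every replicate
  for (s in 1:4) {
    sim <- sim_records(sim_config(n_subjects = 300, n_snps = 0,
                                  n_causal_snps = 0,
                                  true_betas = c(t2_lesions = 0.6),
                                  frailty_sd = 0.2, seed = 400 + s))
    sel <- select_clinical(sim$records, candidates = "t2_lesions",
                           forced = "female")
    expect_true("t2_lesions" %in% sel$selected_labels)
    expect_true("female" %in% sel$selected_labels)
  }
  ## noise: retention stays near the nominal level over replicates
  sim <- sim_records(sim_config(n_subjects = 200, n_snps = 0,
                                n_causal_snps = 0,
                                true_betas = c(t2_lesions = 0.4),
                                seed = 66))
  set.seed(11)
  kept <- vapply(1:30, function(k) {
    d <- sim$records
    d$noise <- rnorm(length(unique(d$id)))[match(d$id, unique(d$id))]
    sel <- select_clinical(d, candidates = "noise", forced = "t2_lesions")
    "noise" %in% sel$selected_labels
  }, logical(1))
  expect_lte(mean(kept), 0.2)
  ## forced covariate with no effect is always present
  d <- sim$records
  d$flat <- rnorm(length(unique(d$id)))[match(d$id, unique(d$id))]
  sel <- select_clinical(d, candidates = "t2_lesions", forced = "flat")
  expect_true("flat" %in% sel$selected_labels)
})

test_that("elimination is deterministic and backfit equals a direct refit", {
  sim <- sim_records(sim_config(n_subjects = 150, n_snps = 0,
                                n_causal_snps = 0,
                                true_betas = c(t2_lesions = 0.4, bmi = 0.05),
                                seed = 55))
  a <- select_clinical(sim$records, candidates = c("bmi", "hads", "vitd_supp"),
                       forced = "t2_lesions")
  b <- select_clinical(sim$records, candidates = c("bmi", "hads", "vitd_supp"),
                       forced = "t2_lesions")
  expect_identical(a$selected_labels, b$selected_labels)
  expect_identical(a$history$eliminated, b$history$eliminated)
  direct <- ag_fit(a$data, a$selected_labels)
  expect_equal(a$betas_backfit, direct$beta, tolerance = 1e-8)
})

test_that("the FP1 power scan finds a strongly curved transform", {
  ## events driven by x^2: the scan should move off the linear term
  set.seed(12)
  n <- 400
  x <- runif(n, 0.5, 3)
  t <- rexp(n, 0.1 * exp(0.8 * (x^2 - mean(x^2))))
  d <- data.frame(id = 1:n, start = 0, stop = pmin(t, 8),
                  status = as.integer(t <= 8), x = x,
                  anchor = rnorm(n))
  sel <- select_clinical(d, candidates = "x", forced = "anchor")
  expect_true("x" %in% sel$selected_labels)
  expect_equal(sel$fp_powers$x, 2)
})
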