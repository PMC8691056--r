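#' Simulation configuration for a synthetic relapsing-onset MS cohort
#'
#' Bundles and validates every knob of the cohort generator.  Defaults emulate
#' a first-demyelinating-event cohort of 253 people followed for 10 years with
#' roughly 2800 visit intervals: 77.5% female, age at entry ~ N(36.6, 9.2^2),
#' 199 independent risk SNPs of which a small subset carries true effects on
#' the relapse and worsening intensities.
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs in the dosage matrix.
#' @param n_causal_snps number of SNPs with nonzero true effects (used only
#'   when `snp_betas` is `NULL`).
#' @param follow_up_years administrative end of follow-up, years since FDE.
#' @param visit_interval_mean mean gap between scheduled visits (years).
#' @param true_betas named numeric vector of log-hazard ratios for the
#'   clinical/environmental covariates shared by the relapse and worsening
#'   intensities.  Names must be among the generated covariates
#'   (`age_fde`, `female`, `t2_lesions`, `vitd_baseline`, `bmi`, `hads`,
#'   `vitd_supp`, `sunlight_change`, `z_latitude`).
#' @param snp_betas matrix with one row per causal SNP (rownames = SNP ids,
#'   e.g. `"snp_12"`) and columns `main`, `log_interattack`, `z_latitude`,
#'   `duration`: additive dosage effect, its decay with the log inter-attack
#'   interval, its modulation by standardized latitude, and an optional slope
#'   on disease duration (years since FDE) used to emulate genetic effects
#'   that grow late in the disease course.  `NULL` auto-generates
#'   `n_causal_snps` rows with alternating-sign main effects.
#' @param baseline_hazards named rates per year, `c(relapse=, worsening=)`.
#' @param frac_female proportion female.
#' @param age_mean,age_sd age at FDE distribution (years).
#' @param maf_range length-2 vector, minor-allele-frequency band (0, 0.5].
#' @param censor_rate rate/year of independent exponential drop-out.
#' @param frailty_sd standard deviation of the log-normal subject frailties;
#'   relapse and worsening frailties are drawn independently so the two
#'   processes can have near-independent drivers.
#' @param improvement_frac downward (EDSS improvement) intensity as a fraction
#'   of the upward intensity.
#' @param latitude_band range (degrees south) latitude is drawn from before
#'   standardization.
#' @param seed integer RNG seed; identical seed + config gives byte-identical
#'   tables.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 253,
                       n_snps = 199,
                       n_causal_snps = 8,
                       follow_up_years = 10,
                       visit_interval_mean = 0.85,
                       true_betas = c(t2_lesions = 0.25, female = 0.3,
                                      bmi = 0.06, hads = 0.05,
                                      vitd_supp = -0.5, age_fde = 0.01),
                       snp_betas = NULL,
                       baseline_hazards = c(relapse = 0.25, worsening = 0.5),
                       frac_female = 0.775,
                       age_mean = 36.6,
                       age_sd = 9.2,
                       maf_range = c(0.05, 0.5),
                       censor_rate = 0.03,
                       frailty_sd = 0.5,
                       improvement_frac = 0.3,
                       latitude_band = c(18, 43),
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_snps = n_snps,
              n_causal_snps = n_causal_snps,
              follow_up_years = follow_up_years,
              visit_interval_mean = visit_interval_mean,
              true_betas = true_betas, snp_betas = snp_betas,
              baseline_hazards = baseline_hazards,
              frac_female = frac_female, age_mean = age_mean, age_sd = age_sd,
              maf_range = maf_range, censor_rate = censor_rate,
              frailty_sd = frailty_sd, improvement_frac = improvement_frac,
              latitude_band = latitude_band, seed = as.integer(seed))
  ## an explicit snp_betas matrix defines the causal set
  if (!is.null(snp_betas)) cfg$n_causal_snps <- nrow(snp_betas)
  validate_sim_config(cfg)
  if (is.null(cfg$snp_betas) && cfg$n_causal_snps > 0) {
    idx <- seq_len(cfg$n_causal_snps)
    sb <- cbind(main = 0.25 * (-1)^(idx + 1),
                log_interattack = ifelse(idx <= 2, -0.1, 0),
                z_latitude = ifelse(idx > 2 & idx <= 4, 0.1, 0),
                duration = 0)
    rownames(sb) <- paste0("snp_", idx)
    cfg$snp_betas <- sb
  } else if (is.null(cfg$snp_betas)) {
    cfg$snp_betas <- matrix(0, 0, 4, dimnames = list(
      NULL, c("main", "log_interattack", "z_latitude", "duration")))
  }
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid sim_config field '%s': %s", field, why), call. = FALSE)
  pos_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  if (!pos_num(cfg$n_subjects) || cfg$n_subjects < 1) bad("n_subjects", "must be >= 1")
  if (!is.numeric(cfg$n_snps) || cfg$n_snps < 0) bad("n_snps", "must be >= 0")
  if (cfg$n_causal_snps > cfg$n_snps)
    bad("n_causal_snps", "cannot exceed n_snps")
  if (!pos_num(cfg$follow_up_years)) bad("follow_up_years", "must be > 0")
  if (!pos_num(cfg$visit_interval_mean)) bad("visit_interval_mean", "must be > 0")
  if (!all(cfg$baseline_hazards > 0) ||
      !all(c("relapse", "worsening") %in% names(cfg$baseline_hazards)))
    bad("baseline_hazards", "needs positive rates named 'relapse' and 'worsening'")
  if (cfg$frac_female < 0 || cfg$frac_female > 1)
    bad("frac_female", "must lie in [0, 1]")
  if (!pos_num(cfg$age_sd)) bad("age_sd", "must be > 0")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    bad("maf_range", "must be increasing within (0, 0.5]")
  if (!is.numeric(cfg$censor_rate) || cfg$censor_rate < 0)
    bad("censor_rate", "must be >= 0")
  if (!is.null(cfg$snp_betas)) {
    if (!is.matrix(cfg$snp_betas) ||
        (nrow(cfg$snp_betas) > 0 && is.null(rownames(cfg$snp_betas))))
      bad("snp_betas", "must be a matrix with SNP-id rownames")
    need <- c("main", "log_interattack", "z_latitude")
    if (nrow(cfg$snp_betas) > 0 && !all(need %in% colnames(cfg$snp_betas)))
      bad("snp_betas", "columns must include main, log_interattack, z_latitude")
  }
  invisible(cfg)
}

# centering constants so that true_betas act on deviations and the configured
# baseline hazards stay interpretable as typical-subject rates
.covariate_centers <- c(age_fde = 36.6, female = 0, t2_lesions = 2,
                        vitd_baseline = 70, bmi = 25, hads = 6,
                        vitd_supp = 0, sunlight_change = 0, z_latitude = 0)

#' Simulate a synthetic MS-like longitudinal cohort
#'
#' Generates subjects, jittered visit schedules, genotypes, recurrent relapses
#' (Poisson counts within visit intervals under an Andersen-Gill intensity)
#' and an EDSS birth-death chain on the half-point 0-10 grid whose upward
#' (worsening) intensity shares the configured covariate effects and whose
#' downward intensity is a fixed fraction of the upward one.  SNP effects are
#' additive in dosage with optional decay in the log inter-attack interval,
#' modulation by standardized latitude, and growth with disease duration.
#' Relapse and worsening share the covariate linear predictor but carry
#' independent log-normal frailties.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_cohort`: list with `subjects`, `visits`,
#'   `genotypes` (subjects x SNPs dosage matrix), `snp_info`, and `truth`
#'   (config, realized per-subject time-fixed linear predictors, frailties).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects

  ## ---- subjects -----------------------------------------------------------
  female <- as.integer(stats::runif(n) < config$frac_female)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  site <- sample(c("TAS", "VIC", "NSW", "QLD"), n, replace = TRUE)
  lat_raw <- stats::runif(n, config$latitude_band[1], config$latitude_band[2])
  z_lat <- as.numeric(scale(lat_raw))
  if (n == 1) z_lat <- 0
  vitd <- stats::rnorm(n, 70, 25)
  t2 <- stats::rpois(n, 2.5)
  edu <- sample(c("LSE", "SE", "HE"), n, replace = TRUE, prob = c(.3, .4, .3))
  subjects <- data.frame(
    id = seq_len(n), age_fde = age, female = female, sex = ifelse(female == 1, "F", "M"),
    site = site, latitude = lat_raw, z_latitude = z_lat,
    vitd_baseline = vitd, t2_lesions = t2, education = edu,
    stringsAsFactors = FALSE)

  ## ---- genotypes ----------------------------------------------------------
  p <- config$n_snps
  maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  G <- matrix(stats::rbinom(n * p, 2, rep(maf, each = n)), nrow = n, ncol = p)
  colnames(G) <- if (p > 0) paste0("snp_", seq_len(p)) else character(0)
  rownames(G) <- subjects$id
  n_mhc <- if (p > 0) max(1L, round(p * 17 / 199)) else 0L
  snp_info <- data.frame(snp = colnames(G), maf = maf,
                         mhc = seq_len(p) <= n_mhc,
                         hla_drb1_tag = seq_len(p) == 1L)

  sb <- config$snp_betas
  causal <- rownames(sb)
  causal <- causal[causal %in% colnames(G)]
  sb <- sb[causal, , drop = FALSE]
  if (!"duration" %in% colnames(sb))
    sb <- cbind(sb, duration = rep(0, nrow(sb)))

  ## time-fixed linear predictor shared by both processes
  tb <- config$true_betas
  lp_fixed <- rep(0, n)
  for (nm in names(tb)) {
    if (!nm %in% names(.covariate_centers) && !nm %in% names(subjects))
      stop(sprintf("invalid sim_config field 'true_betas': unknown covariate '%s'", nm),
           call. = FALSE)
  }
  base_cov <- list(age_fde = age - .covariate_centers["age_fde"],
                   female = female, t2_lesions = t2 - .covariate_centers["t2_lesions"],
                   vitd_baseline = vitd - .covariate_centers["vitd_baseline"],
                   z_latitude = z_lat)
  for (nm in intersect(names(tb), names(base_cov)))
    lp_fixed <- lp_fixed + tb[[nm]] * base_cov[[nm]]
  ## SNP effects act on dosages centered at their population mean (2 * MAF)
  ## so the baseline hazards keep their typical-subject interpretation
  Gc <- if (length(causal))
    sweep(G[, causal, drop = FALSE], 2, 2 * maf[match(causal, colnames(G))])
  else matrix(0, n, 0)
  g_main <- if (length(causal)) as.numeric(Gc %*% sb[, "main"]) else rep(0, n)
  g_lat <- if (length(causal)) as.numeric(Gc %*% sb[, "z_latitude"]) * z_lat else rep(0, n)
  lp_fixed <- lp_fixed + g_main + g_lat
  g_time <- if (length(causal)) Gc %*% sb[, "log_interattack"] else matrix(0, n, 1)
  g_dur <- if (length(causal)) Gc %*% sb[, "duration"] else matrix(0, n, 1)

  fr_rel <- stats::rnorm(n, 0, config$frailty_sd)
  fr_wod <- stats::rnorm(n, 0, config$frailty_sd)
  cens <- if (config$censor_rate > 0) stats::rexp(n, config$censor_rate) else rep(Inf, n)
  fup <- pmin(config$follow_up_years, cens)

  edss_grid <- seq(0, 10, by = 0.5)
  mean_iv <- config$visit_interval_mean
  h_rel0 <- config$baseline_hazards[["relapse"]]
  h_wod0 <- config$baseline_hazards[["worsening"]]

  vis_list <- vector("list", n)
  for (i in seq_len(n)) {
    ## jittered visit schedule
    t_cur <- 0
    times <- 0
    repeat {
      gap <- max(0.05, stats::rgamma(1, shape = 16, rate = 16 / mean_iv))
      t_cur <- t_cur + gap
      if (t_cur > fup[i]) break
      times <- c(times, t_cur)
    }
    k <- length(times)
    edss <- numeric(k); relapse_ct <- integer(k)
    bmi <- numeric(k); hads <- numeric(k); supp <- integer(k)
    income <- integer(k); employ <- character(k); sun <- numeric(k)
    edss[1] <- sample(c(0, 0.5, 1, 1.5, 2), 1, prob = c(.2, .25, .25, .2, .1))
    bmi[1] <- stats::rnorm(1, 25, 3)
    hads[1] <- max(0, stats::rnorm(1, 6, 3))
    supp[1] <- stats::rbinom(1, 1, 0.3)
    income[1] <- sample(1:4, 1)
    employ[1] <- sample(c("FT", "PT", "DP", "UE"), 1, prob = c(.5, .25, .1, .15))
    sun[1] <- stats::rnorm(1, 0, 0.8)
    tot_rel <- 0L
    lp_i <- lp_fixed[i]
    if (k > 1) for (j in 2:k) {
      dt <- times[j] - times[j - 1]
      ldt <- log(dt)
      dur_eff <- g_dur[i] * times[j - 1]
      ## relapse process (Andersen-Gill intensity, piecewise constant)
      lam_r <- h_rel0 * exp(lp_i + fr_rel[i] + g_time[i] * ldt + dur_eff)
      relapse_ct[j] <- stats::rpois(1, lam_r * dt)
      tot_rel <- tot_rel + relapse_ct[j]
      ## EDSS birth-death step
      lam_up <- h_wod0 * exp(lp_i + fr_wod[i] + g_time[i] * ldt + dur_eff)
      lam_dn <- config$improvement_frac * lam_up
      e_prev <- edss[j - 1]
      if (e_prev <= 0) lam_dn <- 0
      if (e_prev >= 10) lam_up <- 0
      p_move <- 1 - exp(-(lam_up + lam_dn) * dt)
      edss[j] <- e_prev
      if (lam_up + lam_dn > 0 && stats::runif(1) < p_move) {
        up <- stats::runif(1) < lam_up / (lam_up + lam_dn)
        edss[j] <- e_prev + if (up) 0.5 else -0.5
      }
      edss[j] <- min(10, max(0, edss[j]))
      ## time-varying covariates: subject-level random walks
      bmi[j] <- bmi[j - 1] + stats::rnorm(1, 0, 0.3)
      hads[j] <- max(0, hads[j - 1] + stats::rnorm(1, 0, 0.8))
      supp[j] <- if (stats::runif(1) < 0.05) 1L - supp[j - 1] else supp[j - 1]
      income[j] <- min(4, max(1, income[j - 1] +
                                sample(c(-1L, 0L, 1L), 1, prob = c(.05, .9, .05))))
      employ[j] <- if (stats::runif(1) < 0.05)
        sample(c("FT", "PT", "DP", "UE"), 1) else employ[j - 1]
      sun[j] <- stats::rnorm(1, 0, 0.8)
    }
    edss <- edss_grid[pmax(1, pmin(length(edss_grid), round(edss * 2) + 1))]
    cdms <- as.integer(cumsum(relapse_ct) >= 2 | edss >= 3)
    cdms <- as.integer(cummax(cdms))
    vis_list[[i]] <- data.frame(
      id = i, time = times, edss = edss,
      relapse = as.integer(relapse_ct > 0), relapse_count = relapse_ct,
      bmi = bmi, hads = hads, vitd_supp = supp, income = income,
      employment = employ, sunlight_change = sun, cdms = cdms,
      stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, vis_list)
  rownames(visits) <- NULL

  truth <- list(config = config,
                lp_fixed = lp_fixed,
                frailty_relapse = fr_rel, frailty_worsening = fr_wod,
                causal_snps = causal, snp_betas = sb,
                note = paste("time-varying covariate forms (random walks) and",
                             "visit-gap distribution (gamma, cv 0.25) are",
                             "generator stand-ins, not estimates from data"))
  structure(list(subjects = subjects, visits = visits, genotypes = G,
                 snp_info = snp_info, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d visit rows, %d SNPs\n",
              nrow(x$subjects), nrow(x$visits), ncol(x$genotypes)))
  invisible(x)
}

#' Annual relapse rate of a cohort
#'
#' Events per person-year, where person-years are the observed follow-up
#' (last visit time) per subject and events are the post-onset relapse counts.
#'
#' @param cohort a `synthetic_cohort` or a list with `subjects` and `visits`
#'   tables following the documented schema.
#' @param by_sex split the rate by sex.
#' @return data.frame with columns `sex` (when `by_sex`), `events`,
#'   `person_years`, `rate`.
#' @export
annual_relapse_rate <- function(cohort, by_sex = FALSE) {
  v <- cohort$visits
  if (is.null(v) || nrow(v) == 0) stop("empty cohort", call. = FALSE)
  py_s <- tapply(v$time, v$id, max)
  ev_s <- tapply(v$relapse_count, v$id, sum)
  ids <- as.integer(names(py_s))
  if (by_sex) {
    sex <- cohort$subjects$sex[match(ids, cohort$subjects$id)]
    out <- do.call(rbind, lapply(split(seq_along(ids), sex), function(ix) {
      py <- sum(py_s[ix])
      if (py <= 0) stop("undefined rate: zero person-years", call. = FALSE)
      data.frame(events = sum(ev_s[ix]), person_years = py,
                 rate = sum(ev_s[ix]) / py)
    }))
    out <- cbind(sex = rownames(out), out)
    rownames(out) <- NULL
    return(out)
  }
  py <- sum(py_s)
  if (py <= 0) stop("undefined rate: zero person-years", call. = FALSE)
  data.frame(events = sum(ev_s), person_years = py, rate = sum(ev_s) / py)
}

#' Write a synthetic cohort to delimited files
#'
#' Emits `subjects.csv`, `visits.csv`, `genotypes.csv` (id x SNP dosage) and
#' `truth.json` (the configuration and realized linear predictors) into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("subjects.csv", "visits.csv", "genotypes.csv",
                            "snp_info.csv", "truth.json"))
  utils::write.csv(cohort$subjects, paths[1], row.names = FALSE)
  utils::write.csv(cohort$visits, paths[2], row.names = FALSE)
  gt <- data.frame(id = rownames(cohort$genotypes), cohort$genotypes,
                   check.names = FALSE)
  utils::write.csv(gt, paths[3], row.names = FALSE)
  utils::write.csv(cohort$snp_info, paths[4], row.names = FALSE)
  tr <- cohort$truth
  tr$config <- unclass(tr$config)
  tr$snp_betas <- as.data.frame(tr$snp_betas)
  jsonlite::write_json(tr, paths[5], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(paths)
}
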