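#' Permutation global score test for the added value of a SNP block
#'
#' Tests the null hypothesis that the genetic markers carry no prognostic
#' value beyond the clinical and environmental predictors.  The statistic is
#' a trace-standardized quadratic form of the SNP-block score vector
#' evaluated at the clinical-model fit (genotype dosages weighted by the
#' clinical model's martingale residuals); its null distribution is obtained
#' by permuting the genotype rows across subjects, which preserves the
#' within-subject correlation of the residuals.
#'
#' @param records interval records.
#' @param clinical_terms terms of the clinical-environmental model (may be
#'   `NULL` for a null clinical model).
#' @param genotypes subjects x SNPs dosage matrix (rownames = subject ids).
#' @param n_perm number of permutations (values below 100 trigger a warning).
#' @param seed optional seed for the permutation stream.
#' @param strata,cluster as in [ag_fit()].
#' @return list of class `global_test_result`: `statistic`, `p_value`,
#'   `n_permutations`, `n_snps_used`.
#' @export
global_test <- function(records, clinical_terms, genotypes, n_perm = 1000,
                        seed = NULL, strata = NULL, cluster = "id") {
  if (ncol(genotypes) < 1) stop("need at least one SNP", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100: permutation p-value is coarse",
                            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data <- as.data.frame(records)
  sf <- strata_factor(data, strata)
  if (length(clinical_terms)) {
    fit <- ag_fit(records, clinical_terms, strata = strata, cluster = cluster)
    lp <- as.numeric(build_design(data, fit$terms, fit$xlevels)$X %*% fit$beta)
  } else {
    lp <- rep(0, nrow(data))
  }
  ## martingale residuals under the clinical model
  bl <- breslow_cumhaz(lp, data$start, data$stop, data$status, sf)
  H <- function(t, s) {
    b <- bl[bl$stratum == s, ]
    if (!nrow(b)) return(rep(0, length(t)))
    c(0, b$cumhaz)[findInterval(t, b$time) + 1]
  }
  sfc <- as.character(sf)
  dH <- numeric(nrow(data))
  for (s in unique(sfc)) {
    ix <- sfc == s
    dH[ix] <- H(data$stop[ix], s) - H(data$start[ix], s)
  }
  m <- data$status - dH * exp(lp)
  ## per-subject summed residuals: the score only depends on these
  ms <- rowsum(m, as.character(data[[cluster]]))
  G <- genotypes[rownames(ms), , drop = FALSE]
  keep <- apply(G, 2, function(g) stats::var(g) > 0)
  if (any(!keep)) message(sum(!keep), " constant SNP(s) excluded from global test")
  G <- G[, keep, drop = FALSE]
  if (ncol(G) == 0) stop("no non-constant SNPs", call. = FALSE)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  stat_of <- function(M) {
    u <- crossprod(Gc, M)
    sum(u^2) / ncol(Gc)
  }
  q_obs <- stat_of(ms)
  nsub <- nrow(ms)
  q_perm <- vapply(seq_len(n_perm), function(k) stat_of(ms[sample(nsub), , drop = FALSE]),
                   numeric(1))
  p <- (1 + sum(q_perm >= q_obs)) / (n_perm + 1)
  structure(list(statistic = q_obs, p_value = p, n_permutations = n_perm,
                 n_snps_used = ncol(Gc)), class = "global_test_result")
}

#' @export
print.global_test_result <- function(x, ...) {
  cat(sprintf("global permutation score test: Q = %.4g, p = %.4g (%d perms, %d SNPs)\n",
              x$statistic, x$p_value, x$n_permutations, x$n_snps_used))
  invisible(x)
}

wald_p <- function(fit, labels = NULL) {
  ## per-term Wald p-values; factor terms are tested jointly (chi-square)
  grp <- fit$groups
  labs <- unique(grp)
  if (!is.null(labels)) labs <- intersect(labs, labels)
  out <- stats::setNames(numeric(length(labs)), labs)
  V <- fit$robust_cov
  if (is.null(V)) V <- fit$naive_cov
  for (l in labs) {
    ix <- which(grp == l)
    b <- fit$beta[ix]
    Vi <- V[ix, ix, drop = FALSE]
    q <- tryCatch(as.numeric(t(b) %*% solve(Vi, b)), error = function(e) 0)
    out[l] <- stats::pchisq(q, df = length(ix), lower.tail = FALSE)
  }
  out
}

#' Select SNPs by Cox-LASSO with cross-validation and backfitting
#'
#' Clinical covariates enter unpenalized; the L1 penalty is chosen by
#' maximizing the cross-validated partial log-likelihood over a path of at
#' least 10 values; SNPs with nonzero penalized coefficients are refitted
#' unpenalized ("backfitting"), and SNPs whose refit Wald p exceeds
#' `alpha_stay` are dropped iteratively until stable.  Kept SNPs are then
#' offered interaction terms with the log inter-attack interval and with
#' standardized latitude, retained at `p <= alpha_stay`.  A designated
#' HLA-DRB1-tag SNP is always included.
#'
#' @inheritParams global_test
#' @param interaction_menu subset of `c("log_interattack", "z_latitude")`.
#' @param forced_snp SNP column always kept (e.g. the HLA-DRB1 tag).
#' @param penalty_grid L1 path; `NULL` derives a log-spaced 12-point grid
#'   from the data.
#' @param folds passed to [cv_partial_loglik()].
#' @param alpha_stay significance level to stay in the model.
#' @return list of class `selection_result`: `selected` (term_spec list),
#'   `betas_backfit`, `forced`, `penalty`, `cv_path`, `history`, `fit`.
#' @export
select_snps <- function(records, clinical_terms, genotypes,
                        interaction_menu = c("log_interattack", "z_latitude"),
                        forced_snp = NULL, penalty_grid = NULL, folds = "loo",
                        alpha_stay = 0.05, strata = NULL, cluster = "id") {
  clinical_terms <- if (length(clinical_terms)) as_term_list(clinical_terms) else list()
  snps <- colnames(genotypes)
  recs <- attach_genotypes(records, genotypes)
  all_terms <- c(clinical_terms, lapply(snps, term_spec))
  clin_labels <- vapply(clinical_terms, term_label, character(1))
  history <- list()

  if (is.null(penalty_grid)) {
    des <- build_design(as.data.frame(recs), all_terms)
    y <- survival::Surv(recs$start, recs$stop, recs$status)
    sf <- strata_factor(as.data.frame(recs), strata)
    yy <- if (nlevels(sf) > 1) glmnet::stratifySurv(y, sf) else y
    pf <- rep(1, ncol(des$X)); pf[des$groups %in% clin_labels] <- 0
    g0 <- glmnet::glmnet(des$X, yy, family = "cox", nlambda = 30,
                         penalty.factor = pf, standardize = TRUE)
    lmax <- max(g0$lambda)
    penalty_grid <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 12))
  }
  if (length(penalty_grid) < 10)
    stop("penalty path must have at least 10 points", call. = FALSE)

  cvpl <- cv_partial_loglik(recs, all_terms, penalty = penalty_grid,
                            folds = folds, strata = strata, cluster = cluster,
                            forced = clin_labels)
  pen <- penalty_grid[which.max(cvpl)]
  history$cv <- data.frame(penalty = penalty_grid, cvpl = as.numeric(cvpl))

  pfit <- ag_fit(recs, all_terms, strata = strata, penalty = pen,
                 cluster = cluster, forced = clin_labels)
  nz <- names(pfit$beta)[pfit$beta != 0]
  kept <- intersect(snps, nz)
  if (!is.null(forced_snp)) kept <- union(kept, forced_snp)
  history$lasso <- kept

  ## backfitting: unpenalized refit, iterated p-value filtering
  repeat {
    if (!length(kept)) break
    terms_k <- c(clinical_terms, lapply(kept, term_spec))
    bfit <- ag_fit(recs, terms_k, strata = strata, cluster = cluster)
    p <- wald_p(bfit, labels = setdiff(kept, forced_snp))
    worst <- names(p)[which.max(p)]
    if (!length(worst) || p[worst] <= alpha_stay) break
    kept <- setdiff(kept, worst)
    history$backfit_dropped <- c(history$backfit_dropped, worst)
  }

  ## interaction menu for kept SNPs
  sel_terms <- lapply(kept, term_spec)
  for (s in kept) {
    for (tr in interaction_menu) {
      cand <- c(clinical_terms, sel_terms, list(term_spec(s, tr)))
      tfit <- tryCatch(ag_fit(recs, cand, strata = strata, cluster = cluster),
                       error = function(e) NULL)
      if (is.null(tfit)) next
      lab <- term_label(term_spec(s, tr))
      p <- wald_p(tfit, labels = lab)
      if (length(p) && is.finite(p) && p <= alpha_stay) {
        sel_terms <- c(sel_terms, list(term_spec(s, tr)))
        history$interactions <- c(history$interactions, lab)
      }
    }
  }

  if (!length(sel_terms)) {
    warning("no SNPs selected; returning forced-only set", call. = FALSE)
    sel_terms <- lapply(forced_snp, term_spec)
  }
  final <- if (length(sel_terms))
    ag_fit(recs, c(clinical_terms, sel_terms), strata = strata,
           cluster = cluster) else NULL
  structure(list(selected = sel_terms,
                 selected_labels = vapply(sel_terms, term_label, character(1)),
                 betas_backfit = if (!is.null(final)) final$beta else numeric(0),
                 forced = forced_snp, penalty = pen,
                 cv_path = history$cv, history = history, fit = final),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d term(s) selected%s\n",
              length(x$selected),
              if (length(x$forced)) paste0(" (forced: ",
                                           paste(x$forced, collapse = ", "), ")")
              else ""))
  if (length(x$selected_labels)) print(x$selected_labels)
  invisible(x)
}

#' Backward elimination of clinical and environmental predictors
#'
#' Backward selection by Wald p at `alpha_stay`, with forced adjusters never
#' dropped.  Before elimination, each continuous candidate undergoes a
#' one-term fractional-polynomial (FP1) power scan over
#' `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}` (log transform for power 0); the best
#' power replaces the linear term when it improves the model deviance by more
#' than 3.84.  Collinear candidates (singular in the joint fit) are dropped
#' with a warning.
#'
#' @inheritParams ag_fit
#' @param candidates covariate names considered for elimination.
#' @param forced covariate names always kept.
#' @param alpha_stay significance level to stay.
#' @param fp_powers FP1 candidate powers.
#' @return `selection_result` with the retained terms and elimination history.
#' @export
select_clinical <- function(records, candidates, forced = character(0),
                            alpha_stay = 0.05,
                            fp_powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                            strata = NULL, cluster = "id") {
  data <- as.data.frame(records)
  history <- list()
  fp_applied <- list()

  is_cont <- vapply(candidates, function(nm)
    is.numeric(data[[nm]]) && length(unique(data[[nm]])) > 5, logical(1))

  ## FP1 scan (continuous, non-forced candidates) on the full model
  fit_dev <- function(d, vars) {
    f <- ag_fit(d, c(forced, vars), strata = strata, cluster = cluster)
    list(fit = f, dev = -2 * f$loglik)
  }
  active <- setdiff(candidates, forced)
  for (nm in candidates[is_cont]) {
    x <- data[[nm]]
    shift <- if (min(x) <= 0) -min(x) + 1 else 0
    base <- fit_dev(data, active)$dev
    best_p <- 1; best_dev <- base
    for (pw in setdiff(fp_powers, 1)) {
      d2 <- data
      xs <- x + shift
      d2[[nm]] <- if (pw == 0) log(xs) else xs^pw
      dv <- tryCatch(fit_dev(d2, active)$dev, error = function(e) Inf)
      if (dv < best_dev) { best_dev <- dv; best_p <- pw }
    }
    if (base - best_dev > 3.84) {
      xs <- x + shift
      data[[nm]] <- if (best_p == 0) log(xs) else xs^best_p
      fp_applied[[nm]] <- best_p
      history$fp <- c(history$fp, stats::setNames(best_p, nm))
    }
  }

  ## backward elimination
  repeat {
    fit <- ag_fit(data, c(forced, active), strata = strata, cluster = cluster)
    if (length(fit$singular)) {
      bad <- unique(fit$groups[match(fit$singular, names(fit$beta))])
      bad <- intersect(bad, active)
      if (length(bad)) {
        warning("dropping collinear candidate(s): ",
                paste(bad, collapse = ", "), call. = FALSE)
        active <- setdiff(active, bad)
        history$collinear <- c(history$collinear, bad)
        next
      }
    }
    if (!length(active)) break
    p <- wald_p(fit, labels = active)
    ## deterministic order: largest p first, ties by name
    ord <- order(-p, names(p))
    worst <- names(p)[ord][1]
    if (p[worst] <= alpha_stay) break
    active <- setdiff(active, worst)
    history$eliminated <- c(history$eliminated,
                            stats::setNames(p[worst], worst))
  }
  final_vars <- c(forced, active)
  final <- ag_fit(data, final_vars, strata = strata, cluster = cluster)
  structure(list(selected = as_term_list(final_vars),
                 selected_labels = final_vars,
                 betas_backfit = final$beta, forced = forced,
                 fp_powers = fp_applied, history = history, fit = final,
                 data = data),
            class = "selection_result")
}
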