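#' Model term specification
#'
#' A term is a covariate plus an optional transform: `identity` enters the
#' covariate as is; `time` enters `x * ln(t + 0.5)` evaluated at the interval
#' stop time (records are episode-split at event times first so the value is
#' exact at every risk-set evaluation); `log_interattack` enters
#' `x * ln(stop - start)`; `z_latitude` enters `x * z_latitude`
#' (gene-environment interaction with standardized latitude).
#'
#' @param name covariate column name.
#' @param transform one of `"identity"`, `"time"`, `"log_interattack"`,
#'   `"z_latitude"`.
#' @return a `term_spec` object.
#' @export
term_spec <- function(name,
                      transform = c("identity", "time", "log_interattack",
                                    "z_latitude")) {
  transform <- match.arg(transform)
  structure(list(name = name, transform = transform), class = "term_spec")
}

as_term_list <- function(terms) {
  if (inherits(terms, "term_spec")) return(list(terms))
  lapply(terms, function(t) {
    if (inherits(t, "term_spec")) t else term_spec(t)
  })
}

term_label <- function(t)
  if (t$transform == "identity") t$name else paste(t$name, t$transform, sep = ":")

## Expand terms into a numeric design matrix.  Factor covariates become
## treatment-coded dummies; `xlevels` pins the level sets so new data expand
## identically.  Returns X, a column -> term-label map, and the levels used.
build_design <- function(data, terms, xlevels = NULL) {
  terms <- as_term_list(terms)
  cols <- list(); groups <- character(0); xlev <- list()
  for (t in terms) {
    if (!t$name %in% names(data))
      stop(sprintf("covariate '%s' not found in records", t$name), call. = FALSE)
    x <- data[[t$name]]
    lab <- term_label(t)
    if (is.character(x) || is.factor(x)) {
      lev <- if (!is.null(xlevels[[t$name]])) xlevels[[t$name]] else
        sort(unique(as.character(x)))
      xlev[[t$name]] <- lev
      f <- factor(as.character(x), levels = lev)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(t$name, lev[-1])
      base <- mm
    } else {
      base <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, t$name))
    }
    mod <- switch(t$transform,
                  identity = base,
                  time = base * log(data$stop + 0.5),
                  log_interattack = base * data$log_interattack,
                  z_latitude = base * data$z_latitude)
    if (t$transform != "identity")
      colnames(mod) <- paste(colnames(base), t$transform, sep = ":")
    cols[[length(cols) + 1]] <- mod
    groups <- c(groups, rep(lab, ncol(mod)))
  }
  X <- do.call(cbind, cols)
  list(X = X, groups = groups, xlevels = xlev)
}

## Split (start, stop] records at interior cut points, carrying the event
## status to the final piece only.
episode_split <- function(data, cut) {
  cut <- sort(unique(cut))
  pieces <- lapply(seq_len(nrow(data)), function(i) {
    s <- data$start[i]; e <- data$stop[i]
    inner <- cut[cut > s & cut < e]
    if (!length(inner)) return(data[i, , drop = FALSE])
    bounds <- c(s, inner, e)
    k <- length(bounds) - 1
    d <- data[rep(i, k), , drop = FALSE]
    d$start <- bounds[-length(bounds)]
    d$stop <- bounds[-1]
    d$status <- c(rep(0L, k - 1), data$status[i])
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

strata_factor <- function(data, strata) {
  if (is.null(strata) || !length(strata)) return(factor(rep("all", nrow(data))))
  interaction(data[strata], drop = TRUE, sep = "/")
}

#' Breslow partial log-likelihood at a given linear predictor
#'
#' Stratified Breslow-ties partial log-likelihood for `(start, stop]`
#' counting-process data, evaluated at an arbitrary linear predictor.
#'
#' @param lp numeric linear predictor per record.
#' @param start,stop,status counting-process fields.
#' @param strata optional stratum factor.
#' @return scalar log partial likelihood.
#' @export
pll_breslow <- function(lp, start, stop, status, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(lp))
  tot <- 0
  for (s in split(seq_along(lp), strata)) {
    st <- status[s]
    if (!any(st == 1)) next
    te <- sort(unique(stop[s][st == 1]))
    K <- length(te)
    w <- exp(lp[s])
    a <- findInterval(start[s], te)  # at risk for te indices a+1 .. b
    b <- findInterval(stop[s], te)
    delta <- numeric(K + 1)
    add <- rowsum(w, a + 1)
    delta[as.integer(rownames(add))] <- delta[as.integer(rownames(add))] + add
    rem <- rowsum(w, b + 1)
    delta[as.integer(rownames(rem))] <- delta[as.integer(rownames(rem))] - rem
    denom <- cumsum(delta)[seq_len(K)]
    ev <- which(st == 1)
    idx <- findInterval(stop[s][ev], te)
    tot <- tot + sum(lp[s][ev] - log(denom[idx]))
  }
  tot
}

#' Breslow baseline cumulative hazard
#'
#' Per-stratum Breslow estimator evaluated at the supplied (uncentered)
#' linear predictor.
#'
#' @inheritParams pll_breslow
#' @return data.frame with `stratum`, `time`, `hazard`, `cumhaz`.
#' @export
breslow_cumhaz <- function(lp, start, stop, status, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", length(lp))
  strata <- as.character(strata)
  out <- lapply(split(seq_along(lp), strata), function(s) {
    st <- status[s]
    if (!any(st == 1)) return(NULL)
    te <- sort(unique(stop[s][st == 1]))
    K <- length(te)
    w <- exp(lp[s])
    a <- findInterval(start[s], te)
    b <- findInterval(stop[s], te)
    delta <- numeric(K + 1)
    add <- rowsum(w, a + 1)
    delta[as.integer(rownames(add))] <- delta[as.integer(rownames(add))] + add
    rem <- rowsum(w, b + 1)
    delta[as.integer(rownames(rem))] <- delta[as.integer(rownames(rem))] - rem
    denom <- cumsum(delta)[seq_len(K)]
    dN <- as.numeric(rowsum(st[st == 1], stop[s][st == 1]))
    h <- dN / denom
    data.frame(stratum = strata[s][1], time = te, hazard = h,
               cumhaz = cumsum(h), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Fit an Andersen-Gill Cox model on counting-process records
#'
#' Stratified Cox partial-likelihood fit with Breslow tie handling on
#' `(start, stop]` interval records.  With `penalty = 0` the fit is the
#' Newton-Raphson maximum partial-likelihood estimate with a cluster-robust
#' sandwich covariance (score residuals summed within subject).  With
#' `penalty > 0` an L1-penalized fit is computed by coordinate descent,
#' with `forced` covariates left unpenalized.  Records with a `time`
#' transform term are episode-split at event times so `x * ln(t + 0.5)` is
#' exact at every risk-set evaluation time.
#'
#' @param records `interval_records` (or any data.frame with `start`, `stop`,
#'   `status` and the referenced covariates).
#' @param terms list of [term_spec()] objects or covariate names.
#' @param strata character vector of stratum column names (e.g.
#'   `c("edss_stratum", "cdms_stratum")`).
#' @param penalty scalar L1 penalty weight (glmnet `lambda`); 0 for the MLE.
#' @param cluster column holding the subject key for the sandwich variance.
#' @param forced covariate labels exempt from the L1 penalty.
#' @return an `ag_fit` object: `beta`, `naive_cov`, `robust_cov`, `loglik0`,
#'   `loglik`, `model_chisq`, `n_events`, `baseline` (per-stratum Breslow
#'   cumulative hazard), `converged`, plus centering means and term metadata.
#' @export
ag_fit <- function(records, terms, strata = NULL, penalty = 0,
                   cluster = "id", forced = NULL) {
  terms <- as_term_list(terms)
  data <- as.data.frame(records)
  if (any(vapply(terms, function(t) t$transform == "time", logical(1)))) {
    data <- episode_split(data, cut = sort(unique(data$stop[data$status == 1])))
    if (!is.null(data$log_interattack))
      data$log_interattack <- log(data$stop - data$start)
  }
  sf <- strata_factor(data, strata)
  ## drop strata without events
  ev_by_s <- tapply(data$status, sf, sum)
  dead <- names(ev_by_s)[is.na(ev_by_s) | ev_by_s == 0]
  if (length(dead)) {
    warning("dropping stratum(s) with zero events: ",
            paste(dead, collapse = ", "), call. = FALSE)
    keep <- !(as.character(sf) %in% dead)
    data <- data[keep, , drop = FALSE]
    sf <- droplevels(sf[keep])
  }
  des <- build_design(data, terms)
  X <- des$X
  cl <- if (!is.null(cluster) && cluster %in% names(data)) data[[cluster]] else
    seq_len(nrow(data))
  y <- survival::Surv(data$start, data$stop, data$status)

  if (penalty > 0) {
    fit <- fit_penalized(X, y, sf, penalty, forced, des$groups)
    beta <- fit$beta
    lp <- as.numeric(X %*% beta)
    ll <- pll_breslow(lp, data$start, data$stop, data$status, sf)
    ll0 <- pll_breslow(rep(0, nrow(data)), data$start, data$stop, data$status, sf)
    res <- list(beta = beta, naive_cov = NULL, robust_cov = NULL,
                loglik0 = ll0, loglik = ll, model_chisq = 2 * (ll - ll0),
                n_events = sum(data$status), penalty = penalty,
                converged = TRUE, singular = character(0))
  } else {
    dd <- data.frame(X, check.names = FALSE)
    dd$.start <- data$start; dd$.stop <- data$stop; dd$.status <- data$status
    dd$.strat <- sf; dd$.cl <- cl
    fm <- stats::as.formula(paste(
      "survival::Surv(.start, .stop, .status) ~",
      paste(sprintf("`%s`", colnames(X)), collapse = " + "),
      "+ survival::strata(.strat)"))
    cox <- survival::coxph(fm, data = dd, ties = "breslow", cluster = .cl,
                           control = survival::coxph.control(
                             eps = 1e-9, iter.max = 50), x = TRUE, y = TRUE)
    beta <- stats::coef(cox)
    singular <- names(beta)[is.na(beta)]
    beta[is.na(beta)] <- 0
    names(beta) <- colnames(X)
    nv <- cox$naive.var
    if (is.null(nv)) nv <- cox$var
    rv <- cox$var
    dimnames(nv) <- dimnames(rv) <- list(colnames(X), colnames(X))
    lp <- as.numeric(X %*% beta)
    res <- list(beta = beta, naive_cov = nv, robust_cov = rv,
                loglik0 = cox$loglik[1], loglik = cox$loglik[2],
                model_chisq = max(0, 2 * diff(cox$loglik)),
                n_events = sum(data$status), penalty = 0,
                converged = is.null(cox$info) || cox$iter < 50,
                singular = singular, cox = cox)
  }
  res$baseline <- breslow_cumhaz(as.numeric(X %*% res$beta),
                                 data$start, data$stop, data$status, sf)
  res$means <- colMeans(X)
  res$terms <- terms
  res$groups <- des$groups
  res$xlevels <- des$xlevels
  res$strata <- strata
  class(res) <- "ag_fit"
  res
}

fit_penalized <- function(X, y, sf, penalty, forced, groups) {
  yy <- if (nlevels(sf) > 1) glmnet::stratifySurv(y, sf) else y
  pf <- rep(1, ncol(X))
  if (!is.null(forced)) pf[groups %in% forced | colnames(X) %in% forced] <- 0
  lam <- sort(unique(c(penalty * c(32, 16, 8, 4, 2, 1))), decreasing = TRUE)
  g <- glmnet::glmnet(X, yy, family = "cox", lambda = lam,
                      penalty.factor = pf, standardize = TRUE)
  beta <- as.numeric(stats::coef(g, s = penalty))
  names(beta) <- colnames(X)
  list(beta = beta, glmnet = g)
}

#' @export
print.ag_fit <- function(x, ...) {
  cat(sprintf("ag_fit: %d terms, D = %d events, model chi-square = %.2f%s\n",
              length(x$beta), x$n_events, x$model_chisq,
              if (x$penalty > 0) sprintf(" (L1 penalty %.4g)", x$penalty) else ""))
  print(round(x$beta, 4))
  invisible(x)
}

#' Linear predictor of an AG fit on (new) records
#'
#' `beta' x` per record, centered on the fitting-sample column means.
#'
#' @param fit an `ag_fit`.
#' @param records records carrying the fit's covariates.
#' @return numeric vector, one value per record.
#' @export
linear_predictor <- function(fit, records) {
  des <- build_design(as.data.frame(records), fit$terms, xlevels = fit$xlevels)
  if (!identical(colnames(des$X), names(fit$beta)))
    stop("records do not yield the covariate columns of the fit", call. = FALSE)
  as.numeric(sweep(des$X, 2, fit$means) %*% fit$beta)
}

#' Harrell concordance for counting-process records
#'
#' Fraction of concordant (risk, event-time) pairs among comparable pairs
#' within `(start, stop]` risk sets; risk ties count one half.
#'
#' @param risk numeric risk score per record (higher = earlier events), or an
#'   `ag_fit` whose linear predictor is used.
#' @param records interval records.
#' @return concordance statistic in `[0, 1]`.
#' @export
concordance_index <- function(risk, records) {
  if (inherits(risk, "ag_fit")) risk <- linear_predictor(risk, records)
  d <- data.frame(start = records$start, stop = records$stop,
                  status = records$status, risk = risk)
  cc <- tryCatch(
    survival::concordance(
      survival::Surv(start, stop, status) ~ risk, data = d, reverse = TRUE),
    error = function(e)
      stop("concordance undefined: no comparable pairs", call. = FALSE))
  npairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (!is.finite(npairs) || npairs == 0)
    stop("concordance undefined: no comparable pairs", call. = FALSE)
  unname(cc$concordance)
}

#' Cross-validated partial log-likelihood (Verweij-van Houwelingen)
#'
#' For each fold (subjects are left out as whole clusters; `folds = "loo"`
#' leaves out one subject at a time) the model is refitted and the fold's
#' contribution is `l(beta_(-i)) - l_(-i)(beta_(-i))`, the full-data minus
#' the training-data partial log-likelihood at the held-out estimate; the
#' sum over folds is returned for each penalty value.
#'
#' @inheritParams ag_fit
#' @param penalty numeric vector of L1 penalties (0 allowed; `Inf` gives the
#'   null model's contribution).
#' @param folds `"loo"` or an integer number of subject-level folds.
#' @return named numeric vector of cross-validated partial log-likelihoods,
#'   one per penalty.
#' @export
cv_partial_loglik <- function(records, terms, penalty, folds = "loo",
                              strata = NULL, cluster = "id", forced = NULL) {
  terms <- as_term_list(terms)
  data <- as.data.frame(records)
  sf <- strata_factor(data, strata)
  des <- build_design(data, terms)
  X <- des$X
  ids <- data[[cluster]]
  subj <- unique(ids)
  if (identical(folds, "loo")) {
    fold_of <- stats::setNames(seq_along(subj), subj)
  } else {
    k <- as.integer(folds)
    fold_of <- stats::setNames(sample(rep(seq_len(k), length.out = length(subj))),
                               subj)
  }
  fold_id <- fold_of[as.character(ids)]
  y <- survival::Surv(data$start, data$stop, data$status)
  pll_all <- function(beta) pll_breslow(as.numeric(X %*% beta),
                                        data$start, data$stop, data$status, sf)
  out <- stats::setNames(numeric(length(penalty)), as.character(penalty))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    Xt <- X[tr, , drop = FALSE]
    sft <- droplevels(sf[tr])
    pll_tr <- function(beta) pll_breslow(as.numeric(Xt %*% beta),
                                         data$start[tr], data$stop[tr],
                                         data$status[tr], sft)
    finite_pen <- penalty[is.finite(penalty) & penalty > 0]
    betas <- list()
    if (length(finite_pen)) {
      yy <- if (nlevels(sft) > 1)
        glmnet::stratifySurv(y[tr], sft) else y[tr]
      pf <- rep(1, ncol(X))
      if (!is.null(forced)) pf[des$groups %in% forced | colnames(X) %in% forced] <- 0
      lam <- sort(unique(c(finite_pen, max(finite_pen) * c(4, 2))),
                  decreasing = TRUE)
      g <- glmnet::glmnet(Xt, yy, family = "cox", lambda = lam,
                          penalty.factor = pf, standardize = TRUE)
      cf <- as.matrix(stats::coef(g, s = finite_pen))
      for (j in seq_along(finite_pen))
        betas[[as.character(finite_pen[j])]] <- cf[, j]
    }
    for (j in seq_along(penalty)) {
      pen <- penalty[j]
      beta <- if (is.infinite(pen)) rep(0, ncol(X))
      else if (pen == 0) {
        ft <- tryCatch(
          ag_fit(data[tr, , drop = FALSE], terms, strata = strata,
                 cluster = cluster),
          error = function(e) NULL)
        if (is.null(ft)) rep(0, ncol(X)) else ft$beta
      } else betas[[as.character(pen)]]
      out[j] <- out[j] + pll_all(beta) - pll_tr(beta)
    }
  }
  out
}
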