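#' Assign subjects to IPI risk groups by index quartiles
#'
#' Quartile split on the subject-level baseline index value (the value of the
#' earliest record per subject): `IPI1` = low risk (0-25%), `IPI2` = low
#' intermediate (25-50%), `IPI3` = high intermediate (50-75%), `IPI4` = high
#' risk (75-100%).  Ties are broken by subject id order; group sizes differ
#' by at most one.  An all-equal index degenerates to all-`IPI1` with a
#' warning.
#'
#' @param index a `prognostic_index`.
#' @param n_groups number of groups (default 4).
#' @return data.frame with `id`, `value` (baseline index) and `group`
#'   (factor `IPI1` ... `IPI<n_groups>`); attribute `cuts` stores the
#'   boundary values.
#' @export
assign_groups <- function(index, n_groups = 4) {
  df <- data.frame(id = index$id, value = index$values)
  if (any(!is.finite(df$value))) stop("index values must be finite", call. = FALSE)
  first <- !duplicated(df$id)
  base <- df[first, , drop = FALSE]
  n <- nrow(base)
  if (n < n_groups)
    stop(sprintf("cannot form %d groups from %d subjects", n_groups, n),
         call. = FALSE)
  labs <- paste0("IPI", seq_len(n_groups))
  if (stats::sd(base$value) == 0) {
    warning("degenerate index (all values equal): all subjects assigned IPI1",
            call. = FALSE)
    g <- factor(rep(labs[1], n), levels = labs)
    out <- data.frame(id = base$id, value = base$value, group = g)
    attr(out, "cuts") <- rep(base$value[1], n_groups - 1)
    return(out)
  }
  ord <- order(base$value, base$id)
  rank <- integer(n); rank[ord] <- seq_len(n)
  g <- labs[floor((rank - 1) * n_groups / n) + 1]
  out <- data.frame(id = base$id, value = base$value,
                    group = factor(g, levels = labs))
  attr(out, "cuts") <- stats::quantile(base$value,
                                       probs = seq_len(n_groups - 1) / n_groups)
  out
}

#' Subject-level time to first event
#'
#' Collapses counting-process records to one row per subject: time of the
#' first event, or the last observed stop time if censored.
#'
#' @param records interval records.
#' @return data.frame with `id`, `time`, `status`.
#' @export
subject_survival <- function(records) {
  d <- as.data.frame(records)
  d <- d[order(d$id, d$stop), ]
  out <- do.call(rbind, lapply(split(d, d$id), function(x) {
    ev <- which(x$status == 1)
    if (length(ev))
      data.frame(id = x$id[1], time = x$stop[ev[1]], status = 1L)
    else
      data.frame(id = x$id[1], time = max(x$stop), status = 0L)
  }))
  rownames(out) <- NULL
  out
}

#' Fit the risk-group hazard model and risk scores
#'
#' Cox model with indicator terms for groups `IPI2 ... IPI4` (`IPI1` is the
#' reference): `h(t) = h0(t) exp(gamma1 IPI2 + gamma2 IPI3 + gamma3 IPI4)`.
#' Group risk scores are `lambda = HR / (1 + HR)`.  Kaplan-Meier curves per
#' group (time to first event) with 5- and 10-year survival read-offs and
#' per-group Weibull fits are attached.
#'
#' @param records interval records.
#' @param groups an [assign_groups()] result.
#' @param cluster subject key.
#' @return object of class `risk_group_model`: `gamma` (with robust SEs),
#'   `hr`, `lam`, `km` (a `survfit`), `surv_at` (5/10-year survival per
#'   group), `weibull` (per-group shape/scale), `fit`.
#' @export
fit_group_model <- function(records, groups, cluster = "id") {
  d <- as.data.frame(records)
  d$group <- groups$group[match(d$id, groups$id)]
  if (anyNA(d$group)) stop("records contain subjects without a group", call. = FALSE)
  ev <- tapply(d$status, d$group, sum)
  if (any(is.na(ev) | ev == 0))
    stop("each risk group needs at least one event; empty: ",
         paste(names(ev)[is.na(ev) | ev == 0], collapse = ", "), call. = FALSE)
  fit <- ag_fit(d, term_spec("group"), cluster = cluster)
  gamma <- fit$beta
  hr <- exp(gamma)
  lam <- risk_score(hr)
  ss <- subject_survival(d)
  ss$group <- groups$group[match(ss$id, groups$id)]
  km <- survival::survfit(survival::Surv(time, status) ~ group, data = ss)
  horizon <- c(5, 10)
  sm <- summary(km, times = horizon, extend = TRUE)
  surv_at <- data.frame(group = sub("group=", "", as.character(sm$strata)),
                        time = sm$time, surv = sm$surv)
  wb <- do.call(rbind, lapply(split(ss, ss$group), function(x) {
    if (sum(x$status) < 2) return(data.frame(group = as.character(x$group[1]),
                                             shape = NA, scale = NA))
    sr <- survival::survreg(survival::Surv(time, status) ~ 1, data = x,
                            dist = "weibull")
    data.frame(group = as.character(x$group[1]),
               shape = 1 / sr$scale, scale = exp(stats::coef(sr)[[1]]))
  }))
  rownames(wb) <- NULL
  structure(list(gamma = gamma, gamma_se = sqrt(diag(fit$robust_cov)),
                 hr = hr, lam = lam, km = km, surv_at = surv_at,
                 weibull = wb, fit = fit, groups = groups),
            class = "risk_group_model")
}

#' @export
print.risk_group_model <- function(x, ...) {
  cat("risk-group hazard model (reference IPI1):\n")
  print(round(rbind(gamma = x$gamma, hr = x$hr, lambda = x$lam), 4))
  invisible(x)
}

#' Group risk score from a hazard ratio
#'
#' `lambda = HR / (1 + HR)`: the probability-scale risk score of a prognostic
#' subgroup; ranges over (0, 1) with `lambda = 0.5` iff `HR = 1`.
#'
#' @param hr hazard ratio(s), non-negative.
#' @return risk score(s) in `[0, 1)`.
#' @export
risk_score <- function(hr) {
  if (any(hr < 0)) stop("hazard ratio must be non-negative", call. = FALSE)
  hr / (1 + hr)
}

#' Validation by calibration with per-group Weibull models
#'
#' Fits a maximum-likelihood Weibull model to the (censored) first-event
#' times of each risk group, then regresses the observed log cumulative
#' hazard on the model-predicted log cumulative hazard over a grid of
#' quantile time points.  A well-calibrated model gives slope 1 and
#' intercept 0 per group.  When `reference_hazard` (a `time`/`cumhaz` table
#' from an external cohort) is supplied, predictions are recalibrated by
#' linear interpolation of the reference baseline before comparison.
#'
#' @param records interval records.
#' @param groups an [assign_groups()] result.
#' @param predicted predicted cumulative hazard: data.frame with `group`,
#'   `time`, `cumhaz`, or `NULL` to use the fitted group Cox model's Breslow
#'   baseline times the group hazard ratios.
#' @param reference_hazard optional external baseline: data.frame with
#'   `time`, `cumhaz`.
#' @param n_grid number of quantile time points per group (default 20).
#' @param min_events groups with fewer events are skipped with a warning.
#' @return data.frame with per-group `shape`, `scale`, `slope`, `intercept`,
#'   `n_events`.
#' @export
weibull_calibration <- function(records, groups, predicted = NULL,
                                reference_hazard = NULL, n_grid = 20,
                                min_events = 5) {
  ss <- subject_survival(records)
  ss$group <- groups$group[match(ss$id, groups$id)]
  if (is.null(predicted)) {
    gm <- fit_group_model(records, groups)
    d <- ss
    lp <- log(c(1, gm$hr))[as.integer(d$group)]
    bl <- breslow_cumhaz(lp, rep(0, nrow(d)), d$time, d$status)
    predicted <- do.call(rbind, lapply(levels(d$group), function(g) {
      hr_g <- c(1, unname(gm$hr))[match(g, levels(d$group))]
      data.frame(group = g, time = bl$time, cumhaz = bl$cumhaz * hr_g)
    }))
  }
  if (!is.null(reference_hazard)) {
    ## external-cohort stub: replace the baseline shape with the reference
    ## curve, linearly interpolated, scaled to match each group at its median
    pred2 <- do.call(rbind, lapply(split(predicted, predicted$group), function(p) {
      h_ref <- stats::approx(reference_hazard$time, reference_hazard$cumhaz,
                             xout = p$time, rule = 2)$y
      anchor <- stats::median(seq_len(nrow(p)))
      sc <- p$cumhaz[anchor] / max(h_ref[anchor], 1e-12)
      data.frame(group = p$group, time = p$time, cumhaz = h_ref * sc)
    }))
    predicted <- pred2
  }
  out <- lapply(split(ss, ss$group), function(x) {
    g <- as.character(x$group[1])
    nev <- sum(x$status)
    if (nev < min_events) {
      warning(sprintf("group %s skipped: only %d event(s)", g, nev),
              call. = FALSE)
      return(NULL)
    }
    sr <- survival::survreg(survival::Surv(time, status) ~ 1, data = x,
                            dist = "weibull")
    shape <- 1 / sr$scale
    scale <- exp(stats::coef(sr)[[1]])
    et <- x$time[x$status == 1]
    grid <- stats::quantile(et, probs = seq(0.05, 0.95, length.out = n_grid))
    h_obs <- (grid / scale)^shape
    p <- predicted[predicted$group == g, , drop = FALSE]
    h_pred <- stats::approx(p$time, p$cumhaz, xout = grid, rule = 2)$y
    ok <- h_obs > 0 & h_pred > 0
    cal <- stats::lm(log(h_obs[ok]) ~ log(h_pred[ok]))
    data.frame(group = g, shape = shape, scale = scale,
               slope = unname(stats::coef(cal)[2]),
               intercept = unname(stats::coef(cal)[1]), n_events = nev)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
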