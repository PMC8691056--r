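#' Build a stacked landmark dataset
#'
#' For every landmark time `s`, subjects still under observation at `s` enter
#' the `s`-slice with covariate values current at `s` (last observation
#' carried forward); their interval records are truncated to the prediction
#' window `(s, s + w]` with administrative censoring at `s + w`.  Slices are
#' stacked and tagged with the landmark interaction basis `f1(s) = s/5`,
#' `f2(s) = (s/5)^2`.
#'
#' @param records interval records (with any index value columns to be used
#'   by the supermodel already attached).
#' @param landmarks ordered landmark times (years), default `0:5`.
#' @param w prediction-window width (years), default 5.
#' @return data.frame of class `landmark_stack` with the truncated records,
#'   frozen covariates, and columns `lm_s`, `lm_f1`, `lm_f2`.  Attributes
#'   `landmarks` and `w`.
#' @export
build_stack <- function(records, landmarks = 0:5, w = 5) {
  stopifnot(w > 0, !is.unsorted(landmarks))
  data <- as.data.frame(records)
  structural <- c("id", "start", "stop", "status", "log_interattack")
  covs <- setdiff(names(data), structural)
  slices <- list()
  for (s in landmarks) {
    active <- data$start <= s & data$stop > s
    if (!any(active)) {
      warning(sprintf("landmark s = %g beyond follow-up: empty slice", s),
              call. = FALSE)
      next
    }
    at_risk <- unique(data$id[active])
    rows <- data$id %in% at_risk & data$stop > s & data$start < s + w
    sl <- data[rows, , drop = FALSE]
    ## freeze covariates at their value current at s
    frozen <- data[active, , drop = FALSE]
    ix <- match(sl$id, frozen$id)
    for (cv in covs) sl[[cv]] <- frozen[[cv]][ix]
    cens <- sl$stop > s + w
    sl$status[cens] <- 0L
    sl$stop <- pmin(sl$stop, s + w)
    sl$start <- pmax(sl$start, s)
    sl$log_interattack <- log(sl$stop - sl$start)
    sl$lm_s <- s
    sl$lm_f1 <- s / 5
    sl$lm_f2 <- (s / 5)^2
    slices[[length(slices) + 1]] <- sl
  }
  out <- do.call(rbind, slices)
  rownames(out) <- NULL
  attr(out, "landmarks") <- landmarks
  attr(out, "w") <- w
  class(out) <- c("landmark_stack", "data.frame")
  out
}

#' Fit a landmark supermodel on a stacked dataset
#'
#' One Cox fit on the whole stack (robust variance clustered on subject, as
#' the same subject appears in several slices), with the index entering with
#' a main effect and linear/quadratic landmark-time interactions
#' `v, v*f1(s), v*f2(s)`.  `proportional` mode shares one baseline across
#' slices and adds `f1(s)`, `f2(s)` as baseline-shift covariates;
#' `stratified` mode gives each landmark its own baseline.
#'
#' @param stack a [build_stack()] result.
#' @param index name of the index value column in the stack.
#' @param mode `"proportional"` or `"stratified"`.
#' @param cluster subject key column.
#' @return object of class `landmark_fit`: `theta` (named coefficients),
#'   `robust_cov`, `baseline` (per-stratum Breslow cumulative hazard),
#'   `mode`, `landmarks`, `w`, `index`.
#' @export
fit_supermodel <- function(stack, index, mode = c("proportional", "stratified"),
                           cluster = "id") {
  mode <- match.arg(mode)
  stopifnot(nrow(stack) > 0, index %in% names(stack))
  d <- as.data.frame(stack)
  v <- d[[index]]
  X <- cbind(pi_main = v, pi_f1 = v * d$lm_f1, pi_f2 = v * d$lm_f2)
  if (mode == "proportional") X <- cbind(X, f1 = d$lm_f1, f2 = d$lm_f2)
  dd <- data.frame(X, check.names = FALSE)
  dd$.start <- d$start; dd$.stop <- d$stop; dd$.status <- d$status
  dd$.cl <- d[[cluster]]
  dd$.strat <- if (mode == "stratified") factor(d$lm_s) else factor(rep(1, nrow(d)))
  fm <- stats::as.formula(paste(
    "survival::Surv(.start, .stop, .status) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + "),
    "+ survival::strata(.strat)"))
  cox <- survival::coxph(fm, data = dd, ties = "breslow", cluster = .cl,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  theta <- stats::coef(cox)
  theta[is.na(theta)] <- 0
  names(theta) <- colnames(X)
  lp <- as.numeric(X %*% theta)
  base <- breslow_cumhaz(lp, d$start, d$stop, d$status,
                         strata = as.character(dd$.strat))
  structure(list(theta = theta, robust_cov = cox$var, fit = cox,
                 baseline = base, mode = mode,
                 landmarks = attr(stack, "landmarks"), w = attr(stack, "w"),
                 index = index),
            class = "landmark_fit")
}

#' @export
print.landmark_fit <- function(x, ...) {
  cat(sprintf("landmark_fit (%s baseline) on index '%s', landmarks %s, w = %g\n",
              x$mode, x$index, paste(x$landmarks, collapse = ","), x$w))
  print(round(x$theta, 4))
  invisible(x)
}

cumhaz_at <- function(baseline, stratum, t) {
  b <- baseline[baseline$stratum == stratum, , drop = FALSE]
  if (!nrow(b)) return(rep(0, length(t)))
  c(0, b$cumhaz)[findInterval(t, b$time) + 1]
}

#' Sliding-window event probability at a landmark
#'
#' `P(event in (s, s + w] | at risk at s)` for a given index value, computed
#' as `1 - exp(-[H0(s+w) - H0(s)] * exp(theta(s) * v))` where
#' `theta(s) = theta0 + theta1 f1(s) + theta2 f2(s)` and, in proportional
#' mode, the baseline shift `exp(gamma1 f1 + gamma2 f2)` multiplies the
#' window hazard.  Monotone increasing in the index whenever `theta(s) > 0`.
#'
#' @param fit a [fit_supermodel()] result.
#' @param value index value(s) on the fitted index scale.
#' @param s landmark time; must be one of the fitted landmarks.
#' @return event probability in `[0, 1]`, vectorized over `value`.
#' @export
dynamic_probability <- function(fit, value, s) {
  if (!s %in% fit$landmarks)
    stop(sprintf("landmark s = %g outside the fitted set (%s)", s,
                 paste(fit$landmarks, collapse = ", ")), call. = FALSE)
  f1 <- s / 5; f2 <- (s / 5)^2
  th <- fit$theta
  theta_s <- th[["pi_main"]] + th[["pi_f1"]] * f1 + th[["pi_f2"]] * f2
  if (fit$mode == "stratified") {
    dH <- cumhaz_at(fit$baseline, as.character(s), s + fit$w) -
      cumhaz_at(fit$baseline, as.character(s), s)
    lp <- theta_s * value
  } else {
    dH <- cumhaz_at(fit$baseline, "1", s + fit$w) -
      cumhaz_at(fit$baseline, "1", s)
    lp <- theta_s * value + th[["f1"]] * f1 + th[["f2"]] * f2
  }
  1 - exp(-dH * exp(lp))
}
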