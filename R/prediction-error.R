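## left-continuous censoring survival G(t-) from the Kaplan-Meier estimate
## of the censoring distribution
censoring_km <- function(time, status) {
  sf <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  f <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  function(t) pmax(f(t - 1e-10), 1e-10)
}

ipcw_weights <- function(time, status, t, Gminus) {
  w <- numeric(length(time))
  past_event <- time <= t & status == 1
  future <- time > t
  w[past_event] <- 1 / Gminus(time[past_event])
  w[future] <- 1 / Gminus(t + 1e-10)
  w
}

point_error <- function(obs_after, S_hat, w, metric, eps = 1e-12) {
  if (metric == "brier") {
    contrib <- (obs_after - S_hat)^2
  } else {
    S <- pmin(pmax(S_hat, eps), 1 - eps)
    contrib <- -(obs_after * log(S) + (1 - obs_after) * log(1 - S))
  }
  sum(w * contrib) / length(w)
}

#' Prediction-error curve at diagnosis
#'
#' Kullback-Leibler or Brier prediction error of per-subject predicted
#' survival curves over a grid of horizons, with inverse-probability-of-
#' censoring weights from the Kaplan-Meier estimate of the censoring
#' distribution (computed on the full sample).  The null model uses the
#' marginal Kaplan-Meier curve; the error-reduction curve is
#' `(err_null - err_model) / err_null`.
#'
#' @param surv subject-level survival data: either interval records (reduced
#'   via [subject_survival()]) or a data.frame with `id`, `time`, `status`.
#' @param pred matrix of predicted survival probabilities, one row per
#'   subject (ordered as in `surv`), one column per horizon.
#' @param metric `"brier"` or `"kl"`.
#' @param horizons evaluation times; default 40 equally spaced points over
#'   `(0, max(time)]`.
#' @param eps clipping bound for KL when a prediction is 0 or 1.
#' @return data.frame of class `error_curve`: `metric`, `t`, `err_null`,
#'   `err_model`, `reduction`.
#' @export
error_curve <- function(surv, pred, metric = c("brier", "kl"),
                        horizons = NULL, eps = 1e-12) {
  metric <- match.arg(metric)
  if (!is.null(surv$start)) surv <- subject_survival(surv)
  if (is.null(horizons))
    horizons <- seq(0, max(surv$time), length.out = 41)[-1]
  pred <- as.matrix(pred)
  if (nrow(pred) != nrow(surv) || ncol(pred) != length(horizons))
    stop("pred must be a subjects x horizons matrix", call. = FALSE)
  Gm <- censoring_km(surv$time, surv$status)
  kmf <- survival::survfit(survival::Surv(time, status) ~ 1, data = surv)
  Snull <- stats::stepfun(kmf$time, c(1, kmf$surv))(horizons)
  out <- data.frame(metric = metric, t = horizons, err_null = NA_real_,
                    err_model = NA_real_)
  for (k in seq_along(horizons)) {
    t <- horizons[k]
    w <- ipcw_weights(surv$time, surv$status, t, Gm)
    obs_after <- as.numeric(surv$time > t)
    out$err_null[k] <- point_error(obs_after, rep(Snull[k], nrow(surv)), w,
                                   metric, eps)
    out$err_model[k] <- point_error(obs_after, pred[, k], w, metric, eps)
  }
  out$reduction <- ifelse(out$err_null > 0,
                          (out$err_null - out$err_model) / out$err_null, 0)
  class(out) <- c("error_curve", "data.frame")
  out
}

## window outcome per subject in one landmark slice: time and status of the
## first event inside (s, s+w], on the window clock u = t - s
slice_outcomes <- function(slice, s) {
  d <- slice[order(slice$id, slice$stop), ]
  out <- do.call(rbind, lapply(split(d, d$id), function(x) {
    ev <- which(x$status == 1)
    if (length(ev))
      data.frame(id = x$id[1], u = x$stop[ev[1]] - s, event = 1L)
    else
      data.frame(id = x$id[1], u = max(x$stop) - s, event = 0L)
  }))
  rownames(out) <- NULL
  out
}

#' Dynamic prediction-error curves at the landmark times
#'
#' At every landmark `s`, the `w`-window event probability of each fitted
#' landmark supermodel is scored against the observed window outcome with
#' IPCW censoring adjustment, and compared with the null (marginal
#' Kaplan-Meier window risk) predictor.
#'
#' @param stack a [build_stack()] whose columns include each fit's index.
#' @param fits named list of [fit_supermodel()] results (e.g. `CEPI`, `GPI`,
#'   `CEGPI` supermodels).
#' @param metric `"brier"` or `"kl"`.
#' @param eps KL clipping bound.
#' @return data.frame of class `error_curve`: `metric`, `s`, `model`,
#'   `err_null`, `err_model`, `reduction`.
#' @export
dynamic_error_curve <- function(stack, fits, metric = c("brier", "kl"),
                                eps = 1e-12) {
  metric <- match.arg(metric)
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be a named list", call. = FALSE)
  w <- attr(stack, "w")
  landmarks <- attr(stack, "landmarks")
  rows <- list()
  for (s in landmarks) {
    sl <- stack[stack$lm_s == s, , drop = FALSE]
    if (!nrow(sl)) next
    oc <- slice_outcomes(sl, s)
    Gm <- censoring_km(oc$u, oc$event)
    wt <- ipcw_weights(oc$u, oc$event, w - 1e-9, Gm)
    obs_after <- as.numeric(oc$u > w - 1e-9)
    kmf <- survival::survfit(survival::Surv(u, event) ~ 1, data = oc)
    Snull <- stats::stepfun(kmf$time, c(1, kmf$surv))(w)
    err_null <- point_error(obs_after, rep(Snull, nrow(oc)), wt, metric, eps)
    first <- sl[!duplicated(sl$id), , drop = FALSE]
    ix <- match(oc$id, first$id)
    for (nm in names(fits)) {
      ft <- fits[[nm]]
      v <- first[[ft$index]][ix]
      p_event <- dynamic_probability(ft, v, s)
      err <- point_error(obs_after, 1 - p_event, wt, metric, eps)
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, s = s, model = nm, err_null = err_null,
        err_model = err,
        reduction = if (err_null > 0) (err_null - err) / err_null else 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("error_curve", "data.frame")
  out
}
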