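#' Build a cross-validated prognostic index
#'
#' The per-record linear predictor of a stratified AG Cox model, with each
#' subject's value computed from coefficients fitted with that subject
#' excluded (leave-one-subject-out), so the index is honest with respect to
#' overfitting.  A fold that fails to converge falls back to the full-fit
#' coefficients (logged).  Values are mean-centered.
#'
#' @inheritParams ag_fit
#' @param loo cross-validate (default) or use the full fit for every record.
#' @param folds `"loo"` or an integer number of subject folds (grouped CV for
#'   large cohorts).
#' @param name index name, e.g. `"CEPI"` or `"GPI"`.
#' @return object of class `prognostic_index`: `name`, `values` (per record),
#'   `id` (per record), `sd`, `full_fit`, `n_fallback`.
#' @export
build_index <- function(records, terms, strata = NULL, cluster = "id",
                        loo = TRUE, folds = "loo", name = "PI") {
  terms <- as_term_list(terms)
  data <- as.data.frame(records)
  full <- ag_fit(records, terms, strata = strata, cluster = cluster)
  vals <- linear_predictor(full, records)
  n_fallback <- 0L
  if (loo) {
    ids <- data[[cluster]]
    subj <- unique(ids)
    if (identical(folds, "loo")) {
      fold_of <- stats::setNames(seq_along(subj), subj)
    } else {
      fold_of <- stats::setNames(
        sample(rep(seq_len(as.integer(folds)), length.out = length(subj))), subj)
    }
    fold_id <- fold_of[as.character(ids)]
    for (f in sort(unique(fold_id))) {
      hold <- fold_id == f
      ft <- tryCatch(
        ag_fit(data[!hold, , drop = FALSE], terms, strata = strata,
               cluster = cluster),
        error = function(e) NULL)
      if (is.null(ft) || !ft$converged) {
        n_fallback <- n_fallback + 1L
        ft <- full
      }
      vals[hold] <- linear_predictor(ft, data[hold, , drop = FALSE])
    }
    if (n_fallback > 0)
      message(n_fallback, " cross-validation fold(s) fell back to full-fit coefficients")
  }
  vals <- vals - mean(vals)
  structure(list(name = name, values = vals, id = data[[cluster]],
                 sd = stats::sd(vals), terms = terms, strata = strata,
                 full_fit = full, loo = loo, n_fallback = n_fallback),
            class = "prognostic_index")
}

#' @export
print.prognostic_index <- function(x, ...) {
  cat(sprintf("prognostic_index %s: %d records, sd = %.3f%s\n", x$name,
              length(x$values), x$sd,
              if (isTRUE(x$loo)) " (cross-validated)" else ""))
  invisible(x)
}

#' Supermodel Cox regression on prognostic indices
#'
#' Fits a stratified AG Cox model (cluster-robust) on one or two
#' cross-validated index value columns.  With two indices (CEPI, GPI) the
#' coefficients are `alpha1`, `alpha2` and the combined index
#' `CEGPI = alpha1 * CEPI + alpha2 * GPI` is derived; with one index the
#' single coefficient (`alpha3` for the super learner on the CEGPI) is
#' expected near 1 when the index is well calibrated.  `time_varying` adds
#' `index * ln(t + 0.5)` terms.
#'
#' @param records interval records aligned with the index values.
#' @param indices a `prognostic_index` or list of one or two.
#' @param time_varying add `ln(t + 0.5)` interaction terms.
#' @param strata,cluster as in [ag_fit()].
#' @return list of class `supermodel`: `alpha` (coefficients), `alpha_se`
#'   (robust), `alpha_se_naive`, `fit`, `metrics` (a [model_metrics()] list)
#'   and, for two indices, `cegpi` (a derived `prognostic_index`).
#' @export
calibrate_supermodel <- function(records, indices, time_varying = FALSE,
                                 strata = NULL, cluster = "id") {
  if (inherits(indices, "prognostic_index")) indices <- list(indices)
  stopifnot(length(indices) %in% 1:2)
  data <- as.data.frame(records)
  nms <- vapply(indices, function(z) z$name, character(1))
  for (i in seq_along(indices)) {
    if (length(indices[[i]]$values) != nrow(data))
      stop("index not aligned to records", call. = FALSE)
    data[[nms[i]]] <- indices[[i]]$values - mean(indices[[i]]$values)
  }
  terms <- lapply(nms, term_spec)
  if (time_varying)
    terms <- c(terms, lapply(nms, term_spec, transform = "time"))
  fit <- ag_fit(data, terms, strata = strata, cluster = cluster)
  alpha <- fit$beta
  cidx <- concordance_index(linear_predictor(fit, data), data)
  met <- model_metrics(chisq = fit$model_chisq, D = fit$n_events,
                       c_index = cidx,
                       aic = -2 * fit$loglik + 2 * sum(fit$beta != 0))
  out <- list(alpha = alpha,
              alpha_se = sqrt(diag(fit$robust_cov)),
              alpha_se_naive = sqrt(diag(fit$naive_cov)),
              fit = fit, metrics = met, indices = nms)
  if (length(indices) == 2) {
    a1 <- alpha[[nms[1]]]; a2 <- alpha[[nms[2]]]
    vals <- a1 * data[[nms[1]]] + a2 * data[[nms[2]]]
    out$cegpi <- structure(
      list(name = "CEGPI", values = vals, id = data[[cluster]],
           sd = stats::sd(vals), alpha = c(alpha1 = a1, alpha2 = a2),
           components = nms, loo = all(vapply(indices, function(z)
             isTRUE(z$loo), logical(1)))),
      class = "prognostic_index")
  }
  class(out) <- "supermodel"
  out
}

#' @export
print.supermodel <- function(x, ...) {
  cat("supermodel Cox fit on:", paste(x$indices, collapse = ", "), "\n")
  print(round(rbind(alpha = x$alpha, robust_se = x$alpha_se), 4))
  cat(sprintf("chi-square = %.1f, D = %d, pseudo-R2 = %.3f, C = %.3f\n",
              x$metrics$chisq, x$metrics$D, x$metrics$pseudo_r2,
              x$metrics$c_index))
  invisible(x)
}

#' Model comparison metrics
#'
#' @param chisq model (likelihood-ratio) chi-square.
#' @param D number of events.
#' @param c_index cross-validated Harrell C.
#' @param aic model AIC.
#' @return list with `chisq`, `D`, `pseudo_r2`, `c_index`, `aic`.
#' @export
model_metrics <- function(chisq, D, c_index = NA_real_, aic = NA_real_) {
  list(chisq = chisq, D = D, pseudo_r2 = pseudo_r2(chisq, D),
       c_index = c_index, aic = aic)
}

#' Pseudo R-squared from the model chi-square
#'
#' `1 - exp(-chisq / D)`: the explained-variation measure computed from the
#' model chi-square statistic and the number of events.
#'
#' @param chisq model chi-square (>= 0).
#' @param D number of events (> 0).
#' @return value in `[0, 1)`.
#' @export
pseudo_r2 <- function(chisq, D) {
  if (any(D <= 0)) stop("pseudo-R2 undefined: D must be positive", call. = FALSE)
  if (any(chisq < 0)) stop("chisq must be non-negative", call. = FALSE)
  1 - exp(-chisq / D)
}

#' Genetic share of the combined index's prognostic information
#'
#' `chisq_gpi / (chisq_gpi + chisq_cegpi)`: the proportion of the combined
#' model's information contributed by the genetic component, computed from
#' the genetic-only and combined supermodel chi-squares.
#'
#' @param chisq_gpi genetic-only supermodel chi-square.
#' @param chisq_cegpi combined supermodel chi-square.
#' @return proportion in `[0, 1]`.
#' @export
genetic_share <- function(chisq_gpi, chisq_cegpi) {
  if (any(chisq_gpi < 0) || any(chisq_cegpi < 0))
    stop("chi-squares must be non-negative", call. = FALSE)
  if (all(chisq_gpi + chisq_cegpi == 0))
    stop("genetic share undefined: both chi-squares are zero", call. = FALSE)
  chisq_gpi / (chisq_gpi + chisq_cegpi)
}

#' Calibration coefficients of the combined index
#'
#' Elementwise ratio of the joint supermodel coefficients to the
#' single-index supermodel coefficients:
#' `psi1 = alpha1(joint) / alpha1(single)`, `psi2 = alpha2(joint) /
#' alpha2(single)`, quantifying how much each component is shrunk when
#' combined.
#'
#' @param alpha_joint coefficient(s) from the joint (two-index) supermodel.
#' @param alpha_single coefficient(s) from the single-index supermodels.
#' @return numeric vector of calibration coefficients.
#' @export
calibration_coefficients <- function(alpha_joint, alpha_single) {
  if (any(alpha_single == 0))
    stop("calibration coefficient undefined: zero single-index coefficient",
         call. = FALSE)
  alpha_joint / alpha_single
}

#' Correlation between two prognostic indices
#' @param pi1,pi2 `prognostic_index` objects aligned to the same records.
#' @return Pearson correlation of the per-record values.
#' @export
index_correlation <- function(pi1, pi2) {
  stats::cor(pi1$values, pi2$values)
}
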