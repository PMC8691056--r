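# Independent brute-force oracles.  These reimplement the partial likelihood,
# concordance and LOO cross-validation literally (double loops, grid search),
# sharing no code with the package internals they check.

oracle_pll <- function(beta, X, start, stop, status, strata = NULL) {
  if (is.null(strata)) strata <- rep(1, length(start))
  lp <- as.numeric(as.matrix(X) %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    t <- stop[i]
    rs <- which(strata == strata[i] & start < t & stop >= t)
    ll <- ll + lp[i] - log(sum(exp(lp[rs])))
  }
  ll
}

# grid search + local refinement of the hand-written partial likelihood
oracle_cox_beta <- function(X, start, stop, status, strata = NULL,
                            lower = -5, upper = 5) {
  X <- as.matrix(X)
  f <- function(b) -oracle_pll(b, X, start, stop, status, strata)
  if (ncol(X) == 1) {
    g <- seq(lower, upper, length.out = 2001)
    v <- vapply(g, f, numeric(1))
    b0 <- g[which.min(v)]
    stats::optimize(f, c(b0 - 0.05, b0 + 0.05), tol = 1e-10)$minimum
  } else {
    gr <- as.matrix(expand.grid(seq(lower, upper, length.out = 41),
                                seq(lower, upper, length.out = 41)))
    v <- apply(gr, 1, f)
    b0 <- gr[which.min(v), ]
    stats::optim(b0, f, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 10000))$par
  }
}

oracle_concordance <- function(risk, start, stop, status) {
  conc <- disc <- tied <- 0
  for (i in which(status == 1)) {
    t <- stop[i]
    for (j in seq_along(risk)) {
      if (j == i) next
      at_risk <- start[j] < t && stop[j] >= t
      tied_time <- status[j] == 1 && stop[j] == t
      if (at_risk && !tied_time) {
        if (risk[i] > risk[j]) conc <- conc + 1
        else if (risk[i] < risk[j]) disc <- disc + 1
        else tied <- tied + 1
      }
    }
  }
  if (conc + disc + tied == 0) return(NA_real_)
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# simulate + restructure convenience used across test files
sim_records <- function(config, endpoint = "RRE", rule = "gte") {
  co <- simulate_cohort(config)
  v <- merge(co$visits, co$subjects, by = "id", sort = FALSE)
  v <- v[order(v$id, v$time), ]
  rec <- suppressWarnings(restructure(v, endpoint_spec(endpoint, rule)))
  list(cohort = co, records = rec, visits = v)
}

fake_index <- function(values, ids = seq_along(values)) {
  structure(list(name = "CEGPI", values = values, id = ids,
                 sd = stats::sd(values)), class = "prognostic_index")
}

# tiny hand-buildable counting-process records
toy_records <- function() {
  data.frame(
    id = c(1, 1, 2, 2, 3, 3),
    start = c(0, 1, 0, 1.5, 0, 2),
    stop = c(1, 2, 1.5, 3, 2, 4),
    status = c(0L, 1L, 0L, 1L, 0L, 1L),
    x = c(0, 1, 1, 0, 1, 1))
}
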