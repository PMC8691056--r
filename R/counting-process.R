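#' Endpoint specification
#'
#' The three survival endpoints are worsening of disability (`WoD`), relapse
#' and/or recurrence of relapsing events (`RRE`), and their union (`RWoD`).
#' A `WoD` event on the interval ending at visit j is `EDSS_j >= EDSS_{j-1}`
#' under the default `gte` rule (the risk-score definition: the probability of
#' observing an EDSS greater than or equal to the previous score) or a strict
#' increase under `gt`.
#'
#' @param name one of `"WoD"`, `"RRE"`, `"RWoD"`.
#' @param worsening_rule `"gte"` (default) or `"gt"`.
#' @return an `endpoint_spec` object.
#' @export
endpoint_spec <- function(name = c("WoD", "RRE", "RWoD"),
                          worsening_rule = c("gte", "gt")) {
  name <- match.arg(name)
  worsening_rule <- match.arg(worsening_rule)
  structure(list(name = name, worsening_rule = worsening_rule),
            class = "endpoint_spec")
}

edss_bin <- function(edss, merge_below = 1) {
  f <- floor(edss)
  ifelse(f <= merge_below, paste0("0-", merge_below), as.character(f))
}

#' Restructure longitudinal visits into counting-process interval records
#'
#' Converts a visit table into one half-open interval `(start, stop]` per
#' consecutive visit pair, under a Markov view of the disease course: the
#' event status of the interval is determined by the state observed at its
#' stop visit, covariates are the values current at its start visit.
#' Terminal intervals without an event are right-censored.  Repeated
#' same-day measurements keep the last record of the day; subjects with a
#' single visit are dropped with a warning.
#'
#' @param visits data.frame with columns `id`, `time` (years since FDE,
#'   sorted within subject), `edss`, and (for RRE/RWoD) `relapse`; an optional
#'   `cdms` flag; any further columns are carried along as covariates.
#' @param endpoint an [endpoint_spec()].
#' @param edss_merge_below EDSS floors at or below this value are merged into
#'   one stratum (default 1, giving strata 0-1, 2, 3, ...).
#' @return data.frame of class `interval_records` with columns `id`, `start`,
#'   `stop`, `status`, `edss_stratum`, `cdms_stratum`, `log_interattack`, plus
#'   covariates at interval start.  Attribute `endpoint` stores the
#'   endpoint specification.
#' @export
restructure <- function(visits, endpoint = endpoint_spec("WoD"),
                        edss_merge_below = 1) {
  if (!inherits(endpoint, "endpoint_spec"))
    stop("endpoint must be an endpoint_spec", call. = FALSE)
  need <- c("id", "time", "edss")
  if (endpoint$name %in% c("RRE", "RWoD")) need <- c(need, "relapse")
  miss <- setdiff(need, names(visits))
  if (length(miss))
    stop("visits table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(visits$edss)) stop("EDSS must be present at each visit", call. = FALSE)
  if (is.null(visits$cdms)) visits$cdms <- 0L

  day <- 1 / 365.25
  parts <- split(visits, visits$id)
  dropped <- character(0)
  out <- lapply(parts, function(d) {
    if (is.unsorted(d$time, strictly = FALSE))
      stop(sprintf("visits for subject %s are not sorted in time", d$id[1]),
           call. = FALSE)
    ## same-day duplicates: keep the last of the day
    if (any(diff(d$time) < day)) {
      keep <- c(diff(d$time) >= day, TRUE)
      message(sprintf("subject %s: %d same-day repeated measure(s) collapsed to the last",
                      d$id[1], sum(!keep)))
      d <- d[keep, , drop = FALSE]
    }
    if (nrow(d) < 2) {
      dropped <<- c(dropped, as.character(d$id[1]))
      return(NULL)
    }
    if (any(diff(d$time) <= 0))
      stop(sprintf("overlapping or zero-length intervals for subject %s", d$id[1]),
           call. = FALSE)
    j <- seq_len(nrow(d))[-1]
    wod <- as.integer(if (endpoint$worsening_rule == "gte")
      d$edss[j] >= d$edss[j - 1] else d$edss[j] > d$edss[j - 1])
    status <- switch(endpoint$name,
                     WoD = wod,
                     RRE = as.integer(d$relapse[j] > 0),
                     RWoD = as.integer(wod | d$relapse[j] > 0))
    covs <- d[j - 1, setdiff(names(d), c("time")), drop = FALSE]
    names(covs)[names(covs) == "edss"] <- "edss_start"
    data.frame(id = d$id[j - 1], start = d$time[j - 1], stop = d$time[j],
               status = status,
               edss_stratum = edss_bin(d$edss[j - 1], edss_merge_below),
               cdms_stratum = as.integer(cummax(d$cdms))[j - 1],
               log_interattack = log(d$time[j] - d$time[j - 1]),
               covs[setdiff(names(covs), "id")],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  if (length(dropped))
    warning("dropped single-visit subject(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  rec <- do.call(rbind, out)
  if (is.null(rec) || nrow(rec) == 0)
    stop("no interval records remain after filtering", call. = FALSE)
  rownames(rec) <- NULL
  attr(rec, "endpoint") <- endpoint
  class(rec) <- c("interval_records", "data.frame")
  rec
}

#' Observation and event counts of an interval-record set
#'
#' @param records an `interval_records` data.frame.
#' @return list with `N` (records) and `D` (events).
#' @export
summarize_intervals <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("no interval records to summarize", call. = FALSE)
  list(N = nrow(records), D = sum(records$status))
}

#' Attach genotype dosages to interval records
#'
#' Expands a subjects x SNPs dosage matrix to one row per interval record.
#'
#' @param records `interval_records`.
#' @param genotypes numeric matrix with subject ids as rownames.
#' @param snps optional subset of SNP column names.
#' @return `records` with the dosage columns appended.
#' @export
attach_genotypes <- function(records, genotypes, snps = colnames(genotypes)) {
  ix <- match(as.character(records$id), rownames(genotypes))
  if (anyNA(ix))
    stop("genotypes missing for subject(s): ",
         paste(unique(records$id[is.na(ix)]), collapse = ", "), call. = FALSE)
  add <- as.data.frame(genotypes[ix, snps, drop = FALSE])
  rownames(add) <- NULL
  out <- cbind(as.data.frame(records), add)
  attr(out, "endpoint") <- attr(records, "endpoint")
  class(out) <- c("interval_records", "data.frame")
  out
}

#' Write interval records per endpoint
#' @param records `interval_records`.
#' @param path output csv path.
#' @return invisibly, `path`.
#' @export
write_intervals <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
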