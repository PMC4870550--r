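# Per-distinct-event-time table for two-sample rank tests:
# nj/n1j at risk (total / group 1), dj/d1j deaths (total / group 1),
# hypergeometric mean e1j and variance vj of d1j given the margins.
event_table <- function(ds) {
  d <- ds$data
  if (!any(d$group == 0) || !any(d$group == 1))
    stop("both groups must be present for a two-sample test")
  if (sum(d$event) == 0) stop("no events: two-sample rank test undefined")
  tj <- sort(unique(d$time[d$event == 1]))
  nj  <- vapply(tj, function(t) sum(d$time >= t), numeric(1))
  n1j <- vapply(tj, function(t) sum(d$time >= t & d$group == 1), numeric(1))
  dj  <- vapply(tj, function(t) sum(d$time == t & d$event == 1), numeric(1))
  d1j <- vapply(tj, function(t) sum(d$time == t & d$event == 1 & d$group == 1),
                numeric(1))
  e1j <- dj * n1j / nj
  vj <- ifelse(nj > 1,
               dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1), 0)
  data.frame(time = tj, nj = nj, n1j = n1j, dj = dj, d1j = d1j,
             e1j = e1j, vj = vj)
}

# weights at the left limit of each event time
rank_test_weights <- function(ds, tab, weight) {
  switch(weight,
         unit = rep(1, nrow(tab)),
         km = km_left_limit(kaplan_meier(ds), tab$time),
         `one-minus-km` = 1 - km_left_limit(kaplan_meier(ds), tab$time),
         stop("unknown weight: ", weight))
}

wlr_htest <- function(stat, p, method, ds_name) {
  structure(list(statistic = c(`chi-square` = stat), parameter = c(df = 1),
                 p.value = p, method = method, data.name = ds_name),
            class = "htest")
}

#' Log-rank test for equality of two hazard functions
#'
#' At each distinct event time the observed group-1 deaths are compared to
#' their hypergeometric expectation given the risk-set margins; the
#' standardized squared sum is referred to chi-square with 1 df.
#'
#' @param ds a [survival_dataset()] with both groups present and at least
#'   one event.
#' @return an object of class `"htest"` with `statistic` and `p.value`.
#' @export
log_rank_test <- function(ds) {
  weighted_log_rank_test(ds, weight = "unit")
}

#' Weighted log-rank (Fleming-Harrington type) test
#'
#' Statistic `(sum_j w_j (O_j - E_j))^2 / sum_j w_j^2 V_j`, chi-square with
#' 1 df, where the weight at each event time is the pooled Kaplan-Meier
#' estimate taken at the left limit: `weight = "km"` uses `S_hat(t-)`
#' (emphasizing early differences), `"one-minus-km"` uses `1 - S_hat(t-)`
#' (late differences), and `"unit"` reduces exactly to the log-rank test.
#'
#' @inheritParams log_rank_test
#' @param weight `"km"`, `"one-minus-km"`, or `"unit"`.
#' @return an `"htest"` object; the weight label is part of `method`.
#' @export
weighted_log_rank_test <- function(ds, weight = c("km", "one-minus-km", "unit")) {
  weight <- match.arg(weight)
  ds_name <- deparse(substitute(ds))
  tab <- event_table(ds)
  w <- rank_test_weights(ds, tab, weight)
  num <- sum(w * (tab$d1j - tab$e1j))
  den <- sum(w^2 * tab$vj)
  stat <- if (den > 0) num^2 / den else 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  lbl <- switch(weight, unit = "log-rank",
                km = "weighted log-rank, pooled-KM weight S(t-)",
                `one-minus-km` = "weighted log-rank, weight 1 - S(t-)")
  wlr_htest(stat, p, paste("Two-sample", lbl, "test"), ds_name)
}

# P( sup_{0<=u<=1} |B(u)| >= q ) for standard Brownian motion: the theta
# series 1 - (4/pi) sum_k (-1)^k/(2k+1) exp(-(2k+1)^2 pi^2 / (8 q^2)),
# truncated once terms fall below 1e-12.
brownian_sup_pvalue <- function(q) {
  if (q <= 0) return(1)
  s <- 0; k <- 0
  repeat {
    term <- exp(-(2 * k + 1)^2 * pi^2 / (8 * q^2)) / (2 * k + 1)
    s <- s + ifelse(k %% 2 == 0, term, -term)
    if (term < 1e-12 || k > 1000) break
    k <- k + 1
  }
  min(1, max(0, 1 - 4 * s / pi))
}

#' Renyi (supremum-over-time) weighted log-rank test
#'
#' The running weighted observed-minus-expected process is standardized by
#' the square root of its total variance; the supremum of its absolute
#' value over event times is referred to the distribution of
#' `sup |B(u)|` on the unit interval for standard Brownian motion.  The
#' supremum form retains power when the hazard ratio changes sign over
#' time (crossing hazards), where the terminal statistic can cancel.
#'
#' @inheritParams log_rank_test
#' @param weight `"early"` (pooled-KM left limit `S_hat(t-)`) or `"late"`
#'   (`1 - S_hat(t-)`), matching the weighted log-rank pair; `"unit"` gives
#'   the unweighted supremum log-rank.
#' @return an `"htest"` object with the supremum statistic and p-value.
#' @export
renyi_test <- function(ds, weight = c("early", "late", "unit")) {
  weight <- match.arg(weight)
  ds_name <- deparse(substitute(ds))
  tab <- event_table(ds)
  w <- rank_test_weights(ds, tab,
                         switch(weight, early = "km", late = "one-minus-km",
                                unit = "unit"))
  z <- cumsum(w * (tab$d1j - tab$e1j))
  v <- sum(w^2 * tab$vj)
  stat <- if (v > 0) max(abs(z)) / sqrt(v) else 0
  structure(list(statistic = c(`sup |Z|` = stat),
                 p.value = brownian_sup_pvalue(stat),
                 method = paste0("Two-sample Renyi supremum test (",
                                 weight, " weight)"),
                 data.name = ds_name),
            class = "htest")
}
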