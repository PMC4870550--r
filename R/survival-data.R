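#' Construct a two-group right-censored survival dataset
#'
#' Bundles observed times `X_i = min(T_i, C_i)`, event indicators
#' `delta_i = I(T_i <= C_i)` and binary group labels `z_i` together with the
#' study horizon `tau`, after validation and canonical sorting.
#'
#' Records are sorted by time; at tied times events precede censorings
#' (so a subject censored at an event time is still in that event's risk
#' set), and ties beyond that keep input order, making the sort stable and
#' deterministic.  Tied event times are handled downstream by the Breslow
#' convention.
#'
#' @param time numeric vector of nonnegative observed times, all `<= tau`.
#' @param event integer/numeric vector in \{0, 1\}; 1 = observed failure,
#'   0 = right-censored.
#' @param group integer/numeric vector in \{0, 1\}; 0 = control/baseline,
#'   1 = treatment.
#' @param tau positive study horizon, in the same time unit as `time`.
#'   Default 6.
#'
#' @return An object of class `"survival_dataset"`: a list with elements
#'   `data` (a data.frame with columns `time`, `event`, `group`, canonically
#'   sorted) and `tau`.
#' @examples
#' ds <- survival_dataset(time = c(1, 2, 3), event = c(1, 1, 0),
#'                        group = c(0, 1, 1), tau = 6)
#' ds
#' @export
survival_dataset <- function(time, event, group, tau = 6) {
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  n <- length(time)
  if (length(event) != n || length(group) != n)
    stop("'time', 'event' and 'group' must have equal length")
  time <- as.numeric(time); event <- as.numeric(event); group <- as.numeric(group)
  if (anyNA(time) || anyNA(event) || anyNA(group))
    stop("missing values are not allowed")
  if (any(!is.finite(time)) || any(time < 0))
    stop("all times must be finite and nonnegative")
  if (!all(event %in% c(0, 1)))
    stop("'event' must be binary (0 = censored, 1 = failure)")
  if (!all(group %in% c(0, 1)))
    stop("'group' must be binary (0 = control, 1 = treatment)")
  if (any(time > tau))
    stop("observed times must not exceed the study horizon 'tau'")
  ord <- order(time, -event)  # stable; events before censorings at ties
  structure(
    list(data = data.frame(time = time[ord], event = event[ord],
                           group = group[ord]),
         tau = tau),
    class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  d <- x$data
  cat("Two-group right-censored survival dataset\n")
  cat(sprintf("  n = %d (group 0: %d, group 1: %d), events = %d, tau = %g\n",
              nrow(d), sum(d$group == 0), sum(d$group == 1),
              sum(d$event == 1), x$tau))
  invisible(x)
}

#' Number of subjects in a survival dataset
#' @param ds a `survival_dataset`.
#' @return integer sample size.
#' @export
n_subjects <- function(ds) nrow(ds$data)

#' Read a two-group survival dataset from a delimited text file
#'
#' @param path path to a CSV (or other delimited) file with a header.
#' @param time_col,event_col,group_col column names holding the observed
#'   time, event indicator and group label.  Defaults `"time"`, `"event"`,
#'   `"group"`.
#' @param tau positive study horizon; rows with `time > tau` are rejected
#'   with an error.
#' @param sep field separator, default `","`.
#' @return a validated [survival_dataset()].
#' @export
read_survival_data <- function(path, time_col = "time", event_col = "event",
                               group_col = "group", tau = 6, sep = ",") {
  if (!file.exists(path))
    stop("file not found: ", path)
  d <- read.csv(path, sep = sep, check.names = FALSE)
  miss <- setdiff(c(time_col, event_col, group_col), names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  survival_dataset(d[[time_col]], d[[event_col]], d[[group_col]], tau = tau)
}

#' Write a survival dataset to a delimited text file
#'
#' Emits the same dialect [read_survival_data()] reads: a header line
#' `time,event,group` followed by one row per subject.
#'
#' @param ds a `survival_dataset`.
#' @param path output file path.
#' @param sep field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_survival_data <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "survival_dataset"))
  write.table(ds$data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Risk set at a time point
#'
#' Indices (1-based, in canonical sort order) of subjects still under
#' observation at time `t`, i.e. `{k : X_k >= t}`.
#'
#' @param ds a `survival_dataset`.
#' @param t nonnegative time.
#' @return integer vector of indices into `ds$data`.
#' @export
risk_set <- function(ds, t) {
  stopifnot(inherits(ds, "survival_dataset"), is.finite(t), t >= 0)
  which(ds$data$time >= t)
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator, pooled over groups or for one group.  A thin
#' wrapper around [survival::survfit()] returning the curve as a
#' right-continuous step function.
#'
#' @param ds a `survival_dataset`.
#' @param group `NULL` (default) for the pooled estimate, or 0/1 for a
#'   single group's curve.
#' @return An object of class `"km_estimate"`: list with `time` (distinct
#'   event/censoring times), `surv` (estimates), and `fun`, a right-continuous
#'   step function with `fun(t) = S_hat(t)` and `fun(0) = 1`.  Beyond the last
#'   observed time the last value is carried forward.
#' @examples
#' ds <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 1, 1), c(0, 0, 1, 1))
#' km <- kaplan_meier(ds)
#' km$fun(2.5)  # 0.5
#' @export
kaplan_meier <- function(ds, group = NULL) {
  stopifnot(inherits(ds, "survival_dataset"))
  d <- ds$data
  if (!is.null(group)) {
    d <- d[d$group == group, , drop = FALSE]
    if (!nrow(d)) stop("no subjects in group ", group)
  }
  if (sum(d$event) == 0) {
    warning("no events: Kaplan-Meier estimate is constant 1")
    f <- function(t) rep(1, length(t))
    return(structure(list(time = numeric(0), surv = numeric(0), fun = f),
                     class = "km_estimate"))
  }
  fit <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  f <- stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(time = fit$time, surv = fit$surv, fun = f),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate over", length(x$time), "time points\n")
  invisible(x)
}

# Left limit S(t-) of a KM curve at each time in `t`.
km_left_limit <- function(km, t) {
  if (!length(km$time)) return(rep(1, length(t)))
  idx <- findInterval(t, km$time, left.open = TRUE)  # strictly earlier times
  c(1, km$surv)[idx + 1L]
}
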