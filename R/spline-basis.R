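#' Data-driven knot interval for the B-spline expansion
#'
#' The spline support is the overlap of the two groups' uncensored time
#' ranges, shrunk by a small `epsilon`:
#' `lo = max over groups of (min uncensored time) + epsilon`,
#' `hi = min over groups of (max uncensored time) - epsilon`.
#' Data outside `[lo, hi]` carry essentially no information about the log
#' hazard ratio, so the basis is confined there (with clamped evaluation
#' outside; see [evaluate_basis()]).
#'
#' @param ds a [survival_dataset()] with at least one uncensored event in
#'   each group.
#' @param epsilon small positive shrinkage; default
#'   `1e-6 * (u_n - l_n)` where `l_n`, `u_n` are the max-min and min-max
#'   uncensored times above.
#' @return An object of class `"knot_interval"`: list with `lo`, `hi`,
#'   `epsilon`.
#' @examples
#' ds <- survival_dataset(c(1, 4, 2, 5), c(1, 1, 1, 1), c(0, 0, 1, 1))
#' knot_interval(ds, epsilon = 0)  # [2, 4]
#' @export
knot_interval <- function(ds, epsilon = NULL) {
  stopifnot(inherits(ds, "survival_dataset"))
  d <- ds$data
  for (g in 0:1)
    if (!any(d$event == 1 & d$group == g))
      stop("group ", g, " has no uncensored events; ",
           "the spline knot interval is undefined")
  t0 <- d$time[d$event == 1 & d$group == 0]
  t1 <- d$time[d$event == 1 & d$group == 1]
  ln <- max(min(t0), min(t1))
  un <- min(max(t0), max(t1))
  if (ln >= un)
    stop(sprintf(paste0("degenerate knot interval: the two groups' ",
                        "uncensored time ranges overlap in [%g, %g]"),
                 ln, un))
  if (is.null(epsilon)) epsilon <- 1e-6 * (un - ln)
  if (epsilon < 0) stop("'epsilon' must be nonnegative")
  lo <- ln + epsilon
  hi <- un - epsilon
  if (lo >= hi)
    stop(sprintf(paste0("degenerate knot interval [%g, %g]: too few events ",
                        "in the overlap of the two groups' event ranges"),
                 lo, hi))
  structure(list(lo = lo, hi = hi, epsilon = epsilon),
            class = "knot_interval")
}

#' Default number of B-spline basis functions
#'
#' The sample-size rule `a_n = floor((n / log n)^(1 / (2p + 1)))`, floored
#' at 1, where `p` is the assumed number of bounded derivatives of the log
#' hazard ratio.  Exposed for completeness; the package default is a fixed
#' basis of 5 functions of degree 2 (see [build_basis()]).
#'
#' @param n sample size, `>= 3`.
#' @param p positive integer smoothness order.
#' @return positive integer.
#' @examples
#' default_n_basis(100, p = 2)  # 1
#' @export
default_n_basis <- function(n, p) {
  stopifnot(n >= 3, p >= 1)
  max(1L, as.integer(floor((n / log(n))^(1 / (2 * p + 1)))))
}

#' Build an open-uniform B-spline basis
#'
#' Constructs `n_basis` B-spline basis functions of the given degree on the
#' interval, with endpoint knots repeated `degree + 1` times and
#' `n_basis - degree - 1` equally spaced interior knots.  The basis is
#' nonnegative, locally supported, and a partition of unity on the support.
#'
#' @param interval a [knot_interval()], or any list with numeric `lo < hi`.
#' @param degree polynomial degree `d >= 0`; default 2.
#' @param n_basis number of basis functions, `>= degree + 1`; default 5.
#' @return An object of class `"spline_basis"`: list with `degree`,
#'   `n_basis`, `knots` (full clamped knot vector), `lo`, `hi`.
#' @examples
#' b <- build_basis(list(lo = 0, hi = 1), degree = 2, n_basis = 5)
#' b$knots  # interior knots at 1/3, 2/3
#' @export
build_basis <- function(interval, degree = 2, n_basis = 5) {
  lo <- interval$lo; hi <- interval$hi
  stopifnot(is.finite(lo), is.finite(hi), lo < hi,
            degree >= 0, degree == round(degree),
            n_basis == round(n_basis))
  if (n_basis < degree + 1)
    stop("'n_basis' must be at least degree + 1")
  n_interior <- n_basis - degree - 1
  interior <- if (n_interior > 0)
    lo + (hi - lo) * seq_len(n_interior) / (n_interior + 1) else numeric(0)
  knots <- c(rep(lo, degree + 1), interior, rep(hi, degree + 1))
  structure(list(degree = as.integer(degree), n_basis = as.integer(n_basis),
                 knots = knots, lo = lo, hi = hi),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("B-spline basis: degree %d, %d functions on [%g, %g]\n",
              x$degree, x$n_basis, x$lo, x$hi))
  invisible(x)
}

#' Evaluate a B-spline basis
#'
#' Evaluates all basis functions at the given times via the Cox-de Boor
#' recursion ([splines::splineDesign()]).  Times outside the support are
#' clamped to the nearest endpoint first, so any linear combination is
#' continued as a constant outside `[lo, hi]`; this keeps risk-set sums
#' well defined at every event time and preserves the partition of unity.
#'
#' @param basis a [build_basis()] object.
#' @param t numeric vector of evaluation times.
#' @return numeric matrix, `length(t)` rows by `basis$n_basis` columns;
#'   rows are nonnegative and sum to 1.
#' @export
evaluate_basis <- function(basis, t) {
  stopifnot(inherits(basis, "spline_basis"))
  t <- pmin(pmax(as.numeric(t), basis$lo), basis$hi)
  m <- splines::splineDesign(basis$knots, t, ord = basis$degree + 1L,
                             outer.ok = FALSE)
  dimnames(m) <- NULL
  m
}
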