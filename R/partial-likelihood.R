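# Precomputed event structure for fast partial-likelihood evaluation.
#
# With a binary group label the risk-set sum collapses to
#   sum_{j in R(t)} exp(z_j b) = r0(t) + r1(t) * exp(b),
# where r0, r1 count at-risk subjects per group.  Everything that does not
# depend on the coefficients (at-risk counts, basis values at event times)
# is computed once here; each likelihood evaluation is then O(#events x
# n_basis) for the basis-coefficient product plus O(#events) vector work.
plk_precompute <- function(ds, basis = NULL) {
  d <- ds$data
  ev <- d$event == 1
  t_ev <- d$time[ev]
  z_ev <- as.integer(d$group[ev])
  t0 <- d$time[d$group == 0]
  t1 <- d$time[d$group == 1]
  r0 <- vapply(t_ev, function(t) sum(t0 >= t), numeric(1))
  r1 <- vapply(t_ev, function(t) sum(t1 >= t), numeric(1))
  B <- if (is.null(basis)) matrix(numeric(0), length(t_ev), 0L)
       else if (!length(t_ev)) matrix(numeric(0), 0L, basis$n_basis)
       else evaluate_basis(basis, t_ev)
  list(t_ev = t_ev, z_ev = z_ev, r0 = r0, r1 = r1, B = B,
       logp0 = -sum(log(r0 + r1)))
}

# log P1 given the linear predictor beta(t) at the event times.
plk_log_p1_beta <- function(pre, beta_ev) {
  if (!length(pre$t_ev)) return(0)
  # log(r0 + r1 e^b), max-subtracted so it is finite for |b| up to ~700+
  logden <- ifelse(beta_ev > 0,
                   beta_ev + log(pre$r1 + pre$r0 * exp(-beta_ev)),
                   log(pre$r0 + pre$r1 * exp(beta_ev)))
  sum(pre$z_ev * beta_ev - logden)
}

#' Null log partial likelihood
#'
#' Log of `P0 = prod over events of 1 / |R(X_i)|`, the Cox partial
#' likelihood under hazard equivalence (`beta == 0`), where `R(t)` is the
#' risk set at `t`.  With tied event times each tied event contributes the
#' shared risk set (Breslow convention).
#'
#' @param ds a [survival_dataset()].
#' @return finite numeric scalar (0 if there are no events).
#' @examples
#' ds <- survival_dataset(c(1, 2, 3), c(1, 1, 0), c(0, 1, 1))
#' log_p0(ds)  # log(1/6): risk sets of size 3 and 2
#' @export
log_p0 <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  plk_precompute(ds)$logp0
}

#' Log partial likelihood under the B-spline log hazard ratio
#'
#' Log of the Cox partial likelihood with time-varying coefficient
#' `beta(t) = sum_l gamma_l B_l(t)` for the binary group covariate:
#' the product over uncensored subjects of
#' `exp(z_i beta(X_i)) / sum_{j in R(X_i)} exp(z_j beta(X_i))`.
#' Computed in log space with max-subtraction inside every risk-set sum, so
#' the result is finite for any bounded coefficient vector.  With
#' `gamma = 0` this equals [log_p0()] exactly.
#'
#' @param ds a [survival_dataset()].
#' @param gamma numeric coefficient vector, length `basis$n_basis`.
#' @param basis a [build_basis()] object.
#' @return finite numeric scalar.
#' @export
log_p1 <- function(ds, gamma, basis) {
  stopifnot(inherits(ds, "survival_dataset"), inherits(basis, "spline_basis"))
  if (length(gamma) != basis$n_basis)
    stop("length(gamma) must equal the number of basis functions")
  pre <- plk_precompute(ds, basis)
  plk_log_p1_beta(pre, drop(pre$B %*% gamma))
}
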