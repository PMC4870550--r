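# Independent oracles, deliberately naive: direct textbook recursions and
# brute-force enumerations against which the package implementations are
# checked.

# Cox-de Boor recursion, one basis function at a time.
oracle_bspline <- function(knots, degree, l, t) {
  if (degree == 0) {
    # right-closed at the final interval so the basis covers [lo, hi]
    last <- max(which(knots < max(knots)))
    if (l == last && t == max(knots)) return(1)
    return(as.numeric(knots[l] <= t & t < knots[l + 1]))
  }
  d1 <- knots[l + degree] - knots[l]
  d2 <- knots[l + degree + 1] - knots[l + 1]
  a <- if (d1 > 0) (t - knots[l]) / d1 *
         oracle_bspline(knots, degree - 1, l, t) else 0
  b <- if (d2 > 0) (knots[l + degree + 1] - t) / d2 *
         oracle_bspline(knots, degree - 1, l + 1, t) else 0
  a + b
}

oracle_basis_row <- function(basis, t) {
  t <- min(max(t, basis$lo), basis$hi)
  vapply(seq_len(basis$n_basis),
         function(l) oracle_bspline(basis$knots, basis$degree, l, t),
         numeric(1))
}

# log partial likelihood by the naive double loop over events and risk sets
oracle_log_p1 <- function(ds, gamma, basis) {
  d <- ds$data
  beta_at <- function(t) drop(evaluate_basis(basis, t) %*% gamma)
  lp <- 0
  for (i in seq_len(nrow(d))) {
    if (d$event[i] != 1) next
    b <- beta_at(d$time[i])
    num <- d$group[i] * b
    den <- 0
    for (j in seq_len(nrow(d)))
      if (d$time[j] >= d$time[i]) den <- den + exp(d$group[j] * b)
    lp <- lp + num - log(den)
  }
  lp
}

# log-rank by explicit enumeration of the 2x2 table at each event time
oracle_log_rank <- function(ds, weightfun = function(t) 1) {
  d <- ds$data
  tj <- sort(unique(d$time[d$event == 1]))
  num <- 0; den <- 0
  for (t in tj) {
    n <- sum(d$time >= t); n1 <- sum(d$time >= t & d$group == 1)
    dd <- sum(d$time == t & d$event == 1)
    d1 <- sum(d$time == t & d$event == 1 & d$group == 1)
    w <- weightfun(t)
    num <- num + w * (d1 - dd * n1 / n)
    if (n > 1)
      den <- den + w^2 * dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1)
  }
  num^2 / den
}

# posterior inclusion probability for a single constant basis function by
# 1-D quadrature of the Bayes factor over the truncated-normal prior
oracle_post_eta_1d <- function(ds, basis, prior) {
  lp0 <- log_p0(ds)
  sd <- sqrt(prior$sigma2)
  integrand <- function(g) {
    lr <- vapply(g, function(gi) log_p1(ds, gi, basis) - lp0, numeric(1))
    exp(lr) * dnorm(g, 0, sd) / prior$c_L
  }
  bf <- integrate(integrand, -prior$L, prior$L, rel.tol = 1e-9)$value
  bf / (1 + bf)
}

# small random two-group dataset whose group-wise event ranges overlap,
# so a data-driven knot interval always exists
random_dataset <- function(n = 30, tau = 6) {
  repeat {
    tt <- pmin(round(rexp(n, 0.4), 6), tau)
    ev <- rbinom(n, 1, 0.7)
    gr <- rep(0:1, length.out = n)
    ds <- survival_dataset(tt, ev, gr, tau = tau)
    if (!any(ev == 1 & gr == 0) || !any(ev == 1 & gr == 1)) next
    if (!inherits(try(knot_interval(ds), silent = TRUE), "try-error"))
      return(ds)
  }
}
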