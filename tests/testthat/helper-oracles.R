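# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: plain arithmetic, bisection, and dense
# trapezoid integration.

two_center_fixture <- function() {
  read_tables_csv(system.file("extdata", "two_center_trial.csv",
                              package = "orhomog"))
}

# bisection root of psi = E(n2 - t + E) / [(n1 - E)(t - E)] on the
# admissible interval
bisect_expected_count <- function(n1, n2, t, psi, tol = 1e-12) {
  lo <- max(0, t - n2)
  hi <- min(n1, t)
  if (lo == hi) return(lo)
  f <- function(e) e * (n2 - t + e) - psi * (n1 - e) * (t - e)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# spreadsheet-style Breslow-Day statistic: every quantity written out
oracle_breslow_day <- function(d) {
  num <- den <- 0
  for (k in seq_len(nrow(d))) {
    num <- num + d$y1[k] * (d$n2[k] - d$y2[k]) / (d$n1[k] + d$n2[k])
    den <- den + (d$n1[k] - d$y1[k]) * d$y2[k] / (d$n1[k] + d$n2[k])
  }
  psi <- num / den
  stat <- 0
  for (k in seq_len(nrow(d))) {
    t_k <- d$y1[k] + d$y2[k]
    e <- bisect_expected_count(d$n1[k], d$n2[k], t_k, psi)
    v <- 1 / (1 / e + 1 / (d$n1[k] - e) + 1 / (t_k - e) +
                1 / (d$n2[k] - t_k + e))
    stat <- stat + (d$y1[k] - e)^2 / v
  }
  list(psi = psi, stat = stat)
}

# term-by-term DerSimonian-Laird Q with 0.5 added to all cells of
# zero-cell tables
oracle_dl_q <- function(d) {
  y <- w <- numeric(nrow(d))
  for (k in seq_len(nrow(d))) {
    cells <- c(d$y1[k], d$n1[k] - d$y1[k], d$y2[k], d$n2[k] - d$y2[k])
    if (any(cells == 0)) cells <- cells + 0.5
    y[k] <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
    w[k] <- 1 / sum(1 / cells)
  }
  ybar <- sum(w * y) / sum(w)
  sum(w * (y - ybar)^2)
}

# dense trapezoid integration of one center's marginal likelihood over the
# random effects; ranges are centered at the posterior mode and padded far
# into the tails, where the trapezoid rule is exponentially accurate
oracle_center_ll <- function(y1, n1, y2, n2, alpha, beta, sigma_u, sigma_b,
                             npts = 1201) {
  stopifnot(sigma_u > 0)
  logf <- function(a, b) {
    dbinom(y1, n1, plogis(alpha + beta + a + b), log = TRUE) +
      dbinom(y2, n2, plogis(alpha + a), log = TRUE) +
      dnorm(a, 0, sigma_u, log = TRUE) +
      if (sigma_b > 0) dnorm(b, 0, sigma_b, log = TRUE) else 0
  }
  opt <- optim(c(0, 0), function(p) -logf(p[1], p[2] * (sigma_b > 0)),
               method = "Nelder-Mead")
  mode_a <- opt$par[1]
  half_a <- 10 * sigma_u + abs(mode_a) + 2
  ag <- seq(mode_a - half_a, mode_a + half_a, length.out = npts)
  ha <- ag[2] - ag[1]
  if (sigma_b == 0) {
    la <- logf(ag, 0)
    mx <- max(la)
    return(mx + log(sum(exp(la - mx)) * ha))
  }
  mode_b <- opt$par[2]
  half_b <- 10 * sigma_b + abs(mode_b) + 2
  bg <- seq(mode_b - half_b, mode_b + half_b, length.out = npts)
  hb <- bg[2] - bg[1]
  M <- outer(ag, bg, logf)
  mx <- max(M)
  mx + log(sum(exp(M - mx)) * ha * hb)
}

oracle_marginal_ll <- function(d, alpha, beta, sigma_u, sigma_b,
                               npts = 1201) {
  sum(vapply(seq_len(nrow(d)), function(k)
    oracle_center_ll(d$y1[k], d$n1[k], d$y2[k], d$n2[k],
                     alpha, beta, sigma_u, sigma_b, npts), numeric(1)))
}
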