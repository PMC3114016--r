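#' Expected arm-1 successes under a common odds ratio
#'
#' Given the margins of a 2x2 table (arm sizes `n1`, `n2`, total successes
#' `t`) and a candidate common odds ratio `psi`, returns the expected count
#' E of arm-1 successes solving
#' \deqn{\psi = \frac{E (n_2 - t + E)}{(n_1 - E)(t - E)},}
#' i.e. the admissible root of the quadratic
#' \eqn{(\psi-1)E^2 - [(n_1+t)\psi + n_2 - t]E + \psi n_1 t = 0}
#' lying in \eqn{[\max(0, t-n_2), \min(n_1, t)]}. The root is unique in
#' that interval; for `psi = 1` the quadratic degenerates to the
#' independence value \eqn{n_1 t / (n_1+n_2)}. Closed-form roots are used,
#' with a bisection fallback should rounding push both outside the
#' interval.
#'
#' @param n1,n2 arm sizes (trials).
#' @param t total successes, `0 <= t <= n1 + n2`.
#' @param psi candidate common odds ratio, `> 0`.
#' @return Expected successes in arm 1 (a real number, not necessarily an
#'   integer).
#' @export
expected_count_given_or <- function(n1, n2, t, psi) {
  stopifnot(psi > 0, t >= 0, t <= n1 + n2, n1 >= 1, n2 >= 1)
  lo <- max(0, t - n2)
  hi <- min(n1, t)
  if (lo == hi) return(lo)
  if (psi == 1) return(n1 * t / (n1 + n2))
  A <- psi - 1
  B <- -((n1 + t) * psi + (n2 - t))
  C <- psi * n1 * t
  disc <- B^2 - 4 * A * C
  if (disc >= 0) {
    # numerically stable quadratic roots
    q <- -(B + sign(B) * sqrt(disc)) / 2
    roots <- c(q / A, if (q != 0) C / q else NA_real_)
    tol <- 1e-9 * max(1, hi)
    ok <- !is.na(roots) & roots >= lo - tol & roots <= hi + tol
    if (any(ok)) return(min(max(roots[ok][1], lo), hi))
  }
  # fallback: f is strictly increasing in E on (lo, hi)
  f <- function(e) e * (n2 - t + e) - psi * (n1 - e) * (t - e)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

new_or_homog_test <- function(method, statistic, df, p, data.name, details) {
  structure(
    list(statistic = c(statistic = statistic),
         parameter = df,
         p.value = p,
         method = method,
         data.name = data.name,
         details = details),
    class = c("or_homog_test", "htest"))
}

#' Breslow-Day test of homogeneity of odds ratios
#'
#' Compares observed arm-1 successes with their expected values under the
#' Mantel-Haenszel common odds ratio:
#' \deqn{BD = \sum_k \frac{(y_{1k} - E_k)^2}{V_k},}
#' where \eqn{E_k = E(y_{1k} \mid OR_{MH})} and
#' \eqn{V_k = [1/E_k + 1/(n_{1k}-E_k) + 1/(t_k-E_k) + 1/(n_{2k}-t_k+E_k)]^{-1}}.
#' Referred to an upper-tail chi-square with K - 1 degrees of freedom.
#' Operates on raw counts (no continuity correction). Tables with
#' \eqn{t_k = 0} or \eqn{t_k = n_k} carry no information about the odds
#' ratio; they contribute 0 to the statistic (df unchanged) and trigger a
#' warning.
#'
#' @param data an `mc_tables` object with K >= 2 centers.
#' @param tarone if `TRUE`, apply Tarone's adjustment (subtract
#'   \eqn{(\sum_k (y_{1k}-E_k))^2 / \sum_k V_k}); off by default.
#' @return An object of classes `or_homog_test` and `htest` with elements
#'   `statistic`, `parameter` (df), `p.value` and `details` (the MH odds
#'   ratio, per-center expected counts and variances).
#' @examples
#' d <- mc_tables(y1 = c(30, 45), n1 = c(100, 100),
#'                y2 = c(50, 75), n2 = c(100, 100))
#' breslow_day_test(d)
#' @export
breslow_day_test <- function(data, tarone = FALSE) {
  stopifnot(inherits(data, "mc_tables"))
  k <- nrow(data)
  if (k < 2) stop("need K >= 2 centers")
  or_mh <- mh_or(data)
  degen <- data$t == 0 | data$t == data$n
  if (any(degen))
    warning("center(s) ", paste(data$center[degen], collapse = ", "),
            " have all-success or all-failure outcomes and contribute no ",
            "information")
  e <- v <- numeric(k)
  for (i in seq_len(k)) {
    if (degen[i]) { e[i] <- data$y1[i]; v[i] <- NA_real_; next }
    e[i] <- expected_count_given_or(data$n1[i], data$n2[i], data$t[i], or_mh)
    v[i] <- 1 / (1 / e[i] + 1 / (data$n1[i] - e[i]) +
                 1 / (data$t[i] - e[i]) + 1 / (data$n2[i] - data$t[i] + e[i]))
  }
  terms <- ifelse(degen, 0, (data$y1 - e)^2 / v)
  stat <- sum(terms)
  if (tarone) stat <- stat - sum(data$y1 - e)^2 / sum(v[!degen])
  stat <- max(stat, 0)
  df <- c(df = k - 1)
  new_or_homog_test(
    method = if (tarone) "Breslow-Day test (Tarone adjusted)" else
      "Breslow-Day test of homogeneity of odds ratios",
    statistic = stat, df = df,
    p = stats::pchisq(stat, k - 1, lower.tail = FALSE),
    data.name = deparse(substitute(data)),
    details = list(or_mh = or_mh, expected = e, variance = v,
                   terms = terms, degenerate = degen))
}

#' DerSimonian-Laird Q test of homogeneity of odds ratios
#'
#' Inverse-variance weighted heterogeneity statistic on the log odds-ratio
#' scale:
#' \deqn{Q = \sum_k w_k (y_k - \bar y)^2, \quad
#'       y_k = \ln OR_k,\; w_k = 1/v_k,\;
#'       \bar y = \sum w_k y_k / \sum w_k,}
#' with \eqn{v_k} the sum of reciprocals of the four (continuity-adjusted)
#' cells. Referred to an upper-tail chi-square with K - 1 degrees of
#' freedom.
#'
#' @param data an `mc_tables` object with K >= 2 centers.
#' @param policy a [continuity_policy()] applied to zero-cell tables before
#'   the log odds ratios and variances are formed.
#' @return An `or_homog_test` / `htest` object; `details` carries the
#'   per-center log odds ratios, weights and the pooled mean.
#' @export
dl_q_test <- function(data, policy = continuity_policy()) {
  stopifnot(inherits(data, "mc_tables"))
  k <- nrow(data)
  if (k < 2) stop("need K >= 2 centers")
  or_k <- sample_or(data, policy)
  if (any(!is.finite(or_k) | or_k <= 0))
    stop("undefined log odds ratio in center ",
         paste(data$center[!is.finite(or_k) | or_k <= 0], collapse = ", "))
  y <- log(or_k)
  w <- 1 / log_or_variance(data, policy)
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  new_or_homog_test(
    method = "DerSimonian-Laird Q test of homogeneity of odds ratios",
    statistic = q, df = c(df = k - 1),
    p = stats::pchisq(q, k - 1, lower.tail = FALSE),
    data.name = deparse(substitute(data)),
    details = list(log_or = y, weights = w, pooled = ybar))
}

#' @export
print.or_homog_test <- function(x, ...) {
  NextMethod()
  if (!is.null(x$details$or_mh))
    cat("Mantel-Haenszel common OR:", format(x$details$or_mh), "\n")
  invisible(x)
}
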