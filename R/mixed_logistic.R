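#' Success probability under the logistic-normal model
#'
#' Inverse logit of the linear predictor
#' \eqn{\alpha + \beta x + a + b x}, where `a` is a center intercept draw
#' and `b` a center-by-treatment slope draw.
#'
#' @param alpha,beta fixed intercept and common treatment effect (logit
#'   scale).
#' @param x treatment indicator, 1 for arm 1, 0 for arm 2.
#' @param a,b random-effect draws (default 0).
#' @return Probability in (0, 1); vectorized over all arguments.
#' @export
success_probability <- function(alpha, beta, x, a = 0, b = 0) {
  stopifnot(all(x %in% c(0, 1)))
  stats::plogis(alpha + beta * x + a + b * x)
}

# log integrand for one center: sum over the two arms of the binomial
# log-pmf at the random-effect values (a, b); vectorized over a and b of
# equal length
center_loglik_integrand <- function(y1, n1, y2, n2, alpha, beta, a, b = 0) {
  stats::dbinom(y1, n1, stats::plogis(alpha + beta + a + b), log = TRUE) +
    stats::dbinom(y2, n2, stats::plogis(alpha + a), log = TRUE)
}

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Hermite rule cache: nodes z (for N(0,1): z = sqrt(2)*x) and
# log-weights logw = log(w) - log(pi)/2, so sum(exp(logw)) == 1
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(nquad) {
  key <- as.character(nquad)
  if (is.null(.gh_cache[[key]])) {
    gh <- pracma::gaussHermite(nquad)
    .gh_cache[[key]] <- list(z = sqrt(2) * gh$x, x = gh$x,
                             logw = log(gh$w) - 0.5 * log(pi))
  }
  .gh_cache[[key]]
}

#' Marginal log-likelihood of the mixed logistic model
#'
#' Integrates the binomial likelihood of each center over its normal random
#' effects by (tensor-product) Gauss-Hermite quadrature and sums the
#' per-center log integrals. The `"null"` variant has a random intercept
#' only (logit \eqn{= \alpha + \beta x + a_k},
#' \eqn{a_k \sim N(0, \sigma_u^2)}); the `"full"` variant adds an
#' independent random treatment slope (\eqn{+\, b_k x},
#' \eqn{b_k \sim N(0, \sigma_b^2)}). With both standard deviations zero the
#' quadrature is exact and the value equals the fixed-effects binomial
#' log-likelihood.
#'
#' @param data an `mc_tables` object.
#' @param alpha,beta fixed effects (logit scale).
#' @param sigma_u,sigma_b random-effect standard deviations, `>= 0`.
#' @param variant `"full"` or `"null"` (the latter ignores `sigma_b`).
#' @param nquad quadrature nodes per dimension (default 15).
#' @param adaptive if `TRUE`, recenter and rescale the nodes per center at
#'   the mode of the integrand (adaptive Gauss-Hermite); the default is the
#'   fixed prior-scaled rule, which is fully deterministic in the
#'   parameters.
#' @return The marginal log-likelihood (a single number).
#' @export
marginal_loglik <- function(data, alpha, beta, sigma_u, sigma_b = 0,
                            variant = c("full", "null"), nquad = 15,
                            adaptive = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "mc_tables"), nquad >= 5,
            sigma_u >= 0, sigma_b >= 0)
  rule <- gh_rule(nquad)
  lls <- if (adaptive) {
    vapply(seq_len(nrow(data)), function(i) {
      if (variant == "null")
        center_ll_1d(data$y1[i], data$n1[i], data$y2[i], data$n2[i],
                     alpha, beta, sigma_u, rule, adaptive = TRUE)
      else
        center_ll_2d(data$y1[i], data$n1[i], data$y2[i], data$n2[i],
                     alpha, beta, sigma_u, sigma_b, rule, adaptive = TRUE)
    }, numeric(1))
  } else if (variant == "null") {
    all_centers_ll_1d(data, alpha, beta, sigma_u, rule)
  } else {
    all_centers_ll_2d(data, alpha, beta, sigma_u, sigma_b, rule)
  }
  if (any(!is.finite(lls)))
    stop("non-finite likelihood contribution for center ",
         paste(data$center[!is.finite(lls)], collapse = ", "),
         " at alpha=", alpha, ", beta=", beta)
  sum(lls)
}

# vectorized over centers: quadrature nodes are shared, so the binomial
# log-pmfs for all centers come from two dbinom calls
all_centers_ll_1d <- function(data, alpha, beta, sigma_u, rule) {
  m <- length(rule$z)
  K <- nrow(data)
  a <- sigma_u * rule$z
  p1 <- stats::plogis(alpha + beta + a)
  p2 <- stats::plogis(alpha + a)
  lb <- matrix(
    stats::dbinom(rep(data$y1, each = m), rep(data$n1, each = m), p1,
                  log = TRUE) +
      stats::dbinom(rep(data$y2, each = m), rep(data$n2, each = m), p2,
                    log = TRUE),
    m, K) + rule$logw
  apply(lb, 2, lse)
}

all_centers_ll_2d <- function(data, alpha, beta, sigma_u, sigma_b, rule) {
  m <- length(rule$z)
  K <- nrow(data)
  a <- sigma_u * rule$z
  b <- sigma_b * rule$z
  p2 <- stats::plogis(alpha + a)
  lb2 <- matrix(
    stats::dbinom(rep(data$y2, each = m), rep(data$n2, each = m), p2,
                  log = TRUE),
    m, K)
  # (a_j, b_l) grid, column-major with j fastest — matches outer()
  p1 <- stats::plogis(alpha + beta + as.vector(outer(a, b, `+`)))
  lb1 <- matrix(
    stats::dbinom(rep(data$y1, each = m * m), rep(data$n1, each = m * m),
                  p1, log = TRUE),
    m * m, K)
  wj <- rule$logw
  wl <- rep(wj, each = m)
  vapply(seq_len(K), function(k)
    lse(lb1[, k] + rep(lb2[, k] + wj, times = m) + wl), numeric(1))
}

center_ll_1d <- function(y1, n1, y2, n2, alpha, beta, sigma_u, rule,
                         adaptive) {
  if (adaptive && sigma_u > 0) {
    h <- function(a) -(center_loglik_integrand(y1, n1, y2, n2, alpha, beta,
                                               a) +
                         stats::dnorm(a, 0, sigma_u, log = TRUE))
    opt <- stats::nlminb(0, h)
    mu <- opt$par
    eps <- 1e-4 * max(1, abs(mu))
    hess <- (h(mu + eps) - 2 * h(mu) + h(mu - eps)) / eps^2
    tau <- if (is.finite(hess) && hess > 0) 1 / sqrt(hess) else sigma_u
    a <- mu + sqrt(2) * tau * rule$x
    logf <- center_loglik_integrand(y1, n1, y2, n2, alpha, beta, a) +
      stats::dnorm(a, 0, sigma_u, log = TRUE)
    return(lse(rule$logw + 0.5 * log(pi) + rule$x^2 + logf) +
             0.5 * log(2) + log(tau))
  }
  a <- sigma_u * rule$z
  lse(rule$logw + center_loglik_integrand(y1, n1, y2, n2, alpha, beta, a))
}

center_ll_2d <- function(y1, n1, y2, n2, alpha, beta, sigma_u, sigma_b,
                         rule, adaptive) {
  if (adaptive && sigma_b == 0)
    return(center_ll_1d(y1, n1, y2, n2, alpha, beta, sigma_u, rule,
                        adaptive))
  if (adaptive && sigma_u > 0) {
    # recenter at the joint posterior mode and rotate by the Cholesky
    # factor of the inverse Hessian: arm 1 depends on a + b, so the
    # posterior is strongly correlated and axis-aligned rescaling alone
    # is not enough
    h <- function(p) -(center_loglik_integrand(y1, n1, y2, n2, alpha, beta,
                                               p[1], p[2]) +
                         stats::dnorm(p[1], 0, sigma_u, log = TRUE) +
                         stats::dnorm(p[2], 0, sigma_b, log = TRUE))
    opt <- stats::nlminb(c(0, 0), h)
    mu <- opt$par
    H <- matrix(NA_real_, 2, 2)
    eps <- 1e-4 * pmax(1, abs(mu))
    for (d1 in 1:2) for (d2 in d1:2) {
      e1 <- c(0, 0); e1[d1] <- eps[d1]
      e2 <- c(0, 0); e2[d2] <- eps[d2]
      H[d1, d2] <- H[d2, d1] <-
        (h(mu + e1 + e2) - h(mu + e1 - e2) -
           h(mu - e1 + e2) + h(mu - e1 - e2)) / (4 * eps[d1] * eps[d2])
    }
    L <- tryCatch(t(chol(solve(H))), error = function(e) NULL)
    if (is.null(L)) L <- diag(c(sigma_u, sigma_b))
    grid <- as.matrix(expand.grid(rule$x, rule$x))
    pts <- sweep(grid %*% (sqrt(2) * t(L)), 2, mu, `+`)
    logf <- center_loglik_integrand(y1, n1, y2, n2, alpha, beta,
                                    pts[, 1], pts[, 2]) +
      stats::dnorm(pts[, 1], 0, sigma_u, log = TRUE) +
      stats::dnorm(pts[, 2], 0, sigma_b, log = TRUE)
    m <- length(rule$x)
    lw <- rep(rule$logw, times = m) + rep(rule$logw, each = m) + log(pi)
    return(lse(lw + rowSums(grid^2) + logf) +
             log(2) + sum(log(diag(L))))
  }
  a <- sigma_u * rule$z
  b <- sigma_b * rule$z
  # b enters arm 1 only; arm 2 depends on a alone
  lp2 <- stats::dbinom(y2, n2, stats::plogis(alpha + a), log = TRUE) +
    rule$logw
  lp1 <- outer(a, b, function(ai, bi)
    stats::dbinom(y1, n1, stats::plogis(alpha + beta + ai + bi), log = TRUE))
  lse(sweep(lp1 + lp2, 2, rule$logw, `+`))
}

# deterministic start-point table: conventional base values first, then
# a data-driven start, then fixed jitters; no RNG so fits never touch the
# simulation stream
start_points <- function(data, variant, start) {
  or0 <- tryCatch(mh_or(data), error = function(e) 1)
  p2 <- sum(data$y2) / sum(data$n2)
  alpha0 <- stats::qlogis(min(max(p2, 0.02), 0.98))
  base <- c(alpha = -1, beta = 1, sigma_u = 0.2, sigma_b = 0.8)
  emp <- c(alpha = alpha0, beta = log(max(or0, 1e-3)),
           sigma_u = 0.3, sigma_b = 0.3)
  jit <- base + c(0.5, -0.5, 0.3, -0.4)
  pts <- list(base, emp, jit)
  if (!is.null(start)) {
    s <- c(alpha = start[["alpha"]], beta = start[["beta"]],
           sigma_u = start[["sigma_u"]],
           sigma_b = if ("sigma_b" %in% names(start)) start[["sigma_b"]]
           else 0.8)
    pts <- c(list(s), pts)
  }
  if (variant == "null") pts <- lapply(pts, function(p) p[1:3])
  pts
}

#' Fit the mixed logistic model by marginal maximum likelihood
#'
#' Maximizes [marginal_loglik()] over \eqn{(\alpha, \beta, \sigma_u)}
#' (`variant = "null"`) or \eqn{(\alpha, \beta, \sigma_u, \sigma_b)}
#' (`variant = "full"`) with the standard deviations box-constrained to
#' `[0, 20]`, so boundary solutions \eqn{\hat\sigma = 0} are attainable and
#' reported as converged. Several deterministic starting points are tried
#' (the conventional defaults \eqn{\alpha=-1, \beta=1, \sigma_u=0.2,
#' \sigma_b=0.8}, a data-driven start from the Mantel-Haenszel odds ratio,
#' and a fixed jitter) and the best log-likelihood is kept.
#'
#' @inheritParams marginal_loglik
#' @param start optional named numeric vector of starting values
#'   (`alpha`, `beta`, `sigma_u`, optionally `sigma_b`), tried first.
#' @param restarts number of starting points to try (default 3).
#' @param control passed to [stats::nlminb()]; defaults set
#'   `rel.tol = 1e-10` and `iter.max = 500`.
#' @return A `mixed_logistic_fit` object: fixed effects, standard
#'   deviations, maximized `loglik`, `converged` flag, and an optimizer
#'   trace (one row per start).
#' @export
fit_mixed_logistic <- function(data, variant = c("full", "null"),
                               start = NULL, nquad = 15, restarts = 3,
                               adaptive = FALSE, control = list()) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "mc_tables"))
  if (nrow(data) < 2) stop("need K >= 2 centers")
  npar <- if (variant == "null") 3L else 4L
  ctl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 500,
                                eval.max = 1000), control)
  lower <- c(-Inf, -Inf, 0, 0)[seq_len(npar)]
  upper <- c(Inf, Inf, 20, 20)[seq_len(npar)]
  nll <- function(theta) {
    v <- tryCatch(
      -marginal_loglik(data, theta[1], theta[2], theta[3],
                       if (npar == 4L) theta[4] else 0,
                       variant = variant, nquad = nquad,
                       adaptive = adaptive),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  pts <- utils::head(start_points(data, variant, start), max(1, restarts))
  best <- NULL
  trace <- vector("list", length(pts))
  for (j in seq_along(pts)) {
    fit <- stats::nlminb(pts[[j]], nll, lower = lower, upper = upper,
                         control = ctl)
    trace[[j]] <- data.frame(start = j, objective = fit$objective,
                             convergence = fit$convergence,
                             iterations = fit$iterations)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  est <- best$par
  structure(list(
    variant = variant,
    coefficients = c(alpha = unname(est[1]), beta = unname(est[2])),
    sigma_u = unname(est[3]),
    sigma_b = if (npar == 4L) unname(est[4]) else 0,
    loglik = -best$objective,
    converged = best$convergence == 0 && best$objective < 1e9,
    nquad = nquad, adaptive = adaptive,
    trace = do.call(rbind, trace)),
    class = "mixed_logistic_fit")
}

#' @export
print.mixed_logistic_fit <- function(x, ...) {
  cat("Mixed logistic model (", x$variant, " variant), ",
      "Gauss-Hermite nquad = ", x$nquad, "\n", sep = "")
  cat(sprintf("  alpha = %.4f  beta = %.4f  sigma_u = %.4f",
              x$coefficients[1], x$coefficients[2], x$sigma_u))
  if (x$variant == "full") cat(sprintf("  sigma_b = %.4f", x$sigma_b))
  cat(sprintf("\n  logLik = %.4f  converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
logLik.mixed_logistic_fit <- function(object, ...) {
  structure(object$loglik,
            df = if (object$variant == "null") 3L else 4L,
            class = "logLik")
}

#' p-value from the 50:50 chi-square mixture null
#'
#' A likelihood-ratio statistic for a variance component tested on the
#' boundary of its parameter space has asymptotic null distribution
#' \eqn{0.5\,\chi^2_0 + 0.5\,\chi^2_1}; the upper-tail p-value is
#' \eqn{0.5\,P(\chi^2_1 > \Delta)}. Small negative statistics (numerical
#' rounding) are clipped to zero.
#'
#' @param delta the likelihood-ratio statistic \eqn{\Delta = -2(l_0-l_1)}.
#' @return p-value in (0, 0.5].
#' @export
mixture_pvalue <- function(delta) {
  0.5 * stats::pchisq(pmax(delta, 0), df = 1, lower.tail = FALSE)
}

#' Likelihood-ratio test of homogeneity of odds ratios
#'
#' Fits the random-intercept (`null`) and random-intercept-plus-slope
#' (`full`) logistic-normal models by marginal maximum likelihood and forms
#' \eqn{\Delta = -2(l_0 - l_1)}, referred to the 50:50 mixture of
#' \eqn{\chi^2_0} and \eqn{\chi^2_1} ([mixture_pvalue()]). Because the
#' models are nested at \eqn{\sigma_b = 0}, the full fit is seeded with the
#' null solution in addition to the default starts, and \eqn{\Delta} is
#' clipped at zero (tolerance 1e-6; larger negative values indicate a
#' failed full-model maximization and flag the result as non-converged).
#'
#' @inheritParams fit_mixed_logistic
#' @param restarts starting points per model fit (default 2; see
#'   [fit_mixed_logistic()]).
#' @return An `or_homog_test` / `htest` object; `details` carries both
#'   fits, the raw (unclipped) statistic and convergence flags.
#' @export
lr_homogeneity_test <- function(data, nquad = 15, restarts = 2,
                                adaptive = FALSE) {
  stopifnot(inherits(data, "mc_tables"))
  dname <- deparse(substitute(data))
  fit0 <- fit_mixed_logistic(data, "null", nquad = nquad,
                             restarts = restarts, adaptive = adaptive)
  s0 <- c(alpha = unname(fit0$coefficients[1]),
          beta = unname(fit0$coefficients[2]),
          sigma_u = fit0$sigma_u, sigma_b = 0.5)
  fit1 <- fit_mixed_logistic(data, "full", start = s0, nquad = nquad,
                             restarts = restarts, adaptive = adaptive)
  # guard against a null fit stuck in a local optimum: the full model at
  # its own solution (with sigma_b dropped) is a valid null start, so the
  # null loglik must be at least as good whenever sigma_b sits near 0
  if (fit1$loglik > fit0$loglik + 1e-8) {
    s1 <- c(alpha = unname(fit1$coefficients[1]),
            beta = unname(fit1$coefficients[2]), sigma_u = fit1$sigma_u)
    fit0b <- fit_mixed_logistic(data, "null", start = s1, nquad = nquad,
                                restarts = 1, adaptive = adaptive)
    if (fit0b$loglik > fit0$loglik) fit0 <- fit0b
  }
  delta_raw <- -2 * (fit0$loglik - fit1$loglik)
  converged <- fit0$converged && fit1$converged
  if (delta_raw < -1e-6) converged <- FALSE
  delta <- max(delta_raw, 0)
  if (delta < 1e-8) delta <- 0  # below optimizer resolution

  out <- new_or_homog_test(
    method = paste("Mixed logistic likelihood-ratio test of homogeneity",
                   "of odds ratios (null: 0.5*chi2_0 + 0.5*chi2_1)"),
    statistic = delta, df = c(`mixture df` = NA_real_),
    p = mixture_pvalue(delta),
    data.name = dname,
    details = list(fit_null = fit0, fit_full = fit1,
                   delta_raw = delta_raw, df = "mixture(0,1)",
                   converged = converged))
  out
}
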