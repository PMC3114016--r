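#' Multicenter sample-size design configurations
#'
#' Reproduces the balanced and unbalanced per-arm sample-size layouts used
#' in the power study. With base per-arm size \eqn{m \in \{20, 50, 100\}}
#' (levels 1-3):
#' \itemize{
#'   \item `equal`: every center gets \eqn{(m, m)}.
#'   \item `within`: the same per-center total split 3:1 between the arms,
#'     arm 1 (treated) small: \eqn{(m/2, 3m/2)}, identical across centers.
#'   \item `among`: balanced arms, \eqn{K - 1} small centers at
#'     \eqn{(m/2, m/2)} and one large center at
#'     \eqn{(m(K+1)/2, m(K+1)/2)} absorbing the remainder.
#' }
#' Every unbalanced layout has the same total sample size as the matching
#' `equal` one.
#'
#' @param K number of centers, one of 4, 6, 8.
#' @param design `"equal"`, `"within"` or `"among"`.
#' @param level size level 1, 2 or 3 (base per-arm sizes 20, 50, 100).
#' @return A data frame with K rows and columns `n1`, `n2`, with
#'   attributes `K`, `design`, `level`, `n_tot`.
#' @examples
#' design_config(4, "equal", 1)   # 4 x (20, 20), total 160
#' design_config(6, "among", 2)   # 5 x (25, 25) + (175, 175)
#' @export
design_config <- function(K, design = c("equal", "within", "among"),
                          level = 1) {
  design <- match.arg(design)
  if (!K %in% c(4, 6, 8)) stop("K must be 4, 6 or 8")
  if (!level %in% 1:3) stop("level must be 1, 2 or 3")
  m <- c(20L, 50L, 100L)[level]
  cfg <- switch(design,
    equal  = data.frame(n1 = rep(m, K), n2 = rep(m, K)),
    within = data.frame(n1 = rep(m %/% 2L, K),
                        n2 = rep((3L * m) %/% 2L, K)),
    among  = {
      small <- m %/% 2L
      big <- (m * (K + 1L)) %/% 2L
      data.frame(n1 = c(rep(small, K - 1), big),
                 n2 = c(rep(small, K - 1), big))
    })
  structure(cfg, K = K, design = design, level = level,
            n_tot = sum(cfg$n1 + cfg$n2))
}

#' Simulation scenario specification
#'
#' Bundles a design configuration with the logistic-normal generating
#' parameters, the replication count and the RNG seed for one Monte-Carlo
#' scenario.
#'
#' @param K,design,level passed to [design_config()]; alternatively supply
#'   `config` directly.
#' @param sigma_u2 center-effect variance \eqn{\sigma_u^2 \ge 0}.
#' @param sigma_b2 center-by-treatment interaction variance
#'   \eqn{\sigma_b^2 \ge 0}; homogeneity of odds ratios holds iff it is 0.
#' @param alpha,beta fixed effects (defaults -1 and 1, the study values).
#' @param generator `"per-arm"` draws independent interaction effects
#'   \eqn{b_{1k}, b_{2k}} for the two arms (true per-center log odds ratio
#'   \eqn{\beta + b_{1k} - b_{2k}}, heterogeneity variance
#'   \eqn{2\sigma_b^2}); `"slope"` draws a single \eqn{b_k} entering arm 1
#'   only (heterogeneity variance \eqn{\sigma_b^2}), matching the fitted
#'   model.
#' @param reps Monte-Carlo replications.
#' @param seed base RNG seed for the scenario.
#' @param config optional [design_config()] output overriding
#'   `K`/`design`/`level`.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(K = 4, design = "equal", level = 1,
                          sigma_u2 = 0.1, sigma_b2 = 0,
                          alpha = -1, beta = 1,
                          generator = c("per-arm", "slope"),
                          reps = 1000, seed = 1, config = NULL) {
  generator <- match.arg(generator)
  if (is.null(config)) config <- design_config(K, design, level)
  stopifnot(sigma_u2 >= 0, sigma_b2 >= 0, reps >= 1)
  structure(list(config = config,
                 K = attr(config, "K"), design = attr(config, "design"),
                 level = attr(config, "level"),
                 sigma_u2 = sigma_u2, sigma_b2 = sigma_b2,
                 alpha = alpha, beta = beta,
                 generator = generator, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario: K=%d %s design level %d (n_tot=%d), sigma_u2=%g, sigma_b2=%g\n",
    x$K, x$design, x$level, attr(x$config, "n_tot"), x$sigma_u2, x$sigma_b2))
  cat(sprintf("  alpha=%g beta=%g, %s generator, reps=%d, seed=%d\n",
              x$alpha, x$beta, x$generator, x$reps, x$seed))
  invisible(x)
}

#' Simulate one multicenter dataset from the logistic-normal model
#'
#' Per center \eqn{k}: draw \eqn{u_k \sim N(0, \sigma_u^2)}; then, under
#' the `per-arm` generator, \eqn{b_{1k}, b_{2k} \sim N(0, \sigma_b^2)}
#' independently and logit \eqn{\pi_{ik} = \alpha + \beta x_{ik} + u_k +
#' b_{ik}}; under the `slope` generator a single \eqn{b_k} enters arm 1
#' only. Finally \eqn{y_{ik} \sim Binomial(n_{ik}, \pi_{ik})}. Draw order
#' is fixed (centers in order; u before b; arm 1 before arm 2) so output is
#' byte-identical given the seed.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional seed set before drawing; if `NULL` the current RNG
#'   state is used (the study engine manages per-replicate seeds itself).
#' @return An `mc_tables` dataset with attribute `truth`: the per-center
#'   random effects and true odds ratios.
#' @export
simulate_tables <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- spec$config
  su <- sqrt(spec$sigma_u2)
  sb <- sqrt(spec$sigma_b2)
  K <- spec$K
  y1 <- y2 <- integer(K)
  b1 <- b2 <- u <- numeric(K)
  for (k in seq_len(K)) {
    u[k] <- stats::rnorm(1, 0, su)
    if (spec$generator == "per-arm") {
      b1[k] <- stats::rnorm(1, 0, sb)
      b2[k] <- stats::rnorm(1, 0, sb)
    } else {
      b1[k] <- stats::rnorm(1, 0, sb)
      b2[k] <- 0
    }
    p1 <- stats::plogis(spec$alpha + spec$beta + u[k] + b1[k])
    p2 <- stats::plogis(spec$alpha + u[k] + b2[k])
    y1[k] <- stats::rbinom(1, cfg$n1[k], p1)
    y2[k] <- stats::rbinom(1, cfg$n2[k], p2)
  }
  out <- mc_tables(y1, cfg$n1, y2, cfg$n2)
  attr(out, "truth") <- data.frame(
    center = seq_len(K), u = u, b1 = b1, b2 = b2,
    true_or = true_center_or(spec$beta, b1, b2))
  out
}

#' True per-center odds ratio under the logistic-normal model
#'
#' \eqn{\exp(\beta + b_1 - b_2)}: the center's odds ratio depends only on
#' the treatment effect and the two interaction draws, never on the
#' intercept or the center effect.
#'
#' @param beta common treatment effect.
#' @param b1,b2 interaction effects for arms 1 and 2 (for the slope
#'   generator pass the slope as `b1` and `b2 = 0`).
#' @return Positive odds ratio(s); vectorized.
#' @export
true_center_or <- function(beta, b1, b2 = 0) exp(beta + b1 - b2)
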