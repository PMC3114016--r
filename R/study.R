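# Monte-Carlo engine: rejection rates of the three homogeneity tests over
# grids of designs and variance components.

# deterministic per-replicate / per-cell sub-seeds below 2^31
derive_seed <- function(base, index, stride = 77003L) {
  s <- (as.double(base) + as.double(stride) * as.double(index)) %%
    2147483629
  as.integer(max(s, 1))
}

#' Run one Monte-Carlo scenario
#'
#' Simulates `spec$reps` datasets and records, for each requested test, the
#' proportion of replicates with p-value below `alpha_level` (strict `<`).
#' Each replicate gets its own seed derived from `spec$seed` and the
#' replicate index, so results do not depend on execution order. A
#' non-converged LR fit is retried once with two extra starting points;
#' replicates still failing are dropped from that test's numerator and
#' denominator (the count is reported).
#'
#' @param spec a [scenario_spec()].
#' @param tests subset of `c("bd", "dl", "lr")`.
#' @param alpha_level nominal significance level (default 0.05).
#' @param nquad,restarts passed to [lr_homogeneity_test()].
#' @param drop_policy `"drop"` excludes non-converged LR replicates from
#'   the denominator; `"nonreject"` counts them as non-rejections.
#' @return A long-format data frame, one row per test: the scenario axes
#'   plus `test`, `n_used`, `rejections`, `power` (rejection proportion),
#'   `mc_se` (binomial standard error) and `dropped`.
#' @export
run_scenario <- function(spec, tests = c("bd", "dl", "lr"),
                         alpha_level = 0.05, nquad = 15, restarts = 2,
                         drop_policy = c("drop", "nonreject")) {
  stopifnot(inherits(spec, "scenario_spec"))
  tests <- match.arg(tests, c("bd", "dl", "lr"), several.ok = TRUE)
  drop_policy <- match.arg(drop_policy)
  rej <- sapply(tests, function(t) integer(0), simplify = FALSE)
  pvals <- matrix(NA_real_, spec$reps, length(tests),
                  dimnames = list(NULL, tests))
  dropped <- stats::setNames(integer(length(tests)), tests)
  for (i in seq_len(spec$reps)) {
    d <- simulate_tables(spec, seed = derive_seed(spec$seed, i))
    for (t in tests) {
      p <- switch(t,
        bd = suppressWarnings(breslow_day_test(d)$p.value),
        dl = tryCatch(dl_q_test(d)$p.value, error = function(e) NA_real_),
        lr = {
          r <- lr_homogeneity_test(d, nquad = nquad, restarts = restarts)
          if (!r$details$converged) {
            r <- lr_homogeneity_test(d, nquad = nquad,
                                     restarts = restarts + 2)
          }
          if (!r$details$converged && drop_policy == "drop") NA_real_
          else r$p.value
        })
      pvals[i, t] <- p
    }
  }
  rows <- lapply(tests, function(t) {
    p <- pvals[, t]
    used <- sum(!is.na(p))
    rj <- sum(p < alpha_level, na.rm = TRUE)
    prop <- if (used > 0) rj / used else NA_real_
    data.frame(K = spec$K, design = spec$design, level = spec$level,
               sigma_u2 = spec$sigma_u2, sigma_b2 = spec$sigma_b2,
               alpha = spec$alpha, beta = spec$beta,
               generator = spec$generator, reps = spec$reps,
               seed = spec$seed, test = t, n_used = used,
               rejections = rj, power = prop,
               mc_se = if (used > 0) sqrt(prop * (1 - prop) / used)
                       else NA_real_,
               dropped = spec$reps - used)
  })
  out <- do.call(rbind, rows)
  lr_drop <- out$dropped[out$test == "lr"]
  if (length(lr_drop) && lr_drop > 0.2 * spec$reps)
    warning("more than 20% of LR replicates dropped; scenario unreliable")
  out
}

#' Study grid configuration
#'
#' Cartesian grid of scenario axes for [run_grid()]. Every cell maps to one
#' [scenario_spec()] with a sub-seed derived from `seed` and the cell
#' index.
#'
#' @param K,designs,levels,sigma_u2,sigma_b2 vectors of axis values.
#' @param alpha,beta fixed effects.
#' @param generator `"per-arm"` or `"slope"`.
#' @param reps replications per cell.
#' @param seed base seed.
#' @param tests tests to run per cell.
#' @param alpha_level nominal level.
#' @return A `study_config` list with the expanded `cells` data frame.
#' @export
study_config <- function(K = c(4, 6, 8),
                         designs = c("equal", "within", "among"),
                         levels = 1:3,
                         sigma_u2 = c(0.1, 0.5),
                         sigma_b2 = c(0, 0.2, 0.4, 0.6, 0.8),
                         alpha = -1, beta = 1, generator = "per-arm",
                         reps = 200, seed = 1,
                         tests = c("bd", "dl", "lr"), alpha_level = 0.05) {
  cells <- expand.grid(K = K, design = designs, level = levels,
                       sigma_u2 = sigma_u2, sigma_b2 = sigma_b2,
                       stringsAsFactors = FALSE)
  structure(list(cells = cells, alpha = alpha, beta = beta,
                 generator = generator, reps = as.integer(reps),
                 seed = as.integer(seed), tests = tests,
                 alpha_level = alpha_level),
            class = "study_config")
}

cell_key <- function(row, cfg) {
  paste0("K", row$K, "_", row$design, "_L", row$level,
         "_su", row$sigma_u2, "_sb", row$sigma_b2,
         "_r", cfg$reps, "_s", cfg$seed, "_", cfg$generator)
}

#' Run a Monte-Carlo study grid
#'
#' Executes [run_scenario()] for every cell of a [study_config()] grid and
#' stacks the long-format results. Cells are independent work units with
#' per-cell sub-seeds, so the output is identical regardless of execution
#' order. With `cache_dir` set, finished cells are cached on disk (keyed by
#' the cell's axes, reps, seed and generator) and reused on re-runs;
#' failures in one cell are logged and the grid continues.
#'
#' @param config a [study_config()].
#' @param cache_dir optional directory for per-cell result caching.
#' @param verbose print one line per cell.
#' @return A tidy data frame, one row per (cell, test).
#' @export
run_grid <- function(config, cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  cells <- config$cells
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    key <- cell_key(row, config)
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(key, ".rds")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      out[[i]] <- readRDS(cache_file)
      next
    }
    spec <- scenario_spec(K = row$K, design = row$design, level = row$level,
                          sigma_u2 = row$sigma_u2, sigma_b2 = row$sigma_b2,
                          alpha = config$alpha, beta = config$beta,
                          generator = config$generator, reps = config$reps,
                          seed = derive_seed(config$seed, i,
                                             stride = 1000003L))
    res <- tryCatch(
      run_scenario(spec, tests = config$tests,
                   alpha_level = config$alpha_level),
      error = function(e) {
        warning("cell ", key, " failed: ", conditionMessage(e))
        NULL
      })
    if (verbose && !is.null(res))
      message(sprintf("[%d/%d] %s: %s", i, nrow(cells), key,
                      paste(sprintf("%s=%.3f", res$test, res$power),
                            collapse = " ")))
    if (!is.null(cache_file) && !is.null(res)) saveRDS(res, cache_file)
    out[[i]] <- res
  }
  do.call(rbind, out)
}

#' Average power reduction from unequal allocation
#'
#' For a given test, number of centers and center-heterogeneity variance,
#' pairs the equal-design power with the comparison design's power at each
#' of the 12 (interaction variance in {0.2, 0.4, 0.6, 0.8}) x (size level
#' 1-3) cells and averages the paired differences — in percentage points,
#' \eqn{\mathrm{mean}\,100 (\hat\pi_{equal} - \hat\pi_{comparison})}, or,
#' with `relative = TRUE`, as the relative percent loss
#' \eqn{\mathrm{mean}\,100 (\hat\pi_{equal} -
#' \hat\pi_{comparison})/\hat\pi_{equal}}, the form in which such
#' reductions are usually quoted.
#'
#' @param results a tidy grid from [run_grid()] (or rows bound from
#'   [run_scenario()]).
#' @param test one of `"bd"`, `"dl"`, `"lr"`.
#' @param K number of centers to summarize.
#' @param comparison `"within"` or `"among"`.
#' @param sigma_u2 center-heterogeneity variance of the cells to use.
#' @param sigma_b2 heterogeneity values averaged over (default the four
#'   nonzero study values).
#' @param levels size levels averaged over (default 1:3).
#' @param relative if `TRUE`, average the relative percent reductions
#'   instead of percentage-point differences.
#' @return A `reduction_summary` list: `value` (the mean reduction), the
#'   per-cell table with both the percentage-point and relative
#'   differences, and the axes used. Missing cells raise an error naming
#'   them.
#' @export
power_reduction_summary <- function(results, test, K,
                                    comparison = c("within", "among"),
                                    sigma_u2 = 0.1,
                                    sigma_b2 = c(0.2, 0.4, 0.6, 0.8),
                                    levels = 1:3, relative = FALSE) {
  comparison <- match.arg(comparison)
  sel <- results$test == test & results$K == K &
    results$sigma_u2 == sigma_u2 & results$sigma_b2 %in% sigma_b2 &
    results$level %in% levels
  base <- results[sel & results$design == "equal", ]
  comp <- results[sel & results$design == comparison, ]
  grid <- expand.grid(level = levels, sigma_b2 = sigma_b2)
  key <- function(d) paste(d$level, d$sigma_b2)
  miss <- setdiff(key(grid), intersect(key(base), key(comp)))
  if (length(miss))
    stop("missing cells (level sigma_b2): ", paste(miss, collapse = "; "))
  comp <- comp[match(key(base), key(comp)), ]
  cells <- data.frame(level = base$level, sigma_b2 = base$sigma_b2,
                      power_equal = base$power,
                      power_comparison = comp$power,
                      diff_pp = 100 * (base$power - comp$power),
                      diff_rel = 100 * (base$power - comp$power) /
                        base$power)
  structure(list(test = test, K = K, comparison = comparison,
                 sigma_u2 = sigma_u2, relative = relative,
                 value = mean(if (relative) cells$diff_rel else
                   cells$diff_pp),
                 cells = cells),
            class = "reduction_summary")
}

#' @export
print.reduction_summary <- function(x, ...) {
  cat(sprintf(
    "Average power reduction, %s test, K=%d, equal vs %s, sigma_u2=%g:\n",
    toupper(x$test), x$K, x$comparison, x$sigma_u2))
  cat(sprintf("  %.2f %s over %d paired cells\n", x$value,
              if (isTRUE(x$relative)) "percent (relative)" else
                "percentage points", nrow(x$cells)))
  invisible(x)
}

#' Check the BD >= DL >= LR power ordering
#'
#' For every grid cell holding all three tests, checks
#' power(BD) >= power(DL) >= power(LR) within `tol_se` paired Monte-Carlo
#' standard errors, and compares the cell-averaged powers.
#'
#' @param results a tidy grid from [run_grid()] containing `"bd"`, `"dl"`
#'   and `"lr"` rows; type-I cells (`sigma_b2 == 0`) are excluded.
#' @param tol_se tolerance in multiples of the paired MC standard error
#'   (default 2).
#' @return A list: per-cell table with a `conforming` flag, the fraction of
#'   conforming cells, the average powers and whether they are ordered.
#' @export
ordering_check <- function(results, tol_se = 2) {
  pow <- results[results$sigma_b2 > 0, ]
  if (nrow(pow) == 0) stop("no power cells (sigma_b2 > 0) in results")
  axes <- c("K", "design", "level", "sigma_u2", "sigma_b2")
  id <- do.call(paste, pow[axes])
  cells <- lapply(split(pow, id), function(g) {
    if (!all(c("bd", "dl", "lr") %in% g$test)) return(NULL)
    p <- stats::setNames(g$power, g$test)
    s <- stats::setNames(g$mc_se, g$test)
    ok <- p["bd"] >= p["dl"] - tol_se * sqrt(s["bd"]^2 + s["dl"]^2) &&
      p["dl"] >= p["lr"] - tol_se * sqrt(s["dl"]^2 + s["lr"]^2)
    cbind(g[1, axes, drop = FALSE],
          data.frame(power_bd = unname(p["bd"]), power_dl = unname(p["dl"]),
                     power_lr = unname(p["lr"]), conforming = unname(ok)))
  })
  cells <- do.call(rbind, Filter(Negate(is.null), cells))
  if (is.null(cells)) stop("no cell contains all three tests")
  avg <- c(bd = mean(cells$power_bd), dl = mean(cells$power_dl),
           lr = mean(cells$power_lr))
  list(cells = cells,
       fraction_conforming = mean(cells$conforming),
       average_power = avg,
       average_ordered = avg["bd"] >= avg["dl"] && avg["dl"] >= avg["lr"])
}
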