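#' Multicenter 2x2 table data
#'
#' Constructs a validated collection of K 2x2 contingency tables, one per
#' center, each cross-classifying treatment arm (1 = treated, 2 = control)
#' against a binary outcome. Arm 1 corresponds to treatment indicator
#' \eqn{x = 1} in the mixed logistic model, arm 2 to \eqn{x = 0}.
#'
#' @param y1,n1 integer vectors: successes and trials in arm 1, one entry
#'   per center.
#' @param y2,n2 integer vectors: successes and trials in arm 2.
#' @param center optional center identifiers; defaults to `1:K`. Centers are
#'   kept in sorted order and are indexable 1..K.
#' @return An object of class `mc_tables`: a data frame with columns
#'   `center`, `y1`, `n1`, `y2`, `n2` plus derived totals `t` (= y1 + y2)
#'   and `n` (= n1 + n2).
#' @examples
#' d <- mc_tables(y1 = c(30, 45), n1 = c(100, 100),
#'                y2 = c(50, 75), n2 = c(100, 100))
#' sample_or(d)
#' @export
mc_tables <- function(y1, n1, y2, n2, center = NULL) {
  k <- length(y1)
  if (is.null(center)) center <- seq_len(k)
  if (!all(lengths(list(n1, y2, n2, center)) == k))
    stop("y1, n1, y2, n2 and center must have equal length")
  df <- data.frame(center = center, y1 = y1, n1 = n1, y2 = y2, n2 = n2)
  validate_tables(df)
}

#' Validate raw center/arm count records
#'
#' Checks integer counts, `0 <= y <= n`, `n >= 1`, and (for long-format
#' input) that every center contributes exactly two arms. Offending centers
#' are named in the error message.
#'
#' @param x either a wide data frame with columns `center`, `y1`, `n1`,
#'   `y2`, `n2`, or a long data frame with columns `center`, `treat`, `y`,
#'   `n` where `treat` is coded `{1, 2}` or `{1, 0}` (`treat == 1` is arm 1).
#' @return A validated `mc_tables` object, centers sorted by id.
#' @export
validate_tables <- function(x) {
  x <- as.data.frame(x)
  if (all(c("center", "treat", "y", "n") %in% names(x))) {
    x <- long_to_wide(x)
  } else if (!all(c("center", "y1", "n1", "y2", "n2") %in% names(x))) {
    stop("need columns center,y1,n1,y2,n2 (wide) or center,treat,y,n (long)")
  }
  x <- x[order(x$center), , drop = FALSE]
  if (anyDuplicated(x$center))
    stop("duplicated center id: ", x$center[duplicated(x$center)][1])
  counts <- c("y1", "n1", "y2", "n2")
  for (cl in counts) {
    v <- x[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v)))
      stop("non-integer or missing counts in column ", cl)
    x[[cl]] <- as.integer(round(v))
  }
  bad <- x$y1 < 0 | x$y1 > x$n1 | x$y2 < 0 | x$y2 > x$n2 | x$n1 < 1 | x$n2 < 1
  if (any(bad))
    stop("invalid counts (need 0 <= y <= n, n >= 1) in center ",
         paste(x$center[bad], collapse = ", "))
  x$t <- x$y1 + x$y2
  x$n <- x$n1 + x$n2
  rownames(x) <- NULL
  structure(x, class = c("mc_tables", "data.frame"))
}

# long (center, treat, y, n) -> wide, treat coded {1,2} or {1,0}
long_to_wide <- function(x) {
  if (anyNA(x$treat) || !all(x$treat %in% c(0, 1, 2)))
    stop("treat must be coded {1,2} or {1,0}")
  x$arm <- ifelse(x$treat == 1, 1L, 2L)
  key <- paste(x$center, x$arm)
  if (anyDuplicated(key)) {
    dup <- x$center[duplicated(key)][1]
    stop("duplicated (center, arm) in center ", dup)
  }
  tab <- table(x$center)
  if (any(tab != 2))
    stop("each center needs exactly two arms; offending center ",
         paste(names(tab)[tab != 2], collapse = ", "))
  a1 <- x[x$arm == 1L, ]
  a2 <- x[x$arm == 2L, ]
  a2 <- a2[match(a1$center, a2$center), ]
  data.frame(center = a1$center, y1 = a1$y, n1 = a1$n, y2 = a2$y, n2 = a2$n)
}

#' @export
print.mc_tables <- function(x, ...) {
  cat("Multicenter 2x2 tables: K =", nrow(x), "centers,",
      sum(x$n), "subjects\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Number of centers
#' @param data an `mc_tables` object.
#' @return Integer K.
#' @export
n_centers <- function(data) nrow(data)

#' Continuity-correction policy for odds-ratio computations
#'
#' Zero cells make the sample log odds ratio and its variance undefined.
#' The default policy adds 0.5 to all four cells of any table containing a
#' zero cell (the Gart correction), leaving other tables untouched. The
#' correction applies only to odds-ratio and variance computations; tests
#' operating on raw counts (Breslow-Day, the mixed-model LR test) ignore it.
#'
#' @param add non-negative value added to all four cells of an affected
#'   table (default 0.5).
#' @param scope one of `"per-table-with-zero"` (default), `"all-tables"`,
#'   `"never"`.
#' @return A `continuity_policy` list.
#' @export
continuity_policy <- function(add = 0.5,
                              scope = c("per-table-with-zero", "all-tables",
                                        "never")) {
  scope <- match.arg(scope)
  stopifnot(is.numeric(add), length(add) == 1, add >= 0)
  structure(list(add = add, scope = scope), class = "continuity_policy")
}

# 2x2 cell layout (y1, n1-y1, y2, n2-y2) per center after policy; K x 4
adjusted_cells <- function(data, policy) {
  cells <- cbind(a = data$y1, b = data$n1 - data$y1,
                 c = data$y2, d = data$n2 - data$y2)
  if (policy$scope == "never" || policy$add == 0) return(cells)
  hit <- switch(policy$scope,
                "per-table-with-zero" = apply(cells == 0, 1, any),
                "all-tables" = rep(TRUE, nrow(cells)))
  cells[hit, ] <- cells[hit, , drop = FALSE] + policy$add
  cells
}

#' Per-center sample odds ratio
#'
#' @param data an `mc_tables` object.
#' @param policy a [continuity_policy()]; with `scope = "never"` a zero
#'   cell yields `Inf`, `0` or `NaN` as arithmetic dictates.
#' @return Numeric vector of K odds ratios
#'   \eqn{OR_k = y_{1k}(n_{2k}-y_{2k}) / [(n_{1k}-y_{1k}) y_{2k}]}.
#' @export
sample_or <- function(data, policy = continuity_policy()) {
  cells <- adjusted_cells(data, policy)
  unname((cells[, "a"] * cells[, "d"]) / (cells[, "b"] * cells[, "c"]))
}

#' Variance of the per-center log odds ratio
#'
#' The standard large-sample variance: the sum of reciprocals of the four
#' (continuity-adjusted) cells of each table.
#'
#' @inheritParams sample_or
#' @return Numeric vector of K variances; `Inf` if a zero cell survives the
#'   policy (an error is raised in that case).
#' @export
log_or_variance <- function(data, policy = continuity_policy()) {
  cells <- adjusted_cells(data, policy)
  if (any(cells == 0))
    stop("zero cell after continuity policy in center ",
         paste(data$center[apply(cells == 0, 1, any)], collapse = ", "))
  rowSums(1 / cells)
}

#' Mantel-Haenszel common odds ratio
#'
#' Pooled estimator
#' \deqn{OR_{MH} = \frac{\sum_k y_{1k}(n_{2k}-y_{2k})/n_k}
#'                     {\sum_k (n_{1k}-y_{1k}) y_{2k}/n_k}.}
#' Computed on raw counts (no continuity correction).
#'
#' @param data an `mc_tables` object.
#' @return A single positive number.
#' @export
mh_or <- function(data) {
  num <- sum(data$y1 * (data$n2 - data$y2) / data$n)
  den <- sum((data$n1 - data$y1) * data$y2 / data$n)
  if (den == 0) stop("Mantel-Haenszel denominator is zero")
  num / den
}

#' Read / write multicenter tables in long CSV format
#'
#' Long format, one row per (center, arm): columns `center`, `treat`
#' (`{1,2}` or `{1,0}`; `treat == 1` is arm 1), `y`, `n`. Comma- or
#' whitespace-delimited files are auto-detected. `write_tables_csv` emits
#' comma-separated output with `treat` coded `{1,2}`; a write/read
#' round-trip is lossless.
#'
#' @param path file path.
#' @return `read_tables_csv` returns an `mc_tables` object.
#' @export
read_tables_csv <- function(path) {
  first <- readLines(path, n = 1)
  df <- if (grepl(",", first)) {
    utils::read.csv(path, strip.white = TRUE)
  } else {
    utils::read.table(path, header = TRUE)
  }
  need <- c("center", "treat", "y", "n")
  if (!all(need %in% names(df)))
    stop("expected columns center, treat, y, n; got: ",
         paste(names(df), collapse = ", "))
  for (cl in c("treat", "y", "n"))
    if (!is.numeric(df[[cl]])) stop("non-numeric values in column ", cl)
  validate_tables(df[need])
}

#' @param data an `mc_tables` object to write.
#' @rdname read_tables_csv
#' @export
write_tables_csv <- function(data, path) {
  long <- data.frame(
    center = rep(data$center, each = 2),
    treat = rep(c(1L, 2L), times = nrow(data)),
    y = as.vector(rbind(data$y1, data$y2)),
    n = as.vector(rbind(data$n1, data$n2)))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
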