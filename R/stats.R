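#' Fit an exponential decay to a survival time series
#'
#' Fits `f(t) = 100 exp(-lambda t)` to a single replicate's survival
#' measurements. The default method fits `log(percent / 100)` linearly in
#' `t` with the intercept fixed at 0 (exactly the stated decay model, and
#' robust); `method = "nls"` performs nonlinear least squares in linear
#' space instead. Non-positive percentages carry no information in the
#' log model and are dropped (with a message attribute) before fitting.
#'
#' @param times measurement times, days.
#' @param percent_live percentages of live cells.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return An object of class `"half_life_fit"`: list with `lambda`
#'   (1/d), `t_half` (days, `ln(2) / lambda`), `fit_residual` (root mean
#'   squared residual on the fitted scale), `n` (points used), `method`.
#' @examples
#' t <- 0:5
#' fit_exponential_decay(t, 100 * exp(-0.5 * t))$lambda   # 0.5
#' @export
fit_exponential_decay <- function(times, percent_live,
                                  method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(percent_live))
  ok <- is.finite(times) & is.finite(percent_live)
  # zero/negative percentages carry no information on the log scale, but
  # they are retained for the linear-space nonlinear fit
  keep <- if (method == "loglinear") ok & percent_live > 0 else ok
  t <- times[keep]
  y <- percent_live[keep]
  if (sum(t > 0) < 1 || length(t) < 2)
    stop("need at least two usable points including one at t > 0",
         call. = FALSE)
  if (method == "loglinear") {
    z <- log(y / 100)
    lambda <- -sum(t * z) / sum(t^2)    # through-origin least squares
    resid <- z + lambda * t
  } else {
    pos <- y > 0 & t > 0
    l0 <- if (any(pos)) max(mean(-log(y[pos] / 100) / t[pos]), 1e-3) else 0.5
    fit <- stats::nls(y ~ 100 * exp(-l * t), start = list(l = l0),
                      lower = 1e-8, algorithm = "port",
                      control = stats::nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
    lambda <- stats::coef(fit)[["l"]]
    resid <- stats::residuals(fit)
  }
  if (!is.finite(lambda) || lambda <= 0)
    stop("no positive decay rate: series does not decay", call. = FALSE)
  structure(list(lambda = lambda, t_half = log(2) / lambda,
                 fit_residual = sqrt(mean(resid^2)), n = length(t),
                 method = method),
            class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("exponential decay fit (%s, n = %d): lambda = %.4g /d, t1/2 = %.4g d\n",
              x$method, x$n, x$lambda, x$t_half))
  invisible(x)
}

#' Summarise half-life estimates by condition
#'
#' Aggregates per-replicate exponential fits into per-condition mean and
#' standard deviation of the half-life.
#'
#' @param estimates a data.frame with columns `condition` and `t_half`
#'   (e.g. one row per replicate fit), or a list of `half_life_fit`
#'   objects accompanied by `condition`.
#' @param condition optional vector of condition labels when `estimates`
#'   is a list of fits.
#' @return data.frame with columns `condition`, `mean_t_half`,
#'   `sd_t_half`, `n`.
#' @export
summarize_half_lives <- function(estimates, condition = NULL) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    stopifnot(!is.null(condition), length(condition) == length(estimates))
    estimates <- data.frame(
      condition = condition,
      t_half = vapply(estimates, function(e) e$t_half, numeric(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("condition", "t_half") %in% names(estimates)))
  split_est <- split(estimates$t_half, estimates$condition)
  bad <- names(split_est)[lengths(split_est) < 2]
  if (length(bad))
    stop("need >= 2 estimates per condition; too few for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(
    condition = names(split_est),
    mean_t_half = vapply(split_est, mean, numeric(1)),
    sd_t_half = vapply(split_est, stats::sd, numeric(1)),
    n = lengths(split_est),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Normalise protein measurements to the Medium condition
#'
#' Divides every measurement of a protein by that protein's geometric
#' mean under the Medium condition, so that the Medium normalized
#' geometric mean is exactly 1 per protein.
#'
#' @param measurements data.frame with columns `protein`, `condition`,
#'   `replicate`, `value` (values > 0; geometric means are undefined
#'   otherwise).
#' @return the same data.frame with `value` replaced by the normalized
#'   value.
#' @export
normalize_to_medium <- function(measurements) {
  stopifnot(all(c("protein", "condition", "value") %in% names(measurements)))
  if (any(measurements$value <= 0))
    stop("measurement values must be > 0", call. = FALSE)
  out <- measurements
  for (p in unique(out$protein)) {
    ref <- out$value[out$protein == p & out$condition == "Medium"]
    if (!length(ref))
      stop("no Medium-condition reference for protein ", p, call. = FALSE)
    out$value[out$protein == p] <- out$value[out$protein == p] /
      geometric_mean(ref)
  }
  out
}

#' Ratio of a pro- to an anti-apoptotic protein
#'
#' Per condition, the ratio of the normalized geometric-mean abundances
#' of a (pro-apoptotic, anti-apoptotic) pair, with bootstrap uncertainty
#' over replicates.
#'
#' @param normalized a normalized measurement table from
#'   [normalize_to_medium()].
#' @param pro,anti species names, e.g. `"BIM"` and `"MCL1"`.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with columns `condition`, `pro`, `anti`, `ratio`,
#'   `sd`.
#' @export
protein_ratio <- function(normalized, pro, anti, n_boot = 10000, seed = 1L) {
  stopifnot(pro %in% normalized$protein, anti %in% normalized$protein)
  conds <- unique(normalized$condition)
  rows <- lapply(conds, function(cc) {
    xp <- normalized$value[normalized$protein == pro &
                             normalized$condition == cc]
    xa <- normalized$value[normalized$protein == anti &
                             normalized$condition == cc]
    ratio <- geometric_mean(xp) / geometric_mean(xa)
    bs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        geometric_mean(sample(xp, replace = TRUE)) /
          geometric_mean(sample(xa, replace = TRUE))
      }, numeric(1))
    })
    data.frame(condition = cc, pro = pro, anti = anti,
               ratio = ratio, sd = stats::sd(bs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# evaluate expr under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bootstrap mean and standard deviation
#'
#' Resamples the input with replacement `n_boot` times and reports the
#' mean and standard deviation of the resampled means. Deterministic
#' under a fixed seed.
#'
#' @param samples numeric vector (>= 2 values).
#' @param n_boot number of resamples (>= 100).
#' @param seed RNG seed.
#' @param statistic function applied to each resample (default [mean()]).
#' @return named vector `c(mean, sd)` of the bootstrap distribution.
#' @export
bootstrap_uncertainty <- function(samples, n_boot = 10000, seed = 1L,
                                  statistic = mean) {
  if (length(samples) < 2) stop("need >= 2 samples", call. = FALSE)
  if (n_boot < 100) stop("'n_boot' must be >= 100", call. = FALSE)
  bs <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) statistic(sample(samples, replace = TRUE)),
           numeric(1))
  })
  c(mean = mean(bs), sd = stats::sd(bs))
}

#' Compare two condition groups
#'
#' Unpaired two-sample Student t-test (equal variances by default, per
#' the study's convention; set `var_equal = FALSE` for Welch).
#'
#' @param groupA,groupB numeric vectors (>= 2 values each).
#' @param var_equal assume equal variances (classic Student test).
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_conditions <- function(groupA, groupB, var_equal = TRUE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need >= 2 values per group", call. = FALSE)
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      mean(groupA) == mean(groupB))
    stop("zero variance in both groups with equal means: ",
         "t statistic undefined", call. = FALSE)
  stats::t.test(groupA, groupB, var.equal = var_equal)
}
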