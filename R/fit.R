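#' Chi-square cost
#'
#' Weighted sum of squared residuals,
#' \deqn{\chi^2 = \sum_i \left(\frac{y_i - f(x_i)}{\sigma_i}\right)^2.}
#'
#' @param predictions model predictions `f(x_i)`.
#' @param observations measured values `y_i`.
#' @param sigma measurement uncertainties (> 0).
#' @return the scalar cost.
#' @examples
#' chi2(c(0, 0), c(1, 2), c(1, 1))  # 5
#' @export
chi2 <- function(predictions, observations, sigma) {
  stopifnot(length(predictions) == length(observations),
            length(sigma) == length(observations))
  if (any(sigma <= 0)) stop("'sigma' must be > 0", call. = FALSE)
  sum(((observations - predictions) / sigma)^2)
}

# --- free-parameter bookkeeping ------------------------------------------

kinetic_par_names <- function()
  c("a_BCL2", "s_MCL1", "s_BCL2", "s_BIM", "s_NOXA", "g_p0",
    "k_plus", "k1", "k2",
    "d_MCL1", "d_BCL2", "d_BIM", "d_NOXA", "d_BAX",
    "Kd_3", "Kd_4", "Kd_5", "Kd_6", "Kd_7")

death_par_names <- function() c("gamma", "kappa", "beta", "alpha", "K_BAX")

default_bounds <- function(free) {
  lower <- c(a_BCL2 = 0, s_MCL1 = 1e-3, s_BCL2 = 1e-3, s_BIM = 1e-3,
             s_NOXA = 1e-3, g_p0 = 1e-3, k_plus = 1e-4, k1 = 1e-3,
             k2 = 1e-3, d_MCL1 = 1e-3, d_BCL2 = 1e-3, d_BIM = 1e-3,
             d_NOXA = 1e-3, d_BAX = 1e-3,
             Kd_3 = 1e-3, Kd_4 = 1e-3, Kd_5 = 1e-3, Kd_6 = 1e-3, Kd_7 = 1e-3,
             gamma = 1e-4, kappa = 0, beta = 0, alpha = 0, K_BAX = 1)
  upper <- c(a_BCL2 = 10, s_MCL1 = 1.5, s_BCL2 = 1.5, s_BIM = 1.5,
             s_NOXA = 1.5, g_p0 = 20, k_plus = 100, k1 = 1000,
             k2 = 1000, d_MCL1 = 200, d_BCL2 = 200, d_BIM = 200,
             d_NOXA = 200, d_BAX = 200,
             Kd_3 = 1e4, Kd_4 = 1e4, Kd_5 = 1e4, Kd_6 = 1e4, Kd_7 = 1e4,
             gamma = 20, kappa = 50, beta = 100, alpha = 200, K_BAX = 5000)
  list(lower = lower[free], upper = upper[free])
}

apply_free <- function(params, dp, values) {
  for (nm in names(values)) {
    if (nm %in% kinetic_par_names()) params[[nm]] <- values[[nm]]
    else if (nm %in% death_par_names()) dp[[nm]] <- values[[nm]]
    else stop("unknown fit parameter: ", nm, call. = FALSE)
  }
  list(params = params, dp = dp)
}

current_values <- function(params, dp, free) {
  vapply(free, function(nm) {
    if (nm %in% kinetic_par_names()) params[[nm]] else dp[[nm]]
  }, numeric(1))
}

# --- observation assembly -------------------------------------------------

default_ratio_pairs <- function()
  list(c("BIM", "MCL1"), c("NOXA", "MCL1"), c("BIM", "BCL2"))

lookup_conditions <- function(labels) {
  all <- default_conditions()
  bad <- setdiff(labels, names(all))
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "),
         " (expected Medium, APRIL, ST2, APRIL+ST2)", call. = FALSE)
  all[labels]
}

# observed protein targets (ratios or normalized abundances) with sigma
build_protein_obs <- function(protein_data, target = "ratios",
                              ratio_pairs = default_ratio_pairs(),
                              n_boot = 2000, seed = 1L,
                              sigma_floor = 0.01) {
  norm <- normalize_to_medium(protein_data)
  conds <- setdiff(unique(norm$condition), "Medium")
  if (target == "ratios") {
    rows <- do.call(rbind, lapply(ratio_pairs, function(pr) {
      rt <- protein_ratio(norm, pr[1], pr[2], n_boot = n_boot, seed = seed)
      rt[rt$condition %in% conds, ]
    }))
    data.frame(condition = rows$condition, pro = rows$pro, anti = rows$anti,
               y = rows$ratio,
               sigma = pmax(rows$sd, sigma_floor * abs(rows$ratio)),
               stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(protein = unique(norm$protein), condition = conds,
                        stringsAsFactors = FALSE)
    grid$y <- NA_real_
    grid$sigma <- NA_real_
    for (i in seq_len(nrow(grid))) {
      v <- norm$value[norm$protein == grid$protein[i] &
                        norm$condition == grid$condition[i]]
      grid$y[i] <- geometric_mean(v)
      grid$sigma[i] <- max(stats::sd(v), sigma_floor * abs(grid$y[i]))
    }
    grid
  }
}

# observed survival targets: per condition x time mean with sigma
build_survival_obs <- function(survival_data, sigma_floor = 0.01) {
  stopifnot(all(c("time_d", "percent_live", "condition") %in%
                  names(survival_data)))
  key <- interaction(survival_data$condition, survival_data$time_d,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(survival_data, key), function(d) {
    s <- if (nrow(d) > 1) stats::sd(d$percent_live) else NA_real_
    data.frame(condition = d$condition[1], time_d = d$time_d[1],
               y = mean(d$percent_live), sd = s, stringsAsFactors = FALSE)
  }))
  agg$sigma <- pmax(ifelse(is.na(agg$sd), 1, agg$sd),
                    sigma_floor * pmax(abs(agg$y), 1))
  agg <- agg[order(agg$condition, agg$time_d), ]
  rownames(agg) <- NULL
  agg
}

# --- model predictions ----------------------------------------------------

# steady states for a set of condition labels, warm-started from a cache
condition_steady_states <- function(params, dp, topo, labels, cache) {
  conds <- lookup_conditions(unique(c("Medium", labels)))
  out <- list()
  for (nm in names(conds)) {
    guess <- cache[[nm]]
    ss <- tryCatch(
      steady_state(params, conds[[nm]], topo, init_guess = guess,
                   fmode = dp$fmode, f_n = dp$f_n, f_K = dp$f_K),
      error = function(e) steady_state(params, conds[[nm]], topo,
                                       fmode = dp$fmode, f_n = dp$f_n,
                                       f_K = dp$f_K))
    cache[[nm]] <- ss
    out[[nm]] <- ss
  }
  out
}

predict_protein_targets <- function(obs, ss_by_cond, topo) {
  totals <- lapply(ss_by_cond, state_totals, topo = topo)
  med <- totals$Medium
  if ("pro" %in% names(obs)) {
    vapply(seq_len(nrow(obs)), function(i) {
      tt <- totals[[obs$condition[i]]]
      (tt[obs$pro[i]] / med[obs$pro[i]]) /
        (tt[obs$anti[i]] / med[obs$anti[i]])
    }, numeric(1))
  } else {
    vapply(seq_len(nrow(obs)), function(i) {
      key <- obs$protein[i]
      totals[[obs$condition[i]]][key] / med[key]
    }, numeric(1))
  }
}

predict_survival_targets <- function(obs, params, dp, topo, ss_by_cond,
                                     mode = "steady") {
  labels <- unique(obs$condition)
  conds <- lookup_conditions(labels)
  pred <- numeric(nrow(obs))
  for (nm in labels) {
    idx <- obs$condition == nm
    tt <- obs$time_d[idx]
    if (mode == "steady") {
      lam <- death_rate_extended(ss_by_cond[[nm]][["BAXa"]] * 1000,
                                 conds[[nm]], dp)
      pred[idx] <- 100 * exp(-lam * tt)
    } else {
      grid <- sort(unique(c(0, tt)))
      sc <- simulate_survival(params, dp, conds[[nm]], topo, times = grid,
                              init = ss_by_cond$Medium, mode = "trajectory")
      pred[idx] <- sc$percent_live[match(tt, sc$time_d)]
    }
  }
  pred
}

# --- the fitting entry point ---------------------------------------------

#' Fit the apoptosis model to protein and/or survival data
#'
#' Chi-square least-squares estimation of free model parameters against
#' protein-abundance measurements, survival time courses, or both jointly
#' (summed chi-square). Optimisation uses the Levenberg--Marquardt
#' algorithm ([minpack.lm::nls.lm()]) with box bounds, optionally from
#' multiple seeded starting points.
#'
#' Protein data are normalized to the Medium condition and summarised as
#' pro-/anti-apoptotic pair ratios (default, `protein_target = "ratios"`,
#' with bootstrap uncertainties) or as normalized per-protein abundances
#' (`"abundances"`, with replicate-sd uncertainties); model predictions
#' are the corresponding steady-state quantities. Survival data are
#' summarised per condition and time point (mean and sd across
#' replicates); predictions are model survival curves with the death rate
#' evaluated at the condition's steady state (`survival_mode = "steady"`,
#' single-exponential) or along the network trajectory
#' (`"trajectory"`). All uncertainties are floored at 1% of the signal.
#'
#' @param protein_data measurement table with columns `protein`,
#'   `condition`, `replicate`, `value`, or `NULL`.
#' @param survival_data survival table with columns `time_d`,
#'   `percent_live`, `condition` (and optionally `replicate`), or `NULL`.
#' @param free character vector of parameters to estimate; any of
#'   `a_BCL2`, `s_MCL1`, `s_BCL2`, `s_BIM`, `s_NOXA`, `g_p0` (production),
#'   `gamma`, `kappa`, `beta`, `alpha`, `K_BAX` (death), and the kinetic
#'   constants.
#' @param start named starting values; defaults to the current values in
#'   `params` / `dp`.
#' @param lower,upper named bound overrides.
#' @param params,dp baseline [apoptosis_parameters()] and
#'   [death_parameters()]; fixed parameters keep these values.
#' @param topo an [pc_topology()].
#' @param protein_target `"ratios"` or `"abundances"`.
#' @param ratio_pairs list of `c(pro, anti)` pairs for `"ratios"`.
#' @param survival_mode `"steady"` or `"trajectory"`.
#' @param n_boot bootstrap resamples for ratio uncertainties.
#' @param seed RNG seed (bootstrap and multistart draws).
#' @param multistart number of additional random starting points (0 for
#'   a single local fit).
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `"apoptosis_fit"`; see
#'   [print.apoptosis_fit()], [coef.apoptosis_fit()],
#'   [predict.apoptosis_fit()], [plot.apoptosis_fit()].
#' @seealso [fit_protein_model()], [fit_survival_model()], [fit_joint()]
#' @export
fit_apoptosis_model <- function(protein_data = NULL, survival_data = NULL,
                                free = c("gamma", "kappa", "beta"),
                                start = NULL, lower = NULL, upper = NULL,
                                params = annotated_parameters()$kinetic,
                                dp = annotated_parameters()$death,
                                topo = default_topology(),
                                protein_target = c("ratios", "abundances"),
                                ratio_pairs = default_ratio_pairs(),
                                survival_mode = c("steady", "trajectory"),
                                n_boot = 2000, seed = 1L, multistart = 0,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, epsfcn = 1e-8)) {
  protein_target <- match.arg(protein_target)
  survival_mode <- match.arg(survival_mode)
  if (is.null(protein_data) && is.null(survival_data))
    stop("supply 'protein_data', 'survival_data', or both", call. = FALSE)
  free <- unique(free)
  bad <- setdiff(free, c(kinetic_par_names(), death_par_names()))
  if (length(bad))
    stop("unknown fit parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)

  p_obs <- if (!is.null(protein_data))
    build_protein_obs(protein_data, protein_target, ratio_pairs,
                      n_boot, seed) else NULL
  s_obs <- if (!is.null(survival_data))
    build_survival_obs(survival_data) else NULL
  N <- sum(nrow(p_obs), nrow(s_obs))
  if (N < length(free))
    stop("fewer data points (", N, ") than free parameters (",
         length(free), ")", call. = FALSE)

  bounds <- default_bounds(free)
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper
  init <- current_values(params, dp, free)
  if (!is.null(start)) init[names(start)] <- unlist(start)[names(start)]
  init <- pmin(pmax(init, bounds$lower), bounds$upper)

  labels <- unique(c(p_obs$condition, s_obs$condition))
  cache <- new.env(parent = emptyenv())

  residual_fn <- function(par) {
    upd <- apply_free(params, dp, stats::setNames(as.list(par), free))
    ss <- tryCatch(
      condition_steady_states(upd$params, upd$dp, topo, labels, cache),
      error = function(e) NULL)
    if (is.null(ss)) return(rep(1e6, N))
    r <- numeric(0)
    if (!is.null(p_obs)) {
      pred <- predict_protein_targets(p_obs, ss, topo)
      r <- c(r, (p_obs$y - pred) / p_obs$sigma)
    }
    if (!is.null(s_obs)) {
      pred <- predict_survival_targets(s_obs, upd$params, upd$dp, topo, ss,
                                       survival_mode)
      r <- c(r, (s_obs$y - pred) / s_obs$sigma)
    }
    r[!is.finite(r)] <- 1e6
    r
  }

  run_one <- function(p0) {
    fit <- minpack.lm::nls.lm(par = p0, fn = residual_fn,
                              lower = unname(bounds$lower),
                              upper = unname(bounds$upper),
                              control = control)
    list(par = stats::setNames(fit$par, free),
         chi2 = fit$deviance, info = fit$info,
         converged = fit$info %in% 1:4, message = fit$message,
         niter = fit$niter)
  }

  best <- run_one(init)
  starts <- list(init)
  if (multistart > 0) {
    draws <- with_seed(seed, {
      lapply(seq_len(multistart), function(i) {
        lo <- pmax(bounds$lower, init / 4)
        hi <- pmin(bounds$upper, pmax(init * 4, bounds$lower * 2 + 1e-6))
        stats::setNames(exp(stats::runif(length(free),
                                         log(pmax(lo, 1e-8)),
                                         log(pmax(hi, 1e-8)))), free)
      })
    })
    for (p0 in draws) {
      p0 <- pmin(pmax(p0, bounds$lower), bounds$upper)
      starts <- c(starts, list(p0))
      cand <- tryCatch(run_one(p0), error = function(e) NULL)
      if (!is.null(cand) && cand$chi2 < best$chi2) best <- cand
    }
  }

  upd <- apply_free(params, dp, as.list(best$par))
  ss <- condition_steady_states(upd$params, upd$dp, topo, labels, cache)
  fitted_p <- if (!is.null(p_obs))
    predict_protein_targets(p_obs, ss, topo) else NULL
  fitted_s <- if (!is.null(s_obs))
    predict_survival_targets(s_obs, upd$params, upd$dp, topo, ss,
                             survival_mode) else NULL
  k <- length(free)
  structure(list(
    estimates = best$par, chi2 = best$chi2, N = N, k = k,
    aic = if (best$chi2 > 0) 2 * k + N * log(best$chi2 / N) else -Inf,
    converged = best$converged, info = best$info, message = best$message,
    init = init, seed = seed, free = free,
    params = upd$params, dp = upd$dp, topo = topo,
    protein_obs = p_obs, survival_obs = s_obs,
    fitted_protein = fitted_p, fitted_survival = fitted_s,
    survival_mode = survival_mode, protein_target = protein_target,
    steady_states = ss),
    class = "apoptosis_fit")
}

#' Convenience wrappers for the three fitting configurations
#'
#' `fit_protein_model()` fits production parameters to protein data
#' alone; `fit_survival_model()` fits death parameters to survival data
#' alone; `fit_joint()` minimises the summed chi-square over both
#' datasets. All are thin wrappers around [fit_apoptosis_model()].
#'
#' @param data,protein_data,survival_data measurement tables (see
#'   [fit_apoptosis_model()]).
#' @param free parameters to estimate.
#' @param ... passed on to [fit_apoptosis_model()].
#' @return an `"apoptosis_fit"`.
#' @export
fit_protein_model <- function(data,
                              free = c("a_BCL2", "s_MCL1", "s_BCL2",
                                       "s_BIM", "s_NOXA"),
                              ...) {
  fit_apoptosis_model(protein_data = data, survival_data = NULL,
                      free = free, ...)
}

#' @rdname fit_protein_model
#' @export
fit_survival_model <- function(data, free = c("gamma", "kappa", "beta"),
                               ...) {
  fit_apoptosis_model(protein_data = NULL, survival_data = data,
                      free = free, ...)
}

#' @rdname fit_protein_model
#' @export
fit_joint <- function(protein_data, survival_data,
                      free = c("a_BCL2", "s_MCL1", "s_BCL2", "s_BIM",
                               "s_NOXA", "gamma", "kappa", "beta"),
                      ...) {
  fit_apoptosis_model(protein_data = protein_data,
                      survival_data = survival_data, free = free, ...)
}

# --- methods --------------------------------------------------------------

#' @export
print.apoptosis_fit <- function(x, ...) {
  cat("apoptosis model fit\n")
  cat(sprintf("  data: %s%s (N = %d)\n",
              if (!is.null(x$protein_obs)) "protein " else "",
              if (!is.null(x$survival_obs)) "survival" else "", x$N))
  cat(sprintf("  chi2 = %.6g, k = %d, AIC = %.4g, converged: %s\n",
              x$chi2, x$k, x$aic, x$converged))
  cat("  estimates:\n")
  print(round(x$estimates, 5))
  invisible(x)
}

#' @export
summary.apoptosis_fit <- function(object, ...) {
  est <- data.frame(parameter = object$free,
                    init = object$init,
                    estimate = object$estimates,
                    row.names = NULL)
  out <- list(estimates = est, chi2 = object$chi2, N = object$N,
              k = object$k, aic = object$aic, converged = object$converged,
              half_lives = tryCatch(
                model_half_lives(object$params, object$dp, object$topo),
                error = function(e) NULL))
  class(out) <- "summary.apoptosis_fit"
  out
}

#' @export
print.summary.apoptosis_fit <- function(x, ...) {
  cat("apoptosis model fit summary\n")
  print(x$estimates)
  cat(sprintf("chi2 = %.6g on N = %d points, k = %d, AIC = %.4g\n",
              x$chi2, x$N, x$k, x$aic))
  if (!is.null(x$half_lives)) {
    cat("model-implied half-lives (d):\n")
    print(round(x$half_lives, 3))
  }
  invisible(x)
}

#' @export
coef.apoptosis_fit <- function(object, ...) object$estimates

#' @export
residuals.apoptosis_fit <- function(object, ...) {
  r <- numeric(0)
  if (!is.null(object$protein_obs))
    r <- c(r, (object$protein_obs$y - object$fitted_protein) /
             object$protein_obs$sigma)
  if (!is.null(object$survival_obs))
    r <- c(r, (object$survival_obs$y - object$fitted_survival) /
             object$survival_obs$sigma)
  r
}

#' Predictions from a fitted apoptosis model
#'
#' @param object an `"apoptosis_fit"`.
#' @param what `"survival"` (curves per condition), `"protein"`
#'   (normalized steady-state targets), or `"half_life"`.
#' @param conditions named list of [condition()]s.
#' @param times time grid for survival curves, days.
#' @param ... unused.
#' @return a data.frame (`"survival"`, `"protein"`) or named vector
#'   (`"half_life"`).
#' @export
predict.apoptosis_fit <- function(object,
                                  what = c("survival", "protein",
                                           "half_life"),
                                  conditions = default_conditions(),
                                  times = seq(0, 10, 0.25), ...) {
  what <- match.arg(what)
  if (what == "half_life")
    return(model_half_lives(object$params, object$dp, object$topo,
                            conditions, mode = object$survival_mode))
  if (what == "survival") {
    out <- lapply(names(conditions), function(nm) {
      sc <- simulate_survival(object$params, object$dp, conditions[[nm]],
                              object$topo, times = times,
                              mode = object$survival_mode)
      as.data.frame(sc)
    })
    return(do.call(rbind, out))
  }
  # protein targets at the fitted parameters
  ss <- condition_steady_states(object$params, object$dp, object$topo,
                                names(conditions),
                                new.env(parent = emptyenv()))
  totals <- lapply(ss, state_totals, topo = object$topo)
  med <- totals$Medium
  do.call(rbind, lapply(names(totals), function(nm) {
    data.frame(condition = nm, protein = names(med),
               normalized = as.numeric(totals[[nm]] / med),
               stringsAsFactors = FALSE)
  }))
}

#' @export
plot.apoptosis_fit <- function(x, ...) {
  has_s <- !is.null(x$survival_obs)
  has_p <- !is.null(x$protein_obs)
  if (has_s && has_p) graphics::par(mfrow = c(1, 2))
  if (has_s) {
    obs <- x$survival_obs
    conds <- unique(obs$condition)
    cols <- seq_along(conds)
    graphics::plot(NA, xlim = range(obs$time_d), ylim = c(0, 105),
                   xlab = "time (d)", ylab = "% live cells",
                   main = "survival: data vs fit")
    for (i in seq_along(conds)) {
      d <- obs[obs$condition == conds[i], ]
      graphics::points(d$time_d, d$y, col = cols[i], pch = 16)
      graphics::arrows(d$time_d, d$y - d$sigma, d$time_d, d$y + d$sigma,
                       length = 0.02, angle = 90, code = 3, col = cols[i])
      f <- x$fitted_survival[x$survival_obs$condition == conds[i]]
      graphics::lines(d$time_d, f, col = cols[i], lwd = 2)
    }
    graphics::legend("topright", legend = conds, col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
  }
  if (has_p) {
    obs <- x$protein_obs
    graphics::plot(obs$y, x$fitted_protein,
                   xlab = "observed", ylab = "fitted",
                   main = "protein targets", pch = 16)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' AIC of a fitted apoptosis model
#'
#' Uses the least-squares convention `AIC = 2k + N log(chi2 / N)`; see
#' [aic()].
#'
#' @param object an `"apoptosis_fit"`.
#' @param ... unused.
#' @param k unused (signature compatibility).
#' @export
AIC.apoptosis_fit <- function(object, ..., k = 2) {
  aic(object$chi2, object$N, object$k)
}

#' Simulate datasets from a fitted model
#'
#' Draws synthetic protein and survival datasets at the fitted parameter
#' values, using the package generators (parametric bootstrap).
#'
#' @param object an `"apoptosis_fit"`.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param n_replicates,noise_cv,noise_sd generator settings, see
#'   [make_protein_dataset()] and [make_survival_dataset()].
#' @param times survival sampling grid, days.
#' @param ... unused.
#' @return list of `nsim` lists with elements `protein` and `survival`.
#' @export
simulate.apoptosis_fit <- function(object, nsim = 1, seed = 1L,
                                   n_replicates = 6, noise_cv = 0.15,
                                   noise_sd = 5, times = 0:5, ...) {
  hl <- model_half_lives(object$params, object$dp, object$topo,
                         mode = "steady")
  lapply(seq_len(nsim), function(i) {
    list(protein = make_protein_dataset(object$params, object$topo,
                                        n_replicates = n_replicates,
                                        noise_cv = noise_cv,
                                        seed = seed + i - 1L),
         survival = make_survival_dataset(hl, times = times,
                                          n_replicates = 2 * n_replicates,
                                          noise_sd = noise_sd,
                                          seed = seed + 100000L + i - 1L))
  })
}
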