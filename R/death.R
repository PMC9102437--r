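#' Regulatory input function
#'
#' Maps a stimulus level to a regulatory weight in \[0, 1\]. In Boolean
#' mode (used for fitting presence/absence culture data) it is the
#' indicator of `x > 0`; in Hill mode it is the graded response
#' `x^n / (x^n + K)`.
#'
#' @param x stimulus level(s), >= 0.
#' @param fmode `"boolean"` or `"hill"`.
#' @param n,K Hill exponent and half-saturation (Hill mode only).
#' @return value(s) in \[0, 1\].
#' @examples
#' regulatory_f(0)                      # 0
#' regulatory_f(50)                     # 1
#' regulatory_f(2, "hill", n = 1, K = 2) # 0.5
#' @export
regulatory_f <- function(x, fmode = c("boolean", "hill"), n = 1, K = 1) {
  fmode <- match.arg(fmode)
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  if (fmode == "boolean") as.numeric(x > 0) else x^n / (x^n + K)
}

#' BAX-driven death rate (core law)
#'
#' Hill-type dependence of the population death rate on activated BAX:
#' \deqn{\lambda = \gamma \frac{x^n}{K_{BAX}^n + x^n}} with `n = 3` by
#' default. Strictly increasing in `bax_star` and bounded by `gamma`.
#'
#' @param bax_star activated BAX concentration, nM (vectorised, >= 0).
#' @param dp a [death_parameters()] set.
#' @return death rate(s) lambda, 1/d.
#' @examples
#' dp <- death_parameters()
#' death_rate_bax(dp$K_BAX, dp)   # half-maximum: gamma / 2
#' @export
death_rate_bax <- function(bax_star, dp = death_parameters()) {
  if (any(bax_star < 0)) stop("'bax_star' must be >= 0", call. = FALSE)
  x <- bax_star^dp$hill_n
  dp$gamma * x / (dp$K_BAX^dp$hill_n + x)
}

#' Extended death rate with caspase regulation
#'
#' Adds BAX-independent caspase regulation to the core law:
#' \deqn{\lambda = \gamma\left(H(x) + \frac{\kappa}{1 + \alpha f(APRIL)}\right)
#'       \frac{1}{1 + \beta f(ST2)},}
#' where `H` is the Hill term of [death_rate_bax()]. The caspase-12
#' contribution `kappa` is suppressed by APRIL (strength `alpha`) and the
#' whole caspase-3/7 output is suppressed by ST2 contact (strength
#' `beta`). With `kappa = 0` and `beta = 0` the law reduces exactly to
#' the core law. Bounded in \[0, gamma * (1 + kappa)\].
#'
#' @inheritParams death_rate_bax
#' @param cond a [condition()].
#' @return death rate(s) lambda, 1/d.
#' @examples
#' dp <- death_parameters()
#' death_rate_extended(1e4, condition(0, 0), dp)  # saturated, Medium
#' @export
death_rate_extended <- function(bax_star, cond, dp = death_parameters()) {
  if (any(bax_star < 0)) stop("'bax_star' must be >= 0", call. = FALSE)
  x <- bax_star^dp$hill_n
  H <- x / (dp$K_BAX^dp$hill_n + x)
  f_apr <- regulatory_f(cond$april, dp$fmode, dp$f_n, dp$f_K)
  f_st2 <- regulatory_f(cond$st2, dp$fmode, dp$f_n, dp$f_K)
  dp$gamma * (H + dp$kappa / (1 + dp$alpha * f_apr)) / (1 + dp$beta * f_st2)
}

#' Simulate a population survival curve
#'
#' Couples the death-rate law to the network dynamics:
#' \deqn{N(t) = 100 \exp\left(-\int_0^t \lambda(s)\, ds\right)}
#' with \eqn{\lambda(s)} evaluated at the activated-BAX level along the
#' network trajectory (`mode = "trajectory"`, integrated jointly with the
#' network ODEs) or frozen at the condition's own steady state
#' (`mode = "steady"`, a single-exponential shortcut; both agree when the
#' network starts in steady state).
#'
#' @inheritParams simulate_network
#' @param dp a [death_parameters()] set.
#' @param mode `"trajectory"` or `"steady"`.
#' @param init initial network state; default `"medium"` starts from the
#'   Medium-condition steady state (cells arriving from an intact niche).
#' @return An object of class `c("survival_curve", "data.frame")` with
#'   columns `time_d`, `percent_live`, `condition`; attribute `lambda`
#'   holds the (final) death rate in 1/d.
#' @examples
#' fx <- annotated_parameters()
#' sc <- simulate_survival(fx$kinetic, fx$death, condition(0, 0),
#'                         times = 0:5)
#' model_half_life(sc)
#' @export
simulate_survival <- function(params, dp, cond, topo = default_topology(),
                              times = seq(0, 10, by = 0.1), init = "medium",
                              mode = c("trajectory", "steady"),
                              complex_decay = "faster",
                              rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  fmode <- dp$fmode
  if (mode == "steady") {
    ss <- steady_state(params, cond, topo, complex_decay = complex_decay,
                       fmode = fmode, f_n = dp$f_n, f_K = dp$f_K)
    lam <- death_rate_extended(ss[["BAXa"]] * 1000, cond, dp)
    pct <- 100 * exp(-lam * (times - times[1]))
  } else {
    ctx <- derivative_context(cond, params, topo, complex_decay,
                              fmode, dp$f_n, dp$f_K)
    nm <- state_names(topo)
    if (identical(init, "medium")) {
      init <- steady_state(params, condition(0, 0), topo,
                           complex_decay = complex_decay,
                           fmode = fmode, f_n = dp$f_n, f_K = dp$f_K)
    } else if (is.null(init)) {
      init <- stats::setNames(rep(0, length(nm)), nm)
    }
    # augment the system with the cumulative hazard
    rhs <- function(t, y, parms) {
      s <- pmax(y[-length(y)], 0)
      lam_t <- death_rate_extended(s[[6]] * 1000, cond, dp)
      list(c(unname(deriv_raw(s, parms)), lam_t))
    }
    y0 <- c(as.numeric(init), 0)
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = ctx,
                        method = "lsoda", rtol = rtol, atol = atol)
    diagn <- attr(sol, "istate")
    if (!is.null(diagn) && diagn[1] < 0)
      stop("ODE integration failed (istate = ", diagn[1], ")", call. = FALSE)
    hazard <- sol[, ncol(sol)]
    pct <- 100 * exp(-hazard)
    lam <- death_rate_extended(max(sol[nrow(sol), 7], 0) * 1000, cond, dp)
  }
  structure(data.frame(time_d = times, percent_live = pct,
                       condition = condition_name(cond),
                       stringsAsFactors = FALSE),
            lambda = lam, class = c("survival_curve", "data.frame"))
}

#' @export
plot.survival_curve <- function(x, log = "", ...) {
  graphics::plot(x$time_d, x$percent_live, type = "l", lwd = 2, log = log,
                 xlab = "time (d)", ylab = "% live cells",
                 main = paste("condition:", x$condition[1]), ylim = c(0, 100),
                 ...)
  graphics::abline(h = 50, lty = 3)
  invisible(x)
}

#' Half-life of a survival curve
#'
#' For a simulated or measured survival curve, returns the time at which
#' the curve crosses 50% of the initial population, log-linearly
#' interpolated between grid points (exact for single-exponential
#' curves, where it equals `ln(2) / lambda`).
#'
#' @param curve a `survival_curve` / data.frame with columns `time_d`
#'   and `percent_live`, or a numeric vector of times (in which case
#'   `percent_live` must be supplied).
#' @param percent_live survival percentages when `curve` is a time vector.
#' @return half-life in days.
#' @examples
#' t <- seq(0, 10, 0.1)
#' model_half_life(t, 100 * exp(-0.1 * t))  # ln(2) / 0.1
#' @export
model_half_life <- function(curve, percent_live = NULL) {
  if (is.data.frame(curve)) {
    times <- curve$time_d
    pct <- curve$percent_live
  } else {
    times <- curve
    pct <- percent_live
  }
  stopifnot(length(times) == length(pct), length(times) >= 2)
  if (any(diff(pct) > 1e-8 * pmax(abs(pct[-length(pct)]), 1)))
    warning("survival curve is not monotone non-increasing")
  below <- which(pct <= 50)
  if (!length(below))
    stop("survival never reaches 50% within the time grid; ",
         "extend the grid", call. = FALSE)
  i <- below[1]
  if (pct[i] == 50) return(times[i])
  if (i == 1) return(times[1])
  # log-linear interpolation of the crossing
  t0 <- times[i - 1]; t1 <- times[i]
  p0 <- pct[i - 1]; p1 <- pct[i]
  if (p1 <= 0) p1 <- .Machine$double.xmin
  t0 + (t1 - t0) * (log(p0) - log(50)) / (log(p0) - log(p1))
}

#' Model-implied half-life per condition
#'
#' Convenience wrapper computing the population half-life of each
#' condition from the model, via [simulate_survival()].
#'
#' @inheritParams simulate_survival
#' @param conditions named list of [condition()]s.
#' @param t_max simulation horizon, days.
#' @return named numeric vector of half-lives, days.
#' @examples
#' fx <- annotated_parameters()
#' model_half_lives(fx$kinetic, fx$death, mode = "steady")
#' @export
model_half_lives <- function(params, dp, topo = default_topology(),
                             conditions = default_conditions(),
                             mode = "steady", init = "medium",
                             t_max = 60) {
  vapply(conditions, function(cc) {
    if (mode == "steady") {
      ss <- steady_state(params, cc, topo, fmode = dp$fmode,
                         f_n = dp$f_n, f_K = dp$f_K)
      lam <- death_rate_extended(ss[["BAXa"]] * 1000, cc, dp)
      log(2) / lam
    } else {
      sc <- simulate_survival(params, dp, cc, topo,
                              times = seq(0, t_max, by = 0.02),
                              init = init, mode = "trajectory")
      model_half_life(sc)
    }
  }, numeric(1))
}
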