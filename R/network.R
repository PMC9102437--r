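#' Condition-dependent production rate
#'
#' Basal production `g_p0` scaled by the condition modifiers: with ST2
#' contact, production of MCL-1, BCL-2, BIM and NOXA is scaled towards the
#' factors `s_P` (fully, under Boolean regulation; proportionally to
#' `f(ST2)` under Hill regulation); with APRIL, BCL-2 production is scaled
#' by `(1 + a_BCL2 * f(APRIL))`. BAX production is condition-independent.
#'
#' @param protein species id, one of `"BIM"`, `"NOXA"`, `"BCL2"`,
#'   `"MCL1"`, `"BAX"` (vectorised).
#' @param cond a [condition()].
#' @param params an [apoptosis_parameters()] set.
#' @param fmode regulatory-function mode, `"boolean"` or `"hill"`.
#' @param f_n,f_K Hill constants when `fmode = "hill"`.
#' @return production rate(s) in uM/d.
#' @examples
#' p <- apoptosis_parameters()
#' production_rate("BIM", condition(0, 0), p)   # basal
#' production_rate("BIM", condition(0, 1), p)   # ST2 downregulation
#' @export
production_rate <- function(protein, cond, params,
                            fmode = c("boolean", "hill"), f_n = 1, f_K = 1) {
  fmode <- match.arg(fmode)
  known <- c("BIM", "NOXA", "BCL2", "MCL1", "BAX")
  bad <- setdiff(protein, known)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")", call. = FALSE)
  f_st2 <- regulatory_f(cond$st2, fmode, f_n, f_K)
  f_apr <- regulatory_f(cond$april, fmode, f_n, f_K)
  s <- c(BIM = params$s_BIM, NOXA = params$s_NOXA,
         BCL2 = params$s_BCL2, MCL1 = params$s_MCL1, BAX = 1)
  # ST2 modifier interpolates 1 -> s_P with f; exact s_P in Boolean mode
  g <- params$g_p0 * (1 - (1 - s[protein]) * f_st2)
  g[protein == "BCL2"] <- g[protein == "BCL2"] * (1 + params$a_BCL2 * f_apr)
  stats::setNames(as.numeric(g), protein)
}

# internal: full production vector incl. BAX
production_vector <- function(cond, params, fmode = "boolean",
                              f_n = 1, f_K = 1) {
  production_rate(c("BIM", "NOXA", "BCL2", "MCL1", "BAX"), cond, params,
                  fmode, f_n, f_K)
}

#' Time derivative of the network state
#'
#' Mass-action right-hand side of the ODE system: production and
#' first-order decay of the free proteins, reversible complex formation
#' for every topology pair (association `k_plus * [A][B]`, dissociation
#' `k_plus * Kd * [C]`), first-order BAX activation/deactivation
#' (`k1 * [BAX]`, `k2 * [BAX*]`), and complex decay at the faster
#' partner's rate.
#'
#' @param state named non-negative state vector: free species
#'   `BIM, NOXA, BCL2, MCL1, BAX, BAXa` then one entry per topology
#'   complex (uM).
#' @param cond a [condition()].
#' @param params an [apoptosis_parameters()] set.
#' @param topo an [pc_topology()]; default [default_topology()].
#' @param complex_decay `"faster"` (default) or `"none"`.
#' @param fmode,f_n,f_K regulatory-function mode for the production terms.
#' @return named derivative vector, uM/d.
#' @export
network_derivative <- function(state, cond, params, topo = default_topology(),
                               complex_decay = "faster",
                               fmode = "boolean", f_n = 1, f_K = 1) {
  nm <- state_names(topo)
  if (is.null(names(state))) names(state) <- nm
  if (any(state < 0))
    stop("negative state entries: ",
         paste(names(state)[state < 0], collapse = ", "), call. = FALSE)
  ctx <- derivative_context(cond, params, topo, complex_decay, fmode, f_n, f_K)
  deriv_raw(state, ctx)
}

# Precomputed constants for fast repeated right-hand-side evaluation.
derivative_context <- function(cond, params, topo, complex_decay = "faster",
                               fmode = "boolean", f_n = 1, f_K = 1) {
  g <- production_vector(cond, params, fmode, f_n, f_K)
  d_free <- c(BIM = params$d_BIM, NOXA = params$d_NOXA, BCL2 = params$d_BCL2,
              MCL1 = params$d_MCL1, BAX = params$d_BAX, BAXa = params$d_BAX)
  kp <- params$k_plus * 1000          # nM^-1 d^-1 -> uM^-1 d^-1
  kd_uM <- topology_kd(params, topo) / 1000
  list(g = g, d_free = d_free, kp = kp,
       km = kp * kd_uM,               # dissociation rates, 1/d
       d_cplx = complex_decay_rates(params, topo, complex_decay),
       k1 = params$k1, k2 = params$k2,
       ia = match(topo$anti, species_names()),
       ip = match(topo$pro, species_names()),
       n_species = 6L, n_cplx = nrow(topo),
       names = state_names(topo))
}

deriv_raw <- function(state, ctx) {
  free <- state[seq_len(ctx$n_species)]
  cplx <- state[ctx$n_species + seq_len(ctx$n_cplx)]
  flux <- ctx$kp * free[ctx$ia] * free[ctx$ip] - ctx$km * cplx
  dfree <- c(ctx$g, 0) - ctx$d_free * free
  dfree[5] <- dfree[5] - ctx$k1 * free[5] + ctx$k2 * free[6]
  dfree[6] <- dfree[6] + ctx$k1 * free[5] - ctx$k2 * free[6]
  for (j in seq_len(ctx$n_cplx)) {
    dfree[ctx$ia[j]] <- dfree[ctx$ia[j]] - flux[j]
    dfree[ctx$ip[j]] <- dfree[ctx$ip[j]] - flux[j]
  }
  out <- c(dfree, flux - ctx$d_cplx * cplx)
  names(out) <- ctx$names
  out
}

# gross per-equation rate magnitude (sum of absolute term sizes); used to
# scale steady-state residuals so convergence is insensitive to the huge
# flux magnitudes of the fast-binding regime
deriv_gross <- function(state, ctx) {
  free <- state[seq_len(ctx$n_species)]
  cplx <- state[ctx$n_species + seq_len(ctx$n_cplx)]
  assoc <- ctx$kp * free[ctx$ia] * free[ctx$ip]
  dissoc <- ctx$km * cplx
  gross_free <- c(ctx$g, 0) + ctx$d_free * free
  gross_free[5] <- gross_free[5] + ctx$k1 * free[5] + ctx$k2 * free[6]
  gross_free[6] <- gross_free[6] + ctx$k1 * free[5] + ctx$k2 * free[6]
  for (j in seq_len(ctx$n_cplx)) {
    gross_free[ctx$ia[j]] <- gross_free[ctx$ia[j]] + assoc[j] + dissoc[j]
    gross_free[ctx$ip[j]] <- gross_free[ctx$ip[j]] + assoc[j] + dissoc[j]
  }
  c(gross_free, assoc + dissoc + ctx$d_cplx * cplx)
}

#' Simulate the network ODE system
#'
#' Integrates the stiff mass-action system with `deSolve::ode`
#' (lsoda). Small negative excursions at solver tolerance are clipped
#' to zero.
#'
#' @inheritParams network_derivative
#' @param times strictly increasing time grid, days.
#' @param init initial [network] state; `NULL` starts from zero, the
#'   string `"medium"` starts from the Medium-condition steady state
#'   (cells arriving from an intact survival niche).
#' @param rtol,atol solver tolerances.
#' @return An object of class `"network_trajectory"`: a matrix of states
#'   with attributes `times` and `condition`.
#' @examples
#' fx <- annotated_parameters()
#' tr <- simulate_network(fx$kinetic, condition(0, 0), times = seq(0, 5, 0.5))
#' tail(as.data.frame(tr), 3)
#' @export
simulate_network <- function(params, cond, topo = default_topology(),
                             times = seq(0, 10, by = 0.1), init = NULL,
                             complex_decay = "faster",
                             fmode = "boolean", f_n = 1, f_K = 1,
                             rtol = 1e-8, atol = 1e-10) {
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  nm <- state_names(topo)
  if (is.null(init)) {
    init <- stats::setNames(rep(0, length(nm)), nm)
  } else if (identical(init, "medium")) {
    init <- steady_state(params, condition(0, 0), topo,
                         complex_decay = complex_decay,
                         fmode = fmode, f_n = f_n, f_K = f_K)
  }
  stopifnot(length(init) == length(nm))
  ctx <- derivative_context(cond, params, topo, complex_decay, fmode, f_n, f_K)
  rhs <- function(t, y, parms) list(unname(deriv_raw(y, parms)))
  sol <- deSolve::ode(y = stats::setNames(as.numeric(init), nm), times = times,
                      func = rhs, parms = ctx, method = "lsoda",
                      rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE integration failed (istate = ", diagn[1], ")", call. = FALSE)
  states <- sol[, -1, drop = FALSE]
  states[states < 0] <- 0
  structure(states, times = sol[, 1], condition = condition_name(cond),
            class = c("network_trajectory", class(states)))
}

#' @export
as.data.frame.network_trajectory <- function(x, ...) {
  times <- attr(x, "times")
  df <- data.frame(time_d = rep(times, ncol(x)),
                   species = rep(colnames(x), each = length(times)),
                   concentration_uM = as.vector(unclass(x)),
                   condition = attr(x, "condition"),
                   stringsAsFactors = FALSE)
  df
}

#' @export
print.network_trajectory <- function(x, ...) {
  times <- attr(x, "times")
  cat(sprintf("network trajectory: %d time points over [%g, %g] d, condition %s\n",
              length(times), min(times), max(times), attr(x, "condition")))
  cat("final state (uM):\n")
  print(round(unclass(x)[nrow(x), ], 6))
  invisible(x)
}

#' @export
plot.network_trajectory <- function(x, species = species_names(), ...) {
  times <- attr(x, "times")
  y <- unclass(x)[, species, drop = FALSE]
  graphics::matplot(times, y, type = "l", lty = 1, lwd = 2,
                    xlab = "time (d)", ylab = "concentration (uM)",
                    main = paste("condition:", attr(x, "condition")), ...)
  graphics::legend("topright", legend = species, col = seq_along(species),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Steady state of the network
#'
#' Solves `network_derivative(state) = 0` by damped Newton iteration with
#' a finite-difference Jacobian, starting from the decoupled
#' production/decay balance (`g_P / d_P`, zero complexes) unless a guess
#' is supplied. If Newton fails to reach a non-negative root, falls back
#' to long-time relaxation of the ODE followed by a Newton polish.
#'
#' @inheritParams network_derivative
#' @param init_guess optional starting state.
#' @param tol relative convergence tolerance: the derivative of each
#'   equation must fall below `tol` times that equation's gross rate
#'   magnitude (with a 1 uM/d floor).
#' @return named steady-state vector (uM), with attribute `residual`.
#' @examples
#' fx <- annotated_parameters()
#' ss <- steady_state(fx$kinetic, condition(0, 0))
#' ss[["BAXa"]] * 1000  # activated BAX in nM
#' @export
steady_state <- function(params, cond, topo = default_topology(),
                         init_guess = NULL, complex_decay = "faster",
                         fmode = "boolean", f_n = 1, f_K = 1,
                         tol = 1e-9) {
  ctx <- derivative_context(cond, params, topo, complex_decay, fmode, f_n, f_K)
  nm <- ctx$names
  n <- length(nm)
  if (is.null(init_guess)) {
    free0 <- c(ctx$g, ctx$g[5] * ctx$k1 / (ctx$k2 + ctx$d_free[6])) /
      c(ctx$d_free[1:5], ctx$d_free[6])
    init_guess <- c(free0, rep(1e-4, ctx$n_cplx))
  }
  x <- pmax(as.numeric(init_guess), 0)

  resid_rel <- function(x, fx = deriv_raw(x, ctx))
    max(abs(fx) / pmax(deriv_gross(x, ctx), 1))

  newton <- function(x, maxit = 100L) {
    for (it in seq_len(maxit)) {
      fx <- deriv_raw(x, ctx)
      if (resid_rel(x, fx) < tol) return(list(x = x, ok = TRUE))
      J <- numeric_jacobian(function(z) deriv_raw(z, ctx), x, fx)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) return(list(x = x, ok = FALSE))
      lam <- 1
      f0 <- sum(fx^2)
      repeat {
        xn <- x + lam * step
        xn[xn < 0] <- 0
        fn <- deriv_raw(xn, ctx)
        if (sum(fn^2) < f0 || lam < 1e-6) break
        lam <- lam / 2
      }
      if (lam < 1e-6 && sum(fn^2) >= f0) return(list(x = x, ok = FALSE))
      x <- xn
    }
    list(x = x, ok = resid_rel(x) < tol)
  }

  res <- newton(x)
  if (!res$ok || any(res$x < 0)) {
    # relaxation fallback: integrate long past the slowest decay time
    t_end <- 20 * max(1 / c(ctx$d_free, ctx$km + ctx$d_cplx))
    rhs <- function(t, y, parms) list(unname(deriv_raw(pmax(y, 0), parms)))
    sol <- deSolve::ode(y = pmax(as.numeric(init_guess), 0),
                        times = c(0, t_end), func = rhs, parms = ctx,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    res <- newton(pmax(sol[nrow(sol), -1], 0))
    if (!res$ok)
      stop("steady-state solver did not converge (relative residual ",
           format(resid_rel(res$x)),
           "); consider a relaxation run with simulate_network()",
           call. = FALSE)
  }
  structure(stats::setNames(res$x, nm), residual = resid_rel(res$x))
}

numeric_jacobian <- function(f, x, fx = f(x), eps = 1e-7) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(x[j]), 1e-3)
    xj <- x
    xj[j] <- xj[j] + h
    J[, j] <- (f(xj) - fx) / h
  }
  J
}

# total abundance per species (free + all complexes containing it)
state_totals <- function(state, topo) {
  sp <- species_names()
  tot <- stats::setNames(as.numeric(state[sp]), sp)
  for (j in seq_len(nrow(topo))) {
    cval <- as.numeric(state[topo$complex[j]])
    tot[topo$anti[j]] <- tot[topo$anti[j]] + cval
    tot[topo$pro[j]] <- tot[topo$pro[j]] + cval
  }
  tot
}
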