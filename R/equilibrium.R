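#' Rapid-equilibrium complex concentrations
#'
#' Solves the coupled binding equilibria of the topology given total
#' abundances: for every pair `[C] = [A]free [B]free / Kd` together with
#' mass conservation `total_S = free_S + sum of complexes containing S`.
#' Solved by damped fixed-point iteration on the free concentrations,
#' \deqn{free_A = total_A / (1 + \sum_B free_B / K_{d,AB}),}
#' which is independent of the mass-action ODE machinery and serves as an
#' oracle for the network steady state in the fast-binding limit.
#'
#' @param totals named non-negative totals per species (uM); names must
#'   cover every species appearing in `topo`.
#' @param topo an [pc_topology()].
#' @param Kd named dissociation constants per complex (nM), names matching
#'   `topo$complex`; alternatively an [apoptosis_parameters()] set from
#'   which they are extracted.
#' @param tol convergence tolerance (relative change per iteration).
#' @param maxit iteration cap.
#' @return list with named vectors `free` and `complexes` (uM).
#' @examples
#' topo <- default_topology()
#' eq <- equilibrium_complexes(
#'   c(BIM = 0.1, NOXA = 0.02, BCL2 = 1, MCL1 = 0.05, BAX = 0.1, BAXa = 0.4),
#'   topo, annotated_parameters()$kinetic)
#' eq$complexes
#' @export
equilibrium_complexes <- function(totals, topo = default_topology(), Kd,
                                  tol = 1e-12, maxit = 10000L) {
  if (inherits(Kd, "apoptosis_parameters")) Kd <- topology_kd(Kd, topo)
  if (is.null(names(Kd))) names(Kd) <- topo$complex
  if (any(Kd <= 0)) stop("'Kd' entries must be > 0", call. = FALSE)
  if (any(totals < 0)) stop("'totals' must be non-negative", call. = FALSE)
  sp <- unique(c(topo$anti, topo$pro))
  missing <- setdiff(sp, names(totals))
  if (length(missing))
    stop("totals missing for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  kd_uM <- Kd[topo$complex] / 1000

  free <- totals[sp]
  for (it in seq_len(maxit)) {
    new <- free
    for (s in sp) {
      ia <- which(topo$anti == s)
      ip <- which(topo$pro == s)
      denom <- 1 +
        sum(new[topo$pro[ia]] / kd_uM[ia]) +
        sum(new[topo$anti[ip]] / kd_uM[ip])
      new[s] <- totals[s] / denom
    }
    new <- (new + free) / 2   # damping for stiff (tight-binding) cases
    delta <- max(abs(new - free) / pmax(abs(free), 1e-300))
    free <- new
    if (delta < tol) break
  }
  cplx <- free[topo$anti] * free[topo$pro] / kd_uM
  names(cplx) <- topo$complex
  # residual check on mass conservation
  resid <- vapply(sp, function(s) {
    bound <- sum(cplx[topo$anti == s]) + sum(cplx[topo$pro == s])
    abs(free[s] + bound - totals[s]) / max(totals[s], 1e-300)
  }, numeric(1))
  if (max(resid) > 1e-8)
    stop("equilibrium solver did not converge (mass-balance residual ",
         format(max(resid)), ")", call. = FALSE)
  other <- setdiff(names(totals), sp)
  list(free = c(free, totals[other])[c(sp, other)], complexes = cplx)
}
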