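#' Binding topology of the BCL-2 family network
#'
#' The network couples anti-apoptotic proteins (MCL-1, BCL-2) to
#' pro-apoptotic partners (BIM, NOXA, activated BAX) through reversible
#' 1:1 complexes. The default topology has five pairs, one per packaged
#' dissociation constant:
#'
#' | pair            | Kd key | default (nM) |
#' |-----------------|--------|--------------|
#' | MCL-1 : BIM     | Kd_3   | 2.0          |
#' | MCL-1 : NOXA    | Kd_4   | 22.0         |
#' | BCL-2 : BIM     | Kd_5   | 40.0         |
#' | MCL-1 : BAX*    | Kd_6   | 2.5          |
#' | BCL-2 : BAX*    | Kd_7   | 68.0         |
#'
#' The assignment maps the smallest Kd to the strongest reported
#' interaction (MCL-1:BIM); NOXA binds only MCL-1. Any other set of pairs
#' can be supplied: `anti` must be one of `"MCL1"`, `"BCL2"`, `pro` one of
#' `"BIM"`, `"NOXA"`, `"BAXa"` (activated BAX), and `kd` names a Kd entry
#' of the kinetic parameter set.
#'
#' @param pairs a data.frame with columns `anti`, `pro`, `kd`.
#' @return An object of class `"apoptosis_topology"`.
#' @examples
#' default_topology()
#' @export
pc_topology <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("anti", "pro", "kd") %in% names(pairs)))
  if (!all(pairs$anti %in% c("MCL1", "BCL2")))
    stop("'anti' entries must be \"MCL1\" or \"BCL2\"", call. = FALSE)
  if (!all(pairs$pro %in% c("BIM", "NOXA", "BAXa")))
    stop("'pro' entries must be \"BIM\", \"NOXA\" or \"BAXa\"", call. = FALSE)
  if (anyDuplicated(paste(pairs$anti, pairs$pro)))
    stop("duplicated binding pair", call. = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  pairs$complex <- paste(pairs$anti, pairs$pro, sep = ":")
  structure(pairs, class = c("apoptosis_topology", "data.frame"))
}

#' @rdname pc_topology
#' @export
default_topology <- function() {
  pc_topology(data.frame(
    anti = c("MCL1", "MCL1", "BCL2", "MCL1", "BCL2"),
    pro  = c("BIM",  "NOXA", "BIM",  "BAXa", "BAXa"),
    kd   = c("Kd_3", "Kd_4", "Kd_5", "Kd_6", "Kd_7"),
    stringsAsFactors = FALSE))
}

#' @export
print.apoptosis_topology <- function(x, ...) {
  cat("BCL-2 family binding topology (", nrow(x), " pairs)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# species bookkeeping shared by the solvers -------------------------------

species_names <- function() c("BIM", "NOXA", "BCL2", "MCL1", "BAX", "BAXa")

state_names <- function(topo) c(species_names(), topo$complex)

# Kd vector (nM) in topology order
topology_kd <- function(params, topo) {
  kd <- unlist(params[topo$kd], use.names = FALSE)
  if (any(is.na(kd)))
    stop("topology references Kd entries absent from the parameter set",
         call. = FALSE)
  names(kd) <- topo$complex
  kd
}

# decay rate of each complex: the faster partner's rate (the conservative
# default keeping complexes from becoming permanent sinks); "none" -> 0
complex_decay_rates <- function(params, topo, rule = c("faster", "none")) {
  rule <- match.arg(rule)
  if (rule == "none") return(stats::setNames(rep(0, nrow(topo)), topo$complex))
  d <- c(BIM = params$d_BIM, NOXA = params$d_NOXA, BCL2 = params$d_BCL2,
         MCL1 = params$d_MCL1, BAX = params$d_BAX, BAXa = params$d_BAX)
  stats::setNames(pmax(d[topo$anti], d[topo$pro]), topo$complex)
}
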