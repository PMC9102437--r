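#' Read and write parameter documents
#'
#' A parameter document is a flat key/value map (JSON or YAML, chosen by
#' file extension) whose keys are the kinetic constants (`g_p0`,
#' `d_MCL1` ... `d_BAX`, `Kd_3` ... `Kd_7`, `k_plus`, `k1`, `k2`,
#' `a_BCL2`, `s_MCL1`, `s_BCL2`, `s_BIM`, `s_NOXA`) and the death
#' parameters (`gamma`, `K_BAX`, `hill_n`, `kappa`, `alpha`, `beta`).
#' Missing keys default to the annotated values; unknown keys are
#' rejected. All validation violations are reported together.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return for `read_parameters()`: list with `kinetic`
#'   ([apoptosis_parameters()]), `death` ([death_parameters()]) and
#'   `topology` ([default_topology()]).
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else stop("unsupported extension (use .json, .yaml or .yml): ", path,
            call. = FALSE)
  if (is.null(doc)) doc <- list()
  kin_keys <- names(formals(apoptosis_parameters))
  death_keys <- setdiff(names(formals(death_parameters)), "fmode")
  known <- c(kin_keys, death_keys, "fmode")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  kin <- do.call(apoptosis_parameters,
                 doc[intersect(names(doc), kin_keys)])
  dth <- do.call(death_parameters,
                 doc[intersect(names(doc), c(death_keys, "fmode"))])
  list(kinetic = kin, death = dth, topology = default_topology())
}

#' @rdname read_parameters
#' @param params an [apoptosis_parameters()] set.
#' @param dp a [death_parameters()] set.
#' @export
write_parameters <- function(params, dp, path) {
  doc <- c(unclass(params),
           unclass(dp)[c("gamma", "K_BAX", "hill_n", "kappa", "alpha",
                         "beta", "fmode")])
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(doc, path)
  else stop("unsupported extension (use .json, .yaml or .yml): ", path,
            call. = FALSE)
  invisible(path)
}

#' Tidy CSV export and import
#'
#' Trajectories are written long-form with columns `time_d`, `species`,
#' `concentration_uM`, `condition`; survival curves with `time_d`,
#' `percent_live`, `condition`, `replicate`; protein measurements with
#' `protein`, `condition`, `replicate`, `value`.
#'
#' @param x object to write (a `network_trajectory` or a data.frame of
#'   the matching dialect).
#' @param path CSV file path.
#' @return the path (writers, invisibly) or the data.frame (readers).
#' @export
write_trajectory_csv <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_survival_csv <- function(x, path) {
  need <- c("time_d", "percent_live", "condition")
  stopifnot(all(need %in% names(x)))
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  utils::write.csv(as.data.frame(x)[, c(need, "replicate")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_d", "percent_live", "condition")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("survival CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname write_trajectory_csv
#' @export
write_protein_csv <- function(x, path) {
  need <- c("protein", "condition", "replicate", "value")
  stopifnot(all(need %in% names(x)))
  utils::write.csv(as.data.frame(x)[, need], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_protein_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "condition", "replicate", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("protein CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' Reproducibility record for a run
#'
#' @param seed the RNG seed used.
#' @param params,dp the parameter sets used.
#' @return list with the seed, a digest of the parameter document, and
#'   the package version.
#' @export
run_record <- function(seed, params, dp) {
  doc <- c(unclass(params), unclass(dp))
  txt <- paste(names(doc), vapply(doc, format, character(1)),
               collapse = ";")
  list(seed = seed,
       parameter_hash = sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
         .Machine$integer.max,
       package_version = as.character(utils::packageVersion("apoptosim")),
       timestamp = format(Sys.time(), tz = "UTC"))
}
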