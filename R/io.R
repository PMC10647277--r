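#' Write a trajectory to CSV with a JSON sidecar
#'
#' Writes the tidy trajectory table (`time_h`, `area_um2`, `a_over_a0`) to
#' `path` and a JSON sidecar `<path>.json` holding the parameters, seed,
#' closure flag and package version.
#'
#' @param traj a `wh_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "wh_trajectory"))
  write.csv(as.data.frame(traj)[, c("time_h", "area_um2", "a_over_a0")],
            path, row.names = FALSE)
  p <- attr(traj, "params")
  meta <- list(
    params = p[c("Tm", "Td", "rho", "delta", "b0", "max_time",
                 "bias_enabled", "bias_exclude", "prolif_enabled",
                 "refill_enabled", "n_rows", "n_cols")],
    seed = attr(traj, "seed"),
    closed = attr(traj, "closed"),
    package_version = as.character(packageVersion("scratchCA"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path; the `<path>.json` sidecar is read when present.
#' @return a `wh_trajectory` (with reconstructed `params` when the sidecar
#'   carries them).
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_h", "area_um2", "a_over_a0") %in% names(d)))
  side <- paste0(path, ".json")
  closed <- any(d$area_um2 == 0)
  seed <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$closed)) closed <- isTRUE(meta$closed)
    seed <- meta$seed
    if (!is.null(meta$params$Tm)) {
      pm <- meta$params
      attr(d, "params") <- ca_params(
        Tm = pm$Tm, Td = pm$Td, rho = pm$rho, b0 = pm$b0, delta = pm$delta,
        n_rows = pm$n_rows, max_time = pm$max_time,
        bias_enabled = isTRUE(pm$bias_enabled),
        bias_exclude = if (is.null(pm$bias_exclude)) "diagonals" else pm$bias_exclude,
        prolif_enabled = isTRUE(pm$prolif_enabled),
        refill_enabled = isTRUE(pm$refill_enabled),
        seed = seed, warn_range = FALSE
      )
    }
  }
  attr(d, "closed") <- closed
  attr(d, "seed") <- seed
  class(d) <- c("wh_trajectory", "data.frame")
  d
}

#' Write a lattice snapshot as a plain-text 0/1 matrix
#'
#' @param state a `lattice_state`.
#' @param path output text path (one lattice row per line, sites separated by
#'   single spaces).
#' @return `path`, invisibly.
#' @export
write_grid_snapshot <- function(state, path) {
  stopifnot(inherits(state, "lattice_state"))
  write.table(state$grid, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read simulation parameters from a YAML config file
#'
#' The file mirrors the [ca_params()] argument names (`Tm`, `Td`, `rho`,
#' `b0`, `delta`, `n_rows`, `max_time`, `bias_enabled`, `bias_exclude`,
#' `prolif_enabled`, `refill_enabled`, `seed`).
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file (e.g. from CLI
#'   flags).
#' @return a [ca_params()] object.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  allowed <- c("Tm", "Td", "rho", "b0", "delta", "n_rows", "max_time",
               "bias_enabled", "bias_exclude", "prolif_enabled",
               "refill_enabled", "seed", "warn_range")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(ca_params, cfg)
}
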