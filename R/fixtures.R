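.cell_lines_md5 <- "6a6c950fdd71dae3cacb965af07bb89d"

#' Bundled cell-line validation table
#'
#' Loads the bundled table of characteristic parameters for the nine cell
#' lines (21 records) used to validate the model: seeding density `rho`
#' (cells/um^2), measured closure rate `alpha_exp` (1/h), initial wound width
#' `b0` (um), doubling time `Td` (h) and migration time `Tm` (h). Values not
#' reported in the original sources are `NA` (never zero-filled); the
#' `derived` column lists fields that were derived from raw data rather than
#' read off directly. Record 15's density exceeds the full-coverage bound for
#' any physiological cell size; it is kept verbatim and simulation clamps the
#' occupancy fraction at 1.
#'
#' @param check_integrity verify the file's md5 checksum. Default `TRUE`.
#' @return data frame with 21 rows and columns `cell_line`, `id`, `rho`,
#'   `alpha_exp`, `b0`, `Td`, `Tm`, `derived`, `reference`.
#' @export
load_cell_lines <- function(check_integrity = TRUE) {
  path <- system.file("extdata", "cell_lines.csv", package = "scratchCA",
                      mustWork = TRUE)
  if (check_integrity) {
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, .cell_lines_md5)) {
      stop("bundled cell_lines.csv failed its integrity check (md5 ", sum,
           ")", call. = FALSE)
    }
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(d) == 21L)
  d
}

#' Bundled model parameter table
#'
#' The physiological ranges of the five model inputs (Tm, Td, rho, delta,
#' b0) and of the derived/output quantities (D, v, alpha).
#'
#' @return data frame with columns `parameter`, `description`, `low`, `high`,
#'   `unit`, `role`.
#' @export
load_param_table <- function() {
  path <- system.file("extdata", "parameter_ranges.csv", package = "scratchCA",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic experimental closure curve
#'
#' Generates an idealized measured `A/A0` series: the line
#' `max(0, 1 - alpha * t)` plus Gaussian noise, truncated by clipping to
#' `[0, 1.05]`. Used as a stand-in for digitized experimental curves in tests
#' and the `validate` CLI command (raw in vitro series are not bundled).
#'
#' @param alpha closure rate (1/h), `>= 0`.
#' @param noise_sd standard deviation of the additive noise. Default 0.02.
#' @param t_end last time point (h); default covers closure plus 20%.
#' @param dt sampling interval (h). Default 0.5.
#' @param seed optional RNG seed.
#' @return data frame with columns `time_h`, `a_over_a0`.
#' @export
make_synthetic_experiment <- function(alpha, noise_sd = 0.02, t_end = NULL,
                                      dt = 0.5, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  }
  .check_positive(dt, "dt")
  if (is.null(t_end)) t_end <- if (alpha > 0) 1.2 / alpha else 24
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_end, by = dt)
  y <- pmax(0, 1 - alpha * t)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  y <- pmin(pmax(y, 0), 1.05)
  data.frame(time_h = t, a_over_a0 = y)
}
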