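## Physiological parameter box used for range warnings and as the default
## sampling box of the sensitivity / scaling analyses.
.physio_box <- list(
  Tm    = c(0.005, 0.5),   # h
  Td    = c(12, 40),       # h
  rho   = c(1e-6, 1e-3),   # cells / um^2
  delta = c(15, 25),       # um
  b0    = c(370, 900)      # um
)

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive finite number", call. = FALSE)
  }
  invisible(x)
}

#' Per-step migration and proliferation probabilities
#'
#' The probability that an active (non-quiescent) cell migrates rather than
#' divides in one automaton step is set by the competition of the two rate
#' processes: `Pm = (1/Tm) / (1/Tm + 1/Td)` and `Pd = (1/Td) / (1/Td + 1/Tm)`,
#' so that `Pm + Pd = 1`.
#'
#' @param Tm characteristic migration time (h): time for a cell to travel one
#'   cell diameter `delta`.
#' @param Td doubling time (h).
#' @return named numeric vector with elements `Pm` and `Pd`.
#' @examples
#' migration_probability(Tm = 0.5, Td = 12)  # Pd = 0.04
#' @export
migration_probability <- function(Tm, Td) {
  .check_positive(Tm, "Tm")
  .check_positive(Td, "Td")
  pm <- (1 / Tm) / (1 / Tm + 1 / Td)
  c(Pm = pm, Pd = 1 - pm)
}

#' Migration time from the random motility coefficient
#'
#' `Tm = delta^2 / D`, where `D` (um^2/h) is the diffusion-like random
#' motility coefficient of the cell line.
#'
#' @param delta cell size / lattice spacing (um).
#' @param D random motility coefficient (um^2/h).
#' @return migration time Tm (h).
#' @examples
#' tm_from_motility(delta = 20, D = 1e4)  # 0.04 h
#' @export
tm_from_motility <- function(delta, D) {
  .check_positive(delta, "delta")
  .check_positive(D, "D")
  delta^2 / D
}

#' Migration/proliferation time ratio Phi
#'
#' The dimensionless ratio `Phi = Tm/Td` compares the contributions of
#' migration and proliferation: small Phi means migration-dominated closure.
#'
#' @param Tm migration time (h); may be a vector.
#' @param Td doubling time (h); may be a vector.
#' @return `Tm/Td`, dimensionless.
#' @export
phi <- function(Tm, Td) {
  if (any(!is.finite(Tm)) || any(Tm <= 0)) stop("`Tm` must be positive", call. = FALSE)
  if (any(!is.finite(Td)) || any(Td <= 0)) stop("`Td` must be positive", call. = FALSE)
  Tm / Td
}

#' Duration of one automaton sweep
#'
#' One sweep advances physical time by `dt = 1 / (1/Tm + 1/Td)`, so that the
#' per-step probabilities are exactly rate times dt: `Pm = dt/Tm`,
#' `Pd = dt/Td`. Migration events then occur at rate `1/Tm` and division
#' events at rate `1/Td` for an unconstrained cell.
#'
#' @inheritParams migration_probability
#' @return time step (h).
#' @export
time_step <- function(Tm, Td) {
  .check_positive(Tm, "Tm")
  .check_positive(Td, "Td")
  1 / (1 / Tm + 1 / Td)
}

## Lattice geometry: wound band width from b0/delta, reservoirs half as wide.
.geometry <- function(b0, delta, n_rows = NULL) {
  n_w <- as.integer(round(b0 / delta))
  if (n_w < 1L) {
    stop("wound band is empty: round(b0/delta) < 1 (b0 = ", b0,
         ", delta = ", delta, ")", call. = FALSE)
  }
  n_l <- as.integer(ceiling(n_w / 2))
  n_cols <- n_l + n_w + n_l
  if (is.null(n_rows)) n_rows <- n_cols
  n_rows <- as.integer(n_rows)
  if (n_rows < 1L) stop("`n_rows` must be >= 1", call. = FALSE)
  ## 1-based column indices; wound_band is inclusive [start, end]
  band <- c(n_l + 1L, n_l + n_w)
  center <- n_l + as.integer(ceiling(n_w / 2))
  list(n_w = n_w, n_l = n_l, n_r = n_l, n_cols = n_cols, n_rows = n_rows,
       wound_band = band, wound_center_col = center)
}

#' Simulation parameters for one wound-healing run
#'
#' Bundles the biological and geometric inputs of one cellular-automaton
#' simulation and derives the lattice geometry, the per-step probabilities
#' and the initial occupancy fraction `f = min(1, rho * delta^2)`.
#'
#' The lattice has `round(b0/delta)` initially empty central columns (the
#' wound band W) flanked by two reservoirs L and R, each `ceiling(n_W/2)`
#' columns wide, seeded by independent per-site occupation with probability
#' `f`. Densities above confluence (`rho * delta^2 > 1`) are clamped to full
#' coverage with a warning.
#'
#' @param Tm characteristic migration time (h).
#' @param Td doubling time (h).
#' @param rho seeding cell density (cells/um^2).
#' @param b0 initial wound width (um).
#' @param delta cell size = lattice spacing (um). Default 20.
#' @param n_rows lattice row count; default makes the lattice square.
#' @param max_time simulation horizon (h). Default 240.
#' @param bias_enabled should migration/division targets be biased toward the
#'   wound? Default `FALSE` (isotropic), the condition used for all shipped
#'   analyses; see the methods vignette.
#' @param bias_exclude which backward sites the bias removes:
#'   `"diagonals"` (default; removes the two backward diagonal sites, leaving
#'   7 of the 9-site Moore block including self) or `"all"` (removes all
#'   three backward sites).
#' @param prolif_enabled if `FALSE`, cells never divide (the migration draw
#'   is unchanged; a non-migrating cell simply rests). Used for the
#'   critical-Phi analysis.
#' @param refill_enabled refill vacancies in the first/last columns each step
#'   with probability `f` (reservoir boundary). Default `TRUE`.
#' @param seed RNG seed used by [simulate_wound()] / [init_lattice()]; `NULL`
#'   leaves the current RNG state untouched.
#' @param warn_range warn when a parameter leaves its physiological range or
#'   when `rho` exceeds confluence. Default `TRUE`.
#' @return an object of class `ca_params`.
#' @examples
#' p <- ca_params(Tm = 0.075, Td = 24, rho = 1e-3, b0 = 575, seed = 1)
#' p
#' @export
ca_params <- function(Tm, Td, rho, b0, delta = 20, n_rows = NULL,
                      max_time = 240, bias_enabled = FALSE,
                      bias_exclude = c("diagonals", "all"),
                      prolif_enabled = TRUE, refill_enabled = TRUE,
                      seed = NULL, warn_range = TRUE) {
  .check_positive(Tm, "Tm")
  .check_positive(Td, "Td")
  .check_positive(b0, "b0")
  .check_positive(delta, "delta")
  .check_positive(max_time, "max_time")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 0) {
    stop("`rho` must be a single non-negative finite number", call. = FALSE)
  }
  bias_exclude <- match.arg(bias_exclude)

  f_raw <- rho * delta^2
  f <- min(1, f_raw)
  if (warn_range && f_raw > 1) {
    warning("rho = ", format(rho), " exceeds confluence for delta = ", delta,
            " um; occupancy fraction clamped to 1", call. = FALSE)
  }
  if (warn_range) {
    chk <- list(Tm = Tm, Td = Td, rho = rho, delta = delta, b0 = b0)
    for (nm in names(chk)) {
      r <- .physio_box[[nm]]
      if (chk[[nm]] < r[1] || chk[[nm]] > r[2]) {
        warning("`", nm, "` = ", format(chk[[nm]]),
                " is outside the physiological range [", r[1], ", ", r[2], "]",
                call. = FALSE)
      }
    }
  }

  geo <- .geometry(b0, delta, n_rows)
  pr <- migration_probability(Tm, Td)
  p <- c(
    list(Tm = Tm, Td = Td, rho = rho, delta = delta, b0 = b0,
         max_time = max_time, bias_enabled = isTRUE(bias_enabled),
         bias_exclude = bias_exclude, prolif_enabled = isTRUE(prolif_enabled),
         refill_enabled = isTRUE(refill_enabled), seed = seed,
         f = f, Pm = unname(pr["Pm"]), Pd = unname(pr["Pd"]),
         dt = time_step(Tm, Td)),
    geo
  )
  class(p) <- "ca_params"
  p
}

## integer bias code for the C++ core
.bias_code <- function(params) {
  if (!params$bias_enabled) 0L
  else if (identical(params$bias_exclude, "diagonals")) 1L
  else 2L
}

#' @export
print.ca_params <- function(x, ...) {
  cat("<ca_params> wound-healing CA parameter set\n")
  cat(sprintf("  Tm = %g h, Td = %g h  (Pm = %.4f, Pd = %.4f, dt = %.4g h)\n",
              x$Tm, x$Td, x$Pm, x$Pd, x$dt))
  cat(sprintf("  rho = %g cells/um^2 (occupancy f = %.3g), delta = %g um, b0 = %g um\n",
              x$rho, x$f, x$delta, x$b0))
  cat(sprintf("  lattice %d x %d (L/W/R = %d/%d/%d cols), wound cols %d..%d, center %d\n",
              x$n_rows, x$n_cols, x$n_l, x$n_w, x$n_r,
              x$wound_band[1], x$wound_band[2], x$wound_center_col))
  cat(sprintf("  max_time = %g h, bias = %s%s, proliferation %s, boundary refill %s\n",
              x$max_time,
              if (x$bias_enabled) "on" else "off (isotropic)",
              if (x$bias_enabled) paste0(" [", x$bias_exclude, "]") else "",
              if (x$prolif_enabled) "on" else "off",
              if (x$refill_enabled) "on" else "off"))
  if (!is.null(x$seed)) cat(sprintf("  seed = %s\n", format(x$seed)))
  invisible(x)
}
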