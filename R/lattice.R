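#' Initialize the lattice for a wound-healing simulation
#'
#' Builds the L/W/R domain: the central wound band of `round(b0/delta)`
#' columns starts empty, and every site of the two lateral reservoirs is
#' occupied independently with probability `f = min(1, rho * delta^2)`.
#'
#' If `params$seed` is non-`NULL`, the RNG is seeded before drawing the
#' initial configuration; otherwise the current RNG state is used.
#'
#' @param params a [ca_params()] object.
#' @return an object of class `lattice_state`: a list with the integer
#'   occupancy matrix `grid` (1 = occupied), elapsed `time` (h),
#'   `step_index`, the fixed `wound_center_col`, the initial `wound_band`
#'   (inclusive column range), `delta`, `f` and the generating `params`.
#' @examples
#' p <- ca_params(Tm = 0.075, Td = 24, rho = 1e-3, b0 = 575, seed = 1)
#' s <- init_lattice(p)
#' s
#' @export
init_lattice <- function(params) {
  stopifnot(inherits(params, "ca_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  grid <- matrix(0L, nrow = params$n_rows, ncol = params$n_cols)
  lateral <- c(seq_len(params$n_l),
               seq(params$wound_band[2] + 1L, params$n_cols))
  if (params$f > 0) {
    grid[, lateral] <- matrix(
      rbinom(params$n_rows * length(lateral), 1L, params$f),
      nrow = params$n_rows
    )
  }
  state <- list(grid = grid, time = 0, step_index = 0L,
                wound_center_col = params$wound_center_col,
                wound_band = params$wound_band,
                delta = params$delta, f = params$f, params = params)
  class(state) <- "lattice_state"
  state
}

#' Empty neighbor sites available to a cell
#'
#' Returns the empty sites of the Moore (3 x 3) neighborhood of an occupied
#' site, with periodic wrap in the row direction and hard column edges. When
#' the directional bias is enabled, cells left of the wound center column
#' lose their backward (leftward) sites as targets — by default the two
#' backward diagonals, reducing the 9-site block (including self) to 7 —
#' and mirror-image for cells right of the center; cells exactly on the
#' center column are unbiased.
#'
#' @param state a `lattice_state`.
#' @param row,col 1-based coordinates of an occupied site.
#' @param bias_enabled,bias_exclude override the values carried by
#'   `state$params` (both optional).
#' @return an integer matrix with columns `row`, `col`, one row per empty
#'   candidate site (0 rows if the cell is quiescent).
#' @export
candidate_sites <- function(state, row, col,
                            bias_enabled = NULL, bias_exclude = NULL) {
  stopifnot(inherits(state, "lattice_state"))
  g <- state$grid
  n <- nrow(g); m <- ncol(g)
  if (row < 1 || row > n || col < 1 || col > m) {
    stop("(row, col) = (", row, ", ", col, ") is outside the lattice",
         call. = FALSE)
  }
  if (g[row, col] != 1L) {
    stop("site (", row, ", ", col, ") is not occupied", call. = FALSE)
  }
  if (is.null(bias_enabled)) bias_enabled <- isTRUE(state$params$bias_enabled)
  if (is.null(bias_exclude)) {
    bias_exclude <- state$params$bias_exclude
    if (is.null(bias_exclude)) bias_exclude <- "diagonals"
  }
  center <- state$wound_center_col
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  keep <- rep(TRUE, 8L)
  if (bias_enabled && col != center) {
    back <- if (col < center) -1L else 1L
    if (identical(bias_exclude, "diagonals")) {
      keep <- !(dc == back & dr != 0L)
    } else {
      keep <- dc != back
    }
  }
  cand <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("row", "col")))
  for (i in which(keep)) {
    cc <- col + dc[i]
    if (cc < 1L || cc > m) next
    rr <- ((row - 1L + dr[i]) %% n) + 1L
    if (g[rr, cc] == 0L) cand <- rbind(cand, c(rr, cc))
  }
  cand
}

#' Advance the lattice by one sweep
#'
#' Visits every occupied site once, in a fresh random permutation; each cell
#' draws lambda ~ U(0,1) and, if it has empty neighbors, migrates
#' (lambda < Pm) into a uniformly chosen candidate or else places a daughter
#' there; cells with no empty neighbor are quiescent. Vacant sites in the
#' first and last columns then refill with probability `f`, and time advances
#' by `dt = 1/(1/Tm + 1/Td)`. Uses the current RNG state.
#'
#' @param state a `lattice_state`.
#' @param params the governing [ca_params()]; defaults to the set stored in
#'   `state`.
#' @return the updated `lattice_state`.
#' @export
ca_step <- function(state, params = state$params) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "ca_params"))
  if (state$time >= params$max_time) {
    stop("state is already at or past max_time = ", params$max_time, " h",
         call. = FALSE)
  }
  state$grid <- cpp_sweep(state$grid, params$Pm,
                          if (params$refill_enabled) params$f else 0,
                          state$wound_center_col - 1L, .bias_code(params),
                          params$prolif_enabled, params$refill_enabled)
  state$step_index <- state$step_index + 1L
  state$time <- state$step_index * params$dt
  state
}

#' Simulate wound closure
#'
#' Runs [init_lattice()] and then [ca_step()] sweeps until the measured wound
#' area (see [wound_area()]) reaches zero or `max_time` is exceeded, recording
#' the cell-free area after every sweep. Identical `params` and seed yield a
#' bit-identical trajectory.
#'
#' @param params a [ca_params()] object.
#' @param seed overrides `params$seed`; `NULL` together with a `NULL`
#'   `params$seed` uses the current RNG state.
#' @param keep_grid attach the final occupancy grid as attribute
#'   `final_grid`. Default `FALSE`.
#' @return a `wh_trajectory`: a data frame with columns `time_h`, `area_um2`,
#'   `a_over_a0` and attributes `params`, `closed`, `seed`.
#' @examples
#' p <- ca_params(Tm = 0.075, Td = 24, rho = 2.5e-3, b0 = 371, seed = 42)
#' traj <- simulate_wound(p)
#' attr(traj, "closed")
#' @export
simulate_wound <- function(params, seed = params$seed, keep_grid = FALSE) {
  stopifnot(inherits(params, "ca_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  p$seed <- NULL
  state <- init_lattice(p)
  max_steps <- as.integer(ceiling(params$max_time / params$dt))
  res <- cpp_simulate(state$grid, params$Pm,
                      if (params$refill_enabled) params$f else 0,
                      state$wound_center_col - 1L,
                      state$wound_band[1] - 1L, state$wound_band[2] - 1L,
                      .bias_code(params), params$prolif_enabled,
                      params$refill_enabled, max_steps)
  areas <- as.numeric(res$areas) * params$delta^2
  times <- (seq_along(areas) - 1) * params$dt
  a0 <- areas[1]
  norm <- if (a0 > 0) areas / a0 else rep(NA_real_, length(areas))
  traj <- data.frame(time_h = times, area_um2 = areas, a_over_a0 = norm)
  attr(traj, "params") <- params
  attr(traj, "closed") <- isTRUE(res$closed)
  attr(traj, "seed") <- seed
  if (keep_grid) attr(traj, "final_grid") <- res$grid
  class(traj) <- c("wh_trajectory", "data.frame")
  traj
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> %d x %d grid, %d cells, t = %.3f h (step %d)\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), x$time, x$step_index))
  cat(sprintf("  wound cols %d..%d (center %d), delta = %g um, f = %.3g\n",
              x$wound_band[1], x$wound_band[2], x$wound_center_col,
              x$delta, x$f))
  invisible(x)
}

#' @export
print.wh_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<wh_trajectory> %d samples over %.2f h, %s\n",
              nrow(x), x$time_h[nrow(x)],
              if (isTRUE(attr(x, "closed"))) "wound closed" else "wound open"))
  if (!is.null(p)) {
    cat(sprintf("  Tm = %g h, Td = %g h, rho = %g, b0 = %g um, delta = %g um\n",
                p$Tm, p$Td, p$rho, p$b0, p$delta))
  }
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... (", nrow(x) - 4, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
plot.wh_trajectory <- function(x, ...) {
  plot(x$time_h, x$a_over_a0, type = "l", xlab = "time (h)",
       ylab = expression(A / A[0]), ylim = c(0, max(1, x$a_over_a0)), ...)
  invisible(x)
}
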