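#' Cell-free wound area of a lattice state
#'
#' The in silico analogue of the image-based cell-free area: the number of
#' empty sites within the initial wound band that belong to a cell-free patch
#' of at least two sites (i.e., have at least one empty Moore neighbor,
#' rows wrapping), times `delta^2`. Isolated single-site vacancies inside the
#' repopulated sheet are ordinary monolayer texture, below the resolution of
#' image-based wound-edge detection, and do not count; the wound is closed
#' (area exactly zero) once every remaining vacancy in the scratch zone is
#' such an isolated pore.
#'
#' @param state a `lattice_state` (any list with elements `grid`,
#'   `wound_band` and `delta` works, which makes hand-built grids easy to
#'   test).
#' @return wound area (um^2).
#' @export
wound_area <- function(state) {
  g <- state$grid
  band <- state$wound_band
  stopifnot(is.matrix(g), length(band) == 2L, band[1] >= 1,
            band[2] <= ncol(g), band[1] <= band[2])
  n <- nrow(g); m <- ncol(g)
  total <- 0L
  for (cl in band[1]:band[2]) {
    for (r in seq_len(n)) {
      if (g[r, cl] == 1L) next
      open <- FALSE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          cc <- cl + dc
          if (cc < 1L || cc > m) next
          rr <- ((r - 1L + dr) %% n) + 1L
          if (g[rr, cc] == 0L) { open <- TRUE; break }
        }
        if (open) break
      }
      if (open) total <- total + 1L
    }
  }
  total * state$delta^2
}

## first time a decreasing series crosses a level, linearly interpolated
.cross_time <- function(t, y, level) {
  k <- which(y <= level)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1L) return(t[1])
  t[k - 1] + (level - y[k - 1]) * (t[k] - t[k - 1]) / (y[k] - y[k - 1])
}

#' Extract wound-closure kinetics from a trajectory
#'
#' The closure rate `alpha` is the negative slope of the ordinary
#' least-squares fit of `A/A0` against time over the window from `t = 0`
#' until `A/A0` first drops to `fit_floor` (default 0.1; the flat closed tail
#' is excluded), or the whole trajectory if that level is never reached.
#' `t_half` is the first time `A/A0 <= 0.5` (linear interpolation between
#' samples); `t_closure` the first time the area is exactly zero (`NA` if the
#' wound never closes); and the front velocity is `v = alpha * b0 / 2` (two
#' fronts sharing the areal closure rate).
#'
#' @param traj a `wh_trajectory`, or any data frame with columns `time_h` and
#'   `a_over_a0` (and optionally `area_um2`).
#' @param fit_floor A/A0 level ending the fit window. Default 0.1.
#' @return an object of class `closure_metrics` with elements `alpha` (1/h),
#'   `t_half` (h), `t_closure` (h or `NA`), `v_front` (um/h or `NA` when no
#'   `b0` is available), `r_squared`, `fit_window`, `n_fit` and `slope` (the
#'   raw OLS slope, before clamping `alpha` at zero).
#' @examples
#' tr <- data.frame(time_h = 0:10, a_over_a0 = pmax(0, 1 - 0.1 * (0:10)))
#' tr$area_um2 <- tr$a_over_a0 * 1e5
#' fit_closure_rate(tr)  # alpha = 0.1/h, t_half = 5 h, t_closure = 10 h
#' @export
fit_closure_rate <- function(traj, fit_floor = 0.1) {
  t <- traj$time_h
  a <- traj$a_over_a0
  if (is.null(t) || is.null(a)) {
    stop("`traj` needs columns `time_h` and `a_over_a0`", call. = FALSE)
  }
  if (length(t) < 3L) {
    stop("at least 3 trajectory points are needed to fit a closure rate",
         call. = FALSE)
  }
  end <- which(a <= fit_floor)[1]
  if (is.na(end)) end <- length(t)
  end <- max(end, 3L)
  tw <- t[1:end]; aw <- a[1:end]
  if (sd(tw) == 0) stop("degenerate fit: no variance in time", call. = FALSE)
  fit <- lm(aw ~ tw)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared

  area <- traj$area_um2
  t_closure <- if (!is.null(area)) {
    k <- which(area == 0)[1]
    if (is.na(k)) NA_real_ else t[k]
  } else {
    k <- which(a <= 0)[1]
    if (is.na(k)) NA_real_ else t[k]
  }
  p <- attr(traj, "params")
  alpha <- max(0, -slope)
  out <- list(
    alpha = alpha,
    t_half = .cross_time(t, a, 0.5),
    t_closure = t_closure,
    v_front = if (!is.null(p)) alpha * p$b0 / 2 else NA_real_,
    r_squared = r2,
    fit_window = c(t_start = tw[1], t_end = tw[end]),
    n_fit = end,
    slope = slope
  )
  class(out) <- "closure_metrics"
  out
}

#' @export
print.closure_metrics <- function(x, ...) {
  cat("<closure_metrics>\n")
  cat(sprintf("  alpha     = %.5g 1/h  (R^2 = %.4f, fit window %.2f..%.2f h, n = %d)\n",
              x$alpha, x$r_squared, x$fit_window[1], x$fit_window[2], x$n_fit))
  cat(sprintf("  t_half    = %s h\n",
              if (is.na(x$t_half)) "NA" else format(x$t_half, digits = 4)))
  cat(sprintf("  t_closure = %s h\n",
              if (is.na(x$t_closure)) "NA (not closed)" else format(x$t_closure, digits = 4)))
  if (!is.na(x$v_front)) cat(sprintf("  v_front   = %.4g um/h\n", x$v_front))
  invisible(x)
}

#' Pearson correlation between simulated and experimental closure curves
#'
#' Linearly interpolates the simulated `A/A0` curve onto the experimental
#' time points (those inside the simulated time span) and returns the Pearson
#' correlation coefficient.
#'
#' @param sim a `wh_trajectory` (or data frame with `time_h`, `a_over_a0`).
#' @param exp a data frame whose first two columns are time (h) and `A/A0`
#'   (column names `time_h`, `a_over_a0` are used when present).
#' @return Pearson correlation coefficient (dimensionless).
#' @export
compare_to_experiment <- function(sim, exp) {
  ts <- sim$time_h; as_ <- sim$a_over_a0
  if (is.null(ts) || is.null(as_)) {
    stop("`sim` needs columns `time_h` and `a_over_a0`", call. = FALSE)
  }
  te <- if (!is.null(exp$time_h)) exp$time_h else exp[[1]]
  ae <- if (!is.null(exp$a_over_a0)) exp$a_over_a0 else exp[[2]]
  inside <- te >= min(ts) & te <= max(ts)
  if (sum(inside) < 3L) {
    stop("experimental series has fewer than 3 points inside the simulated ",
         "time span [", format(min(ts)), ", ", format(max(ts)), "] h",
         call. = FALSE)
  }
  si <- approx(ts, as_, xout = te[inside])$y
  cor(si, ae[inside])
}
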