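#' Sweep the parameter box and collect (Phi, alpha) pairs
#'
#' Draws `n_sims` parameter triples — `Tm` log-uniform (so Phi covers its
#' span roughly evenly on the log scale), `Td` and `rho` uniform — with
#' `delta` and `b0` fixed, simulates each and fits the closure rate.
#'
#' @param n_sims number of simulations (2000 at full scale).
#' @param ranges a [param_ranges()] box.
#' @param master_seed master RNG seed.
#' @param tm_log sample `Tm` log-uniformly. Default `TRUE`.
#' @param max_time simulation horizon per run (h).
#' @return a batch table as from [run_batch()] (columns `Tm`, `Td`, `rho`,
#'   `phi`, `seed`, `closed`, `alpha`, `t_half`, `t_closure`, `r_squared`).
#' @export
phi_sweep <- function(n_sims, ranges = param_ranges(), master_seed = 1,
                      tm_log = TRUE, max_time = 240) {
  if (!is.numeric(n_sims) || length(n_sims) != 1L || n_sims < 1) {
    stop("`n_sims` must be a positive count", call. = FALSE)
  }
  n_sims <- as.integer(n_sims)
  set.seed(master_seed)
  Tm <- if (tm_log) {
    exp(runif(n_sims, log(ranges$Tm[1]), log(ranges$Tm[2])))
  } else {
    runif(n_sims, ranges$Tm[1], ranges$Tm[2])
  }
  sets <- data.frame(
    Tm = Tm,
    Td = runif(n_sims, ranges$Td[1], ranges$Td[2]),
    rho = runif(n_sims, ranges$rho[1], ranges$rho[2])
  )
  batch_seed <- sample.int(.Machine$integer.max, 1)
  run_batch(sets, ranges, master_seed = batch_seed, max_time = max_time)
}

#' Fit the power law alpha = a * Phi^(-b)
#'
#' Ordinary least squares of `log(alpha)` on `log(phi)`; the exponent is
#' `b = -slope` and the prefactor `a = exp(intercept)` (standard error of `a`
#' by the delta method). Only pairs with positive `alpha` and `phi` enter the
#' fit; rows flagged as non-closing (a `closed` column, when present) are
#' excluded with a message.
#'
#' @param pairs a data frame with columns `phi` and `alpha` (e.g. from
#'   [phi_sweep()]), optionally with a logical `closed` column.
#' @return an object of class `power_law_fit` with elements `a`, `b`, `a_se`,
#'   `b_se`, `n_points`, `n_excluded`, `phi_range`, `r_squared` and the
#'   underlying `lm` fit.
#' @examples
#' ph <- 10^seq(-4, -0.5, length.out = 50)
#' fit_power_law(data.frame(phi = ph, alpha = 2e-3 * ph^-0.66))
#' @export
fit_power_law <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("phi", "alpha") %in% names(pairs)))
  n0 <- nrow(pairs)
  if (!is.null(pairs$closed)) pairs <- pairs[pairs$closed %in% TRUE, ]
  keep <- is.finite(pairs$phi) & is.finite(pairs$alpha) &
    pairs$phi > 0 & pairs$alpha > 0
  d <- pairs[keep, ]
  n_excluded <- n0 - nrow(d)
  if (n_excluded > 0) {
    message(n_excluded, " of ", n0,
            " pairs excluded from the power-law fit (non-closing or non-positive)")
  }
  if (nrow(d) < 3L) {
    stop("need at least 3 usable (phi, alpha) pairs to fit the power law",
         call. = FALSE)
  }
  fit <- lm(log(alpha) ~ log(phi), data = d)
  cf <- summary(fit)$coefficients
  out <- list(
    a = exp(cf[1, 1]), b = -cf[2, 1],
    a_se = exp(cf[1, 1]) * cf[1, 2], b_se = cf[2, 2],
    n_points = nrow(d), n_excluded = n_excluded,
    phi_range = range(d$phi), r_squared = summary(fit)$r.squared,
    fit = fit
  )
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> alpha = a * Phi^(-b)\n")
  cat(sprintf("  a = %.4g 1/h (se %.2g), b = %.4g (se %.2g)\n",
              x$a, x$a_se, x$b, x$b_se))
  cat(sprintf("  n = %d pairs (%d excluded), Phi in [%.3g, %.3g], log-log R^2 = %.3f\n",
              x$n_points, x$n_excluded, x$phi_range[1], x$phi_range[2],
              x$r_squared))
  invisible(x)
}

#' Predict the closure rate from a fitted power law
#'
#' @param fit a `power_law_fit` (or any list with elements `a` and `b`).
#' @param phi dimensionless ratio Tm/Td; may be a vector, all entries
#'   positive.
#' @return predicted closure rate `a * phi^(-b)` (1/h).
#' @export
predict_alpha <- function(fit, phi) {
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("`phi` must be positive", call. = FALSE)
  }
  fit$a * phi^(-fit$b)
}

#' How much does proliferation contribute at a given Phi?
#'
#' For each grid value of Phi, runs matched pairs of simulations (same seed)
#' with proliferation enabled vs disabled (the migration draw is unchanged; a
#' non-migrating cell simply rests) at `n_seeds` seeds, and reports the
#' relative closure-rate change
#' `epsilon(Phi) = |alpha_full - alpha_no_prolif| / alpha_full`
#' computed on the ensemble means. The critical Phi is the smallest grid
#' value where `epsilon` exceeds `threshold`.
#'
#' `Td` is held fixed and `Tm = Phi * Td`, at full reservoir coverage, so
#' closure is never density-limited and the comparison isolates the
#' proliferation contribution.
#'
#' @param phi_grid positive Phi values (default: 7 log-spaced points covering
#'   1e-4 .. 0.5).
#' @param n_seeds matched seeds per grid point. Default 20.
#' @param Td fixed doubling time (h). Default 24.
#' @param rho seeding density; default full coverage.
#' @param b0,delta geometry (um).
#' @param threshold relative change defining "proliferation matters".
#'   Default 0.1.
#' @param master_seed master RNG seed.
#' @param max_time simulation horizon (h); generous because high-Phi runs
#'   close slowly. Default 2000.
#' @return an object of class `critical_phi`: list with `table` (per-Phi
#'   `phi`, `Tm`, `alpha_full`, `alpha_no_prolif`, `epsilon`, `n_closed_full`,
#'   `n_closed_np`), `critical_phi` (smallest grid Phi with
#'   `epsilon > threshold`, `NA` if none) and `threshold`.
#' @export
critical_phi_analysis <- function(phi_grid = 10^seq(-4, log10(0.5),
                                                    length.out = 7),
                                  n_seeds = 20, Td = 24, rho = 2.5e-3,
                                  b0 = 575, delta = 20, threshold = 0.1,
                                  master_seed = 1, max_time = 2000) {
  if (any(!is.finite(phi_grid)) || any(phi_grid <= 0)) {
    stop("`phi_grid` must be positive", call. = FALSE)
  }
  phi_grid <- sort(phi_grid)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_seeds)
  rows <- vector("list", length(phi_grid))
  for (k in seq_along(phi_grid)) {
    Tm <- phi_grid[k] * Td
    p_full <- ca_params(Tm = Tm, Td = Td, rho = rho, b0 = b0, delta = delta,
                        max_time = max_time, warn_range = FALSE)
    p_np <- ca_params(Tm = Tm, Td = Td, rho = rho, b0 = b0, delta = delta,
                      max_time = max_time, prolif_enabled = FALSE,
                      warn_range = FALSE)
    af <- anp <- numeric(n_seeds)
    cf <- cnp <- logical(n_seeds)
    for (s in seq_len(n_seeds)) {
      tf <- simulate_wound(p_full, seed = seeds[s])
      tn <- simulate_wound(p_np, seed = seeds[s])
      af[s] <- fit_closure_rate(tf)$alpha
      anp[s] <- fit_closure_rate(tn)$alpha
      cf[s] <- isTRUE(attr(tf, "closed"))
      cnp[s] <- isTRUE(attr(tn, "closed"))
    }
    mf <- mean(af); mnp <- mean(anp)
    rows[[k]] <- data.frame(
      phi = phi_grid[k], Tm = Tm, alpha_full = mf, alpha_no_prolif = mnp,
      epsilon = if (mf > 0) abs(mf - mnp) / mf else NA_real_,
      n_closed_full = sum(cf), n_closed_np = sum(cnp)
    )
  }
  tab <- do.call(rbind, rows)
  above <- which(tab$epsilon > threshold)
  res <- list(table = tab,
              critical_phi = if (length(above)) tab$phi[min(above)] else NA_real_,
              threshold = threshold)
  class(res) <- "critical_phi"
  res
}

#' @export
print.critical_phi <- function(x, ...) {
  cat("<critical_phi> proliferation contribution vs Phi\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("smallest grid Phi with epsilon > %g: %s\n", x$threshold,
              if (is.na(x$critical_phi)) "none" else format(x$critical_phi)))
  invisible(x)
}
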