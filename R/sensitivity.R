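#' Sampled parameter ranges for the sensitivity and scaling analyses
#'
#' The box of physiological variation for the three sampled inputs (Tm, Td,
#' rho), plus the two geometric parameters which are held fixed at their
#' mid-range values (delta = 20 um, b0 = 575 um) since they only set the
#' lattice scale.
#'
#' @param Tm,Td,rho length-2 numeric vectors `c(low, high)`.
#' @param delta,b0 fixed geometric values (um).
#' @return an object of class `param_ranges`.
#' @export
param_ranges <- function(Tm = c(0.005, 0.5), Td = c(12, 40),
                         rho = c(1e-6, 1e-3), delta = 20, b0 = 575) {
  for (nm in c("Tm", "Td", "rho")) {
    r <- get(nm)
    if (length(r) != 2L || !all(is.finite(r)) || r[1] <= 0 || r[1] >= r[2]) {
      stop("range for `", nm, "` must be c(low, high) with 0 < low < high",
           call. = FALSE)
    }
  }
  .check_positive(delta, "delta")
  .check_positive(b0, "b0")
  structure(list(Tm = Tm, Td = Td, rho = rho, delta = delta, b0 = b0),
            class = "param_ranges")
}

#' Latin hypercube sample of (Tm, Td, rho)
#'
#' Draws `n` parameter triples by Latin hypercube sampling: for each
#' dimension, exactly one point falls in each of the `n` equal-probability
#' strata of the uniform range.
#'
#' @param ranges a [param_ranges()] object.
#' @param n number of parameter sets.
#' @param seed optional RNG seed (deterministic sample when given).
#' @return data frame with `n` rows and columns `Tm`, `Td`, `rho`.
#' @export
lhs_sample <- function(ranges = param_ranges(), n, seed = NULL) {
  stopifnot(inherits(ranges, "param_ranges"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(as.integer(n), 3L)
  data.frame(
    Tm  = ranges$Tm[1] + u[, 1] * diff(ranges$Tm),
    Td  = ranges$Td[1] + u[, 2] * diff(ranges$Td),
    rho = ranges$rho[1] + u[, 3] * diff(ranges$rho)
  )
}

#' Simulate a batch of parameter sets
#'
#' Runs one seeded simulation plus closure-kinetics fit per parameter set,
#' with per-run child seeds derived deterministically from `master_seed`.
#'
#' @param sets data frame with columns `Tm`, `Td`, `rho` (e.g. from
#'   [lhs_sample()]).
#' @param ranges a [param_ranges()] carrying the fixed `delta` and `b0`.
#' @param master_seed master RNG seed for the batch.
#' @param max_time simulation horizon per run (h).
#' @param n_rows optional lattice row count passed to [ca_params()].
#' @return data frame with one row per set: the inputs, `phi`, `seed`,
#'   `closed`, and the outputs `alpha`, `t_half`, `t_closure` (`NA` when the
#'   wound did not close), `r_squared`.
#' @export
run_batch <- function(sets, ranges = param_ranges(), master_seed = 1,
                      max_time = 240, n_rows = NULL) {
  stopifnot(is.data.frame(sets), nrow(sets) >= 1,
            all(c("Tm", "Td", "rho") %in% names(sets)))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, nrow(sets))
  out <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    p <- ca_params(Tm = sets$Tm[i], Td = sets$Td[i], rho = sets$rho[i],
                   b0 = ranges$b0, delta = ranges$delta, n_rows = n_rows,
                   max_time = max_time, warn_range = FALSE)
    traj <- simulate_wound(p, seed = seeds[i])
    m <- fit_closure_rate(traj)
    out[[i]] <- data.frame(
      Tm = sets$Tm[i], Td = sets$Td[i], rho = sets$rho[i],
      phi = sets$Tm[i] / sets$Td[i], seed = seeds[i],
      closed = isTRUE(attr(traj, "closed")),
      alpha = m$alpha, t_half = m$t_half, t_closure = m$t_closure,
      r_squared = m$r_squared
    )
  }
  do.call(rbind, out)
}

#' Standardized multiple linear regression of one output on (rho, Tm, Td)
#'
#' Fits `output = beta0 + beta_rho * rho + beta_Tm * Tm + beta_Td * Td` by
#' ordinary least squares after z-score standardization of the inputs and the
#' output, so the coefficients are comparable effect sizes across parameters
#' with different units.
#'
#' @param tab a batch table from [run_batch()].
#' @param output which output to regress: `"alpha"`, `"t_half"` or
#'   `"t_closure"`. Rows where the output is `NA` (e.g. non-closing runs for
#'   `t_closure`) are excluded.
#' @return a list with `betas` (named: `beta_0`, `beta_rho`, `beta_Tm`,
#'   `beta_Td`), `p_values`, `n_used`, `n_excluded` and the underlying `lm`
#'   fit.
#' @export
mlra <- function(tab, output = c("alpha", "t_half", "t_closure")) {
  output <- match.arg(output)
  stopifnot(all(c("Tm", "Td", "rho", output) %in% names(tab)))
  keep <- complete.cases(tab[, c("Tm", "Td", "rho", output)])
  d <- tab[keep, ]
  if (nrow(d) < 5L) {
    stop("need at least 5 complete rows to fit the regression (have ",
         nrow(d), ")", call. = FALSE)
  }
  z <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop("degenerate design: column has zero variance", call. = FALSE)
    }
    (x - mean(x)) / s
  }
  df <- data.frame(y = z(d[[output]]), rho = z(d$rho), Tm = z(d$Tm),
                   Td = z(d$Td))
  fit <- lm(y ~ rho + Tm + Td, data = df)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 4L || any(!is.finite(cf[, 1]))) {
    stop("degenerate design: collinear inputs", call. = FALSE)
  }
  betas <- setNames(cf[, 1], c("beta_0", "beta_rho", "beta_Tm", "beta_Td"))
  pvals <- setNames(cf[, 4], c("beta_0", "beta_rho", "beta_Tm", "beta_Td"))
  list(betas = betas, p_values = pvals, n_used = nrow(d),
       n_excluded = sum(!keep), fit = fit)
}

#' Rank parameters by their replicate regression-coefficient magnitudes
#'
#' For each output, compares the replicate distributions of |beta| across the
#' three parameters by one-way ANOVA followed by Tukey's HSD at 95%
#' confidence. Parameters are ordered by mean |beta| and ranked 1 (most
#' significant) to 3 (least); a pair whose Tukey comparison is not
#' significant shares the better rank.
#'
#' @param betas data frame with columns `output`, `parameter`, `replicate`,
#'   `beta` (as produced by [run_gsa()]).
#' @param conf_level Tukey confidence level. Default 0.95.
#' @return a list with `ranks` (data frame: `output`, `parameter`,
#'   `mean_abs_beta`, `rank`), `anova_p` (per output) and `tukey` (per-output
#'   Tukey tables).
#' @export
rank_parameters <- function(betas, conf_level = 0.95) {
  stopifnot(all(c("output", "parameter", "beta") %in% names(betas)))
  ranks <- list(); anova_p <- c(); tukey <- list()
  for (out in unique(betas$output)) {
    d <- betas[betas$output == out, ]
    if (min(table(d$parameter)) < 2L) {
      stop("need at least 2 replicates per parameter to rank (output ",
           out, ")", call. = FALSE)
    }
    d$ab <- abs(d$beta)
    d$parameter <- factor(d$parameter)
    fit <- aov(ab ~ parameter, data = d)
    anova_p[out] <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit, conf.level = conf_level)$parameter
    tukey[[out]] <- tk
    mu <- sort(tapply(d$ab, d$parameter, mean), decreasing = TRUE)
    prm <- names(mu)
    rk <- seq_along(prm)
    for (i in seq_along(prm)[-1]) {
      pair <- c(paste(prm[i - 1], prm[i], sep = "-"),
                paste(prm[i], prm[i - 1], sep = "-"))
      p_adj <- tk[rownames(tk) %in% pair, "p adj"]
      if (length(p_adj) == 1L && is.finite(p_adj) && p_adj >= 1 - conf_level) {
        rk[i] <- rk[i - 1]
      }
    }
    ranks[[out]] <- data.frame(output = out, parameter = prm,
                               mean_abs_beta = as.numeric(mu), rank = rk)
  }
  list(ranks = do.call(rbind, c(ranks, list(make.row.names = FALSE))),
       anova_p = anova_p, tukey = tukey)
}

#' Global sensitivity analysis pipeline
#'
#' Repeats, `n_replicates` times: draw `n_samples` Latin hypercube parameter
#' sets, simulate each, and regress every output (`alpha`, `t_half`,
#' `t_closure`) on the standardized inputs. The replicate coefficient
#' distributions are then ranked per output via ANOVA + Tukey
#' ([rank_parameters()]) and combined into an equally weighted overall
#' ranking.
#'
#' @param n_samples Latin hypercube samples per replicate (500 at full
#'   scale).
#' @param n_replicates independent replicates (10 at full scale).
#' @param ranges a [param_ranges()].
#' @param master_seed master RNG seed; all child seeds derive from it.
#' @param max_time simulation horizon per run (h). Default 48 h, the upper
#'   end of standard scratch-assay durations: the characteristic times
#'   `T_half` and `T_closure` are the quantities an assay measures, so runs
#'   are right-censored at assay duration and conditions that have not closed
#'   by then are excluded from the `t_closure` regression (their count is
#'   recorded per replicate).
#' @param weights per-output weights for the combined ranking; equal by
#'   default.
#' @return an object of class `gsa_result`: list with `betas` (long data
#'   frame of replicate coefficients with p-values and a `flagged` column
#'   marking p >= 0.05), `ranks`, `anova_p`, `tukey`, `weighted_ranking`,
#'   `n_samples`, `n_replicates`.
#' @export
run_gsa <- function(n_samples = 500, n_replicates = 10,
                    ranges = param_ranges(), master_seed = 1,
                    max_time = 48,
                    weights = c(alpha = 1, t_half = 1, t_closure = 1) / 3) {
  set.seed(master_seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, 2L * n_replicates),
                      ncol = 2L)
  outputs <- c("alpha", "t_half", "t_closure")
  rows <- list()
  for (r in seq_len(n_replicates)) {
    sets <- lhs_sample(ranges, n_samples, seed = rep_seeds[r, 1])
    tab <- run_batch(sets, ranges, master_seed = rep_seeds[r, 2],
                     max_time = max_time)
    for (out in outputs) {
      m <- mlra(tab, out)
      for (prm in c("rho", "Tm", "Td")) {
        nm <- paste0("beta_", prm)
        rows[[length(rows) + 1L]] <- data.frame(
          output = out, parameter = prm, replicate = r,
          beta = unname(m$betas[nm]), p_value = unname(m$p_values[nm]),
          n_used = m$n_used, n_excluded = m$n_excluded
        )
      }
    }
  }
  betas <- do.call(rbind, rows)
  betas$flagged <- betas$p_value >= 0.05
  rk <- rank_parameters(betas)
  ## equally weighted average of per-output ranks (overall parameter ranking)
  w <- weights[rk$ranks$output]
  wr <- tapply(rk$ranks$rank * w, rk$ranks$parameter, sum) /
    tapply(w, rk$ranks$parameter, sum)
  res <- list(betas = betas, ranks = rk$ranks, anova_p = rk$anova_p,
              tukey = rk$tukey, weighted_ranking = sort(wr),
              n_samples = n_samples, n_replicates = n_replicates)
  class(res) <- "gsa_result"
  res
}

#' @export
print.gsa_result <- function(x, ...) {
  cat(sprintf("<gsa_result> %d replicates x %d LHS samples\n",
              x$n_replicates, x$n_samples))
  cat("Per-output parameter ranks (1 = most significant):\n")
  print(x$ranks, row.names = FALSE)
  cat("Weighted overall ranking (lower = more significant):\n")
  print(round(x$weighted_ranking, 3))
  invisible(x)
}
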