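# Reference implementations used as independent oracles. The sweep oracle is
# a plain-R transliteration of the update rules that consumes the RNG stream
# in the documented order (shuffle draws, then per cell: one lambda, one
# target draw when acting), so a seeded run must match the package's compiled
# sweep bit for bit.

moore_offsets <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

oracle_candidates <- function(grid, r, cl, center, bias) {
  n <- nrow(grid); m <- ncol(grid)
  out <- list()
  for (i in seq_len(8L)) {
    dr <- moore_offsets[i, "dr"]; dc <- moore_offsets[i, "dc"]
    if (bias > 0L && cl != center) {
      back <- if (cl < center) -1L else 1L
      if (dc == back && (bias == 2L || dr != 0L)) next
    }
    cc <- cl + dc
    if (cc < 1L || cc > m) next
    rr <- ((r - 1L + dr) %% n) + 1L
    if (grid[rr, cc] == 0L) out[[length(out) + 1L]] <- c(rr, cc)
  }
  out
}

oracle_sweep <- function(grid, pm, f, center, bias = 0L, prolif = TRUE,
                         refill = TRUE) {
  n <- nrow(grid); m <- ncol(grid)
  occ <- which(grid == 1L)            # column-major ascending
  N <- length(occ)
  if (N > 1L) {
    for (i in N:2L) {                 # Fisher-Yates, same draws as the core
      j <- floor(runif(1) * i) + 1L
      if (j > i) j <- i
      tmp <- occ[i]; occ[i] <- occ[j]; occ[j] <- tmp
    }
  }
  for (idx in occ) {
    r <- ((idx - 1L) %% n) + 1L
    cl <- ((idx - 1L) %/% n) + 1L
    if (grid[r, cl] == 0L) next       # vacated earlier this sweep
    cand <- oracle_candidates(grid, r, cl, center, bias)
    k <- length(cand)
    if (k == 0L) next                 # quiescent
    lambda <- runif(1)
    if (lambda < pm) {
      j <- min(floor(runif(1) * k) + 1L, k)
      grid[cand[[j]][1], cand[[j]][2]] <- 1L
      grid[r, cl] <- 0L
    } else if (prolif) {
      j <- min(floor(runif(1) * k) + 1L, k)
      grid[cand[[j]][1], cand[[j]][2]] <- 1L
    }
  }
  if (refill) {
    for (r in seq_len(n)) if (grid[r, 1L] == 0L && runif(1) < f) grid[r, 1L] <- 1L
    if (m > 1L) {
      for (r in seq_len(n)) if (grid[r, m] == 0L && runif(1) < f) grid[r, m] <- 1L
    }
  }
  grid
}

# Brute-force wound area in sites: empty band sites with >= 1 empty Moore
# neighbor (rows wrap).
oracle_area_sites <- function(grid, band) {
  n <- nrow(grid); m <- ncol(grid)
  count <- 0L
  for (cl in band[1]:band[2]) {
    for (r in seq_len(n)) {
      if (grid[r, cl] == 1L) next
      nb <- integer(0)
      for (i in seq_len(8L)) {
        cc <- cl + moore_offsets[i, "dc"]
        if (cc < 1L || cc > m) next
        rr <- ((r - 1L + moore_offsets[i, "dr"]) %% n) + 1L
        nb <- c(nb, grid[rr, cc])
      }
      if (any(nb == 0L)) count <- count + 1L
    }
  }
  count
}

# Minimal lattice_state around a hand-built grid.
make_state <- function(grid, band, center = NULL, delta = 20) {
  if (is.null(center)) center <- band[1] + (band[2] - band[1]) %/% 2L
  structure(list(grid = grid, time = 0, step_index = 0L,
                 wound_center_col = center, wound_band = band,
                 delta = delta, f = NA_real_, params = NULL),
            class = "lattice_state")
}

# Closed-form OLS via normal equations (independent of stats::lm).
normal_eq <- function(X, y) solve(crossprod(X), crossprod(X, y))

id2_params <- function(...) {
  suppressWarnings(ca_params(Tm = 0.075, Td = 24, rho = 2.9e-3, b0 = 371,
                             delta = 20, warn_range = FALSE, ...))
}
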