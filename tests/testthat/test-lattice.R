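test_that("init_lattice builds the L/W/R domain", {
  p0 <- ca_params(Tm = 0.1, Td = 24, rho = 0, b0 = 575, delta = 20,
                  n_rows = 50, warn_range = FALSE)
  s0 <- init_lattice(p0)
  expect_equal(dim(s0$grid), c(50L, 59L))
  expect_equal(sum(s0$grid), 0L)              # zero density: no cells at all
  expect_equal(s0$time, 0)

  p1 <- ca_params(Tm = 0.1, Td = 24, rho = 2.5e-3, b0 = 575, delta = 20,
                  seed = 9, warn_range = FALSE)
  s1 <- init_lattice(p1)
  lateral <- c(1:p1$n_l, (p1$wound_band[2] + 1):p1$n_cols)
  expect_true(all(s1$grid[, lateral] == 1L))  # f = 1: full coverage
  expect_true(all(s1$grid[, p1$wound_band[1]:p1$wound_band[2]] == 0L))
})

test_that("lateral seeding matches the binomial expectation", {
  # b0 = 400, delta = 20 -> 20 wound cols, 10 + 10 lateral; f = 0.4;
  # expected occupied count = 0.4 * 20 * 100 = 800
  p <- ca_params(Tm = 0.1, Td = 24, rho = 1e-3, b0 = 400, delta = 20,
                 n_rows = 100, warn_range = FALSE)
  set.seed(123)
  counts <- replicate(200, sum(init_lattice(p)$grid))
  se_mean <- sqrt(2000 * 0.4 * 0.6) / sqrt(200)
  expect_lt(abs(mean(counts) - 800), 3 * se_mean)
})

test_that("candidate_sites enumerates empty Moore neighbors with optional bias", {
  p <- ca_params(Tm = 0.1, Td = 24, rho = 0, b0 = 100, delta = 20,
                 n_rows = 9, warn_range = FALSE)
  s <- init_lattice(p)                         # 5 wound cols, center col 6
  s$grid[5, 3] <- 1L                           # isolated cell left of center
  expect_equal(nrow(candidate_sites(s, 5, 3, bias_enabled = FALSE)), 8L)

  cand <- candidate_sites(s, 5, 3, bias_enabled = TRUE,
                          bias_exclude = "diagonals")
  expect_equal(nrow(cand), 6L)                 # 8 minus the 2 backward diagonals
  expect_false(any(cand[, "row"] != 5 & cand[, "col"] == 2))
  expect_true(any(cand[, "row"] == 5 & cand[, "col"] == 2))  # straight back kept

  expect_equal(nrow(candidate_sites(s, 5, 3, bias_enabled = TRUE,
                                    bias_exclude = "all")), 5L)

  # mirror image right of center
  s$grid[5, 3] <- 0L; s$grid[5, 10] <- 1L
  cand_r <- candidate_sites(s, 5, 10, bias_enabled = TRUE)
  expect_equal(nrow(cand_r), 6L)
  expect_false(any(cand_r[, "row"] != 5 & cand_r[, "col"] == 11))

  # fully surrounded cell is quiescent
  s$grid[, ] <- 1L
  expect_equal(nrow(candidate_sites(s, 5, 6)), 0L)

  # vertical wrap: cell in top row sees bottom row
  s$grid[, ] <- 0L; s$grid[1, 6] <- 1L
  cand_w <- candidate_sites(s, 1, 6, bias_enabled = FALSE)
  expect_true(any(cand_w[, "row"] == 9))

  expect_error(candidate_sites(s, 1, 99), "outside")
  expect_error(candidate_sites(s, 2, 6), "not occupied")
})

test_that("a fully occupied lattice is a fixed point of the sweep", {
  p <- ca_params(Tm = 0.05, Td = 20, rho = 2.5e-3, b0 = 400, delta = 20,
                 seed = 4, warn_range = FALSE)
  s <- init_lattice(p)
  s$grid[, ] <- 1L
  s2 <- ca_step(s, p)
  expect_identical(s2$grid, s$grid)
  expect_equal(s2$time, p$dt)
})

test_that("a lone motile cell with room must move", {
  p <- ca_params(Tm = 0.01, Td = 1e6, rho = 0, b0 = 400, delta = 20,
                 n_rows = 11, refill_enabled = FALSE, warn_range = FALSE)
  # Pm = 1 - 1e-8: over 50 sweeps the cell essentially always migrates
  set.seed(7)
  s <- init_lattice(p)
  s$grid[6, 15] <- 1L
  for (i in 1:10) {
    before <- which(s$grid == 1L)
    s <- ca_step(s, p)
    expect_equal(sum(s$grid), 1L)
    expect_false(identical(which(s$grid == 1L), before))
  }
})

test_that("cell count is conserved under pure migration and non-decreasing otherwise", {
  # migration only: proliferation and refill off
  p <- ca_params(Tm = 0.05, Td = 24, rho = 1e-3, b0 = 400, delta = 20,
                 prolif_enabled = FALSE, refill_enabled = FALSE, seed = 11,
                 warn_range = FALSE)
  s <- init_lattice(p)
  n0 <- sum(s$grid)
  for (i in 1:50) s <- ca_step(s, p)
  expect_equal(sum(s$grid), n0)

  # proliferation-dominated: occupied count monotone non-decreasing
  p2 <- ca_params(Tm = 1e6, Td = 12, rho = 5e-4, b0 = 400, delta = 20,
                  max_time = 1e6, refill_enabled = FALSE, seed = 12,
                  warn_range = FALSE)
  s2 <- init_lattice(p2)
  last <- sum(s2$grid)
  for (i in 1:100) {
    s2 <- ca_step(s2, p2)
    now <- sum(s2$grid)
    expect_gte(now, last)
    last <- now
  }

  # boundary refill on: count never decreases either
  p3 <- ca_params(Tm = 0.05, Td = 24, rho = 1e-3, b0 = 400, delta = 20,
                  seed = 13, warn_range = FALSE)
  s3 <- init_lattice(p3)
  last <- sum(s3$grid)
  for (i in 1:50) {
    s3 <- ca_step(s3, p3)
    now <- sum(s3$grid)
    expect_gte(now, last)
    last <- now
  }
})

test_that("no site ever holds more than one cell", {
  p <- ca_params(Tm = 0.05, Td = 15, rho = 1e-3, b0 = 400, delta = 20,
                 seed = 5, warn_range = FALSE)
  s <- init_lattice(p)
  for (i in 1:30) {
    s <- ca_step(s, p)
    expect_true(all(s$grid %in% c(0L, 1L)))
  }
})

test_that("the compiled sweep matches the plain-R rule transliteration", {
  for (case in 1:20) {
    set.seed(1000 + case)
    n <- sample(4:9, 1); m <- sample(5:11, 1)
    g <- matrix(rbinom(n * m, 1L, runif(1, 0.2, 0.8)), n, m)
    pm <- runif(1); f <- runif(1)
    center <- sample(2:(m - 1), 1)
    bias <- sample(0:2, 1)
    prolif <- sample(c(TRUE, FALSE), 1)

    seed <- 5000 + case
    set.seed(seed)
    g_cpp <- scratchCA:::cpp_sweep(g, pm, f, center - 1L, bias, prolif, TRUE)
    set.seed(seed)
    g_ref <- oracle_sweep(g, pm, f, center, bias, prolif, TRUE)
    expect_identical(g_cpp, matrix(as.integer(g_ref), n, m))
  }
})

test_that("hand-checked single-cell sweeps behave deterministically", {
  g <- matrix(0L, 5, 5); g[3, 3] <- 1L
  set.seed(1)
  g1 <- scratchCA:::cpp_sweep(g, 1.0, 0, 2L, 0L, TRUE, FALSE)
  expect_equal(sum(g1), 1L)
  expect_equal(g1[3, 3], 0L)                  # Pm = 1: the cell moved
  moved_to <- which(g1 == 1L)
  rr <- (moved_to - 1) %% 5 + 1; cc <- (moved_to - 1) %/% 5 + 1
  expect_lte(abs(rr - 3), 1); expect_lte(abs(cc - 3), 1)

  set.seed(1)
  g2 <- scratchCA:::cpp_sweep(g, 0.0, 0, 2L, 0L, TRUE, FALSE)
  expect_equal(sum(g2), 2L)                   # Pm = 0: divided instead
  expect_equal(g2[3, 3], 1L)                  # mother stays
})

test_that("simulate_wound is deterministic and consistent with stepwise evolution", {
  p <- id2_params()
  t1 <- simulate_wound(p, seed = 21)
  t2 <- simulate_wound(p, seed = 21)
  expect_identical(t1, t2)

  # stepwise path (ca_step + wound_area) consumes the same RNG stream
  set.seed(21)
  p2 <- p; p2$seed <- NULL
  s <- init_lattice(p2)
  areas <- wound_area(s)
  while (tail(areas, 1) > 0) {
    s <- ca_step(s, p)
    areas <- c(areas, wound_area(s))
  }
  expect_equal(areas, t1$area_um2)

  # trajectory invariants
  expect_equal(t1$a_over_a0[1], 1)
  expect_true(all(diff(t1$time_h) > 0))
  expect_true(all(t1$area_um2 >= 0))
  expect_true(isTRUE(attr(t1, "closed")))
})

test_that("an empty lattice without refill never closes", {
  p <- ca_params(Tm = 0.1, Td = 24, rho = 0, b0 = 400, delta = 20,
                 n_rows = 20, max_time = 5, refill_enabled = FALSE,
                 warn_range = FALSE)
  tr <- simulate_wound(p, seed = 2)
  expect_false(attr(tr, "closed"))
  expect_true(all(tr$a_over_a0 == 1))
})

test_that("mean wound area is monotone non-increasing", {
  p <- id2_params()
  trajs <- lapply(1:20, function(s) simulate_wound(p, seed = 300 + s))
  len <- max(vapply(trajs, nrow, 1L))
  padded <- vapply(trajs, function(tr) {
    a <- tr$a_over_a0
    c(a, rep(0, len - length(a)))   # closed wounds stay closed
  }, numeric(len))
  mean_curve <- rowMeans(padded)
  expect_true(all(diff(mean_curve) <= 0.01))
})

test_that("mean closure rate increases as migration gets faster", {
  alphas <- sapply(c(0.3, 0.1, 0.03), function(Tm) {
    p <- ca_params(Tm = Tm, Td = 24, rho = 2.5e-3, b0 = 400, delta = 20,
                   warn_range = FALSE)
    mean(sapply(1:20, function(s) fit_closure_rate(simulate_wound(p, seed = s))$alpha))
  })
  expect_true(all(diff(alphas) > 0))
})
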