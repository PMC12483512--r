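bd <- idrsearch:::bd_trajectory_cpp

test_that("forces are the negative analytic gradient (finite differences)", {
  cfg <- search_config(R = 50, a = 1, d = 10, L = 40, l0 = 5, n_tilde = 4,
                       E_B = 6)
  set.seed(42)
  h <- 1e-5
  for (rep in 1:20) {
    pos <- matrix(rnorm(12, sd = 8), 4, 3)
    f <- total_force(pos, cfg)
    for (probe in 1:5) {
      i <- sample(4, 1); j <- sample(3, 1)
      pp <- pos; pm <- pos
      pp[i, j] <- pp[i, j] + h
      pm[i, j] <- pm[i, j] - h
      num <- -(total_energy(pp, cfg) - total_energy(pm, cfg)) / (2 * h)
      expect_equal(f[i, j], num, tolerance = 1e-5)
    }
  }
})

test_that("spring and well forces take their textbook values", {
  cfg <- search_config(R = 50, a = 1, d = 10, L = 40, l0 = 5, n_tilde = 2,
                       E_B = 6, sigma = 0.5)
  # two bonded sites a bond length apart, far from any target: Hooke pair
  pos <- rbind(c(20, 20, 0), c(20 + 5, 20, 0))
  f <- total_force(pos, cfg)
  k <- 3 / 25
  expect_equal(f[1, ], c(k * 5, 0, 0), tolerance = 1e-9)
  expect_equal(f[2, ], c(-k * 5, 0, 0), tolerance = 1e-9)
  # a site exactly at a target centre feels no well force
  cfg1 <- search_config(R = 50, a = 1, d = 10, L = 40, l0 = 5, n_tilde = 1,
                        E_B = 6)
  f1 <- total_force(matrix(c(0, 0, 10), 1, 3), cfg1)
  expect_equal(max(abs(f1)), 0, tolerance = 1e-12)
})

test_that("adaptive time step follows the capped force rule", {
  cfg <- search_config(R = 50, a = 1, d = 10, L = 40, l0 = 5, n_tilde = 2,
                       E_B = 6)
  expect_equal(adaptive_dt(matrix(0, 2, 3), cfg), 0.01)
  expect_equal(adaptive_dt(matrix(c(100, 0, 0, 0, 0, 0), 2, 3), cfg), 1e-4)
  expect_equal(adaptive_dt(matrix(c(0.5, 0, 0, 0, 0, 0), 2, 3), cfg), 0.01)
  # drift per step never exceeds the well width
  set.seed(1)
  for (i in 1:200) {
    f <- matrix(rnorm(6, sd = 10^runif(1, -1, 3)), 2, 3)
    dt <- adaptive_dt(f, cfg)
    expect_lt(dt * sqrt(max(rowSums(f^2))), cfg$w_d)
  }
})

test_that("initial states are equilibrated and uniformly placed", {
  cfg <- search_config(R = 50, a = 1, d = 10, L = 40, l0 = 5, n_tilde = 4)
  set.seed(3)
  draws <- replicate(3000, sample_initial_state(cfg), simplify = FALSE)
  b2 <- unlist(lapply(draws, function(p) rowSums(diff(p)^2)))
  expect_equal(mean(b2), cfg$l0^2, tolerance = 0.03)
  expect_true(all(vapply(draws, function(p) all(rowSums(p^2) <= cfg$R^2), TRUE)))
  # a single-site chain is a point exactly uniform in the sphere (a chain's
  # centre is additionally depleted near the wall by the resampling)
  cfg1 <- search_config(R = 50, a = 1, d = 10, L = 40, l0 = 5, n_tilde = 1)
  radii <- vapply(1:4000, function(i) sqrt(sum(sample_initial_state(cfg1)^2)), 0)
  ks <- stats::ks.test(radii / cfg1$R, function(q) q^3)
  expect_gt(ks$p.value, 0.01)
})

test_that("free diffusion reproduces MSD = 6 D t within 2%", {
  t_end <- 10
  msd <- vapply(1:10000, function(i) {
    m <- bd(matrix(0, 1, 3), matrix(0, 0, 3), 0, 1, 0, 0, 0,
            dt = 0.05, n_steps = 200, stride = 200, seed = i)
    sum(m[1, ]^2)
  }, 0)
  expect_equal(mean(msd), 6 * t_end, tolerance = 0.02)
})

test_that("chain centre of mass diffuses with D / n_tilde", {
  pos0 <- cbind(cumsum(c(0, 5, 5, 5)), 0, 0)
  com0 <- colMeans(pos0)
  t_end <- 10
  msd <- vapply(1:6000, function(i) {
    m <- bd(pos0, matrix(0, 0, 3), 0, 1, 3 / 25, 0, 0,
            dt = 0.02, n_steps = 500, stride = 500, seed = 20000 + i)
    com1 <- c(mean(m[1, c(1, 4, 7, 10)]), mean(m[1, c(2, 5, 8, 11)]),
              mean(m[1, c(3, 6, 9, 12)]))
    sum((com1 - com0)^2)
  }, 0)
  expect_equal(mean(msd), 6 * t_end / 4, tolerance = 0.03)
})

test_that("reflection at the sphere preserves the uniform measure", {
  R <- 10
  # stride of 50 t0 (about three sphere relaxation times) decorrelates the
  # samples; the mirror reflection keeps the radial law r^2 dr
  m <- bd(matrix(c(1, 0, 0), 1, 3), matrix(0, 0, 3), 0, 1, 0, 0, R,
          dt = 0.2, n_steps = 1e6, stride = 250, seed = 99)
  radii <- sqrt(rowSums(m[-(1:10), ]^2))
  expect_true(all(radii <= R))
  ks <- stats::ks.test(radii / R, function(q) q^3)
  expect_gt(ks$p.value, 0.01)
})

test_that("the integrator samples the Boltzmann weight of a single well", {
  # one site confined to a small sphere with one Gaussian well at the centre;
  # occupancy of r < w compared to the analytic Boltzmann ratio
  E_B <- 3; w <- 1; R <- 6
  m <- bd(matrix(c(3, 0, 0), 1, 3), matrix(0, 1, 3), E_B, w, 0, 0, R,
          dt = 2e-3, n_steps = 2e6, stride = 20, seed = 11)
  r <- sqrt(rowSums(m[-(1:5000), ]^2))
  occ <- mean(r < w)
  boltz <- function(r) exp(E_B * exp(-r^2 / (2 * w^2))) * r^2
  p_in <- stats::integrate(boltz, 0, w)$value /
    stats::integrate(boltz, 0, R)$value
  expect_equal(occ, p_in, tolerance = 0.1)
})

test_that("searches are deterministic under a fixed seed", {
  cfg <- search_config(R = 30, a = 1, d = 6, L = 24, l0 = 5, n_tilde = 3,
                       E_B = 5, sample_dt = 5)
  r1 <- run_search(cfg, seed = 17, store_series = TRUE)
  r2 <- run_search(cfg, seed = 17, store_series = TRUE)
  expect_identical(r1$t_total, r2$t_total)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$n_rounds, r2$n_rounds)
  r3 <- run_search(cfg, seed = 18)
  expect_false(identical(r1$t_total, r3$t_total))
})

test_that("a search starting on the target ends immediately", {
  cfg <- search_config(R = 30, a = 1, d = 6, L = 24, l0 = 5, n_tilde = 2)
  rec <- idrsearch:::simulate_search_cpp(
    matrix(0, 2, 3), 2, cfg$l0, cfg$R, cfg$a, cfg$d, cfg$L, cfg$E_B,
    cfg$w_d, cfg$sigma, cfg$far_threshold, cfg$dt_base, cfg$max_time,
    cfg$capture_radius, cfg$detach_time, cfg$sample_dt, 1, FALSE)
  expect_equal(rec$t_total, 0)
  expect_equal(rec$terminated, "success")
})

test_that("single-site search with no wells matches the volume-trap MFPT", {
  # E_B = 0, one site: mean first-passage to the central sphere is
  # R^3 / (3 D a) up to O(a / R)
  cfg <- search_config(R = 25, a = 1.25, d = 10, L = 21, l0 = 5, n_tilde = 1,
                       E_B = 0)
  m <- estimate_mfpt(cfg, n_runs = 300, seed = 12)
  # exact volume-averaged MFPT for reflecting outer / absorbing inner sphere
  a <- cfg$a; R <- cfg$R
  tau <- function(r) (R^3 / 3) * (1 / a - 1 / r) + (a^2 - r^2) / 6
  theory <- stats::integrate(function(r) tau(r) * r^2, a, R)$value * 3 /
    (R^3 - a^3)
  expect_lt(abs(m$mean - theory), 3 * m$se + 0.05 * theory)
})

test_that("standard error shrinks with the square root of the sample size", {
  cfg <- search_config(R = 20, a = 2, d = 6, L = 12, l0 = 5, n_tilde = 1,
                       E_B = 0)
  m1 <- estimate_mfpt(cfg, n_runs = 50, seed = 2)
  m2 <- estimate_mfpt(cfg, n_runs = 400, seed = 3)
  ratio <- m1$se / m2$se
  expect_gt(ratio, sqrt(8) * 0.6)
  expect_lt(ratio, sqrt(8) / 0.6)
})

test_that("search time is insensitive to the far-field threshold", {
  base <- list(R = 30, a = 1.5, d = 8, L = 16, l0 = 5, n_tilde = 2, E_B = 3)
  cfg10 <- do.call(search_config, c(base, far_threshold = 10))
  cfg20 <- do.call(search_config, c(base, far_threshold = 20))
  m10 <- estimate_mfpt(cfg10, n_runs = 120, seed = 4)
  m20 <- estimate_mfpt(cfg20, n_runs = 120, seed = 4)
  expect_lt(abs(m10$mean - m20$mean), 3 * sqrt(m10$se^2 + m20$se^2))
})

test_that("no site ever leaves the sphere along a recorded trajectory", {
  cfg <- search_config(R = 25, a = 1, d = 6, L = 24, l0 = 5, n_tilde = 3,
                       E_B = 6, sample_dt = 2)
  rec <- run_search(cfg, seed = 5, store_series = TRUE)
  # the recorded minimal antenna distance can never exceed the sphere radius
  # plus the half-span, and the axial coordinate stays inside the sphere
  expect_true(all(abs(rec$series$z_com) <= cfg$R))
  expect_true(all(rec$series$min_antenna_dist <= 2 * cfg$R))
})
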