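#' Configuration of the first-passage search simulation
#'
#' Sets up the overdamped Brownian-dynamics search: a bead-spring TF chain
#' of `n_tilde` sites diffuses inside a reflecting sphere of radius `R`; the
#' antenna lies along a diameter with the absorbing DBD target (capture
#' radius `a`) at the centre and IDR targets (Gaussian wells of depth
#' `E_B`, width `w_d`) at spacing `d` symmetrically on both sides, total
#' span `L`.  Units: bp, kT, t0 = bp^2/D with D the single-site diffusion
#' coefficient.
#'
#' @param R sphere radius (bp).
#' @param a DBD capture radius (bp).
#' @param d target spacing on the antenna (bp).
#' @param L antenna length (bp); the realised span is `2 d floor(L / (2 d))`.
#' @param l0 bond length (bp); spring stiffness is `3 / l0^2` kT/bp^2.
#' @param n_tilde chain length (IDR sites + 1 DBD site).
#' @param E_B well depth (kT); 0 disables the wells.
#' @param w_d well width (bp).
#' @param sigma excluded-volume (WCA) diameter (bp); applied between all
#'   site pairs in near-field mode only.
#' @param far_threshold near/far switching distance from the antenna (bp);
#'   beyond it the chain moves as a rigid body with diffusion `D / n_tilde`.
#' @param dt_base near-field time-step scale: `dt = dt_base * min(1, 1/max|f|)`.
#' @param max_time censoring horizon (t0); default 50x the two-term
#'   search-time prediction with the reference prefactors.
#' @param capture_radius site-target distance defining "attached"
#'   (default `2 * w_d`, shared with the trajectory analytics).
#' @param sample_dt series subsampling interval (t0).
#' @return object of class `"search_config"`.
#' @examples
#' search_config(R = 50, L = 40, n_tilde = 3)
#' @export
search_config <- function(R = 50, a = 1, d = 10, L = 40, l0 = 5, n_tilde = 3,
                          E_B = 6, w_d = 1, sigma = 1, far_threshold = 10,
                          dt_base = 0.01, max_time = NULL,
                          capture_radius = 2 * w_d, sample_dt = 1) {
  stopifnot(a > 0, d > 0, L > 0, R > 0, l0 > 0, n_tilde >= 1,
            E_B >= 0, w_d > 0, far_threshold > w_d, dt_base > 0)
  if (!(a < d && d <= L && L < 2 * R)) {
    stop("require a < d <= L < 2 R")
  }
  if (is.null(max_time)) {
    r_p <- sqrt(n_tilde / 6) * l0
    pred <- if (L > exp(1) * r_p) {
      t_total_theory(L, n_tilde, R, 1, l0)$t_total
    } else {
      simple_tf_time(R, 1, a)
    }
    max_time <- 50 * max(pred, simple_tf_time(R, 1, a) / n_tilde)
  }
  structure(
    list(R = R, a = a, d = d, L = L, l0 = l0, n_tilde = as.integer(n_tilde),
         E_B = E_B, w_d = w_d, sigma = sigma, far_threshold = far_threshold,
         dt_base = dt_base, max_time = max_time,
         capture_radius = capture_radius,
         detach_time = n_tilde^2 * l0^2,   # chain relaxation time, D = 1
         sample_dt = sample_dt),
    class = "search_config"
  )
}

#' @export
print.search_config <- function(x, ...) {
  cat(sprintf(
    "Search: R = %g bp, a = %g bp, antenna L = %g bp (d = %g bp), chain n = %d (l0 = %g bp), E_B = %g kT\n",
    x$R, x$a, x$L, x$d, x$n_tilde, x$l0, x$E_B
  ))
  invisible(x)
}

#' Draw an equilibrium initial chain state
#'
#' Chain centre uniform in the sphere, bond vectors i.i.d. Gaussian with
#' `<b^2> = l0^2`; the draw is rejected and repeated until every site lies
#' inside the sphere.
#'
#' @param config a [search_config()].
#' @return an `n_tilde x 3` matrix of site positions (bp).
#' @export
sample_initial_state <- function(config) {
  n <- config$n_tilde
  repeat {
    repeat {
      com <- stats::runif(3, -config$R, config$R)
      if (sum(com^2) <= config$R^2) break
    }
    pos <- if (n == 1) {
      matrix(0, 1, 3)
    } else {
      bonds <- matrix(stats::rnorm(3 * (n - 1), sd = config$l0 / sqrt(3)),
                      ncol = 3)
      rbind(0, apply(bonds, 2, cumsum))
    }
    pos <- sweep(pos, 2, colMeans(pos) - com, "-")
    if (all(rowSums(pos^2) <= config$R^2)) return(pos)
  }
}

#' Forces on the chain sites
#'
#' Negative gradient of the near-field potential (springs + Gaussian wells
#' at the IDR targets + WCA between site pairs); exposed for inspection and
#' the finite-difference audits.
#'
#' @param positions `n x 3` matrix of site positions (bp).
#' @param config a [search_config()].
#' @return `n x 3` matrix of forces (kT/bp).
#' @export
total_force <- function(positions, config) {
  total_force_cpp(positions, search_targets(config), config$E_B, config$w_d,
                  if (config$n_tilde > 1) 3 / config$l0^2 else 0,
                  config$sigma)
}

#' @rdname total_force
#' @export
total_energy <- function(positions, config) {
  total_energy_cpp(positions, search_targets(config), config$E_B, config$w_d,
                   if (config$n_tilde > 1) 3 / config$l0^2 else 0,
                   config$sigma)
}

# well positions realised by a search_config (z-axis antenna): the central
# DBD target plus the IDR targets; every site feels every well
search_targets <- function(config) {
  per_side <- floor(config$L / (2 * config$d) + 1e-9)
  zs <- if (per_side >= 1) c(outer(c(1, -1), seq_len(per_side) * config$d)) else numeric(0)
  cbind(0, 0, c(0, zs))
}

#' Near-field adaptive time step
#'
#' `dt = dt_base * min(1, kT / (max_i |f_i| * bp))` in t0 units, ensuring
#' the deterministic drift per step stays well below the well width.
#'
#' @param forces `n x 3` force matrix (kT/bp).
#' @param config a [search_config()].
#' @return time step (t0).
#' @export
adaptive_dt <- function(forces, config) {
  fmax <- sqrt(max(rowSums(forces^2)))
  config$dt_base * min(1, 1 / fmax)
}

#' Run one first-passage search
#'
#' Simulates the search until the DBD site reaches the central target
#' (`|r_DBD| < a`) or the censoring horizon.  Records the total time, the
#' time of first antenna attachment (`t_3d`), the number of 3D excursions
#' (`n_rounds` = attachment events; detachment requires every site to stay
#' beyond `far_threshold` for longer than the chain relaxation time
#' `n_tilde^2 l0^2 / D`), and optionally a subsampled series of the bound
#' count, the antenna-axis centre-of-mass coordinate and the minimal
#' antenna distance.
#'
#' @param config a [search_config()].
#' @param seed integer seed (also seeds the initial state).
#' @param store_series keep the subsampled trajectory series.
#' @return object of class `"first_passage_record"`.
#' @export
run_search <- function(config, seed = 1, store_series = FALSE) {
  set.seed(seed)
  pos0 <- sample_initial_state(config)
  rec <- simulate_search_cpp(pos0, config$n_tilde, config$l0, config$R,
                             config$a, config$d, config$L, config$E_B,
                             config$w_d, config$sigma, config$far_threshold,
                             config$dt_base, config$max_time,
                             config$capture_radius, config$detach_time,
                             config$sample_dt, seed, store_series)
  rec$config <- config
  rec$seed <- seed
  class(rec) <- "first_passage_record"
  rec
}

#' @export
print.first_passage_record <- function(x, ...) {
  cat(sprintf(
    "First passage: t_total = %.4g t0 (%s), t_3d = %.4g, rounds = %d\n",
    x$t_total, x$terminated, if (is.na(x$t_3d)) NA else x$t_3d, x$n_rounds
  ))
  invisible(x)
}

#' Mean first-passage time over independent searches
#'
#' Runs `n_runs` seeded searches (seed + run index) and returns the sample
#' mean and standard error of the successful first-passage times.  Censored
#' runs are reported separately and excluded from the mean; if more than
#' 10% are censored a warning is raised.
#'
#' @param config a [search_config()].
#' @param n_runs number of independent runs (>= 2).
#' @param seed master seed; run `i` uses `seed + i`.
#' @param store_series keep per-run series (memory heavy).
#' @return list with `mean`, `se`, `times`, `t_3d`, `n_rounds`,
#'   `n_censored` and the records (if `store_series`).
#' @export
estimate_mfpt <- function(config, n_runs = 500, seed = 1, store_series = FALSE) {
  stopifnot(n_runs >= 2)
  recs <- lapply(seq_len(n_runs), function(i) {
    run_search(config, seed = seed + i, store_series = store_series)
  })
  ok <- vapply(recs, function(r) r$terminated == "success", TRUE)
  times <- vapply(recs[ok], `[[`, 0, "t_total")
  n_cens <- sum(!ok)
  if (n_cens > 0.1 * n_runs) {
    warning(sprintf("%d of %d runs censored at max_time", n_cens, n_runs))
  }
  list(mean = mean(times), se = stats::sd(times) / sqrt(length(times)),
       times = times,
       t_3d = vapply(recs[ok], `[[`, 0, "t_3d"),
       n_rounds = vapply(recs[ok], `[[`, 0L, "n_rounds"),
       n_censored = n_cens,
       records = if (store_series) recs)
}

#' Point-searcher first-passage reference
#'
#' Single-particle simulation with distance-adaptive time steps, used to
#' validate the analytic baselines: absorption on a central sphere of
#' radius `a` (mean `R^3 / (3 D a)`) or on a thin central cylinder of
#' length `L` and capture radius `r_p` (mean
#' `alpha (R^3 / D L) log(L / r_p)` with `alpha = 2/3`).
#'
#' @param R sphere radius (bp).
#' @param a absorbing-sphere radius (`mode = "sphere"`).
#' @param L,r_p cylinder length and capture radius (`mode = "antenna"`).
#' @param n_runs number of passages.
#' @param seed integer seed.
#' @param c_adapt RMS step as a fraction of the distance to the absorber.
#' @param min_step smallest RMS step (bp).
#' @return list with `mean`, `se` and the sample `times` (t0; D = 1).
#' @export
point_searcher_reference <- function(R, a = NULL, L = NULL, r_p = NULL,
                                     n_runs = 500, seed = 1,
                                     c_adapt = 0.1, min_step = NULL) {
  mode <- if (!is.null(a)) 0L else 1L
  if (mode == 1L && (is.null(L) || is.null(r_p))) {
    stop("give either a (sphere mode) or L and r_p (antenna mode)")
  }
  cap <- if (mode == 0L) a else r_p
  if (is.null(min_step)) min_step <- 0.2 * cap
  max_time <- 1e4 * R^3 / (3 * cap)
  times <- point_mfpt_cpp(R, mode, a %||% 0, L %||% 0, r_p %||% 0,
                          n_runs, c_adapt, min_step, max_time, seed)
  list(mean = mean(times), se = stats::sd(times) / sqrt(length(times)),
       times = times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
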