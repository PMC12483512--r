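#' Two-term semi-analytic search time
#'
#' Mean total search time of the chain searcher as the sum of a 3D capture
#' term and a 1D sliding term:
#'
#'   t_total = alpha * (n_tilde R^3 / (D L)) * log(L / r_p) + beta * L^2 / D,
#'
#' with `r_p = sqrt(n_tilde / 6) l0` the chain gyration radius.  The first
#' term is the capture time of a thin cylindrical antenna by a searcher
#' whose 3D diffusion coefficient is `D / n_tilde`; the second is the 1D
#' walk over the antenna.  `alpha` and `beta` are dimensionless prefactors,
#' obtained from simulation fits (reference values `alpha = 0.5`,
#' `beta = 14.5`; the point-searcher limit gives `alpha = 2/3`).
#'
#' @param L antenna length (bp); vectorised.
#' @param n_tilde chain site count.
#' @param R confining radius (bp).
#' @param D single-site diffusion coefficient (bp^2/t0; 1 in simulation
#'   units).
#' @param l0 bond length (bp).
#' @param alpha,beta dimensionless prefactors.
#' @return list with vectors `t_3d`, `t_1d`, `t_total` (time units of
#'   `bp^2 / D`).
#' @examples
#' t_total_theory(300, 4, 500, 1, 5)
#' @export
t_total_theory <- function(L, n_tilde, R, D = 1, l0 = 5,
                           alpha = 0.5, beta = 14.5) {
  r_p <- sqrt(n_tilde / 6) * l0
  if (any(L <= r_p)) stop("L must exceed the gyration radius r_p")
  t3 <- alpha * n_tilde * R^3 / (D * L) * log(L / r_p)
  t1 <- beta * L^2 / D
  list(t_3d = t3, t_1d = t1, t_total = t3 + t1)
}

#' Fit the search-time prefactors
#'
#' Weighted least squares of measured 3D times on
#' `(n_tilde R^3 / (D L)) log(L / r_p)` and measured 1D times on `L^2 / D`
#' (no intercepts), weights `1 / se^2`.
#'
#' @param data data frame with columns `L`, `t_3d`, `t_1d` and (optionally)
#'   `se_3d`, `se_1d`; needs >= 3 distinct `L`.
#' @param n_tilde,R,D,l0 model parameters (see [t_total_theory()]).
#' @return object of class `"search_time_fit"`: `alpha`, `beta`, their
#'   standard errors, the (diagonal) covariance and residual summaries.
#' @examples
#' L <- c(100, 200, 400)
#' th <- t_total_theory(L, 4, 500, 1, 5)
#' fit_alpha_beta(data.frame(L = L, t_3d = th$t_3d, t_1d = th$t_1d), 4, 500, 1, 5)
#' @export
fit_alpha_beta <- function(data, n_tilde, R, D = 1, l0 = 5) {
  stopifnot(all(c("L", "t_3d", "t_1d") %in% names(data)))
  if (length(unique(data$L)) < 3) stop("need at least 3 distinct L values")
  r_p <- sqrt(n_tilde / 6) * l0
  x3 <- n_tilde * R^3 / (D * data$L) * log(data$L / r_p)
  x1 <- data$L^2 / D
  w3 <- if ("se_3d" %in% names(data)) 1 / data$se_3d^2 else rep(1, nrow(data))
  w1 <- if ("se_1d" %in% names(data)) 1 / data$se_1d^2 else rep(1, nrow(data))
  f3 <- stats::lm(t_3d ~ 0 + x3, data = cbind(data, x3 = x3), weights = w3)
  f1 <- stats::lm(t_1d ~ 0 + x1, data = cbind(data, x1 = x1), weights = w1)
  s3 <- summary(f3)$coefficients
  s1 <- summary(f1)$coefficients
  structure(
    list(alpha = unname(s3[1, 1]), beta = unname(s1[1, 1]),
         alpha_se = unname(s3[1, 2]), beta_se = unname(s1[1, 2]),
         covariance = diag(c(s3[1, 2]^2, s1[1, 2]^2)),
         residuals_3d = stats::residuals(f3),
         residuals_1d = stats::residuals(f1),
         n_tilde = n_tilde, R = R, D = D, l0 = l0),
    class = "search_time_fit"
  )
}

#' @export
print.search_time_fit <- function(x, ...) {
  cat(sprintf("Search-time fit: alpha = %.3g +- %.2g, beta = %.3g +- %.2g\n",
              x$alpha, x$alpha_se, x$beta, x$beta_se))
  invisible(x)
}

#' Optimal antenna length
#'
#' Minimises the two-term search time over `L` by bracketed scalar
#' minimisation (relative tolerance 1e-6, ties toward smaller `L`).
#'
#' @inheritParams t_total_theory
#' @param L_max upper end of the search bracket (bp).
#' @return list with `L_star` (bp) and `t_min` (bp^2/D).
#' @examples
#' optimal_antenna(4, 500, 1, 5)
#' @export
optimal_antenna <- function(n_tilde, R, D = 1, l0 = 5,
                            alpha = 0.5, beta = 14.5, L_max = 20 * R) {
  r_p <- sqrt(n_tilde / 6) * l0
  obj <- function(L) t_total_theory(L, n_tilde, R, D, l0, alpha, beta)$t_total
  opt <- stats::optimize(obj, c(r_p * (1 + 1e-9), L_max), tol = 1e-6 * R)
  list(L_star = opt$minimum, t_min = opt$objective)
}

#' Minimal search time of a simple TF
#'
#' Diffusion-limited mean first-passage time of a point searcher to a
#' central absorbing sphere of radius `a` inside a reflecting sphere of
#' radius `R`: `t_simple = R^3 / (3 D a)`.
#'
#' @param R confining radius (bp).
#' @param D diffusion coefficient (bp^2/t0).
#' @param a absorber radius (bp).
#' @return time in `bp^2 / D` units.
#' @export
simple_tf_time <- function(R, D = 1, a = 0.5) {
  stopifnot(a > 0, a < R)
  R^3 / (3 * D * a)
}

#' Convert a search time and binding probability into biochemical rates
#'
#' With `copy_number` TFs searching independently, the effective per-cell
#' association time is `t_eff = t_total / copy_number` (seconds).  For one
#' target in the nuclear volume the target concentration is
#' `c = 1 / (V_nucleus N_A)`, and
#'
#'   k_on  = 1 / (t_eff c)          (M^-1 s^-1)
#'   k_off = (1 - P_TF) / (P_TF t_eff)   (s^-1)
#'   k_D   = k_off / k_on           (M)
#'
#' `t_total` is given in simulation units and converted through
#' `t0 = (0.34 nm)^2 / D_SI`.
#'
#' @param t_total search time in t0 units.
#' @param P_TF equilibrium binding probability, strictly inside (0, 1).
#' @param D_SI site diffusion coefficient in m^2/s.
#' @param copy_number number of TF copies.
#' @param nucleus_volume nuclear volume in m^3.
#' @return list with `k_on`, `k_off`, `k_D`, `t_search_s` (single-copy
#'   seconds) and `t_eff_s`.
#' @examples
#' tt <- optimal_antenna(4, 1e-6 / 0.34e-9, 1, 5)$t_min
#' binding_rates(tt, P_TF = 0.9)
#' @export
binding_rates <- function(t_total, P_TF, D_SI = 1e-13, copy_number = 100,
                          nucleus_volume = 4 / 3 * pi * (1e-6)^3) {
  if (!(P_TF > 0 && P_TF < 1)) stop("P_TF must lie strictly in (0, 1)")
  stopifnot(t_total > 0, D_SI > 0, copy_number > 0, nucleus_volume > 0)
  N_A <- 6.02214076e23
  t0 <- (0.34e-9)^2 / D_SI             # seconds per simulation time unit
  t_s <- t_total * t0
  t_eff <- t_s / copy_number
  c_target <- 1 / (nucleus_volume * 1000 * N_A)   # mol / L
  k_on <- 1 / (t_eff * c_target)
  k_off <- (1 - P_TF) / (P_TF * t_eff)
  list(k_on = k_on, k_off = k_off, k_D = k_off / k_on,
       t_search_s = t_s, t_eff_s = t_eff)
}
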