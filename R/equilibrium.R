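#' Single-contact enhancement factor
#'
#' The multiplicative gain in statistical weight contributed by one IDR
#' contact: `P = exp(E_B) * V1 * f(d, l0)`, with `f` the ideal-chain
#' propagator over one segment.  Always positive; for a single IDR site and
#' a single IDR target the affinity ratio is `Q = 1 + P` in the
#' volume-dominated regime.
#'
#' @param E_B IDR contact energy (kT, > 0).
#' @param d distance between the two targets (bp).
#' @param l0 segment length between the two chain sites (bp).
#' @param V1 target volume (bp^3).
#' @return dimensionless enhancement factor.
#' @examples
#' enhancement_factor(10, sqrt(50), sqrt(50), 1)
#' @export
enhancement_factor <- function(E_B, d, l0, V1 = 1) {
  stopifnot(E_B > 0, d > 0, V1 > 0)
  exp(E_B) * V1 * gaussian_propagator(d, 1, l0)
}

#' Threshold contact energy
#'
#' The per-contact energy at which the enhancement factor equals one when the
#' segment length matches the target spacing (`l0 = d`):
#'
#'   E_th = (3/2) * (log(2 pi / (3 phi^2)) + 1),
#'
#' where `phi = V1^{1/3} / d` is the linear fraction of the antenna occupied
#' by targets.  Above `E_th`, multivalent IDR binding dominates the affinity.
#'
#' @param phi dimensionless target fraction, `0 < phi <= 1`.
#' @return threshold energy in kT; decreasing in `phi`.
#' @examples
#' threshold_energy(sqrt(0.02))   # about 8.5 kT
#' @export
threshold_energy <- function(phi) {
  if (any(phi <= 0)) stop("phi must be positive")
  1.5 * (log(2 * pi / (3 * phi^2)) + 1)
}

#' Count or enumerate binding configurations
#'
#' Enumerates every injective partial matching of the IDR sites onto the IDR
#' targets (all site subsets, target subsets and orderings, including
#' order-crossing ones), each in a DBD-bound and a DBD-unbound variant:
#' `2 * sum_n C(n_b, n) C(n_t, n) n!` configurations in total.
#'
#' @param arch a [tf_architecture()].
#' @param layout a [target_layout()].
#' @param cap refuse to enumerate more configurations than this (the
#'   configuration *sum* in [binding_probability()] prunes negligible
#'   branches instead and has no such limit).
#' @return a data frame with one row per configuration: `dbd_bound`,
#'   `n_bound` (IDR contacts) and `matching` (a list column of integer
#'   vectors, `matching[[k]][i]` = target index bound by IDR site `i`, NA if
#'   unbound).
#' @examples
#' nrow(enumerate_configurations(tf_architecture(1, 5), target_layout(1, 5)))
#' @export
enumerate_configurations <- function(arch, layout, cap = 1e7) {
  n_b <- arch$n_b
  n_t <- layout$n_t
  n_pred <- configuration_count(n_b, n_t)
  if (n_pred > cap) {
    stop(sprintf(
      "%.3g configurations exceed the cap (%g); use binding_probability(), which prunes negligible weights",
      n_pred, cap
    ))
  }
  matchings <- list(rep(NA_integer_, n_b))
  if (n_b > 0 && n_t > 0) {
    for (n in seq_len(min(n_b, n_t))) {
      site_sets <- utils::combn(n_b, n, simplify = FALSE)
      tgt_sets <- utils::combn(n_t, n, simplify = FALSE)
      perms <- permutations_of(n)
      for (ss in site_sets) {
        for (ts in tgt_sets) {
          for (p in perms) {
            m <- rep(NA_integer_, n_b)
            m[ss] <- ts[p]
            matchings[[length(matchings) + 1]] <- m
          }
        }
      }
    }
  }
  out <- data.frame(
    dbd_bound = rep(c(FALSE, TRUE), each = length(matchings)),
    n_bound = rep(vapply(matchings, function(m) sum(!is.na(m)), 0L), 2)
  )
  out$matching <- c(matchings, matchings)
  out
}

# all permutations of 1..n as a list of integer vectors
permutations_of <- function(n) {
  if (n <= 1) return(list(seq_len(n)))
  sub <- permutations_of(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in 0:(n - 1)) {
      k <- k + 1
      out[[k]] <- append(p, as.integer(n), after = pos)
    }
  }
  out
}

#' Predicted number of binding configurations
#'
#' `2 * sum_{n=0}^{min(n_b, n_t)} C(n_b, n) C(n_t, n) n!` (the factor 2 is
#' the DBD bound/unbound choice).
#'
#' @param n_b,n_t counts of IDR sites and IDR targets.
#' @return numeric count.
#' @export
configuration_count <- function(n_b, n_t) {
  n <- 0:min(n_b, n_t)
  2 * sum(choose(n_b, n) * choose(n_t, n) * factorial(n))
}

#' Statistical weight of one binding configuration
#'
#' Weight convention (bp^3 throughout): the fully free state carries the
#' translational volume `V`; a bound configuration, with bound contacts
#' ordered by chain index, carries `exp(E_1) * V1` for the first contact and
#' `exp(E_k) * V1 * f(target separation, contour between the sites)` for
#' each further contact, where `E_k` is `E_DBD` for the DBD contact and
#' `E_B` otherwise.  Dangling unbound chain ends contribute a factor one.
#' This is the unique convention that reduces to `Q = 1 + P` for one site
#' and one target; it is verified independently against
#' [metropolis_binding()].
#'
#' @param dbd_bound logical flag.
#' @param matching integer vector of length `n_b` (target index per IDR
#'   site, NA = unbound), as produced by [enumerate_configurations()].
#' @param arch a [tf_architecture()].
#' @param layout a [target_layout()].
#' @param energy an [energy_model()].
#' @return the weight in bp^3 (strictly positive).
#' @export
configuration_weight <- function(dbd_bound, matching, arch, layout, energy) {
  sites <- integer(0)
  tgts <- integer(0)   # rows of layout$positions (1 = DBD target)
  if (dbd_bound) {
    sites <- 0L
    tgts <- 1L
  }
  bound <- which(!is.na(matching))
  sites <- c(sites, bound)
  tgts <- c(tgts, matching[bound] + 1L)
  if (length(sites) == 0) return(energy$V)
  e_per <- ifelse(sites == 0L, energy$E_DBD, energy$E_B)
  logw <- e_per[1] + log(energy$V1)
  if (length(sites) > 1) {
    for (k in 2:length(sites)) {
      dr <- layout$positions[tgts[k], ] - layout$positions[tgts[k - 1], ]
      r <- sqrt(sum(dr^2))
      l2 <- arch$cum_l2[sites[k] + 1] - arch$cum_l2[sites[k - 1] + 1]
      logw <- logw + e_per[k] + log(energy$V1) +
        1.5 * log(3 / (2 * pi * l2)) - 1.5 * r^2 / l2
    }
  }
  exp(logw)
}

#' Equilibrium binding probability by exact configuration sum
#'
#' Sums the statistical weights of all binding configurations (in log space,
#' with branch pruning of configurations whose Gaussian factor product falls
#' below `exp(log_prune)`) and returns the occupancy of the three state
#' classes together with the affinity ratio `Q = P_TF / P_simple`, where
#' `P_simple = exp(E_DBD) V1 / (V + exp(E_DBD) V1)` is the binding
#' probability of the bare DBD.
#'
#' @inheritParams configuration_weight
#' @param log_prune log of the Gaussian-product pruning threshold.
#' @return an object of class `"equilibrium_result"`: list with `P_free`,
#'   `P_IDR_only`, `P_TF`, `P_simple`, `Q`, `log_Z`, `n_configs` and the
#'   call parameters.  `P_free + P_IDR_only + P_TF = 1` to machine
#'   precision.
#' @examples
#' arch <- tf_architecture(1, sqrt(50))
#' lay <- target_layout(1, sqrt(50))
#' en <- energy_model(E_B = 10, E_DBD = 15, V1 = 1, V = nm3_to_bp3(1e9))
#' binding_probability(arch, lay, en)
#' @export
binding_probability <- function(arch, layout, energy, log_prune = log(1e-300)) {
  stopifnot(inherits(arch, "tf_architecture"), inherits(layout, "target_layout"),
            inherits(energy, "energy_model"))
  s <- config_sum_cpp(arch$n_b, arch$cum_l2, layout$positions,
                      energy$E_B, energy$E_DBD, energy$V1, energy$V,
                      log_prune)
  logs <- c(free = s$log_w_free, idr = s$log_w_idr, tf = s$log_w_tf)
  m <- max(logs)
  w <- exp(logs - m)
  Z <- sum(w)
  P <- w / Z
  P_simple <- 1 / (1 + exp(log(energy$V) - energy$E_DBD - log(energy$V1)))
  structure(
    list(
      P_free = unname(P["free"]), P_IDR_only = unname(P["idr"]),
      P_TF = unname(P["tf"]), P_simple = P_simple,
      Q = unname(P["tf"]) / P_simple,
      log_Z = m + log(Z), n_configs = s$n_configs,
      arch = arch, layout = layout, energy = energy
    ),
    class = "equilibrium_result"
  )
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium binding (%d IDR sites, %d IDR targets):\n",
              x$arch$n_b, x$layout$n_t))
  cat(sprintf("  P_TF = %.4g   P_IDR_only = %.4g   P_free = %.4g\n",
              x$P_TF, x$P_IDR_only, x$P_free))
  cat(sprintf("  P_simple = %.4g   Q = P_TF / P_simple = %.4g\n",
              x$P_simple, x$Q))
  invisible(x)
}

#' Weak-binding approximation to the affinity ratio
#'
#' Evaluates the low-occupancy approximation
#' `Q ~ 1 + sum over bound patterns of prod_i P(E_B, r_i, l_i)`, i.e. the
#' ratio of the total weight of DBD-bound configurations to the bare DBD
#' weight `exp(E_DBD) V1`.  Valid when `P_TF << 1`; reduces exactly to
#' `1 + P` for `n_b = n_t = 1`.
#'
#' @inheritParams binding_probability
#' @return the approximate `Q` (>= 1).
#' @export
approximate_q <- function(arch, layout, energy, log_prune = log(1e-300)) {
  s <- config_sum_cpp(arch$n_b, arch$cum_l2, layout$positions,
                      energy$E_B, energy$E_DBD, energy$V1, energy$V,
                      log_prune)
  exp(s$log_w_tf - energy$E_DBD - log(energy$V1))
}

#' Metropolis Monte Carlo estimate of the binding probability
#'
#' Independent continuous-space check on [binding_probability()]: the chain
#' (harmonic bonds) is sampled in a periodic cell of volume `V`; targets are
#' square wells of volume `V1` (depth `E_DBD` for the DBD pair, `E_B` for
#' IDR pairs).  Returns the occupancy of the DBD-bound state with a
#' batch-means standard error.  Intended for small systems
#' (`n_b, n_t <= ~3`) where the mixing is tractable.
#'
#' @inheritParams binding_probability
#' @param n_sweeps Monte Carlo sweeps (one local move per site plus one
#'   rigid translation and one conformation redraw per sweep).
#' @param seed integer seed.
#' @param n_batches batches for the standard error.
#' @param step_local standard deviation of the local displacement (bp).
#' @return list with `P_TF`, `se`, `batch_occupancy`, `acceptance_local` and
#'   a `converged` flag (batch means within 5 SE of each other).
#' @export
metropolis_binding <- function(arch, layout, energy, n_sweeps = 2e6,
                               seed = 1, n_batches = 20, step_local = 1) {
  r_well <- (3 * energy$V1 / (4 * pi))^(1 / 3)
  box <- energy$V^(1 / 3)
  res <- metropolis_binding_cpp(arch$segment_lengths, layout$positions,
                                energy$E_B, energy$E_DBD, r_well, box,
                                n_sweeps, burnin = n_sweeps * 0.1,
                                n_batches = n_batches,
                                step_local = step_local, seed = seed)
  occ <- res$batch_occupancy
  se <- stats::sd(occ) / sqrt(length(occ))
  m <- mean(occ)
  conv <- (max(occ) - min(occ)) <= 5 * max(se * sqrt(length(occ)), 1e-12) * 2
  list(P_TF = m, se = se, batch_occupancy = occ,
       acceptance_local = res$acceptance_local, converged = conv)
}
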