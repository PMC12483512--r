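#' Equilibrium design-principle scans
#'
#' Long-format parameter scans of the affinity ratio `Q` and the binding
#' probability `P_TF`:
#'
#' * `"l0_over_d"` — `Q` against the segment-length/spacing ratio for each
#'   `(n_b, n_t)` pair (the optimum sits near `l0 = d`);
#' * `"heatmap"` — `Q` over the `n_b x n_t` grid at `l0 = d`;
#' * `"contour"` — per contact energy, the minimal `n_t` reaching
#'   `P_TF >= threshold` for each `n_b`, plus the diagonal optimum
#'   `n_star` (minimal `n` with `n_b = n_t = n` reaching the threshold);
#' * `"energy"` — `Q` against `E_B` at `l0 = d` for each diagonal size,
#'   annotated with the threshold energy and the saturation level
#'   `1 / P_simple`;
#' * `"truncation"` — relative `P_TF` against the number of distal IDR
#'   sites removed (normalised to 1 at zero truncation), with the removed
#'   length also expressed in amino acids.
#'
#' @param scan one of `"l0_over_d"`, `"heatmap"`, `"contour"`, `"energy"`,
#'   `"truncation"`.
#' @param energy an [energy_model()]; `E_B` is overridden along the grid in
#'   the `"contour"` and `"energy"` scans.
#' @param d target spacing (bp).
#' @param n_b,n_t vectors of site/target counts used by the scan.
#' @param ratio grid of `l0 / d` values (`"l0_over_d"` scan).
#' @param E_B_grid contact-energy grid (`"contour"`, `"energy"` scans).
#' @param threshold `P_TF` threshold for the `"contour"` scan.
#' @param n_max largest diagonal size searched in the `"contour"` scan.
#' @param aa_per_segment amino acids represented by one coarse-grained
#'   segment (`"truncation"` scan x-axis).
#' @param E_DBD_truncation optional DBD energy override for the
#'   `"truncation"` scan (the single free parameter of that comparison).
#' @return a long-format `data.frame`; the `"energy"` scan carries the
#'   threshold energy and saturation as attributes `E_th` and `Q_max`.
#' @examples
#' scan_design_principles("heatmap", n_b = 1:3, n_t = 1:3)
#' @export
scan_design_principles <- function(scan = c("l0_over_d", "heatmap", "contour",
                                            "energy", "truncation"),
                                   energy = energy_model(10, 15, 1, nm3_to_bp3(1e9)),
                                   d = sqrt(50),
                                   n_b = c(1, 2, 4, 8), n_t = c(1, 2, 4, 8),
                                   ratio = seq(0.3, 2.5, by = 0.1),
                                   E_B_grid = seq(6, 16, by = 1),
                                   threshold = 0.9, n_max = 8,
                                   aa_per_segment = 20,
                                   E_DBD_truncation = NULL) {
  scan <- match.arg(scan)
  grid_cap <- 2e4
  switch(scan,
    l0_over_d = {
      grid <- expand.grid(n_b = n_b, n_t = n_t, ratio = ratio)
      if (nrow(grid) > grid_cap) stop("scan grid too large")
      grid$Q <- vapply(seq_len(nrow(grid)), function(i) {
        arch <- tf_architecture(grid$n_b[i], grid$ratio[i] * d)
        lay <- target_layout(grid$n_t[i], d)
        binding_probability(arch, lay, energy)$Q
      }, 0)
      grid
    },
    heatmap = {
      grid <- expand.grid(n_b = n_b, n_t = n_t)
      res <- lapply(seq_len(nrow(grid)), function(i) {
        binding_probability(tf_architecture(grid$n_b[i], d),
                            target_layout(grid$n_t[i], d), energy)
      })
      grid$Q <- vapply(res, `[[`, 0, "Q")
      grid$P_TF <- vapply(res, `[[`, 0, "P_TF")
      grid
    },
    contour = {
      rows <- list()
      for (EB in E_B_grid) {
        en <- energy_model(EB, energy$E_DBD, energy$V1, energy$V)
        ptf <- matrix(NA_real_, n_max, n_max)
        for (nb in seq_len(n_max)) {
          for (nt in seq_len(n_max)) {
            ptf[nb, nt] <- binding_probability(tf_architecture(nb, d),
                                               target_layout(nt, d), en)$P_TF
          }
        }
        min_nt <- apply(ptf, 1, function(p) {
          i <- which(p >= threshold)
          if (length(i)) min(i) else NA_integer_
        })
        diag_ok <- which(diag(ptf) >= threshold)
        n_star <- if (length(diag_ok)) min(diag_ok) else NA_integer_
        rows[[length(rows) + 1]] <- data.frame(
          E_B = EB, n_b = seq_len(n_max), min_n_t = min_nt, n_star = n_star
        )
      }
      do.call(rbind, rows)
    },
    energy = {
      grid <- expand.grid(n = n_b, E_B = E_B_grid)
      grid$Q <- vapply(seq_len(nrow(grid)), function(i) {
        en <- energy_model(grid$E_B[i], energy$E_DBD, energy$V1, energy$V)
        binding_probability(tf_architecture(grid$n[i], d),
                            target_layout(grid$n[i], d), en)$Q
      }, 0)
      phi <- energy$V1^(1 / 3) / d
      attr(grid, "E_th") <- threshold_energy(phi)
      P_simple <- 1 / (1 + energy$V / (exp(energy$E_DBD) * energy$V1))
      attr(grid, "Q_max") <- 1 / P_simple
      grid
    },
    truncation = {
      nb_full <- max(n_b)
      en <- if (is.null(E_DBD_truncation)) energy else {
        energy_model(energy$E_B, E_DBD_truncation, energy$V1, energy$V)
      }
      lay <- target_layout(max(n_t), d)
      ptf <- vapply(0:nb_full, function(removed) {
        binding_probability(tf_architecture(nb_full - removed, d),
                            lay, en)$P_TF
      }, 0)
      data.frame(
        removed_sites = 0:nb_full,
        truncation_aa = (0:nb_full) * aa_per_segment,
        P_TF = ptf,
        relative_P_TF = ptf / ptf[1]
      )
    }
  )
}

#' Robustness scan over randomised layouts and site spacings
#'
#' Repeats the affinity calculation over replicate layouts whose
#' inter-target spacings (and, optionally, chain segment lengths) are drawn
#' from exponential distributions — Poisson statistics of site and target
#' positions — and summarises the distribution of `Q` per grid point.
#'
#' @param n_b,n_t site/target counts.
#' @param energy an [energy_model()]; `E_B` is overridden when an
#'   `E_B_grid` is supplied.
#' @param mean_d mean target spacing (bp).
#' @param ratio grid of mean-segment-length / mean-spacing values.
#' @param E_B_grid optional energy grid; when given, `ratio` is fixed at 1.
#' @param n_replicates random layouts per grid point.
#' @param randomize_sites also draw the chain segment lengths from an
#'   exponential distribution (mean `ratio * mean_d`).
#' @param randomize_targets draw the target spacings from an exponential
#'   distribution; `FALSE` gives the zero-variance (equal-spaced) limit, in
#'   which every replicate reproduces the deterministic scan exactly.
#' @param seed integer master seed; replicate `k` at grid row `g` uses the
#'   derived stream `seed + 1000 * g + k`.
#' @return data frame with one row per grid point: median and quartiles of
#'   `Q` over replicates.
#' @export
randomized_layout_scan <- function(n_b = 4, n_t = 4,
                                   energy = energy_model(10, 15, 1, nm3_to_bp3(1e9)),
                                   mean_d = sqrt(50),
                                   ratio = seq(0.4, 2.2, by = 0.2),
                                   E_B_grid = NULL,
                                   n_replicates = 100,
                                   randomize_sites = TRUE,
                                   randomize_targets = TRUE,
                                   seed = 1) {
  grid <- if (is.null(E_B_grid)) {
    data.frame(ratio = ratio, E_B = energy$E_B)
  } else {
    data.frame(ratio = 1, E_B = E_B_grid)
  }
  out <- lapply(seq_len(nrow(grid)), function(g) {
    en <- energy_model(grid$E_B[g], energy$E_DBD, energy$V1, energy$V)
    l_mean <- grid$ratio[g] * mean_d
    qs <- vapply(seq_len(n_replicates), function(k) {
      sd_seed <- seed + 1000 * g + k
      lay <- if (randomize_targets) {
        target_layout(n_t, mean_d, mode = "poisson", seed = sd_seed)
      } else {
        target_layout(n_t, mean_d, mode = "equal")
      }
      segs <- if (randomize_sites) {
        set.seed(sd_seed + 5e8)
        stats::rexp(n_b, rate = 1 / l_mean)
      } else {
        rep(l_mean, n_b)
      }
      arch <- tf_architecture(n_b, l_mean, segment_lengths = segs)
      binding_probability(arch, lay, en)$Q
    }, 0)
    data.frame(ratio = grid$ratio[g], E_B = grid$E_B[g],
               Q_median = stats::median(qs),
               Q_q25 = unname(stats::quantile(qs, 0.25)),
               Q_q75 = unname(stats::quantile(qs, 0.75)))
  })
  do.call(rbind, out)
}
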