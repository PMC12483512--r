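#' Unit conventions
#'
#' All lengths in the package are measured in base pairs (1 bp = 0.34 nm),
#' energies in units of the thermal energy kT, volumes in bp^3, and times in
#' the diffusive unit t0 = bp^2 / D, where D is the diffusion coefficient of
#' one coarse-grained chain site.  SI quantities appear only at the
#' rate-conversion boundary (see [binding_rates()]).
#'
#' @name idrsearch-units
#' @keywords internal
NULL

#: one base pair in nanometres
BP_NM <- 0.34

#' Convert between base pairs and nanometres
#'
#' @param x numeric vector of lengths (or volumes for the `3` variants).
#' @return numeric vector in the target unit.
#' @examples
#' nm_to_bp(0.34)      # 1 bp
#' bp3_to_nm3(1)       # (0.34 nm)^3
#' @export
bp_to_nm <- function(x) x * BP_NM

#' @rdname bp_to_nm
#' @export
nm_to_bp <- function(x) x / BP_NM

#' @rdname bp_to_nm
#' @export
bp3_to_nm3 <- function(x) x * BP_NM^3

#' @rdname bp_to_nm
#' @export
nm3_to_bp3 <- function(x) x / BP_NM^3

#' Ideal-chain end-to-end probability density
#'
#' Probability density (per bp^3) of the vector separation between two sites
#' of an ideal Gaussian chain that are `n_seg` statistical segments apart:
#'
#'   f(r, l) = (3 / (2 pi l^2))^{3/2} exp(-3 r^2 / (2 l^2)),   l = sqrt(n_seg) l0.
#'
#' Each Cartesian component of the separation is normal with variance l^2/3,
#' so the density integrates to one over all space and `<r^2> = l^2`.
#'
#' @param r separation distance (bp), `r >= 0`; vectorised.
#' @param n_seg number of chain segments between the two sites (`>= 1`).
#'   Non-integer values are allowed (used for variable segment lengths, where
#'   the caller supplies the summed squared length through `n_seg * l0^2`).
#' @param l0 statistical segment length (bp, `> 0`).
#' @return probability density in bp^-3, strictly positive.
#' @examples
#' gaussian_propagator(0, 1, sqrt(50))
#' integrate(function(r) 4 * pi * r^2 * gaussian_propagator(r, 2, 5), 0, Inf)
#' @export
gaussian_propagator <- function(r, n_seg, l0) {
  if (any(n_seg < 1)) stop("n_seg must be >= 1")
  if (any(l0 <= 0)) stop("l0 must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  l2 <- n_seg * l0^2
  (3 / (2 * pi * l2))^1.5 * exp(-3 * r^2 / (2 * l2))
}

#' Coarse-grained transcription-factor architecture
#'
#' A TF is a linear ideal chain of `n_tilde = n_b + 1` sites: one terminal
#' DNA-binding-domain (DBD) site (chain index 0) followed by `n_b` IDR
#' binding sites connected by Gaussian segments.  Segment `i` joins site
#' `i - 1` to site `i`; by default all segments share the length `l0`, but a
#' per-segment vector can be given (used for Poisson-spaced binding sites).
#'
#' @param n_b number of IDR binding sites (`>= 0`).
#' @param l0 nominal segment length in bp (`> 0`).
#' @param segment_lengths optional numeric vector of length `n_b` with the
#'   individual segment lengths (bp); defaults to `rep(l0, n_b)`.
#' @return an object of class `"tf_architecture"` with fields `n_b`, `l0`,
#'   `n_tilde`, `segment_lengths`, `cum_l2` (cumulative squared contour,
#'   `cum_l2[i + 1]` = summed squared segment length from the DBD site to
#'   site `i`) and the gyration radius `r_p = sqrt(n_tilde / 6) * l0`.
#' @examples
#' arch <- tf_architecture(n_b = 3, l0 = 5)
#' arch$r_p
#' @export
tf_architecture <- function(n_b, l0, segment_lengths = NULL) {
  stopifnot(length(n_b) == 1, n_b >= 0, n_b == round(n_b))
  stopifnot(length(l0) == 1, l0 > 0)
  if (is.null(segment_lengths)) segment_lengths <- rep(l0, n_b)
  stopifnot(length(segment_lengths) == n_b, all(segment_lengths > 0))
  n_tilde <- n_b + 1
  structure(
    list(
      n_b = as.integer(n_b),
      l0 = l0,
      n_tilde = as.integer(n_tilde),
      segment_lengths = segment_lengths,
      cum_l2 = c(0, cumsum(segment_lengths^2)),
      r_p = sqrt(n_tilde / 6) * l0
    ),
    class = "tf_architecture"
  )
}

#' @export
print.tf_architecture <- function(x, ...) {
  cat(sprintf(
    "TF chain: %d IDR site(s) + 1 DBD site (n_tilde = %d), l0 = %g bp, r_p = %.3g bp\n",
    x$n_b, x$n_tilde, x$l0, x$r_p
  ))
  invisible(x)
}
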