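#' Target layout on the antenna
#'
#' Places the DBD target at the origin and `n_t` IDR targets on a straight
#' "antenna" line.  For the equilibrium calculations the IDR targets sit on
#' one side of the DBD target (distal order = increasing chain distance from
#' the DBD target), matching a chain whose DBD site is terminal; a
#' double-sided layout (targets alternating on both sides, as in the search
#' simulations) is available with `side = "both"`.
#'
#' @param n_t number of IDR targets (`>= 0`).
#' @param d nominal spacing between consecutive targets (bp, `> 0`).
#' @param mode `"equal"` for exact spacing `d`, `"poisson"` for independent
#'   exponential spacings with mean `d` (requires `seed` or an active RNG).
#' @param side `"one"` (default) or `"both"`.
#' @param axis unit 3-vector giving the antenna direction (default x-axis).
#' @param seed optional integer seed used only for `mode = "poisson"`.
#' @return an object of class `"target_layout"`: a list with `positions`
#'   (an `(n_t + 1) x 3` matrix, first row the DBD target at the origin, the
#'   remaining rows the IDR targets), `spacings`, `d`, `n_t`, `mode`, `side`,
#'   `axis` and the antenna span `L` (distance between extreme targets).
#' @examples
#' target_layout(4, d = 10)
#' @export
target_layout <- function(n_t, d, mode = c("equal", "poisson"),
                          side = c("one", "both"), axis = c(1, 0, 0),
                          seed = NULL) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  stopifnot(length(n_t) == 1, n_t >= 0, n_t == round(n_t))
  stopifnot(length(d) == 1, d > 0)
  stopifnot(length(axis) == 3, sum(axis^2) > 0)
  axis <- axis / sqrt(sum(axis^2))
  if (mode == "poisson") {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    spacings <- stats::rexp(n_t, rate = 1 / d)
  } else {
    spacings <- rep(d, n_t)
  }
  coords <- cumsum(spacings)                 # distance from the DBD target
  if (side == "both" && n_t > 0) {
    # alternate distal targets left/right of the DBD target
    half <- cumsum(spacings[seq(1, n_t, by = 2)])
    s <- numeric(n_t)
    s[seq(1, n_t, by = 2)] <- half
    if (n_t > 1) {
      half2 <- cumsum(spacings[seq(2, n_t, by = 2)])
      s[seq(2, n_t, by = 2)] <- -half2
    }
    coords <- s
  }
  positions <- rbind(0, outer(coords, axis))
  rownames(positions) <- c("DBD", if (n_t > 0) paste0("IDR", seq_len(n_t)))
  L <- if (n_t > 0) max(coords) - min(c(0, coords)) else 0
  structure(
    list(positions = positions, spacings = spacings, d = d,
         n_t = as.integer(n_t), mode = mode, side = side, axis = axis,
         L = L),
    class = "target_layout"
  )
}

#' @export
print.target_layout <- function(x, ...) {
  cat(sprintf(
    "Antenna layout: DBD target at origin + %d IDR target(s), %s spacing d = %g bp (%s-sided), span L = %.3g bp\n",
    x$n_t, x$mode, x$d, x$side, x$L
  ))
  invisible(x)
}

#' Energy and volume model for equilibrium binding
#'
#' @param E_B per-contact IDR binding energy in kT (`> 0`; the bound state has
#'   energy `-E_B`).
#' @param E_DBD DBD binding energy in kT (`> 0`).
#' @param V1 target (binding-site) volume in bp^3.
#' @param V confining (nucleus) volume in bp^3; must greatly exceed `V1`.
#' @return object of class `"energy_model"`.
#' @examples
#' energy_model(E_B = 10, E_DBD = 15, V1 = 1, V = nm3_to_bp3(1e9))  # 1 um^3
#' @export
energy_model <- function(E_B, E_DBD, V1 = 1, V = nm3_to_bp3(1e9)) {
  stopifnot(E_B > 0, E_DBD > 0, V1 > 0, V > 0)
  if (V <= 100 * V1) stop("V must be much larger than V1")
  structure(list(E_B = E_B, E_DBD = E_DBD, V1 = V1, V = V),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    "Energies: E_B = %g kT, E_DBD = %g kT; V1 = %g bp^3, V = %.4g bp^3\n",
    x$E_B, x$E_DBD, x$V1, x$V
  ))
  invisible(x)
}
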