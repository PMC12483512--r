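#' Bound-site count time series
#'
#' Number of chain sites within the capture radius of any target, per
#' subsample of a search trajectory.  With the default capture radius this
#' simply returns the series recorded during the simulation; the series
#' stride should not exceed `w_d^2 / D` for the on/off events to be
#' resolved.
#'
#' @param record a [run_search()] record with `store_series = TRUE`.
#' @return data frame with columns `time` and `n_bound`.
#' @export
bound_count_series <- function(record) {
  if (is.null(record$series)) stop("record has no stored series")
  if (record$config$sample_dt > record$config$w_d^2) {
    warning("series stride exceeds w_d^2 / D; on/off events may be missed")
  }
  data.frame(time = record$series$time, n_bound = record$series$n_bound)
}

# contiguous attached segments (>= 1 bound site) of a record's series;
# returns a list of index ranges
attached_segments <- function(record, min_len = 2) {
  nb <- record$series$n_bound
  att <- nb >= 1
  r <- rle(att)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  Map(function(s, e) s:e, starts[keep], ends[keep])
}

#' Effective 1D diffusion coefficient of the octopusing walk
#'
#' Mean squared displacement of the antenna-axis centre-of-mass coordinate
#' within attached episodes (at least one site within the capture radius),
#' fitted linearly over a stated lag window; `D1 = slope / 2`.
#'
#' @param records list of [run_search()] records with stored series, or a
#'   single record.
#' @param lag_range lag window in series strides used for the fit.
#' @return list with `D1` (bp^2/t0), `se`, `fit_lags`, `msd`, and
#'   `n_segments`; `D1` is `NA` (with a diagnostic message) when no
#'   attached episode is long enough.
#' @export
effective_d1 <- function(records, lag_range = c(10, 100)) {
  if (inherits(records, "first_passage_record")) records <- list(records)
  lags <- seq(lag_range[1], lag_range[2])
  acc <- matrix(0, length(lags), 2)  # sum of squared displacement, count
  n_seg <- 0
  dt <- NULL
  for (rec in records) {
    if (is.null(rec$series)) next
    dt <- rec$config$sample_dt
    for (idx in attached_segments(rec)) {
      z <- rec$series$z_com[idx]
      n_seg <- n_seg + 1
      for (k in seq_along(lags)) {
        lag <- lags[k]
        if (length(z) > lag) {
          dz <- z[(1 + lag):length(z)] - z[1:(length(z) - lag)]
          acc[k, 1] <- acc[k, 1] + sum(dz^2)
          acc[k, 2] <- acc[k, 2] + length(dz)
        }
      }
    }
  }
  ok <- acc[, 2] > 0
  if (sum(ok) < 3) {
    message("no attached episode long enough for a D1 fit")
    return(list(D1 = NA_real_, se = NA_real_, fit_lags = lags,
                msd = rep(NA_real_, length(lags)), n_segments = n_seg))
  }
  msd <- ifelse(ok, acc[, 1] / pmax(acc[, 2], 1), NA)
  tau <- lags * dt
  fit <- stats::lm(msd[ok] ~ 0 + tau[ok])
  sl <- summary(fit)$coefficients
  list(D1 = unname(sl[1, 1]) / 2, se = unname(sl[1, 2]) / 2,
       fit_lags = lags, msd = msd, n_segments = n_seg)
}

#' On/off feedback statistics of the octopusing walk
#'
#' Conditional transition rates of the bound-site count `m`: for each
#' populated level, the rate of gaining (`m -> m + 1`) and losing
#' (`m -> m - 1`) a contact, estimated from consecutive series samples as
#' (transition count) / (time spent at `m`).  The compensatory feedback of
#' the walk appears as an on-rate decreasing in `m` and an off-rate
#' increasing in `m`.
#'
#' @param records list of records with stored series (or a single record).
#' @param min_time minimal occupancy time (t0) for a level to be reported.
#' @return data frame with columns `m`, `time_at_m`, `n_up`, `n_down`,
#'   `rate_up`, `rate_down`, `sparse` (flag for thinly populated levels).
#' @export
feedback_statistics <- function(records, min_time = 10) {
  if (inherits(records, "first_passage_record")) records <- list(records)
  time_at <- numeric(0)
  n_up <- numeric(0)
  n_down <- numeric(0)
  bump <- function(v, i, by) {
    if (length(v) < i + 1) v <- c(v, numeric(i + 1 - length(v)))
    v[i + 1] <- v[i + 1] + by
    v
  }
  for (rec in records) {
    if (is.null(rec$series)) next
    nb <- rec$series$n_bound
    dt <- rec$config$sample_dt
    if (length(nb) < 2) next
    for (j in seq_len(length(nb) - 1)) {
      m <- nb[j]
      time_at <- bump(time_at, m, dt)
      if (nb[j + 1] > m) n_up <- bump(n_up, m, 1)
      if (nb[j + 1] < m) n_down <- bump(n_down, m, 1)
    }
  }
  levels <- seq_along(time_at) - 1
  pad <- function(v) c(v, numeric(length(levels) - length(v)))
  n_up <- pad(n_up)
  n_down <- pad(n_down)
  out <- data.frame(
    m = levels, time_at_m = time_at, n_up = n_up, n_down = n_down,
    rate_up = ifelse(time_at > 0, n_up / time_at, NA),
    rate_down = ifelse(time_at > 0, n_down / time_at, NA),
    sparse = time_at < min_time
  )
  out
}

#' Summary of the octopusing walk
#'
#' @param records list of records with stored series.
#' @param lag_range lag window passed to [effective_d1()].
#' @return object of class `"octopus_summary"`: mean bound count and
#'   normalised histogram over attached samples, `D1` estimate, overall
#'   detachment rate (full-detachment events per attached time), fraction
#'   of time attached, and the feedback table.
#' @export
octopus_summary <- function(records, lag_range = c(10, 100)) {
  if (inherits(records, "first_passage_record")) records <- list(records)
  nb_all <- unlist(lapply(records, function(r) r$series$n_bound))
  dt <- records[[1]]$config$sample_dt
  att <- nb_all[nb_all >= 1]
  hist <- table(factor(att, levels = 0:max(nb_all)))
  hist <- as.numeric(hist) / max(length(att), 1)
  detach_events <- sum(vapply(records, function(r) length(r$detach_times), 0))
  attached_time <- length(att) * dt
  structure(
    list(
      mean_bound = mean(att),
      bound_histogram = data.frame(m = 0:max(nb_all), frequency = hist),
      D1 = effective_d1(records, lag_range),
      detachment_rate = detach_events / max(attached_time, .Machine$double.eps),
      fraction_attached = length(att) / max(length(nb_all), 1),
      feedback = feedback_statistics(records)
    ),
    class = "octopus_summary"
  )
}

#' @export
print.octopus_summary <- function(x, ...) {
  cat(sprintf(
    "Octopusing walk: mean bound sites %.2f, attached %.0f%% of the time, D1 = %.3g bp^2/t0, detachment rate %.3g / t0\n",
    x$mean_bound, 100 * x$fraction_attached,
    x$D1$D1, x$detachment_rate
  ))
  invisible(x)
}
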