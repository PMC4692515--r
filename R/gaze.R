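#' Simulate gaze recordings for an imagery session
#'
#' Produces a fixation trace (Gaussian jitter around the screen center)
#' sampled at a fixed rate over the concatenated runs of an event table.
#' If `direction_lock` is given, each trial receives `saccades_per_trial`
#' injected saccades: smooth sigmoidal position steps whose direction is
#' the locked angle of the trial's condition plus von Mises noise. Blinks
#' are simulated as drops of the pupil aspect ratio with gaze dropout
#' (missing x/y samples).
#'
#' @param events An `event_table`.
#' @param direction_lock Named numeric vector mapping condition labels to
#'   saccade angles in degrees, or `NULL` for pure fixation.
#' @param blink_rate_hz Expected blink rate (Poisson, per second).
#' @param sampling_rate_hz Sampling rate (default 60 Hz, typical for
#'   MR-compatible video trackers).
#' @param noise_sd_deg Fixation jitter SD in degrees.
#' @param saccade_amplitude_deg Amplitude of injected saccades.
#' @param saccades_per_trial Injected saccades per trial when locked.
#' @param kappa von Mises concentration of the direction noise.
#' @param seed Integer seed.
#' @return A `gaze_recording` data frame with columns
#'   `time`, `x`, `y`, `par`, `trial`, `condition` (trial 0 outside trials)
#'   and attributes `sampling_rate_hz` and `saccade_log` (ground-truth
#'   injected events: trial, time, angle_deg).
#' @export
generate_gaze <- function(events, direction_lock = NULL, blink_rate_hz = 0,
                          sampling_rate_hz = 60, noise_sd_deg = 0.03,
                          saccade_amplitude_deg = 1, saccades_per_trial = 1,
                          kappa = 100, seed = 1L) {
  if (blink_rate_hz < 0 || sampling_rate_hz <= 0)
    stop("rates must be non-negative (sampling rate positive)")
  tr_s <- attr(events, "tr_s")
  if (is.null(tr_s)) tr_s <- 2
  n_volumes <- events_n_volumes(events, tr_s)
  runs <- sort(unique(events$run))
  dt <- 1 / sampling_rate_hz
  with_seed(derive_seed(seed, "gaze"), {
    pieces <- vector("list", length(runs))
    logs <- list()
    t0 <- 0
    for (ri in seq_along(runs)) {
      dur <- n_volumes[ri] * tr_s
      n <- as.integer(round(dur * sampling_rate_hz))
      tt <- t0 + (seq_len(n) - 1L) * dt
      x <- stats::rnorm(n, sd = noise_sd_deg)
      y <- stats::rnorm(n, sd = noise_sd_deg)
      par <- 1 + stats::rnorm(n, sd = 0.01)
      trial <- integer(n)
      cond <- integer(n)
      e <- events[events$run == runs[ri], , drop = FALSE]
      e_global <- which(events$run == runs[ri])
      rel <- tt - t0
      for (j in seq_len(nrow(e))) {
        sel <- rel >= e$onset[j] & rel < e$onset[j] + e$duration[j]
        trial[sel] <- e_global[j]
        cond[sel] <- e$condition[j]
        if (!is.null(direction_lock)) {
          ang0 <- direction_lock[as.character(e$condition[j])]
          if (!is.na(ang0)) {
            for (s in seq_len(saccades_per_trial)) {
              ang <- (ang0 + rvonmises(1, 0, kappa) * 180 / pi) %% 360
              # saccade center placed away from trial edges
              t_sac <- e$onset[j] + stats::runif(1, 0.2, e$duration[j] - 0.2)
              step <- saccade_amplitude_deg /
                (1 + exp(-(rel - t_sac) / 0.008))
              on_trial <- sel  # step applies within the trial only
              x[on_trial] <- x[on_trial] +
                cospi(ang / 180) * step[on_trial]
              y[on_trial] <- y[on_trial] +
                sinpi(ang / 180) * step[on_trial]
              logs[[length(logs) + 1L]] <-
                data.frame(trial = e_global[j], time = t0 + t_sac,
                           angle_deg = ang)
            }
          }
        }
      }
      if (blink_rate_hz > 0) {
        n_blinks <- stats::rpois(1, blink_rate_hz * dur)
        if (n_blinks > 0) {
          starts <- sort(stats::runif(n_blinks, 0, dur - 0.3))
          for (b in starts) {
            sel <- rel >= b & rel < b + 0.2
            par[sel] <- 0.2 + stats::rnorm(sum(sel), sd = 0.01)
            x[sel] <- NA_real_
            y[sel] <- NA_real_
          }
        }
      }
      pieces[[ri]] <- data.frame(time = tt, x = x, y = y, par = par,
                                 trial = trial, condition = cond)
      t0 <- t0 + dur
    }
    gz <- do.call(rbind, pieces)
    rownames(gz) <- NULL
    structure(gz, sampling_rate_hz = sampling_rate_hz,
              saccade_log = if (length(logs)) do.call(rbind, logs)
                            else data.frame(trial = integer(), time = numeric(),
                                            angle_deg = numeric()),
              class = c("gaze_recording", "data.frame"))
  })
}

# von Mises sampler (Best & Fisher 1979 rejection method); radians
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

#' Write / read gaze recordings as CSV
#'
#' Format: header `time,x,y,par,trial,condition`, one row per sample.
#'
#' @param gaze A `gaze_recording`.
#' @param path File path.
#' @param sampling_rate_hz Restored onto the read recording.
#' @export
write_gaze <- function(gaze, path) {
  utils::write.csv(as.data.frame(gaze), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path, sampling_rate_hz = NULL) {
  gz <- utils::read.csv(path)
  stopifnot(all(c("time", "x", "y", "par", "trial", "condition") %in% names(gz)))
  if (is.null(sampling_rate_hz))
    sampling_rate_hz <- 1 / stats::median(diff(gz$time))
  structure(gz, sampling_rate_hz = sampling_rate_hz,
            class = c("gaze_recording", "data.frame"))
}
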