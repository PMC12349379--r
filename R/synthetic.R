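#' Specification for a synthetic multimodal recording
#'
#' Describes a simulated binocular pupillometry recording with an
#' independent facial-expression stream, used to validate every pipeline
#' stage against known ground truth.  The clean pupil signal is a baseline
#' plus slow hippus (spontaneous oscillation) plus smooth raised-cosine
#' task-evoked dilation events; the right eye is an affine function of the
#' left plus noise (stable anisocoria).  Artifacts mirror what video
#' eye trackers actually produce: full blinks (a fast in-range closing
#' edge, a span of missing samples, a fast reopening edge), single-sample
#' partial-occlusion spikes, physically impossible out-of-range values,
#' and duplicated rows from export glitches.
#'
#' Defaults describe a typical adult recording on a 120 Hz tracker:
#' 4 mm baseline, 0.02 mm measurement noise, 12 blinks/min of 150-400 ms,
#' occasional occlusion spikes of 0.4-0.9 mm apparent constriction.
#'
#' @param duration_s recording length in seconds.
#' @param pupil_rate_hz pupil sampling rate (default 120).
#' @param facial_rate_hz facial stream rate (default 30).
#' @param baseline_mm true baseline diameter, inside (2, 8).
#' @param event_rate_per_min rate of evoked dilation events.
#' @param event_amplitude_mm amplitude range (mm) of dilation events.
#' @param event_duration_s duration range (s) of dilation events.
#' @param hippus_amplitude_mm amplitude of the slow oscillation.
#' @param hippus_freq_hz frequency of the slow oscillation.
#' @param measurement_noise_sd per-sample tracker noise (mm).
#' @param eye_coupling list with `slope`, `intercept`, `noise_sd` giving
#'   right = slope * left + intercept + noise.
#' @param blink_rate_per_min blink events per minute (both eyes).
#' @param blink_duration_range_ms blink duration range (default 150-400 ms).
#' @param occlusion_spike_rate_per_min single-sample spikes per minute per eye.
#' @param spike_amplitude_mm apparent constriction range of a spike (mm).
#' @param out_of_range_rate_per_min impossible-value samples per minute per eye.
#' @param duplicate_timestamp_rate fraction of pupil rows duplicated verbatim.
#' @param quiet_period_s initial span kept free of dilation events so a
#'   baseline window exists.
#' @param seed integer seed; a fixed seed makes the recording reproducible
#'   byte for byte.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_s = 60,
                           pupil_rate_hz = 120,
                           facial_rate_hz = 30,
                           baseline_mm = 4.0,
                           event_rate_per_min = 4,
                           event_amplitude_mm = c(0.2, 0.6),
                           event_duration_s = c(1, 3),
                           hippus_amplitude_mm = 0.1,
                           hippus_freq_hz = 0.2,
                           measurement_noise_sd = 0.02,
                           eye_coupling = list(slope = 0.9, intercept = 0.3,
                                               noise_sd = 0.02),
                           blink_rate_per_min = 12,
                           blink_duration_range_ms = c(150, 400),
                           occlusion_spike_rate_per_min = 6,
                           spike_amplitude_mm = c(0.4, 0.9),
                           out_of_range_rate_per_min = 4,
                           duplicate_timestamp_rate = 0.005,
                           quiet_period_s = 2,
                           seed = NULL) {
  spec <- as.list(environment())
  rates <- c(event_rate_per_min, blink_rate_per_min,
             occlusion_spike_rate_per_min, out_of_range_rate_per_min,
             duplicate_timestamp_rate, measurement_noise_sd,
             eye_coupling$noise_sd)
  if (any(rates < 0)) stop("synthetic_spec: rates and noise must be >= 0")
  if (duration_s <= 0) stop("synthetic_spec: duration must be positive")
  if (baseline_mm <= 2 || baseline_mm >= 8) {
    stop("synthetic_spec: baseline must lie strictly inside (2, 8) mm")
  }
  if (blink_duration_range_ms[1] > blink_duration_range_ms[2] ||
      blink_duration_range_ms[1] <= 0) {
    stop("synthetic_spec: invalid blink duration range")
  }
  structure(spec, class = "synthetic_spec")
}

# Clean (noise- and artifact-free) signal closure for a drawn recording.
make_clean_fun <- function(baseline, hip_amp, hip_freq, hip_phase, events) {
  force(events)
  function(t_ms) {
    t_s <- t_ms / 1000
    y <- baseline + hip_amp * sin(2 * pi * hip_freq * t_s + hip_phase)
    if (nrow(events) > 0) {
      for (e in seq_len(nrow(events))) {
        on <- events$onset_s[e]; du <- events$duration_s[e]
        inside <- t_s >= on & t_s <= on + du
        y[inside] <- y[inside] + events$amplitude_mm[e] / 2 *
          (1 - cos(2 * pi * (t_s[inside] - on) / du))
      }
    }
    y
  }
}

#' Generate a synthetic multimodal recording with ground truth
#'
#' Draws a recording according to `spec` and returns both the corrupted
#' wide table (the same dialect [read_multimodal()] parses, with pupil and
#' facial rows interleaved on their own misaligned timestamp grids) and
#' the ground truth: the clean binocular series, a per-sample artifact
#' label for each eye, the true baseline and coupling coefficients, and a
#' function evaluating the clean signal at arbitrary times.
#'
#' Artifact labels are `"clean"`, `"blink_step"` (the fast in-range
#' closing/reopening edge samples of a blink), `"blink"` (missing samples
#' during closure), `"occlusion"`, `"out_of_range"`, and `"duplicate"`
#' (verbatim row copies).  Labels align 1:1 with the pupil rows of the
#' emitted table (`truth$pupil_rows` gives their row indices).
#'
#' @param spec a `synthetic_spec`.
#' @return A list with elements `table` (class `multimodal_table`) and
#'   `truth`.
#' @export
generate_recording <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  period <- 1000 / spec$pupil_rate_hz
  n <- floor(spec$duration_s * spec$pupil_rate_hz)
  t_pupil <- (seq_len(n) - 1) * period
  dur_min <- spec$duration_s / 60

  # -- clean signal ---------------------------------------------------------
  hip_phase <- stats::runif(1, 0, 2 * pi)
  n_ev <- stats::rpois(1, spec$event_rate_per_min * dur_min)
  events <- data.frame(
    onset_s = stats::runif(n_ev, spec$quiet_period_s,
                           max(spec$quiet_period_s, spec$duration_s)),
    duration_s = stats::runif(n_ev, spec$event_duration_s[1],
                              spec$event_duration_s[2]),
    amplitude_mm = stats::runif(n_ev, spec$event_amplitude_mm[1],
                                spec$event_amplitude_mm[2])
  )
  clean_at <- make_clean_fun(spec$baseline_mm, spec$hippus_amplitude_mm,
                             spec$hippus_freq_hz, hip_phase, events)
  clean_left <- clean_at(t_pupil)
  clean_right <- spec$eye_coupling$slope * clean_left +
    spec$eye_coupling$intercept

  obs_left <- clean_left + stats::rnorm(n, 0, spec$measurement_noise_sd)
  obs_right <- clean_right +
    stats::rnorm(n, 0, spec$eye_coupling$noise_sd) +
    stats::rnorm(n, 0, spec$measurement_noise_sd)
  lab_left <- rep("clean", n)
  lab_right <- rep("clean", n)

  # -- blinks (both eyes close together) ------------------------------------
  n_blink <- stats::rpois(1, spec$blink_rate_per_min * dur_min)
  if (n_blink > 0) {
    starts <- sort(sample.int(n, n_blink))
    last_end <- -Inf
    for (s in starts) {
      dur_ms <- stats::runif(1, spec$blink_duration_range_ms[1],
                             spec$blink_duration_range_ms[2])
      nb <- max(6L, round(dur_ms / period))
      if (s <= last_end + 2 || s + nb - 1 > n) next
      idx <- s:(s + nb - 1)
      edge_in <- c(idx[1], idx[2])            # closing edge (still in range)
      edge_out <- c(idx[nb - 1], idx[nb])     # reopening edge
      closure <- idx[3:(nb - 2)]
      for (eye in c("left", "right")) {
        base_here <- if (eye == "left") clean_left[s] else clean_right[s]
        e_close <- base_here * stats::runif(2, c(0.78, 0.55), c(0.85, 0.65))
        e_open <- base_here * stats::runif(2, c(0.55, 0.78), c(0.65, 0.85))
        if (eye == "left") {
          obs_left[edge_in] <- e_close; obs_left[edge_out] <- e_open
          obs_left[closure] <- NA
          lab_left[c(edge_in, edge_out)] <- "blink_step"
          lab_left[closure] <- "blink"
        } else {
          obs_right[edge_in] <- e_close; obs_right[edge_out] <- e_open
          obs_right[closure] <- NA
          lab_right[c(edge_in, edge_out)] <- "blink_step"
          lab_right[closure] <- "blink"
        }
      }
      last_end <- s + nb - 1
    }
  }

  # -- single-sample partial-occlusion spikes -------------------------------
  inject_spikes <- function(obs, lab) {
    n_sp <- stats::rpois(1, spec$occlusion_spike_rate_per_min * dur_min)
    pool <- which(lab == "clean")
    # spikes must be isolated single samples between clean neighbours
    pool <- pool[pool > 1 & pool < n &
                   lab[pmax(pool - 1, 1)] == "clean" &
                   lab[pmin(pool + 1, n)] == "clean"]
    n_sp <- min(n_sp, length(pool))
    if (n_sp > 0) {
      at <- sample(pool, n_sp)
      obs[at] <- obs[at] - stats::runif(n_sp, spec$spike_amplitude_mm[1],
                                        spec$spike_amplitude_mm[2])
      lab[at] <- "occlusion"
    }
    list(obs = obs, lab = lab)
  }
  z <- inject_spikes(obs_left, lab_left); obs_left <- z$obs; lab_left <- z$lab
  z <- inject_spikes(obs_right, lab_right); obs_right <- z$obs; lab_right <- z$lab

  # -- out-of-range tracker failures ----------------------------------------
  inject_oor <- function(obs, lab) {
    n_or <- stats::rpois(1, spec$out_of_range_rate_per_min * dur_min)
    pool <- which(lab == "clean")
    n_or <- min(n_or, length(pool))
    if (n_or > 0) {
      at <- sample(pool, n_or)
      low <- stats::runif(n_or) < 0.5
      obs[at] <- ifelse(low, stats::runif(n_or, 0.2, 1.5),
                        stats::runif(n_or, 8.5, 12))
      lab[at] <- "out_of_range"
    }
    list(obs = obs, lab = lab)
  }
  z <- inject_oor(obs_left, lab_left); obs_left <- z$obs; lab_left <- z$lab
  z <- inject_oor(obs_right, lab_right); obs_right <- z$obs; lab_right <- z$lab

  # -- duplicated export rows -----------------------------------------------
  pupil <- data.frame(time = t_pupil, left = obs_left, right = obs_right,
                      lab_left = lab_left, lab_right = lab_right,
                      clean_left = clean_left, clean_right = clean_right,
                      stringsAsFactors = FALSE)
  if (spec$duplicate_timestamp_rate > 0) {
    dup <- which(stats::runif(n) < spec$duplicate_timestamp_rate)
    if (length(dup) > 0) {
      copies <- pupil[dup, , drop = FALSE]
      copies$lab_left <- "duplicate"
      copies$lab_right <- "duplicate"
      pupil <- rbind(pupil, copies)
      # stable sort keeps the original ahead of its copy
      pupil <- pupil[order(pupil$time), , drop = FALSE]
    }
  }

  # -- facial stream on its own 30 Hz grid ----------------------------------
  nf <- floor(spec$duration_s * spec$facial_rate_hz)
  t_facial <- stats::runif(1, 0, 1000 / spec$facial_rate_hz) +
    (seq_len(nf) - 1) * 1000 / spec$facial_rate_hz
  ar1 <- function(nf, mu, sd) {
    x <- numeric(nf)
    x[1] <- mu
    for (i in seq_len(nf - 1)) x[i + 1] <- mu + 0.95 * (x[i] - mu) +
        stats::rnorm(1, 0, sd)
    pmin(pmax(x, 0), 100)
  }
  facial <- data.frame(Engagement = ar1(nf, 55, 2),
                       Joy = ar1(nf, 12, 1.5),
                       Surprise = ar1(nf, 8, 1))

  # -- assemble the interleaved wide table ----------------------------------
  cmap <- default_column_map()
  prow <- data.frame(Timestamp = pupil$time,
                     ET_PupilLeft = pupil$left,
                     ET_PupilRight = pupil$right,
                     Engagement = NA_real_, Joy = NA_real_,
                     Surprise = NA_real_)
  frow <- data.frame(Timestamp = t_facial,
                     ET_PupilLeft = NA_real_, ET_PupilRight = NA_real_,
                     facial)
  is_pupil <- c(rep(TRUE, nrow(prow)), rep(FALSE, nrow(frow)))
  tab <- rbind(prow, frow)
  o <- order(tab$Timestamp)
  tab <- tab[o, , drop = FALSE]
  is_pupil <- is_pupil[o]
  rownames(tab) <- NULL
  tab <- structure(tab, column_map = cmap,
                   class = c("multimodal_table", "data.frame"))

  truth <- list(
    time = pupil$time,
    clean_left = pupil$clean_left,
    clean_right = pupil$clean_right,
    labels_left = pupil$lab_left,
    labels_right = pupil$lab_right,
    pupil_rows = which(is_pupil),
    baseline_mm = spec$baseline_mm,
    coupling = spec$eye_coupling,
    clean_at = clean_at,
    events = events,
    spec = spec
  )
  list(table = tab, truth = truth)
}
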