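# Synthetic postictal EEG with known ground truth: a suppression interval of
# low-amplitude noise, resumption via intermittent slow-wave bursts over a
# postictal background, and optional artifact bursts with configurable
# per-channel / per-time profiles.

# zero-phase band-pass for a plain vector (reflective padding)
.bp_vec <- function(x, low, high, fs, order = 4L) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / low)))
  xp <- c(2 * x[1L] - rev(x[2L:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]
}

# band-limited (0.5-30 Hz) Gaussian noise with RMS `sigma`
.bg_noise <- function(n, fs, sigma) {
  if (sigma <= 0) return(numeric(n))
  x <- .bp_vec(rnorm(n), 0.5, 30, fs)
  x / sd(x) * sigma
}

#' Parameters of the synthetic postictal EEG generator
#'
#' Defaults describe the study conditions the pipeline targets: an
#' 18-channel, 200 Hz, 5-minute postictal window; suppression-level noise
#' well below the 10 uV peak-to-peak attenuation criterion; intermittent
#' slow waves (ISW) in the 0.5-5 Hz band resuming after the suppression
#' interval.
#'
#' @param n_channels Number of channels (default 18, the canonical montage).
#' @param fs Sampling frequency in Hz (default 200).
#' @param duration Window length in seconds (default 300).
#' @param pges_duration Suppression duration in seconds (first-ISW time), or
#'   `NA` for a recording without PGES.
#' @param background_sigma RMS of the non-suppressed postictal background in
#'   microvolts (default 10).
#' @param suppression_sigma RMS during suppression in microvolts (default
#'   1.0; keeps per-epoch peak-to-peak below 10 uV on every channel).
#' @param isw_rate ISW burst rate after PGES end, bursts per second
#'   (default 0.5).
#' @param isw_band ISW frequency band in Hz (default `c(0.5, 5)`).
#' @param isw_amplitude Typical ISW burst amplitude in microvolts
#'   (default 40).
#' @param archetypes List of [artifact_archetype()] objects to superimpose.
#' @param seed Integer RNG seed; the simulation is deterministic given it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_channels = 18L, fs = 200, duration = 300,
                              pges_duration = 40, background_sigma = 10,
                              suppression_sigma = 1.0, isw_rate = 0.5,
                              isw_band = c(0.5, 5), isw_amplitude = 40,
                              archetypes = list(), seed = 1L) {
  stopifnot(n_channels >= 1L, fs > 0, duration > 0,
            isw_band[1L] >= 0.5, isw_band[2L] <= 5,
            isw_band[1L] < isw_band[2L])
  if (!is.na(pges_duration) && pges_duration > duration) {
    stop("pges_duration (", pges_duration,
         " s) exceeds the recording duration (", duration, " s)")
  }
  structure(list(n_channels = n_channels, fs = fs, duration = duration,
                 pges_duration = pges_duration,
                 background_sigma = background_sigma,
                 suppression_sigma = suppression_sigma,
                 isw_rate = isw_rate, isw_band = isw_band,
                 isw_amplitude = isw_amplitude,
                 archetypes = archetypes, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Artifact archetype: a spatiotemporal artifact pattern
#'
#' Describes one family of physiological artifacts: which channels it
#' touches, when it is active (seconds after seizure end), how strong it is,
#' and its kind — `breathing` (0.2-0.5 Hz high-amplitude rhythm), `muscle`
#' (20-30 Hz broadband bursts) or `movement` (large smooth transients).
#'
#' @param name Archetype label.
#' @param channels Integer indices of affected channels (1-18).
#' @param kind One of `"breathing"`, `"muscle"`, `"movement"`.
#' @param onset,offset Active interval in seconds after seizure end.
#' @param intensity Artifact amplitude in microvolts (>= 0).
#' @return An `artifact_archetype` list.
#' @export
artifact_archetype <- function(name, channels, kind, onset, offset,
                               intensity) {
  kind <- match.arg(kind, c("breathing", "muscle", "movement"))
  stopifnot(intensity >= 0, onset >= 0, offset > onset,
            all(channels >= 1L))
  structure(list(name = name, channels = as.integer(channels), kind = kind,
                 onset = onset, offset = offset, intensity = intensity),
            class = "artifact_archetype")
}

# Hann-edged rectangular activity envelope on the sample grid
.window_env <- function(n, fs, onset, offset, ramp = 1) {
  t <- (seq_len(n) - 1L) / fs
  env <- as.numeric(t >= onset & t < offset)
  r <- t >= onset & t < onset + ramp
  env[r] <- 0.5 * (1 - cos(pi * (t[r] - onset) / ramp))
  r <- t >= offset - ramp & t < offset
  env[r] <- 0.5 * (1 - cos(pi * (offset - t[r]) / ramp))
  env
}

# artifact waveform for one archetype on one channel
.artifact_wave <- function(arch, n, fs) {
  env <- .window_env(n, fs, arch$onset, arch$offset)
  t <- (seq_len(n) - 1L) / fs
  if (arch$kind == "breathing") {
    # respiration-coupled rhythm: non-sinusoidal, so besides the 0.2-0.5 Hz
    # fundamental it carries harmonics reaching into the 0.5-2 Hz range
    f <- runif(1L, 0.25, 0.4)
    ph <- runif(1L, 0, 2 * pi)
    w <- 0.6 * sin(2 * pi * f * t + ph) + 0.3 * sin(4 * pi * f * t + 2 * ph) +
      0.15 * sin(6 * pi * f * t + 3 * ph)
  } else if (arch$kind == "muscle") {
    w <- .bp_vec(rnorm(n), 20, 30, fs)
    w <- w / max(sd(w), 1e-12)
  } else {  # movement: repeated sharp high-amplitude transients
    w <- numeric(n)
    active <- arch$offset - arch$onset
    n_ev <- max(2L, rpois(1L, 0.8 * active))
    centers <- runif(n_ev, arch$onset, arch$offset)
    widths <- runif(n_ev, 0.1, 0.4)
    signs <- sample(c(-1, 1), n_ev, replace = TRUE)
    for (k in seq_len(n_ev)) {
      w <- w + signs[k] * exp(-((t - centers[k])^2) / (2 * widths[k]^2))
    }
  }
  arch$intensity * env * w
}

#' Simulate one postictal EEG recording with ground truth
#'
#' Builds a recording as suppression-level noise on `[0, pges_duration)`,
#' then postictal background noise plus intermittent slow-wave bursts from
#' `pges_duration` onward, with artifact waveforms from each archetype
#' superimposed on its channels. ISW bursts are raised-cosine-windowed
#' sinusoids with jittered frequency and phase, arriving as a Poisson
#' process; the first burst starts exactly at `pges_duration`, so the
#' annotated ground truth is exact. Deterministic given `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return List with `recording` (a `pges_recording`, `t0 = 0`) and
#'   `annotation` (one-row data frame, `seizure_end = 0`).
#' @export
simulate_recording <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    fs <- params$fs
    n <- as.integer(round(params$duration * fs))
    nch <- params$n_channels
    t <- (seq_len(n) - 1L) / fs
    has_pges <- !is.na(params$pges_duration)
    p_end <- if (has_pges) params$pges_duration else 0

    samples <- matrix(0, nrow = nch, ncol = n)
    supp <- t < p_end
    for (ch in seq_len(nch)) {
      x <- numeric(n)
      if (any(supp)) {
        x[supp] <- .bg_noise(sum(supp), fs, params$suppression_sigma)
      }
      if (any(!supp)) {
        x[!supp] <- .bg_noise(sum(!supp), fs, params$background_sigma)
      }
      samples[ch, ] <- x
    }

    # ISW bursts: Poisson arrivals after PGES end, first burst at p_end
    starts <- p_end
    repeat {
      nxt <- starts[length(starts)] + rexp(1L, params$isw_rate)
      if (nxt >= params$duration) break
      starts <- c(starts, nxt)
    }
    for (s0 in starts) {
      f <- runif(1L, params$isw_band[1L] + 0.5, params$isw_band[2L] - 1)
      dur <- min(runif(1L, 0.75, 1.5), params$duration - s0)
      idx <- which(t >= s0 & t < s0 + dur)
      if (length(idx) < 4L) next
      win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(idx))))
      amp <- params$isw_amplitude * runif(1L, 0.8, 1.2)
      burst <- amp * win * sin(2 * pi * f * (t[idx] - s0) + runif(1L, 0, 2 * pi))
      gains <- runif(nch, 0.7, 1.3)
      samples[, idx] <- samples[, idx] + outer(gains, burst)
    }

    for (arch in params$archetypes) {
      for (ch in arch$channels) {
        if (ch > nch) next
        samples[ch, ] <- samples[ch, ] +
          .artifact_wave(arch, n, fs) * runif(1L, 0.8, 1.2)
      }
    }

    labels <- if (nch == 18L) pges_montage() else paste0("ch", seq_len(nch))
    rec <- recording(samples, fs, channel_labels = labels,
                     id = sprintf("sim-%d", params$seed), t0 = 0)
    ann <- annotation(rec$id, seizure_end = 0, has_pges = has_pges,
                      pges_end = if (has_pges) p_end else NA_real_)
    list(recording = rec, annotation = ann)
  })
}

#' Simulate a dataset of postictal recordings
#'
#' Generates `n` recordings, assigning artifact archetypes by deterministic
#' stratified allocation of the `mix` proportions (largest-remainder
#' rounding, block order), and drawing PGES durations from a lognormal
#' distribution (median `exp(pges_meanlog)`, default about 40 s) truncated
#' to `[pges_min, duration - pges_margin]`. Each element carries its
#' generating archetype name as clustering ground truth; the detection
#' pipeline itself never sees the tag.
#'
#' @param n Number of recordings (>= 1).
#' @param archetypes List of [artifact_archetype()] (possibly empty for
#'   artifact-free data).
#' @param mix Proportions per archetype, summing to 1; default uniform.
#' @param seed Integer seed for the whole dataset.
#' @param params Template [simulation_params()]; per-recording seed,
#'   pges_duration and archetype are filled in.
#' @param pges_meanlog,pges_sdlog Lognormal parameters of the PGES-duration
#'   distribution (defaults `log(40)`, 0.5).
#' @param pges_min Minimum PGES duration in seconds (default 5).
#' @param pges_margin Seconds of post-PGES signal guaranteed at the end of
#'   the window (default 20).
#' @param pges_range Optional `c(lo, hi)`: draw PGES durations uniformly in
#'   this range instead of lognormally.
#' @param p_no_pges Probability that a recording has no PGES (default 0).
#' @return List of `n` elements, each with `recording`, `annotation`, and
#'   `archetype` (the generating tag, or `"none"`).
#' @export
simulate_dataset <- function(n, archetypes = list(), mix = NULL, seed = 1L,
                             params = simulation_params(),
                             pges_meanlog = log(40), pges_sdlog = 0.5,
                             pges_min = 5, pges_margin = 20,
                             pges_range = NULL, p_no_pges = 0) {
  if (n <= 0L) stop("n must be a positive count")
  k <- length(archetypes)
  if (k > 0L) {
    if (is.null(mix)) mix <- rep(1 / k, k)
    stopifnot(length(mix) == k, abs(sum(mix) - 1) < 1e-8)
    counts <- floor(n * mix)
    rem <- n - sum(counts)
    if (rem > 0L) {
      frac <- n * mix - counts
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    tags <- rep(seq_len(k), counts)
  } else {
    tags <- rep(0L, n)
  }
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    no_pges <- runif(n) < p_no_pges
    durs <- if (is.null(pges_range)) {
      if (params$duration - pges_margin <= pges_min) {
        stop("duration too short for the PGES-duration distribution; ",
             "pass pges_range or a longer duration")
      }
      pmin(pmax(rlnorm(n, pges_meanlog, pges_sdlog), pges_min),
           params$duration - pges_margin)
    } else {
      runif(n, pges_range[1L], pges_range[2L])
    }
    lapply(seq_len(n), function(i) {
      p <- params
      p$seed <- seeds[i]
      p$pges_duration <- if (no_pges[i]) NA_real_ else durs[i]
      p$archetypes <- if (tags[i] > 0L) archetypes[tags[i]] else list()
      sim <- simulate_recording(p)
      sim$recording$id <- sprintf("sim-%03d", i)
      sim$annotation$recording_id <- sim$recording$id
      sim$archetype <- if (tags[i] > 0L) archetypes[[tags[i]]]$name else "none"
      sim
    })
  })
}
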