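#' Configuration of a synthetic EEG study cohort
#'
#' Bundles every parameter of the synthetic cohort generator: group sizes,
#' recording geometry, the planted coherence structure, ocular-artifact
#' process, and the linear model coupling the clinical change ratio to the
#' latent change in characteristic path length.
#'
#' The defaults emulate the study conditions the package models: 21 patients
#' ("sp") recorded before and after an 8-week treatment and 24 controls
#' ("hc"), three cool-executive tasks, 21-channel 10-20 montage at 1000 Hz,
#' and a medial fronto-parietal ("DMN-like") edge set carrying a coherence
#' increment in the pre-treatment patient group only.
#'
#' @param n_sp,n_hc Number of patients / controls (each >= 2).
#' @param fs Sampling rate, Hz.
#' @param duration Recording length per task, seconds.
#' @param montage Ordered electrode labels; default [canonical_montage()].
#' @param dmn_edges Two-column character matrix of electrode pairs carrying
#'   the planted effect; default [default_dmn_edges()].
#' @param coupling_base Target band coherence of background edges, in
#'   `[0, 1]`.
#' @param coupling_effect Additive coherence increment on planted edges in
#'   the pre-treatment patient condition.
#' @param attenuation Fraction of the planted effect removed in the
#'   post-treatment condition (1 = fully removed, matching the absence of a
#'   post-treatment vs control difference).
#' @param artifact_rate Ocular-artifact (blink) rate, events per minute.
#' @param artifact_amplitude Peak blink amplitude at the frontal pole, uV.
#' @param amplitude_uv RMS amplitude of the background EEG, uV.
#' @param panss_intercept,panss_slope,panss_noise_sd Parameters `a`, `b`,
#'   `sd` of the change-ratio model `r = a + b * delta_L + Normal(0, sd)`.
#' @param delta_l_mean,delta_l_sd Distribution of the per-subject latent
#'   change in characteristic path length that drives the change ratio.
#' @param band Frequency band (lo, hi) in Hz used when calibrating planted
#'   coherence and analysing the cohort.
#' @param window,overlap Welch window length (s) and overlap fraction used
#'   for calibration and analysis.
#' @param seg_len Segment length in seconds.
#' @param seed Integer seed fixing all randomness of the cohort.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_sp = 21, n_hc = 24, fs = 1000, duration = 60,
                       montage = canonical_montage(),
                       dmn_edges = default_dmn_edges(),
                       coupling_base = 0.2, coupling_effect = 0.3,
                       attenuation = 1,
                       artifact_rate = 12, artifact_amplitude = 150,
                       amplitude_uv = 10,
                       panss_intercept = 0.197, panss_slope = -2.081,
                       panss_noise_sd = 0.05,
                       delta_l_mean = -0.017, delta_l_sd = 0.02,
                       band = c(1, 45), window = 1, overlap = 0.5,
                       seg_len = 3, seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_sp >= 2, cfg$n_hc >= 2, cfg$fs > 0, cfg$duration > 0)
  if (cfg$coupling_base < 0 || cfg$coupling_base + cfg$coupling_effect > 1 ||
      cfg$coupling_base > 1)
    stop("coherence targets must satisfy 0 <= base, base + effect <= 1")
  if (anyDuplicated(cfg$montage)) stop("montage labels must be unique")
  edges <- cfg$dmn_edges
  if (!is.matrix(edges) || ncol(edges) != 2)
    stop("`dmn_edges` must be a two-column matrix of electrode pairs")
  if (any(edges[, 1] == edges[, 2]))
    stop("`dmn_edges` pairs must join distinct electrodes")
  if (!all(edges %in% cfg$montage))
    stop("`dmn_edges` refers to labels outside the montage")
  if (cfg$attenuation < 0 || cfg$attenuation > 1)
    stop("`attenuation` must lie in [0, 1]")
  invisible(cfg)
}

# ---- background signal model -----------------------------------------------

# 1/f-shaped noise with an alpha-band (10 Hz) bump; unit variance.
# All sources (shared and private) use the same spectral shape so that the
# magnitude-squared coherence of mixed channels is flat across frequency.
shaped_noise <- function(n, fs, n_series = 1) {
  nf <- floor((n - 1) / 2)
  f <- (1:nf) * fs / n
  amp <- 1 / pmax(f, 0.5)^0.5 * (1 + 2 * exp(-((f - 10)^2) / (2 * 1.5^2)))
  out <- matrix(0, n_series, n)
  for (s in seq_len(n_series)) {
    spec <- complex(length.out = n)
    spec[1 + (1:nf)] <- amp *
      complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf))
    spec[n + 1 - (1:nf)] <- Conj(spec[1 + (1:nf)])
    x <- Re(stats::fft(spec, inverse = TRUE))
    out[s, ] <- x / stats::sd(x)
  }
  out
}

# ---- gain -> coherence calibration -----------------------------------------

.cal_cache <- new.env(parent = emptyenv())

# Measured band coherence of a two-channel mixture sharing variance
# fraction `t`, as a function of t, estimated with the package's own Welch
# coherence estimator. No closed form is attempted: the map absorbs the
# finite-window estimator bias. Deterministic (internal fixed seed), cached
# per parameter set.
coupling_map <- function(fs, window, overlap, band, seg_len = 3,
                         n_segments = 80) {
  key <- paste(fs, window, overlap, band[1], band[2], seg_len, n_segments,
               sep = "|")
  if (!is.null(.cal_cache[[key]])) return(.cal_cache[[key]])
  t_grid <- c(0, 0.05, seq(0.1, 0.9, by = 0.1), 0.95, 0.99)
  measured <- numeric(length(t_grid))
  n <- round(seg_len * fs)
  local_seed({
    set.seed(20230427L)
    for (k in seq_along(t_grid)) {
      t <- t_grid[k]
      src <- shaped_noise(n * n_segments, fs, 3)
      x1 <- sqrt(t) * src[1, ] + sqrt(1 - t) * src[2, ]
      x2 <- sqrt(t) * src[1, ] + sqrt(1 - t) * src[3, ]
      vals <- numeric(n_segments)
      for (s in seq_len(n_segments)) {
        idx <- ((s - 1) * n + 1):(s * n)
        cm <- coherence_matrix(rbind(x1[idx], x2[idx]), fs,
                               labels = c("a", "b"), band = band,
                               window = window, overlap = overlap)
        vals[s] <- cm$values[1, 2]
      }
      measured[k] <- mean(vals)
    }
  })
  measured <- cummax(measured)  # enforce monotonicity against MC jitter
  fn <- stats::approxfun(measured, t_grid, rule = 2)
  .cal_cache[[key]] <- fn
  fn
}

# shared-variance fraction achieving a target measured band coherence
coupling_for_coherence <- function(target, cfg) {
  fn <- coupling_map(cfg$fs, cfg$window, cfg$overlap, cfg$band, cfg$seg_len)
  fn(target)
}

# run code without disturbing the caller's RNG stream
local_seed <- function(code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  force(code)
}

# ---- recording simulation ---------------------------------------------------

#' Simulate one multichannel EEG recording
#'
#' Generates a channels-by-samples recording under one of three conditions:
#' `"sp_before"` (planted coherence increment on the configured DMN-like
#' edge set), `"sp_after"` (increment attenuated by `cfg$attenuation`), or
#' `"hc"` (background coupling only). Channels are built from shared
#' band-limited latent sources plus independent channel noise; the mixing
#' gain is calibrated numerically with the package's own coherence
#' estimator so that the realized band coherence approximates the targets.
#'
#' @param cfg A [sim_config()].
#' @param condition One of `"sp_before"`, `"sp_after"`, `"hc"`.
#' @param seed Integer seed for this recording.
#' @return A [recording()].
#' @export
simulate_recording <- function(cfg, condition = c("sp_before", "sp_after", "hc"),
                               seed = 1) {
  condition <- match.arg(condition)
  validate_sim_config(cfg)
  factor <- switch(condition,
                   sp_before = 1,
                   sp_after = 1 - cfg$attenuation,
                   hc = 0)
  target_bg <- cfg$coupling_base
  target_pl <- cfg$coupling_base + factor * cfg$coupling_effect
  t_bg <- if (target_bg > 0) coupling_for_coherence(target_bg, cfg) else 0
  t_pl <- if (target_pl > target_bg) coupling_for_coherence(target_pl, cfg)
          else t_bg
  rho_d <- max(t_pl - t_bg, 0)

  n <- round(cfg$duration * cfg$fs)
  labels <- cfg$montage
  planted <- unique(as.vector(cfg$dmn_edges))
  set.seed(seed)
  shared <- shaped_noise(n, cfg$fs, 2)   # global + DMN-like source
  priv <- shaped_noise(n, cfg$fs, length(labels))
  data <- matrix(0, length(labels), n)
  for (c in seq_along(labels)) {
    rd <- if (labels[c] %in% planted) rho_d else 0
    data[c, ] <- sqrt(t_bg) * shared[1, ] +
      sqrt(rd) * shared[2, ] +
      sqrt(max(1 - t_bg - rd, 0)) * priv[c, ]
  }
  recording(data * cfg$amplitude_uv, cfg$fs, labels)
}

#' Inject ocular (blink) artifacts into a recording
#'
#' Adds slow (below 4 Hz) high-amplitude transient deflections with a
#' frontal-dominated spatial pattern: full amplitude at FP1/FP2/FPz,
#' decaying toward posterior channels. Event count is Poisson with the
#' requested rate; onsets are uniform over the recording.
#'
#' @param rec A [recording()].
#' @param rate Blink rate, events per minute (>= 0).
#' @param amplitude Peak amplitude at the frontal pole, uV (>= 0).
#' @param seed Integer seed.
#' @return The recording with artifacts added; ground-truth onset times in
#'   seconds are attached as attribute `"artifact_onsets"`.
#' @export
inject_ocular_artifacts <- function(rec, rate = 12, amplitude = 150, seed = 1) {
  stopifnot(is_recording(rec), rate >= 0, amplitude >= 0)
  dur <- recording_duration(rec)
  if (rate == 0 || amplitude == 0) {
    attr(rec, "artifact_onsets") <- numeric(0)
    return(rec)
  }
  set.seed(seed)
  n_ev <- stats::rpois(1, rate * dur / 60)
  blink_T <- 0.35  # seconds; raised-sine bump, spectral mass < 4 Hz
  onsets <- sort(stats::runif(n_ev, 0, max(dur - blink_T, 0)))
  wlen <- round(blink_T * rec$fs)
  wave <- sin(pi * seq(0, 1, length.out = wlen))^2
  topo <- blink_topography(rec$labels)
  data <- rec$data
  for (t0 in onsets) {
    i0 <- floor(t0 * rec$fs) + 1
    idx <- i0:min(i0 + wlen - 1, ncol(data))
    data[, idx] <- data[, idx] +
      amplitude * topo %o% wave[seq_along(idx)]
  }
  out <- recording(data, rec$fs, rec$labels)
  attr(out, "artifact_onsets") <- onsets
  out
}

# ---- clinical simulation ----------------------------------------------------

# group/task behavioral targets (mean, sd) emulating the printed summaries:
# reaction times lognormal; error counts Poisson; Tower-of-Hanoi steps
# 7 + Poisson (7 = 3-disk minimum).
behavior_targets <- function() {
  list(
    before = list(tht_rt = c(90.71, 61.17), tht_steps = 18.38,
                  tmta_rt = c(63.57, 22.96), tmta_err = 0.38,
                  tmtb_rt = c(203.00, 94.05), tmtb_err = 4.19),
    after  = list(tht_rt = c(87.67, 61.27), tht_steps = 19.38,
                  tmta_rt = c(50.57, 18.93), tmta_err = 0.45,
                  tmtb_rt = c(160.95, 56.72), tmtb_err = 2.00),
    hc     = list(tht_rt = c(66.42, 52.03), tht_steps = 14.17,
                  tmta_rt = c(35.29, 10.35), tmta_err = 0.29,
                  tmtb_rt = c(82.33, 35.16), tmtb_err = 0.33)
  )
}

rlnorm_ms <- function(n, m, s) {
  v <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - v / 2, sdlog = sqrt(v))
}

behavior_row <- function(n, tg) {
  data.frame(
    tht_rt = rlnorm_ms(n, tg$tht_rt[1], tg$tht_rt[2]),
    tht_steps = 7 + stats::rpois(n, max(tg$tht_steps - 7, 0)),
    tmta_rt = rlnorm_ms(n, tg$tmta_rt[1], tg$tmta_rt[2]),
    tmta_err = stats::rpois(n, tg$tmta_err),
    tmtb_rt = rlnorm_ms(n, tg$tmtb_rt[1], tg$tmtb_rt[2]),
    tmtb_err = stats::rpois(n, tg$tmtb_err)
  )
}

#' Simulate the clinical table of a cohort
#'
#' Draws PANSS pre-treatment totals (30-item scale, range 30-210), computes
#' each patient's change ratio from the linear model
#' `r_i = a + b * delta_L_i + Normal(0, sd)` clipped to `[0, 1)`, derives
#' integer post-treatment scores (round-half-even, floored at the scale
#' minimum), and simulates task behavior (lognormal reaction times, Poisson
#' error counts, Tower-of-Hanoi steps of at least 7) with group/phase
#' shifts: patients slower pre-treatment, improving after treatment.
#'
#' @param cfg A [sim_config()].
#' @param delta_l Numeric vector, one latent change in characteristic path
#'   length per patient.
#' @param seed Integer seed.
#' @return Long-format data frame, one row per subject and phase
#'   (`"before"`/`"after"` for patients, `"hc"` for controls) with behavior
#'   columns and per-subject clinical columns (`panss_pre`, `panss_post`,
#'   `change_ratio`, `delta_l`; `NA` for controls).
#' @export
simulate_clinical <- function(cfg, delta_l, seed = 1) {
  validate_sim_config(cfg)
  if (length(delta_l) != cfg$n_sp)
    stop("`delta_l` must have one entry per patient (length ", cfg$n_sp, ")")
  set.seed(seed)
  tg <- behavior_targets()

  pre <- round(stats::rnorm(cfg$n_sp, 74.62, 13.76))
  pre <- pmin(pmax(pre, 30), 210)
  ratio <- cfg$panss_intercept + cfg$panss_slope * delta_l +
    stats::rnorm(cfg$n_sp, 0, cfg$panss_noise_sd)
  ratio <- pmin(pmax(ratio, 0), 1 - 1e-9)
  post <- pmax(round(pre * (1 - ratio)), 30)
  change_ratio <- (pre - post) / pre

  sp_ids <- sprintf("SP%02d", seq_len(cfg$n_sp))
  hc_ids <- sprintf("HC%02d", seq_len(cfg$n_hc))
  rows <- list(
    cbind(data.frame(subject = sp_ids, group = "sp", phase = "before"),
          behavior_row(cfg$n_sp, tg$before),
          data.frame(panss_pre = pre, panss_post = post,
                     change_ratio = change_ratio, delta_l = delta_l)),
    cbind(data.frame(subject = sp_ids, group = "sp", phase = "after"),
          behavior_row(cfg$n_sp, tg$after),
          data.frame(panss_pre = pre, panss_post = post,
                     change_ratio = change_ratio, delta_l = delta_l)),
    cbind(data.frame(subject = hc_ids, group = "hc", phase = "hc"),
          behavior_row(cfg$n_hc, tg$hc),
          data.frame(panss_pre = NA_real_, panss_post = NA_real_,
                     change_ratio = NA_real_, delta_l = NA_real_))
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- whole-cohort simulation ------------------------------------------------

#' Simulate a complete synthetic study
#'
#' Generates EEG recordings (patients: both phases; controls: one), the
#' clinical table, and a ground-truth record, all determined by
#' `cfg$seed`. Recordings are keyed `"<subject>.<task>.<phase>"` with tasks
#' `task1`-`task3`.
#'
#' @param cfg A [sim_config()].
#' @param tasks Number of tasks per subject (default 3).
#' @param artifacts Logical; inject ocular artifacts at the configured rate.
#' @return A list of class `"cohort_bundle"` with elements `recordings`
#'   (named list of [recording()]s), `index` (data frame of keys), `clinical`
#'   and `truth` (config, latent `delta_l`, artifact onsets).
#' @export
simulate_cohort <- function(cfg, tasks = 3, artifacts = TRUE) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  delta_l <- stats::rnorm(cfg$n_sp, cfg$delta_l_mean, cfg$delta_l_sd)
  seed_pool <- sample.int(2^31 - 2, 10000)
  k <- 0L
  next_seed <- function() { k <<- k + 1L; seed_pool[k] }

  clinical <- simulate_clinical(cfg, delta_l, seed = next_seed())

  sp_ids <- sprintf("SP%02d", seq_len(cfg$n_sp))
  hc_ids <- sprintf("HC%02d", seq_len(cfg$n_hc))
  index <- rbind(
    expand.grid(subject = sp_ids, task = paste0("task", seq_len(tasks)),
                phase = c("before", "after"), stringsAsFactors = FALSE),
    expand.grid(subject = hc_ids, task = paste0("task", seq_len(tasks)),
                phase = "hc", stringsAsFactors = FALSE)
  )
  index$condition <- ifelse(index$phase == "hc", "hc",
                            paste0("sp_", index$phase))
  index$key <- paste(index$subject, index$task, index$phase, sep = ".")

  recordings <- vector("list", nrow(index))
  names(recordings) <- index$key
  onsets <- vector("list", nrow(index))
  names(onsets) <- index$key
  for (i in seq_len(nrow(index))) {
    rec <- simulate_recording(cfg, index$condition[i], seed = next_seed())
    if (artifacts && cfg$artifact_rate > 0) {
      rec <- inject_ocular_artifacts(rec, cfg$artifact_rate,
                                     cfg$artifact_amplitude,
                                     seed = next_seed())
      onsets[[i]] <- attr(rec, "artifact_onsets")
    } else onsets[[i]] <- numeric(0)
    recordings[[i]] <- rec
  }
  structure(list(recordings = recordings, index = index,
                 clinical = clinical,
                 truth = list(config = cfg, delta_l = delta_l,
                              artifact_onsets = onsets)),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d recordings, %d clinical rows\n",
              length(x$recordings), nrow(x$clinical)))
  invisible(x)
}
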