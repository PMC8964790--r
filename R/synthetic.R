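#' Coupling specification for the synthetic generator
#'
#' Describes the latent inter-ROI correlation structure of simulated
#' hemoglobin oscillations: one 8x8 symmetric positive-semidefinite target
#' correlation matrix per frequency band, per-band amplitudes, the channel
#' noise level and the HbO->HbR coupling coefficient kappa (the HbR latent
#' is `-kappa` times the HbO latent plus independent structure).
#'
#' @param targets Named list (one per band) of symmetric PSD correlation
#'   matrices with unit diagonal.
#' @param amplitudes Named numeric vector of per-band signal amplitudes
#'   (standard deviations), `>= 0`.
#' @param noise_sd Channel noise standard deviation.
#' @param kappa HbO->HbR anticorrelation coefficient in `[0, 1]`.
#' @param hbr_scale Amplitude of the HbR latent relative to HbO.
#' @param band_guard Fraction of each band's width trimmed from both edges
#'   when synthesizing session latents. The five analysis bands share
#'   edges, and a flat-spectrum synthetic signal places full power at the
#'   shared edge, so without a guard adjacent-band coupling leaks through
#'   the analysis filters' transition bands and per-band coupling stops
#'   being controllable. Real hemodynamic spectra roll off within bands.
#' @return A `coupling_spec` object.
#' @seealso [default_coupling_spec()]
#' @export
coupling_spec <- function(targets, amplitudes, noise_sd = 0.3, kappa = 0.5,
                          hbr_scale = 0.4, band_guard = 0.10) {
  stopifnot(is.list(targets), length(targets) >= 1)
  for (nm in names(targets)) {
    R <- targets[[nm]]
    if (!isTRUE(all.equal(diag(R), rep(1, nrow(R)), check.attributes = FALSE)))
      stop("target for band ", nm, " must have unit diagonal")
    if (any(abs(R - t(R)) > 1e-12))
      stop("target for band ", nm, " must be symmetric")
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("target for band ", nm, " is not positive semidefinite")
  }
  if (!all(names(targets) %in% names(amplitudes)))
    stop("amplitudes missing for band(s): ",
         paste(setdiff(names(targets), names(amplitudes)), collapse = ", "))
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  if (band_guard < 0 || band_guard >= 0.5)
    stop("band_guard must be in [0, 0.5)")
  structure(list(targets = targets, amplitudes = amplitudes,
                 noise_sd = noise_sd, kappa = kappa, hbr_scale = hbr_scale,
                 band_guard = band_guard),
            class = "coupling_spec")
}

# two-community block correlation matrix over the default ROI order
modular_target <- function(within, between, rois = default_montage()$roi_order,
                           frontal = c("L-PFC", "M-PFC", "R-PFC",
                                       "L-FEF", "R-FEF")) {
  n <- length(rois)
  same <- outer(rois %in% frontal, rois %in% frontal,
                function(a, b) a == b)
  R <- ifelse(same, within, between)
  diag(R) <- 1
  dimnames(R) <- list(rois, rois)
  R
}

#' Default modular coupling structure
#'
#' Two latent communities — a frontal/attention module (the three PFC
#' ROIs plus both FEF) and a motor module (SMA plus both PMC) — with
#' stronger within- than between-module correlations, declining with
#' frequency, and 1/f-like per-band amplitudes. These values are generator
#' parameters, not measured quantities.
#'
#' @return A [coupling_spec()].
#' @export
default_coupling_spec <- function() {
  coupling_spec(
    targets = list(
      I   = modular_target(0.65, 0.25),
      II  = modular_target(0.60, 0.25),
      III = modular_target(0.60, 0.20),
      IV  = modular_target(0.55, 0.20),
      V   = modular_target(0.50, 0.15)
    ),
    amplitudes = c(I = 1.0, II = 0.9, III = 0.7, IV = 0.5, V = 0.4),
    noise_sd = 0.3, kappa = 0.5, hbr_scale = 0.4
  )
}

#' Study design for the synthetic generator
#'
#' Fixes the composition of a simulated study (participants per
#' task x fatigue-level cell, session duration, sampling rate) and the
#' fatigue-level effects: per-level multiplicative modifiers of the
#' per-band coupling, MFI-20 item-score distributions and n-back
#' reaction-time/accuracy distributions. The default level effects mirror,
#' qualitatively, the directions seen in fatigued cohorts: in moderate
#' fatigue (L2) band-II coupling rises — more on right-hemisphere pairs —
#' and band-III coupling falls; in severe fatigue (L3) band-III and
#' band-IV coupling fall globally while band II stays elevated.
#'
#' @param n_per_cell Sessions per (task, level) cell. The default 12
#'   mirrors a 36-participant cohort tested three times (108 analysed
#'   sessions, balanced over 3 tasks x 3 levels).
#' @param duration Session length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Master seed for the study.
#' @param coupling A [coupling_spec()].
#' @param level_effects Per-level list with `band_mult` (named off-diagonal
#'   multipliers per band) and optional `right_mult` (extra multiplier on
#'   right-hemisphere pairs).
#' @param mfi List: per-level item-score `center`, between-participant
#'   `participant_sd`, within-questionnaire `item_sd`.
#' @param nback List: per-level `rt_mean`, `rt_sd`, `accuracy`, plus
#'   per-session RT jitter `session_sd`, the within-level coupling
#'   `mfi_slope` (seconds of mean reaction time per MFI point: a session
#'   whose latent fatigue severity sits above its level's MFI center is
#'   also slower, so behaviour tracks severity continuously as it does
#'   across levels), and `n_trials`.
#' @param tasks,levels Factor levels of the design.
#' @return A `study_design` object.
#' @export
study_design <- function(n_per_cell = 12, duration = 600, fs = 16, seed = 1,
                         coupling = default_coupling_spec(),
                         level_effects = default_level_effects(),
                         mfi = list(center = c(L1 = 1.7, L2 = 2.8, L3 = 3.4),
                                    participant_sd = 0.18, item_sd = 0.6),
                         nback = list(rt_mean = c(L1 = 0.55, L2 = 0.65, L3 = 0.80),
                                      rt_sd = c(L1 = 0.08, L2 = 0.10, L3 = 0.12),
                                      accuracy = c(L1 = 0.95, L2 = 0.88, L3 = 0.78),
                                      session_sd = 0.05, mfi_slope = 0.15,
                                      n_trials = 30),
                         tasks = c("PVT", "cognitive", "driving"),
                         levels = c("L1", "L2", "L3")) {
  if (n_per_cell < 1) stop("n_per_cell must be >= 1")
  if (duration * fs < 512) stop("duration * fs must be >= 512 samples")
  structure(list(n_per_cell = n_per_cell, duration = duration, fs = fs,
                 seed = seed, coupling = coupling,
                 level_effects = level_effects, mfi = mfi, nback = nback,
                 tasks = tasks, levels = levels),
            class = "study_design")
}

#' @rdname study_design
#' @export
default_level_effects <- function() {
  list(
    L1 = list(band_mult = c(), right_mult = c()),
    L2 = list(band_mult = c(II = 1.10, III = 0.75),
              right_mult = c(II = 1.20)),
    L3 = list(band_mult = c(II = 1.10, III = 0.70, IV = 0.70),
              right_mult = c())
  )
}

# apply a level's coupling modifiers to one band's target matrix
level_target <- function(target, band_name, effect, montage) {
  R <- target
  off <- row(R) != col(R)
  bm <- effect$band_mult
  if (!is.null(bm) && band_name %in% names(bm))
    R[off] <- R[off] * bm[[band_name]]
  rm_ <- effect$right_mult
  if (!is.null(rm_) && band_name %in% names(rm_)) {
    rois <- rownames(R)
    right <- montage$hemisphere[rois] == "right"
    pair <- outer(right, right, `&`) & off
    R[pair] <- R[pair] * rm_[[band_name]]
  }
  R[off] <- pmin(pmax(R[off], -0.97), 0.97)
  psd_repair(R)
}

#' Generate correlated band-limited ROI signals
#'
#' Draws independent white-noise series, band-pass filters them into the
#' band, standardizes, mixes with the symmetric matrix square root of the
#' target correlation matrix, and re-standardizes columns. Sample Pearson
#' correlations converge to the target as the series lengthens.
#'
#' @param target Symmetric PSD correlation matrix (ROIs x ROIs).
#' @param band A [band_spec()].
#' @param n_samples Series length.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Numeric matrix, `n_samples` x `nrow(target)`, unit-variance
#'   columns.
#' @export
generate_band_signals <- function(target, band, n_samples, fs, seed) {
  if (min(eigen(target, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("target correlation matrix is not positive semidefinite")
  k <- nrow(target)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_samples * k), n_samples, k)
    z <- bandpass(z, band, fs)
    z <- scale(z)                  # unit variance before mixing
    y <- z %*% sqrtm_psd(target)
    y <- scale(y, center = TRUE, scale = apply(y, 2, stats::sd))
    dimnames(y) <- list(NULL, rownames(target))
    y[, , drop = FALSE]
  })
}

# latent ROI series summed over all bands for one level, one draw
latent_roi_signals <- function(design, level, n, seed_tag) {
  cs <- design$coupling
  montage <- default_montage()
  bands <- default_bands()
  effect <- design$level_effects[[level]]
  total <- NULL
  for (bn in names(cs$targets)) {
    R <- level_target(cs$targets[[bn]], bn, effect, montage)
    b <- bands[[bn]]
    g <- cs$band_guard * (b$high - b$low)
    gen_band <- band_spec(b$name, b$low + g, b$high - g)
    s <- generate_band_signals(R, gen_band, n, design$fs,
                               derive_seed(design$seed, seed_tag, bn))
    contrib <- cs$amplitudes[[bn]] * s
    total <- if (is.null(total)) contrib else total + contrib
  }
  total
}

#' Generate one synthetic participant-session
#'
#' Builds band-limited, module-coupled ROI latents, maps each ROI latent
#' to its montage channels plus Gaussian channel noise to form HbO;
#' forms the HbR latent as `-kappa` times the HbO latent plus independent
#' band-structured signal; sets HbT = HbO + HbR channelwise; and draws
#' MFI-20 items and n-back trials from the level's distributions.
#'
#' @param design A [study_design()].
#' @param participant_id Character id.
#' @param task Task name.
#' @param level Fatigue level `"L1"`, `"L2"` or `"L3"`.
#' @param seed Integer seed for this session.
#' @param species Hemoglobin species to generate (`"HbT"` requires both
#'   others). Each species draws from its own derived seed stream, so a
#'   subset run reproduces the full run's signals exactly. `NULL`
#'   generates questionnaire/behaviour data only (no recordings), which
#'   is much faster when signals are not needed.
#' @return A [participant_session()] with `fatigue_level` set to the
#'   ground-truth level.
#' @export
generate_session <- function(design, participant_id, task, level,
                             seed = derive_seed(design$seed, participant_id,
                                                task, level),
                             species = hb_species()) {
  if (!level %in% c("L1", "L2", "L3")) stop("unknown fatigue level: ", level)
  task <- match.arg(task, design$tasks)
  n <- round(design$duration * design$fs)
  montage <- default_montage()
  cs <- design$coupling

  recs <- list()
  if (length(species)) {
    stopifnot(all(species %in% hb_species()))
    need_hbr <- any(c("HbR", "HbT") %in% species)
    hbo_lat <- latent_roi_signals(design, level, n, paste0(seed, ":hbo"))
    hbr_lat <- if (need_hbr) {
      ind_lat <- latent_roi_signals(design, level, n, paste0(seed, ":hbr"))
      cs$hbr_scale * (-cs$kappa * hbo_lat + sqrt(1 - cs$kappa^2) * ind_lat)
    }

    chans <- montage_channels(montage)
    roi_of <- rep(names(montage$roi_channels),
                  lengths(montage$roi_channels))[order(unlist(montage$roi_channels))]
    expand <- function(lat, noise_seed) with_seed(noise_seed, {
      m <- lat[, roi_of, drop = FALSE] +
        cs$noise_sd * matrix(stats::rnorm(n * length(chans)), n)
      colnames(m) <- chans
      m
    })
    hbo <- expand(hbo_lat, derive_seed(seed, "noise", "HbO"))
    hbr <- if (need_hbr) expand(hbr_lat, derive_seed(seed, "noise", "HbR"))
    if ("HbO" %in% species)
      recs$HbO <- channel_recording(hbo, design$fs, "HbO", chans)
    if ("HbR" %in% species)
      recs$HbR <- channel_recording(hbr, design$fs, "HbR", chans)
    if ("HbT" %in% species)
      recs$HbT <- channel_recording(hbo + hbr, design$fs, "HbT", chans)
  }

  beh <- with_seed(derive_seed(seed, "behaviour"), {
    center <- stats::rnorm(1, design$mfi$center[[level]],
                           design$mfi$participant_sd)
    items <- pmin(pmax(round(stats::rnorm(20, center, design$mfi$item_sd)),
                       1L), 5L)
    nb <- design$nback
    slope <- if (is.null(nb$mfi_slope)) 0 else nb$mfi_slope
    rt_center <- stats::rnorm(1, nb$rt_mean[[level]] +
                                slope * (center - design$mfi$center[[level]]),
                              nb$session_sd)
    rt <- pmax(stats::rnorm(nb$n_trials, rt_center, nb$rt_sd[[level]]), 0.15)
    correct <- stats::runif(nb$n_trials) < nb$accuracy[[level]]
    if (!any(correct)) correct[1] <- TRUE  # keep behaviour score defined
    list(items = items, nback = data.frame(rt = rt, correct = correct))
  })

  session_time <- c(L1 = "morning", L2 = "afternoon", L3 = "evening")[[level]]
  participant_session(participant_id, task, session_time, recs,
                      beh$items, beh$nback, fatigue_level = level)
}

#' Generate a full synthetic study
#'
#' One session per (participant, task, level) cell. Each cell's seed is
#' derived by hashing the master seed with the cell tags, so enlarging
#' `n_per_cell` reproduces the smaller study's sessions unchanged.
#'
#' @param design A [study_design()].
#' @param out_dir Optional directory; when given, every session's
#'   recordings are written as CSV + JSON and the study's MFI/n-back
#'   tables as CSV.
#' @param species Passed to [generate_session()].
#' @return List of [participant_session()]s.
#' @export
generate_study <- function(design, out_dir = NULL, species = hb_species()) {
  sessions <- list()
  for (task in design$tasks) {
    for (level in design$levels) {
      for (i in seq_len(design$n_per_cell)) {
        pid <- sprintf("%s-%s-%02d", task, level, i)
        sessions[[pid]] <- generate_session(design, pid, task, level,
                                            species = species)
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in sessions) {
      for (sp in names(s$recordings)) {
        base <- file.path(out_dir, paste0(s$participant_id, "_", sp))
        write_recording(s$recordings[[sp]], paste0(base, ".csv"),
                        paste0(base, ".json"),
                        meta = list(participant_id = s$participant_id,
                                    task = s$task, session = s$session))
      }
    }
    write_mfi_table(sessions, file.path(out_dir, "mfi.csv"))
    write_nback_table(sessions, file.path(out_dir, "nback.csv"))
  }
  sessions
}
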