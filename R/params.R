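# Parameter bundles for the synthetic-data generators, plus the named
# condition presets calibrated to published group-level observables.

#' Parameters of the run-and-pause cargo transport simulator
#'
#' Cargo moves along a one-dimensional axon axis in a two-state
#' (run/pause) Markov process with per-frame Bernoulli switching, so dwell
#' times in each state are geometric. During a run the position advances by
#' `direction * speed * frame_interval_s` per frame plus Gaussian
#' localization noise; during a pause only the noise moves it. The per-track
#' run speed is drawn once per track from a normal distribution truncated
#' at zero, so a cohort shows a spread of instantaneous velocities.
#'
#' Defaults mirror live-imaging of quantum-dot-labelled BDNF: one frame
#' every 3 s (20 frames per minute) for 100 frames (a 5-minute movie).
#' Speed and pause magnitudes are free parameters of the simulator.
#'
#' @param frame_interval_s Seconds between frames (> 0).
#' @param n_frames Number of frames per track (>= 2).
#' @param run_speed_mean_um_s,run_speed_sd_um_s Mean and SD of the
#'   per-track run speed in um/s (mean >= 0, sd >= 0).
#' @param pause_entry_prob Per-frame probability of switching run -> pause.
#' @param pause_exit_prob Per-frame probability of switching pause -> run.
#' @param retrograde_fraction Fraction of tracks whose fixed direction is
#'   retrograde (towards the soma, negative increments).
#' @param noise_sd_um SD of the per-step Gaussian localization noise, um.
#' @return A `transport_params` object (validated list).
#' @export
transport_params <- function(frame_interval_s = 3,
                             n_frames = 100,
                             run_speed_mean_um_s = 0.8,
                             run_speed_sd_um_s = 0.2,
                             pause_entry_prob = 0.05,
                             pause_exit_prob = 0.5,
                             retrograde_fraction = 0.9,
                             noise_sd_um = 0.05) {
  check_scalar_number(frame_interval_s, "frame_interval_s", min = 0,
                      strict_min = TRUE)
  check_count(n_frames, "n_frames", min = 2L)
  check_scalar_number(run_speed_mean_um_s, "run_speed_mean_um_s", min = 0)
  check_scalar_number(run_speed_sd_um_s, "run_speed_sd_um_s", min = 0)
  check_probability(pause_entry_prob, "pause_entry_prob")
  check_probability(pause_exit_prob, "pause_exit_prob")
  check_probability(retrograde_fraction, "retrograde_fraction")
  check_scalar_number(noise_sd_um, "noise_sd_um", min = 0)
  structure(
    list(
      frame_interval_s = frame_interval_s,
      n_frames = as.integer(n_frames),
      run_speed_mean_um_s = run_speed_mean_um_s,
      run_speed_sd_um_s = run_speed_sd_um_s,
      pause_entry_prob = pause_entry_prob,
      pause_exit_prob = pause_exit_prob,
      retrograde_fraction = retrograde_fraction,
      noise_sd_um = noise_sd_um
    ),
    class = c("transport_params", "motorunit_params")
  )
}

#' Parameters of the myofiber contraction-trace simulator
#'
#' Non-contracting fibers produce a flat baseline of 1.0 plus Gaussian
#' noise. Contracting fibers additionally carry a Poisson number of burst
#' events (count ~ Poisson(burst_rate_hz * movie duration)) of fixed
#' relative amplitude and duration at uniformly random onsets. Defaults
#' match brightfield contraction movies recorded at 30 frames per second
#' for 1000 frames.
#'
#' @param fps Frames per second (> 0).
#' @param n_frames Frames per trace (>= 10).
#' @param fraction_contracting Probability that a fiber is a contractor.
#' @param burst_rate_hz Burst events per second for contractors (>= 0).
#' @param burst_amplitude_rel Relative intensity deflection of a burst;
#'   must exceed `noise_sd_rel` or the ground truth is undetectable by
#'   construction.
#' @param burst_duration_frames Frames per burst (>= 1).
#' @param noise_sd_rel Relative SD of the baseline noise (>= 0).
#' @return A `contraction_params` object.
#' @export
contraction_params <- function(fps = 30,
                               n_frames = 1000,
                               fraction_contracting = 0.5,
                               burst_rate_hz = 0.3,
                               burst_amplitude_rel = 0.5,
                               burst_duration_frames = 5,
                               noise_sd_rel = 0.02) {
  check_scalar_number(fps, "fps", min = 0, strict_min = TRUE)
  check_count(n_frames, "n_frames", min = 10L)
  check_probability(fraction_contracting, "fraction_contracting")
  check_scalar_number(burst_rate_hz, "burst_rate_hz", min = 0)
  check_scalar_number(burst_amplitude_rel, "burst_amplitude_rel", min = 0)
  check_count(burst_duration_frames, "burst_duration_frames", min = 1L)
  check_scalar_number(noise_sd_rel, "noise_sd_rel", min = 0)
  if (burst_amplitude_rel <= noise_sd_rel) {
    stop_parameter(
      "`burst_amplitude_rel` must exceed `noise_sd_rel`: bursts would be undetectable by construction"
    )
  }
  if (burst_duration_frames > n_frames) {
    stop_parameter("`burst_duration_frames` must be <= `n_frames`")
  }
  structure(
    list(
      fps = fps,
      n_frames = as.integer(n_frames),
      fraction_contracting = fraction_contracting,
      burst_rate_hz = burst_rate_hz,
      burst_amplitude_rel = burst_amplitude_rel,
      burst_duration_frames = as.integer(burst_duration_frames),
      noise_sd_rel = noise_sd_rel
    ),
    class = c("contraction_params", "motorunit_params")
  )
}

#' Parameters of the explant motor-neuron survival simulator
#'
#' An explant starts with `initial_count` motor neurons at the baseline
#' observation day and is thinned over subsequent days so that the
#' expected count at day d equals `initial_count *
#' surviving_fraction_by_day[d]`. With `count_noise = TRUE` thinning is
#' sequential binomial (guaranteeing non-increasing counts); otherwise the
#' expectation is rounded exactly.
#'
#' @param initial_count Motor neurons at baseline (>= 1).
#' @param observation_days Strictly increasing observation days; the first
#'   is the baseline. Defaults to days 7, 10, 12, 14 and 16 of co-culture.
#' @param surviving_fraction_by_day Non-increasing survival fractions, one
#'   per day, first entry exactly 1.
#' @param count_noise Apply binomial thinning noise?
#' @return A `survival_params` object.
#' @export
survival_params <- function(initial_count = 40,
                            observation_days = c(7, 10, 12, 14, 16),
                            surviving_fraction_by_day = c(1, 0.95, 0.8, 0.65, 0.5),
                            count_noise = TRUE) {
  check_count(initial_count, "initial_count", min = 1L)
  if (length(observation_days) < 1L || is.unsorted(observation_days, strictly = TRUE)) {
    stop_parameter("`observation_days` must be strictly increasing")
  }
  if (length(surviving_fraction_by_day) != length(observation_days)) {
    stop_parameter(
      "`surviving_fraction_by_day` must have one entry per observation day"
    )
  }
  if (any(surviving_fraction_by_day < 0) || any(surviving_fraction_by_day > 1)) {
    stop_parameter("`surviving_fraction_by_day` entries must lie in [0, 1]")
  }
  if (surviving_fraction_by_day[1] != 1) {
    stop_parameter("`surviving_fraction_by_day` must start at 1 (baseline day)")
  }
  if (is.unsorted(rev(surviving_fraction_by_day))) {
    stop_parameter("`surviving_fraction_by_day` must be non-increasing")
  }
  if (!is.logical(count_noise) || length(count_noise) != 1L || is.na(count_noise)) {
    stop_parameter("`count_noise` must be TRUE or FALSE")
  }
  structure(
    list(
      initial_count = as.integer(initial_count),
      observation_days = as.numeric(observation_days),
      surviving_fraction_by_day = as.numeric(surviving_fraction_by_day),
      count_noise = count_noise
    ),
    class = c("survival_params", "motorunit_params")
  )
}

#' @export
print.motorunit_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Named condition presets for every simulated assay
#'
#' Presets pin the group-level observables reported for each experimental
#' condition: the fraction of contracting myofibers (about 10% for
#' denervated muscle versus 74% in healthy co-cultures), the fraction of
#' intact in vitro NMJs (about 75% in wild-type co-cultures), day-16
#' motor-neuron survival (about 50% in mutant-SOD1 co-cultures), in vivo
#' innervation (about 40% of postsynaptic sites innervated in untreated
#' disease versus 80% under 30 mg/kg pridopidine, against a fully
#' innervated wild-type reference), a treated aggregate density of half
#' the vehicle density, and a treated fiber-diameter mean 4 um above the
#' vehicle mean. All remaining magnitudes (kinematic speeds and pause
#' rates, burst shape, absolute aggregate density, absolute fiber
#' diameters, intermediate survival days) are free parameters of the
#' simulators, chosen once and documented in the methods vignette.
#'
#' @return A nested named list: `presets[[assay]][[condition]]`.
#' @export
condition_presets <- function() {
  list(
    transport = list(
      WT = transport_params(),
      SOD1 = transport_params(run_speed_mean_um_s = 0.55,
                              pause_entry_prob = 0.08)
    ),
    contraction = list(
      no_MN = contraction_params(fraction_contracting = 0.10),
      WT_cocult = contraction_params(fraction_contracting = 0.74)
    ),
    nmj_invitro = list(
      WT_cocult = list(p_intact = 0.75)
    ),
    nmj_invivo = list(
      WT_vehicle = list(p_innervated = 1.0),
      SOD1_vehicle = list(p_innervated = 0.40),
      SOD1_prido30 = list(p_innervated = 0.80)
    ),
    survival = list(
      WT_cocult = survival_params(
        surviving_fraction_by_day = c(1, 0.99, 0.97, 0.95, 0.93)
      ),
      SOD1_cocult = survival_params(
        surviving_fraction_by_day = c(1, 0.95, 0.80, 0.65, 0.50)
      )
    ),
    aggregates = list(
      WT_vehicle = list(density_per_mm2 = 2),
      SOD1_vehicle = list(density_per_mm2 = 50),
      SOD1_prido30 = list(density_per_mm2 = 25)
    ),
    fibers = list(
      WT_vehicle = list(mean_um = 40, sd_um = 8),
      SOD1_vehicle = list(mean_um = 32, sd_um = 8),
      SOD1_prido30 = list(mean_um = 36, sd_um = 8)
    )
  )
}

#' Look up one condition preset
#'
#' @param assay One of `"transport"`, `"contraction"`, `"nmj_invitro"`,
#'   `"nmj_invivo"`, `"survival"`, `"aggregates"`, `"fibers"`.
#' @param name Preset name within the assay.
#' @param presets Preset table, defaulting to [condition_presets()].
#' @return The assay-specific parameter bundle.
#' @export
get_preset <- function(assay, name, presets = condition_presets()) {
  if (!assay %in% names(presets)) {
    stop_parameter(sprintf(
      "unknown assay '%s' (known: %s)", assay,
      paste(names(presets), collapse = ", ")
    ))
  }
  if (!name %in% names(presets[[assay]])) {
    stop_parameter(sprintf(
      "unknown preset '%s' for assay '%s' (known: %s)", name, assay,
      paste(names(presets[[assay]]), collapse = ", ")
    ))
  }
  presets[[assay]][[name]]
}

# Allowed keys for the plain-list assays when reading config files.
preset_allowed_keys <- list(
  nmj_invitro = "p_intact",
  nmj_invivo = "p_innervated",
  aggregates = "density_per_mm2",
  fibers = c("mean_um", "sd_um")
)

#' Write condition presets to a YAML configuration file
#'
#' @param presets Nested preset list as from [condition_presets()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preset_config <- function(presets = condition_presets(), path) {
  plain <- lapply(presets, function(assay) lapply(assay, unclass))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read condition presets from a YAML or JSON configuration file
#'
#' Parameter bundles are re-validated through their constructors; unknown
#' keys anywhere in the file are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` preset file.
#' @return A nested preset list as from [condition_presets()].
#' @export
read_preset_config <- function(path) {
  if (!file.exists(path)) {
    stop_data(sprintf("config file '%s' does not exist", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  known_assays <- c("transport", "contraction", "nmj_invitro", "nmj_invivo",
                    "survival", "aggregates", "fibers")
  bad <- setdiff(names(raw), known_assays)
  if (length(bad) > 0L) {
    stop_schema(sprintf("unknown assay key(s) in config: %s",
                        paste(bad, collapse = ", ")))
  }
  rebuild <- function(assay, fields) {
    ctor <- switch(assay,
      transport = transport_params,
      contraction = contraction_params,
      survival = survival_params,
      NULL
    )
    if (!is.null(ctor)) {
      out <- tryCatch(
        do.call(ctor, fields),
        error = function(e) {
          if (inherits(e, "motorunit_parameter_error")) rlang::cnd_signal(e)
          stop_schema(sprintf("invalid keys for assay '%s': %s",
                              assay, conditionMessage(e)))
        }
      )
      return(out)
    }
    allowed <- preset_allowed_keys[[assay]]
    bad <- setdiff(names(fields), allowed)
    if (length(bad) > 0L) {
      stop_schema(sprintf("unknown key(s) for assay '%s': %s",
                          assay, paste(bad, collapse = ", ")))
    }
    fields
  }
  out <- lapply(known_assays, function(a) {
    if (is.null(raw[[a]])) return(NULL)
    lapply(raw[[a]], function(fields) rebuild(a, fields))
  })
  names(out) <- known_assays
  out[!vapply(out, is.null, logical(1))]
}
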