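#' Specify a synthetic cell population
#'
#' Describes a set of virtual transfected cells for one variant:
#' cell-to-cell parameter variability (by default the population SD implied
#' by the published per-variant SEM and n, SD = SEM * sqrt(n)) plus additive
#' band-limited recording noise. A seed is mandatory; there is no unseeded
#' randomness anywhere in the package.
#'
#' @param variant Variant name (must exist in the library).
#' @param n_cells Number of cells (>= 1).
#' @param dispersion_scale Multiplier on the implied population SDs
#'   (0 disables cell-to-cell variability).
#' @param noise_sigma_pA Recording-noise SD before low-pass filtering, pA.
#' @param seed Integer seed.
#' @return An object of class `cell_population_spec`.
#' @export
cell_population <- function(variant, n_cells, dispersion_scale = 1,
                            noise_sigma_pA = 5, seed) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_cells >= 1, noise_sigma_pA >= 0, dispersion_scale >= 0)
  structure(list(variant = variant, n_cells = as.integer(n_cells),
                 dispersion_scale = dispersion_scale,
                 noise_sigma_pA = noise_sigma_pA, seed = as.integer(seed)),
            class = "cell_population_spec")
}

#' Draw per-cell parameter sets for a variant
#'
#' Each cell's peak density, activation/inactivation midpoints, persistent
#' floor and recovery time constant are drawn independently from normal
#' distributions centered on the variant's parameters with the population
#' SDs implied by the published SEM and n. Draws are clipped to the
#' parameter invariants (persistent fraction in \[0, 1\], positive density
#' and time constants).
#'
#' @param spec A [cell_population()] spec.
#' @param library A `variant_library`; defaults to the packaged table.
#' @return List of `variant_params`, length `n_cells`; reproducible for a
#'   fixed seed.
#' @export
sample_cells <- function(spec, library = load_variant_table()) {
  stopifnot(inherits(spec, "cell_population_spec"))
  base <- nav_variant(spec$variant, library)
  vb <- load_variability_table()
  i <- match(spec$variant, vb$name)
  if (is.na(i)) stop("no variability row for variant '", spec$variant, "'", call. = FALSE)
  sd_of <- function(sem, n) {
    if (is.na(sem) || is.na(n)) 0 else sem * sqrt(n)
  }
  sds <- c(
    peak = sd_of(vb$sem_peak_density[i], vb$n_peak_density[i]),
    vact = sd_of(vb$sem_v_half_act[i], vb$n_v_half_act[i]),
    vinact = sd_of(vb$sem_v_half_inact[i], vb$n_v_half_inact[i]),
    pf = sd_of(vb$sem_persistent_pct[i], vb$n_persistent_pct[i]) / 100,
    taurec = sd_of(vb$sem_tau_rec[i], vb$n_tau_rec[i])
  ) * spec$dispersion_scale
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(restore_rng(old), add = TRUE)
  lapply(seq_len(spec$n_cells), function(j) {
    draw <- function(mu, sd) if (sd > 0) stats::rnorm(1, mu, sd) else mu
    pf <- min(1, max(0, draw(base$persistent_frac, sds[["pf"]])))
    variant_params(
      name = sprintf("%s_cell%02d", base$name, j),
      peak_density_pA_per_pF = max(1, draw(base$peak_density_pA_per_pF, sds[["peak"]])),
      v_half_act_mV = draw(base$v_half_act_mV, sds[["vact"]]),
      k_act_mV = base$k_act_mV,
      v_half_inact_mV = draw(base$v_half_inact_mV, sds[["vinact"]]),
      k_inact_mV = base$k_inact_mV,
      persistent_frac = pf,
      tau_rec_ms = max(0.05, draw(base$tau_rec_ms, sds[["taurec"]])),
      tau_inact_ms = base$tau_inact_ms,
      e_na_mV = base$e_na_mV,
      non_inactivating = pf >= 0.5
    )
  })
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Add band-limited recording noise to traces
#'
#' Adds i.i.d. Gaussian noise per sample and then applies a 10 kHz
#' zero-phase low-pass (4th-order Butterworth, forward-backward), emulating
#' the amplifier's anti-alias filtering of recording noise. `sigma_pA = 0`
#' returns the input unchanged.
#'
#' @param traces A `nav_traces` tibble.
#' @param sigma_pA Pre-filter noise SD, pA (>= 0).
#' @param seed Integer seed (mandatory when `sigma_pA > 0`).
#' @param cutoff_hz Low-pass cut-off frequency, Hz.
#' @return The traces with noisy `i_pA`, attributes preserved.
#' @export
add_recording_noise <- function(traces, sigma_pA, seed, cutoff_hz = 10000) {
  stopifnot(sigma_pA >= 0)
  if (sigma_pA == 0) return(traces)
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory", call. = FALSE)
  dt <- attr(traces, "dt")
  fs <- 1000 / dt
  w <- cutoff_hz / (fs / 2)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)
  bf <- if (w < 1) signal::butter(4, w, type = "low") else NULL
  noisy <- traces
  noisy$i_pA <- unlist(lapply(split(traces$i_pA, traces$sweep)[as.character(unique(traces$sweep))],
    function(x) {
      e <- stats::rnorm(length(x), 0, sigma_pA)
      if (!is.null(bf)) e <- signal::filtfilt(bf, e)
      x + e
    }), use.names = FALSE)
  noisy
}

#' Parameter-recovery experiment
#'
#' End-to-end validation loop: sample cells, simulate the standard activation
#' / inactivation / recovery protocols for each, add recording noise, run the
#' full analysis pipeline, and compare estimates to each cell's true
#' parameters. Individual fit failures are recorded, not fatal.
#'
#' @param spec A [cell_population()] spec.
#' @param library A `variant_library`.
#' @param dt Integration/sampling step, ms.
#' @return List of class `recovery_report`: `cells` (per-cell estimates and
#'   truths), `summary` (per parameter: true population value, mean and SD of
#'   estimates, relative bias, success count), `n_failed`.
#' @export
recovery_experiment <- function(spec, library = load_variant_table(), dt = 0.02) {
  cells <- sample_cells(spec, library)
  base <- nav_variant(spec$variant, library)
  protos <- standard_protocols()
  mode <- recovery_mode_for(base)
  rows <- purrr::imap(cells, function(p, j) {
    noise_seed <- spec$seed + 1000L + j
    est <- tryCatch({
      sim <- function(proto) {
        tr <- run_voltage_clamp(p, proto, recording_conditions(), dt = dt)
        add_recording_noise(tr, spec$noise_sigma_pA, seed = noise_seed)
      }
      act <- activation_analysis(sim(protos$activation))
      ina <- inactivation_analysis(sim(protos$inactivation))
      rec <- recovery_analysis(sim(protos$recovery), mode = mode)
      per <- measure_persistent(sim(protos$activation))
      # quality control, as in lab practice: cells whose currents are too
      # small relative to the noise converge to implausibly shallow sigmoids
      if (act$k > 15 || ina$k > 15) stop("fit failed quality control")
      tibble(
        cell = p$name, ok = TRUE,
        v_half_act_est = act$v_half, v_half_inact_est = ina$v_half,
        tau_rec_est = rec$tau, persistent_pct_est = per$percent
      )
    }, error = function(e) {
      tibble(cell = p$name, ok = FALSE, v_half_act_est = NA_real_,
             v_half_inact_est = NA_real_, tau_rec_est = NA_real_,
             persistent_pct_est = NA_real_)
    })
    est$v_half_act_true <- p$v_half_act_mV
    est$v_half_inact_true <- p$v_half_inact_mV
    est$tau_rec_true <- p$tau_rec_ms
    est
  })
  cells_tbl <- dplyr::bind_rows(rows)
  ok <- cells_tbl[cells_tbl$ok, ]
  summarise_par <- function(param, est, true) {
    est <- est[is.finite(est)]
    tibble(parameter = param, true = true,
           mean_estimate = mean(est), sd_estimate = stats::sd(est),
           rel_bias = (mean(est) - true) / abs(true), n_success = length(est))
  }
  summary <- dplyr::bind_rows(
    summarise_par("v_half_act_mV", ok$v_half_act_est, base$v_half_act_mV),
    summarise_par("v_half_inact_mV", ok$v_half_inact_est, base$v_half_inact_mV),
    summarise_par("tau_rec_ms", ok$tau_rec_est, base$tau_rec_ms)
  )
  structure(list(cells = cells_tbl, summary = summary,
                 n_failed = sum(!cells_tbl$ok)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d cells (%d failed)\n",
              nrow(x$cells), x$n_failed))
  print(x$summary)
  invisible(x)
}
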