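#' @importFrom stats coef lm resid setNames
NULL

# Most-negative current during a step, ignoring the first `blank` ms after
# segment onset (capacitive-artifact convention), refined by a three-point
# quadratic interpolation around the discrete extremum so the measured peak
# is insensitive to the sample grid.
step_peak <- function(time_ms, i_pA, blank = 0.1) {
  if (length(i_pA) == 0L) stop("empty trace segment", call. = FALSE)
  dt <- if (length(time_ms) > 1L) time_ms[2] - time_ms[1] else 0
  onset <- time_ms[1] - dt
  keep <- which(time_ms - onset > blank)
  if (length(keep) == 0L) keep <- seq_along(i_pA)
  y <- i_pA[keep]
  j <- which.min(y)
  pk <- y[j]
  if (j > 1L && j < length(y)) {
    den <- y[j + 1] - 2 * y[j] + y[j - 1]
    if (den > 0) pk <- y[j] - (y[j + 1] - y[j - 1])^2 / (8 * den)
  }
  pk
}

segment_peaks <- function(traces, segment, blank = 0.1) {
  traces |>
    dplyr::filter(.data$segment == !!segment) |>
    dplyr::group_by(.data$sweep) |>
    dplyr::summarise(i_peak_pA = step_peak(.data$time_ms, .data$i_pA, blank = blank),
                     .groups = "drop")
}

#' Peak current-voltage relationship
#'
#' Per sweep of an activation-protocol trace set, the most-negative current
#' during the depolarizing step and its density (peak / C_m).
#'
#' @param traces A `nav_traces` tibble from [run_voltage_clamp()] with a
#'   `"step"` segment.
#' @param cond [recording_conditions()]; defaults to the conditions stored on
#'   `traces`.
#' @return A tibble with columns `v_mV`, `i_peak_pA`, `density_pA_per_pF`.
#' @export
peak_iv <- function(traces, cond = attr(traces, "conditions")) {
  if (nrow(traces) == 0L) stop("empty trace set", call. = FALSE)
  if (!"step" %in% traces$segment) {
    stop("peak_iv needs activation-protocol traces with a 'step' segment", call. = FALSE)
  }
  segment_peaks(traces, "step") |>
    dplyr::transmute(v_mV = .data$sweep, i_peak_pA = .data$i_peak_pA,
                     density_pA_per_pF = .data$i_peak_pA / cond$c_m_pF)
}

new_boltzmann_fit <- function(v_half, k, direction, residual, n_points, data) {
  structure(list(v_half = v_half, k = k, direction = direction,
                 residual = residual, n_points = n_points, data = data),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s: V0.5 = %.2f mV, k = %.2f mV (n = %d, resid = %.2e)\n",
              x$direction, x$v_half, x$k, x$n_points, x$residual))
  invisible(x)
}

#' Fit a Boltzmann sigmoid by nonlinear least squares
#'
#' Fits `y = 1 / (1 + exp(-s (V - V0.5)/k))` (s = +1 rising, -1 falling) to
#' normalized points in \[0, 1\]. Starting values: `V0.5` from the
#' half-maximum crossing by linear interpolation, `k = 6` mV.
#'
#' @param points Data frame with columns `v` (mV) and `y` (normalized).
#' @param direction `"rising"` or `"falling"`.
#' @return A `boltzmann_fit` object with elements `v_half`, `k`, `residual`
#'   (residual norm), `n_points`, `data`.
#' @export
fit_boltzmann <- function(points, direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  points <- as_tibble(points)
  stopifnot(all(c("v", "y") %in% names(points)))
  points <- points[is.finite(points$v) & is.finite(points$y), ]
  if (nrow(points) < 4L) stop("Boltzmann fit needs at least 4 points", call. = FALSE)
  if (diff(range(points$y)) < 1e-6) {
    stop("degenerate input: y is constant, no sigmoid can be fit", call. = FALSE)
  }
  if (max(points$y) < 0.5 || min(points$y) > 0.5) {
    stop("points do not span the half-maximum; cannot locate V0.5", call. = FALSE)
  }
  s <- if (direction == "rising") 1 else -1
  o <- order(points$v)
  vv <- points$v[o]; yy <- points$y[o]
  cross <- which(diff(sign(yy - 0.5)) != 0)
  vh0 <- if (length(cross)) {
    i <- cross[1]
    vv[i] + (0.5 - yy[i]) * (vv[i + 1] - vv[i]) / (yy[i + 1] - yy[i])
  } else vv[which.min(abs(yy - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 + exp(-s * (v - v_half) / k)),
      data = points,
      start = list(v_half = vh0, k = 6),
      lower = c(v_half = -150, k = 0.1),
      upper = c(v_half = 100, k = 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("Boltzmann fit did not converge: ", conditionMessage(e),
                             call. = FALSE)
  )
  cf <- coef(fit)
  new_boltzmann_fit(unname(cf["v_half"]), unname(cf["k"]), direction,
                    sqrt(sum(resid(fit)^2)), nrow(points), points)
}

#' Activation analysis: peak conductance to Boltzmann fit
#'
#' Converts peak currents to conductance with `G = I / (V - V_rev)`,
#' excluding sweeps within 10 mV of the reversal potential (where the
#' transform blows up), normalizes to the maximum over included sweeps, and
#' fits a rising Boltzmann.
#'
#' @inheritParams peak_iv
#' @return A `boltzmann_fit`; the normalized conductance points are stored in
#'   `$data`.
#' @export
activation_analysis <- function(traces, cond = attr(traces, "conditions")) {
  v_rev <- cond$v_rev_mV
  if (is.null(v_rev)) v_rev <- attr(traces, "params")$e_na_mV
  iv <- peak_iv(traces, cond)
  iv <- iv[abs(iv$v_mV - v_rev) >= 10, ]
  if (nrow(iv) == 0L) stop("all sweeps excluded by the reversal-potential window", call. = FALSE)
  g <- iv$i_peak_pA / (iv$v_mV - v_rev)
  g_max <- max(g)
  if (g_max <= 0) stop("no inward conductance; cannot build an activation curve", call. = FALSE)
  fit_boltzmann(tibble(v = iv$v_mV, y = g / g_max), "rising")
}

#' Steady-state inactivation analysis
#'
#' Availability is the inward test-pulse peak as a function of prepulse
#' voltage, normalized to the maximum-availability (most hyperpolarized)
#' sweep. For non-inactivating variants the analysis is done on the
#' inactivatable fraction only: the non-inactivating floor (the plateau at
#' depolarized prepulses) is subtracted and the curve renormalized before the
#' falling Boltzmann fit.
#'
#' @inheritParams peak_iv
#' @param floor_subtract Subtract the non-inactivating floor first? `NULL`
#'   (default) subtracts automatically when the normalized availability
#'   plateau exceeds 0.5 percent (any variant with an appreciable persistent
#'   fraction), leaving fully inactivating synthetic channels untouched.
#' @return A `boltzmann_fit`.
#' @export
inactivation_analysis <- function(traces, floor_subtract = NULL) {
  if (!"test" %in% traces$segment) {
    stop("inactivation_analysis needs traces with prepulse + 'test' segments", call. = FALSE)
  }
  # 1 ms blanking (10 activation time constants) excludes the deactivation
  # transient of channels left open by depolarized prepulses, leaving a test
  # current proportional to prepulse availability
  pk <- segment_peaks(traces, "test", blank = 1)
  avail <- abs(pk$i_peak_pA)
  if (max(avail) <= 0 || diff(range(avail)) / max(avail) < 1e-3) {
    stop("flat availability curve; nothing to fit", call. = FALSE)
  }
  y <- avail / max(avail)
  if (is.null(floor_subtract)) {
    # subtract whenever an appreciable non-inactivating plateau is present,
    # so the fit sees the inactivatable fraction only
    floor_subtract <- min(y) > 0.005
  }
  if (floor_subtract) {
    fl <- min(y)
    y <- (y - fl) / (1 - fl)
  }
  fit_boltzmann(tibble(v = pk$sweep, y = y), "falling")
}

#' Persistent sodium current (percent of peak) with the 50 percent rule
#'
#' On the -10 mV sweep of an activation-type protocol, the ratio of the
#' current 40 ms after step onset to the inward transient peak, as a
#' percentage. Ratios of at least 50 percent are flagged `nd` (the variant is
#' non-inactivating and a persistent percentage is not determined).
#'
#' @inheritParams peak_iv
#' @param at_mV Step level to measure at (default -10 mV).
#' @param t_ms Time after step onset (default 40 ms).
#' @return One-row tibble: `variant`, `percent` (`NA` when `nd`), `ratio_pct`
#'   (the raw ratio), `nd` (logical).
#' @export
measure_persistent <- function(traces, at_mV = -10, t_ms = 40) {
  step <- traces |>
    dplyr::filter(.data$segment == "step", abs(.data$sweep - at_mV) < 1e-9)
  if (nrow(step) == 0L) {
    stop("no step sweep at ", at_mV, " mV in these traces", call. = FALSE)
  }
  dt <- attr(traces, "dt")
  onset <- step$time_ms[1] - dt
  if (max(step$time_ms) - onset < t_ms - 1e-9) {
    stop("step is shorter than ", t_ms, " ms", call. = FALSE)
  }
  pk <- step_peak(step$time_ms, step$i_pA)
  if (pk == 0) stop("zero peak current; persistent fraction undefined", call. = FALSE)
  i_late <- step$i_pA[which.min(abs(step$time_ms - (onset + t_ms)))]
  ratio <- 100 * i_late / pk
  params <- attr(traces, "params")
  nd <- ratio >= 50
  tibble(
    variant = if (is.null(params)) NA_character_ else params$name,
    percent = ifelse(nd, NA_real_, ratio),
    ratio_pct = ratio,
    nd = nd
  )
}

#' Recommended recovery-analysis mode for a variant
#'
#' Variants with a large non-inactivating current fraction (persistent floor
#' of at least 0.2) are analyzed on the inactivated current fraction (the
#' P1 - P2 difference method); others use the standard P2/P1 ratio.
#'
#' @param params A [variant_params()] object.
#' @return `"standard"` or `"inactivated_fraction"`.
#' @export
recovery_mode_for <- function(params) {
  params <- as_variant_params(params)
  if (params$persistent_frac >= 0.2) "inactivated_fraction" else "standard"
}

new_recovery_fit <- function(tau, amplitude, residual, n_points, mode, data) {
  structure(list(tau = tau, amplitude = amplitude, residual = residual,
                 n_points = n_points, mode = mode, data = data),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> %s: tau = %.3f ms (A = %.3f, n = %d, resid = %.2e)\n",
              x$mode, x$tau, x$amplitude, x$n_points, x$residual))
  invisible(x)
}

#' Fit a single-exponential recovery time course
#'
#' Least-squares fit of `y = 1 - A exp(-t / tau)` to recovery points. With
#' `amplitude = "fixed"` (the default) A is pinned to 1, the textbook
#' recovery equation; `amplitude = "free"` also estimates A, which absorbs a
#' known normalization offset in the inactivated-fraction analysis mode.
#' The starting tau comes from a log-linear regression of `1 - y` on `t`.
#'
#' @param points Data frame with columns `t` (ms, > 0) and `y`.
#' @param amplitude `"fixed"` or `"free"`.
#' @param mode Label stored on the result.
#' @return A `recovery_fit` object with elements `tau`, `amplitude`,
#'   `residual`, `n_points`.
#' @export
fit_exponential <- function(points, amplitude = c("fixed", "free"),
                            mode = "standard") {
  amplitude <- match.arg(amplitude)
  points <- as_tibble(points)
  stopifnot(all(c("t", "y") %in% names(points)))
  if (nrow(points) < 4L) stop("exponential fit needs at least 4 points", call. = FALSE)
  if (any(points$t <= 0)) stop("all recovery times must be positive", call. = FALSE)
  o <- order(points$t)
  yy <- points$y[o]
  if (any(diff(yy) < -0.05)) {
    warning("recovery points are non-monotone beyond noise tolerance", call. = FALSE)
  }
  z <- pmax(1 - points$y, 1e-8)
  sl <- unname(coef(lm(log(z) ~ points$t))[2])
  tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else mean(points$t)
  fit <- tryCatch(
    if (amplitude == "fixed") {
      minpack.lm::nlsLM(y ~ 1 - exp(-t / tau), data = points,
                        start = list(tau = tau0), lower = c(tau = 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ 1 - A * exp(-t / tau), data = points,
                        start = list(tau = tau0, A = 1),
                        lower = c(tau = 1e-4, A = 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- coef(fit)
  A <- if (amplitude == "fixed") 1 else unname(cf["A"])
  new_recovery_fit(unname(cf["tau"]), A, sqrt(sum(resid(fit)^2)),
                   nrow(points), mode, points)
}

#' Recovery-from-fast-inactivation analysis
#'
#' From paired-pulse traces: in `standard` mode the recovery curve is the
#' P2/P1 inward-peak ratio against the interpulse interval. In
#' `inactivated_fraction` mode (for variants with a large non-inactivating
#' fraction) the inactivated current is first isolated as the P1 - P2 peak
#' difference and its decay is normalized to the shortest interval (0.1 ms).
#' Both modes fit the single-exponential recovery form `1 - A exp(-t/tau)`
#' with a free amplitude: A absorbs the non-inactivated baseline (standard
#' mode) or the known normalization offset at 0.1 ms (inactivated-fraction
#' mode), leaving tau unbiased.
#'
#' @inheritParams peak_iv
#' @param mode `"standard"` or `"inactivated_fraction"`.
#' @return A `recovery_fit`.
#' @export
recovery_analysis <- function(traces, mode = c("standard", "inactivated_fraction")) {
  mode <- match.arg(mode)
  if (!all(c("p1", "p2") %in% traces$segment)) {
    stop("recovery_analysis needs paired-pulse traces with 'p1' and 'p2' segments",
         call. = FALSE)
  }
  p1 <- segment_peaks(traces, "p1")
  p2 <- segment_peaks(traces, "p2")
  d <- dplyr::inner_join(p1, p2, by = "sweep", suffix = c("_p1", "_p2"))
  if (nrow(d) < 6L) stop("need at least 6 interpulse intervals", call. = FALSE)
  if (any(abs(d$i_peak_pA_p1) <= 0)) stop("P1 peak is zero; cannot normalize", call. = FALSE)
  if (mode == "standard") {
    pts <- tibble(t = d$sweep, y = abs(d$i_peak_pA_p2) / abs(d$i_peak_pA_p1))
    fit_exponential(pts, amplitude = "free", mode = mode)
  } else {
    diffs <- abs(d$i_peak_pA_p1) - abs(d$i_peak_pA_p2)
    ref <- diffs[which.min(d$sweep)]
    if (ref <= 0) stop("no inactivated fraction at the shortest interval", call. = FALSE)
    pts <- tibble(t = d$sweep, y = 1 - diffs / ref)
    fit_exponential(pts, amplitude = "free", mode = mode)
  }
}
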