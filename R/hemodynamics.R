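#' Smoothed time derivative of an LV pressure waveform
#'
#' Applies zero-phase Savitzky-Golay smoothing (local least-squares
#' quadratic, so linear and quadratic pressure segments pass through
#' unattenuated) followed by centred finite differences; the first and last
#' samples use one-sided differences. `smooth_window = 1` disables smoothing
#' and returns the raw centred difference.
#'
#' @param waveform A `pressure_waveform`.
#' @param smooth_window Odd window length in samples (default 21 at 1 kHz,
#'   i.e. 21 ms).
#' @return Numeric vector of dP/dt (mmHg/s), same length as the input.
#' @export
compute_dpdt <- function(waveform, smooth_window = 21) {
  check_waveform(waveform)
  sm <- smooth_pressure(waveform$pressure, smooth_window)
  finite_diff(sm, 1 / waveform$sampling_rate)
}

check_waveform <- function(waveform) {
  if (!inherits(waveform, "pressure_waveform"))
    stop("expected a 'pressure_waveform' object", call. = FALSE)
  invisible(waveform)
}

check_window <- function(w, n) {
  if (!is.numeric(w) || length(w) != 1L || w != round(w) || w < 1 ||
      w %% 2 == 0)
    stop("smooth_window must be an odd positive integer", call. = FALSE)
  if (w >= n)
    stop("smooth_window must be smaller than the series length", call. = FALSE)
  as.integer(w)
}

smooth_pressure <- function(pressure, smooth_window) {
  w <- check_window(smooth_window, length(pressure))
  if (w <= 3L) return(pressure)  # order-2 fit through <=3 points is identity
  as.numeric(signal::sgolayfilt(pressure, p = 2, n = w))
}

finite_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

# dominant cardiac period (s) from the spectral peak of the detrended trace,
# searched over the physiologic band 0.5-4 Hz (30-240 bpm)
dominant_period <- function(waveform) {
  x <- waveform$pressure - mean(waveform$pressure)
  n <- length(x)
  sp <- Mod(fft(x))[seq_len(floor(n / 2))]^2
  freq <- (seq_len(floor(n / 2)) - 1L) * waveform$sampling_rate / n
  band <- freq >= 0.5 & freq <= 4
  if (!any(band) || max(sp[band]) <= 0)
    stop("segmentation error: no dominant cardiac frequency in 0.5-4 Hz",
         call. = FALSE)
  1 / freq[band][which.max(sp[band])]
}

#' Segment an LV pressure waveform into cardiac cycles
#'
#' Upstroke onsets are located where the smoothed dP/dt crosses above 20% of
#' its global maximum. Crossings are deduplicated with a refractory period of
#' 0.3 times the expected beat interval, initialised from the dominant
#' spectral period of the trace and then refined to 0.3 times the median
#' inter-onset interval. Consecutive onsets delimit contiguous,
#' non-overlapping cycles.
#'
#' @param waveform A `pressure_waveform` at least 1 s long.
#' @param smooth_window Passed to [compute_dpdt()].
#' @return Integer matrix with columns `start`, `end`: per-cycle sample index
#'   ranges `[onset_i, onset_{i+1} - 1]`.
#' @export
segment_cycles <- function(waveform, smooth_window = 21) {
  check_waveform(waveform)
  if (waveform$time[length(waveform$time)] - waveform$time[1] < 1)
    stop("waveform must be at least 1 s long to segment", call. = FALSE)
  d <- compute_dpdt(waveform, smooth_window)
  thr <- 0.2 * max(d)
  # 1e-9 mmHg/s floor guards against numerical dust on flat signals
  if (!is.finite(thr) || thr <= 1e-9)
    stop("segmentation error: no positive upstrokes in the waveform",
         call. = FALSE)
  n <- length(d)
  cross <- which(d[-1L] >= thr & d[-n] < thr) + 1L
  # hysteresis: a crossing only counts once dP/dt has re-armed below thr/2,
  # so noise dips during one slow upstroke cannot fire twice
  if (length(cross) > 1L) {
    keep <- cross[1L]
    for (i in cross[-1L]) {
      prev <- keep[length(keep)]
      if (any(d[prev:i] < 0.5 * thr)) keep <- c(keep, i)
    }
    cross <- keep
  }
  if (length(cross) < 2L)
    stop("segmentation error: fewer than 2 upstroke onsets detected",
         call. = FALSE)
  refr <- 0.3 * dominant_period(waveform) * waveform$sampling_rate
  onsets <- enforce_refractory(cross, refr)
  if (length(onsets) >= 3L)  # refine with the empirical beat interval
    onsets <- enforce_refractory(cross, 0.3 * median(diff(onsets)))
  if (length(onsets) < 2L)
    stop("segmentation error: fewer than 2 upstroke onsets detected",
         call. = FALSE)
  starts <- onsets[-length(onsets)]
  ends <- onsets[-1L] - 1L
  # a near-complete trailing cycle after the last onset is kept as a cycle
  last <- onsets[length(onsets)]
  if (n - last + 1L >= 0.5 * median(diff(onsets))) {
    starts <- c(starts, last)
    ends <- c(ends, n)
  }
  cbind(start = starts, end = ends)
}

enforce_refractory <- function(idx, refractory) {
  keep <- idx[1L]
  for (i in idx[-1L]) if (i - keep[length(keep)] >= refractory) keep <- c(keep, i)
  keep
}

#' Detect per-cycle fiducial points (end-diastole, peak systole, end-systole)
#'
#' Within one segmented cycle: peak systole is the maximum of the smoothed
#' pressure; end-systole is the post-relaxation pressure nadir between the
#' peak and the cycle end (the classical aortic-valve-closure end-systole is
#' not observable from LV pressure alone, and catheterization traces show
#' near-zero nadir pressures); end-diastole is found by scanning backwards
#' from the upstroke onset to the last sample at which the smoothed dP/dt
#' falls below 10% of the cycle's maximum dP/dt.
#'
#' @param waveform A `pressure_waveform`.
#' @param cycle Length-2 integer vector (or one row of [segment_cycles()]
#'   output): first and last sample index of the cycle.
#' @param smooth_window Passed to [compute_dpdt()].
#' @return Object of class `fiducials`: list with sample indices
#'   `end_diastole`, `peak_systole`, `end_systole` and the smoothed pressures
#'   at those samples.
#' @export
detect_fiducials <- function(waveform, cycle, smooth_window = 21) {
  check_waveform(waveform)
  d <- compute_dpdt(waveform, smooth_window)
  sm <- smooth_pressure(waveform$pressure, smooth_window)
  detect_fiducials_impl(sm, d, cycle)
}

detect_fiducials_impl <- function(sm, d, cycle) {
  start <- as.integer(cycle[1L]); end <- as.integer(cycle[2L])
  if (start < 1L || end > length(sm) || start >= end)
    stop("cycle bounds outside the waveform", call. = FALSE)
  seg <- start:end
  pk <- seg[which.max(sm[seg])]
  if (pk >= end)
    stop("fiducial error: no relaxation nadir after the systolic peak ",
         "(monotone segment?)", call. = FALSE)
  es <- (pk:end)[which.min(sm[pk:end])]
  cyc_max <- max(d[seg])
  if (cyc_max <= 0)
    stop("fiducial error: cycle has no positive dP/dt", call. = FALSE)
  ed <- start
  while (ed > 1L && d[ed] >= 0.1 * cyc_max) ed <- ed - 1L
  if (d[ed] >= 0.1 * cyc_max) {
    # recording begins on the upstroke itself (differentiation edge effects
    # can keep dP/dt above threshold): fall back to the quietest sample
    ed <- which.min(d[1:start])
    if (ed >= pk)
      stop("fiducial error: no end-diastolic point before the upstroke",
           call. = FALSE)
  }
  if (!(ed < pk && pk < es) || sm[pk] < sm[ed] || sm[pk] < sm[es])
    stop(sprintf(paste0("fiducial error: non-physiologic ordering ",
                        "(ed=%d, peak=%d, es=%d; pressures %.1f, %.1f, %.1f mmHg)"),
                 ed, pk, es, sm[ed], sm[pk], sm[es]), call. = FALSE)
  structure(list(end_diastole = ed, peak_systole = pk, end_systole = es,
                 p_end_diastole = sm[ed], p_peak_systole = sm[pk],
                 p_end_systole = sm[es]),
            class = "fiducials")
}

#' Select the run of consecutive beats recorded at end-expiration
#'
#' Clinically, beats are averaged at end-expiration, where respiratory
#' baseline modulation is at its trough. Among all runs of `k` consecutive
#' detected cycles, this picks the run whose mean end-diastolic (baseline)
#' pressure is lowest; ties go to the earliest run.
#'
#' @param waveform A `pressure_waveform`.
#' @param cycles Cycle index matrix from [segment_cycles()].
#' @param k Number of consecutive cycles to select (default 5).
#' @param smooth_window Passed to [compute_dpdt()].
#' @return Integer vector of `k` consecutive row indices into `cycles`.
#' @export
select_end_expiration_cycles <- function(waveform, cycles, k = 5,
                                         smooth_window = 21) {
  check_waveform(waveform)
  n_cyc <- nrow(cycles)
  if (is.null(n_cyc) || n_cyc < k)
    stop(sprintf("selection error: %d cycles detected but k=%d requested",
                 ifelse(is.null(n_cyc), 0L, n_cyc), k), call. = FALSE)
  d <- compute_dpdt(waveform, smooth_window)
  sm <- smooth_pressure(waveform$pressure, smooth_window)
  baseline <- vapply(seq_len(n_cyc), function(i) {
    detect_fiducials_impl(sm, d, cycles[i, ])$p_end_diastole
  }, numeric(1))
  run_means <- vapply(seq_len(n_cyc - k + 1L),
                      function(i) mean(baseline[i:(i + k - 1L)]), numeric(1))
  first <- which(run_means <= min(run_means) + 1e-9)[1L]
  seq.int(first, first + k - 1L)
}

#' Classify diastolic dysfunction from LVEDP
#'
#' Diastolic dysfunction is defined as an invasively measured left
#' ventricular end-diastolic pressure elevated above 15 mmHg (strict
#' inequality: exactly 15 mmHg is not classified as dysfunction).
#'
#' @param lvedp LVEDP in mmHg (vectorised).
#' @return Logical vector.
#' @export
#' @examples
#' classify_diastolic_dysfunction(c(8, 15, 20))
classify_diastolic_dysfunction <- function(lvedp) {
  if (!is.numeric(lvedp) || any(!is.finite(lvedp)))
    stop("lvedp must be finite numeric", call. = FALSE)
  lvedp > DD_LVEDP_THRESHOLD
}

#' Derived hemodynamic parameters averaged over end-expiration beats
#'
#' Runs the full pressure-curve post-processing chain: cycle segmentation,
#' fiducial detection, selection of `k` consecutive end-expiration cycles,
#' then per-cycle computation of
#' \itemize{
#'   \item LVEDP and LV end-systolic pressure (smoothed pressure at the
#'     fiducials),
#'   \item maximum and minimum dP/dt over the cycle,
#'   \item LV contraction integral: trapezoidal area under dP/dt from
#'     end-diastole to peak systole (mmHg),
#'   \item LV relaxation integral: magnitude of the trapezoidal area under
#'     dP/dt from peak systole to end-systole (mmHg; the signed area is
#'     negative, clinical convention reports the magnitude),
#'   \item LV diastolic integral: trapezoidal area under the pressure curve
#'     from end-systole to the next end-diastole (mmHg s), per cycle.
#' }
#' All parameters are the unweighted arithmetic mean over the `k` selected
#' cycles. By the fundamental theorem of calculus the contraction and
#' relaxation integrals equal the pressure differences between their
#' bounding fiducials, which is used as an internal consistency oracle in
#' the package tests.
#'
#' @param waveform A `pressure_waveform` segmentable into at least `k`
#'   (plus preferably one trailing) cycles.
#' @param k Number of consecutive end-expiration cycles to average
#'   (default 5).
#' @param smooth_window Passed to [compute_dpdt()].
#' @return Object of class `hemodynamic_params`: list with `lvedp`, `lvesp`
#'   (mmHg), `max_dpdt`, `min_dpdt` (mmHg/s), `contraction_integral`,
#'   `relaxation_integral` (mmHg), `diastolic_integral` (mmHg s),
#'   `n_cycles_used` and logical `diastolic_dysfunction`.
#' @export
#' @examples
#' sim <- simulate_waveform(waveform_params(noise_sd = 0, resp_amplitude = 0))
#' compute_hemodynamic_params(sim$waveform)
compute_hemodynamic_params <- function(waveform, k = 5, smooth_window = 21) {
  check_waveform(waveform)
  cycles <- segment_cycles(waveform, smooth_window)
  sel <- select_end_expiration_cycles(waveform, cycles, k, smooth_window)
  d <- compute_dpdt(waveform, smooth_window)
  sm <- smooth_pressure(waveform$pressure, smooth_window)
  dt <- 1 / waveform$sampling_rate
  fids <- lapply(seq_len(nrow(cycles)), function(i)
    detect_fiducials_impl(sm, d, cycles[i, ]))
  per_cycle <- vapply(sel, function(i) {
    f <- fids[[i]]
    seg <- cycles[i, 1L]:cycles[i, 2L]
    # diastolic filling runs to the next cycle's end-diastole when available
    dia_end <- if (i < nrow(cycles)) fids[[i + 1L]]$end_diastole else cycles[i, 2L]
    c(lvedp = f$p_end_diastole,
      lvesp = f$p_end_systole,
      max_dpdt = max(d[seg]),
      min_dpdt = min(d[seg]),
      contraction_integral = dt * pracma::trapz(d[f$end_diastole:f$peak_systole]),
      relaxation_integral = abs(dt * pracma::trapz(d[f$peak_systole:f$end_systole])),
      diastolic_integral = dt * pracma::trapz(sm[f$end_systole:dia_end]))
  }, numeric(7))
  out <- as.list(rowMeans(per_cycle))
  out$n_cycles_used <- length(sel)
  out$diastolic_dysfunction <- classify_diastolic_dysfunction(out$lvedp)
  structure(out, class = "hemodynamic_params")
}

#' @export
print.hemodynamic_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Hemodynamic parameters (mean of %d end-expiration cycles)\n",
    "  LVEDP                %8.1f mmHg   (diastolic dysfunction: %s)\n",
    "  LV end-systolic P    %8.1f mmHg\n",
    "  max dP/dt            %8.0f mmHg/s\n",
    "  min dP/dt            %8.0f mmHg/s\n",
    "  contraction integral %8.1f mmHg\n",
    "  relaxation integral  %8.1f mmHg\n",
    "  diastolic integral   %8.2f mmHg*s\n"),
    x$n_cycles_used, x$lvedp, ifelse(x$diastolic_dysfunction, "yes", "no"),
    x$lvesp, x$max_dpdt, x$min_dpdt, x$contraction_integral,
    x$relaxation_integral, x$diastolic_integral))
  invisible(x)
}
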