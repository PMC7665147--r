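#' Default frequency grid for window spectra
#'
#' The short-time Fourier transform of each 10 s window is evaluated on a
#' fixed physical frequency grid running from 0 to 39.9 Hz in steps of
#' 0.1 Hz (400 points). At the study sampling frequency of 80 Hz and a
#' 10 s window this coincides with the natural DFT bin spacing, so every
#' grid frequency is an exact DFT bin.
#'
#' @param freq_max Largest frequency on the grid (Hz).
#' @param freq_step Grid spacing (Hz).
#' @return Numeric vector of frequencies in Hz, starting at 0.
#' @export
freq_grid <- function(freq_max = 39.9, freq_step = 0.1) {
  n <- round(freq_max / freq_step)
  (0:n) * freq_step
}

#' Default order-domain grid
#'
#' Cadence-normalized spectra are restricted to 546 equally spaced points
#' between 0.3 and 5.75 multiples of the cadence; the implied spacing is
#' 0.01 order units.
#'
#' @param order_min Lowest order (multiple of the cadence).
#' @param order_max Highest order.
#' @param order_points Number of grid points.
#' @return Numeric vector of orders (unitless multiples of the cadence).
#' @export
order_grid <- function(order_min = 0.3, order_max = 5.75, order_points = 546L) {
  seq(order_min, order_max, length.out = order_points)
}

#' Vector magnitude of a tri-axial bout
#'
#' Collapses three orthogonal acceleration axes into the orientation-invariant
#' vector magnitude, the root sum of squares of the axes at each time point.
#'
#' @param x1,x2,x3 Numeric acceleration series (device units, g), equal length.
#' @return Nonnegative numeric series of the same length.
#' @export
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
vector_magnitude <- function(x1, x2, x3) {
  if (length(x1) != length(x2) || length(x2) != length(x3)) {
    stop("axis series must have equal length", call. = FALSE)
  }
  sqrt(x1^2 + x2^2 + x3^2)
}

#' Split a series into non-overlapping windows
#'
#' Divides a signal into consecutive windows of `window_s` seconds
#' (`window_s * fs` samples). A trailing remainder shorter than one window
#' is discarded, since the windowed statistics require exactly tau samples.
#'
#' @param x Numeric series.
#' @param fs Sampling frequency (Hz).
#' @param window_s Window length in seconds (default 10).
#' @return List of numeric vectors, each of length `window_s * fs`.
#' @export
split_windows <- function(x, fs, window_s = 10) {
  tau <- round(window_s * fs)
  n <- length(x)
  if (n < tau) {
    stop("series shorter than one window (", n, " < ", tau, " samples)",
         call. = FALSE)
  }
  k <- n %/% tau
  lapply(seq_len(k), function(i) x[((i - 1L) * tau + 1L):(i * tau)])
}

#' Vector magnitude count of a window
#'
#' The vector magnitude count (VMC) summarizes movement energy as the mean
#' absolute deviation of the vector magnitude within a window:
#' \eqn{v_\tau = \tau^{-1} \sum_u |vm(u) - \bar{vm}|}, with the mean taken
#' over the same window.
#'
#' @param vm Numeric vector of vector-magnitude values for one window.
#' @return Scalar VMC (g); zero iff `vm` is constant.
#' @export
vmc <- function(vm) {
  if (length(vm) == 0L) stop("empty window", call. = FALSE)
  mean(abs(vm - mean(vm)))
}

#' Hanning taper weights
#'
#' Raised-cosine weights \eqn{h(u) = 0.5[1 - \cos\{2\pi u/(\tau-1)\}]} for
#' \eqn{u = 0, \ldots, \tau-1}, applied to each window before the Fourier
#' transform to limit spectral leakage.
#'
#' @param tau Window length in samples (at least 2).
#' @return Numeric vector of length `tau`; zero at both ends.
#' @export
hanning_weights <- function(tau) {
  if (tau < 2) stop("tau must be >= 2", call. = FALSE)
  u <- 0:(tau - 1)
  0.5 * (1 - cos(2 * pi * u / (tau - 1)))
}

# Cache for the complex STFT evaluation matrix keyed by (tau, fs, grid).
.stft_cache <- new.env(parent = emptyenv())

stft_basis <- function(tau, fs, freqs) {
  key <- paste(tau, fs, length(freqs), freqs[1L], freqs[length(freqs)],
               sep = "|")
  E <- .stft_cache[[key]]
  if (is.null(E)) {
    u <- 0:(tau - 1)
    E <- exp(-2i * pi * outer(freqs, u / fs))
    .stft_cache[[key]] <- E
  }
  E
}

#' Magnitude spectrum of one window (short-time Fourier transform)
#'
#' Evaluates \eqn{|X(f)| = |\sum_u vm(u)\,h(u)\,e^{-i 2\pi f u / f_s}|} on a
#' fixed physical frequency grid (Hz), with Hanning weights `h`. The grid is
#' evaluated directly in Hz, which reduces to the standard DFT whenever a
#' grid frequency is a natural bin of the window.
#'
#' @param vm Numeric vector, the vector magnitude of one window (length tau).
#' @param fs Sampling frequency (Hz).
#' @param freqs Frequency grid in Hz; must be uniformly spaced and start
#'   at 0. Defaults to [freq_grid()].
#' @return Nonnegative numeric vector of magnitudes, one per grid frequency.
#' @export
window_spectrum <- function(vm, fs, freqs = freq_grid()) {
  if (length(freqs) < 2L || freqs[1L] != 0) {
    stop("frequency grid must start at 0 and have >= 2 points", call. = FALSE)
  }
  steps <- diff(freqs)
  if (max(steps) - min(steps) > 1e-8 * steps[1L]) {
    stop("frequency grid must be uniformly spaced", call. = FALSE)
  }
  tau <- length(vm)
  h <- hanning_weights(tau)
  as.numeric(Mod(stft_basis(tau, fs, freqs) %*% (vm * h)))
}

#' Estimate cadence from a window spectrum
#'
#' The cadence (fundamental walking frequency, steps per second) is the
#' location of the largest spectral peak inside a conservative search range,
#' by default 1.2 to 4.0 Hz. Ties are broken toward the lowest frequency so
#' the fundamental is favored over its harmonics.
#'
#' @param magnitude Numeric spectrum magnitudes.
#' @param freqs Frequency grid (Hz) matching `magnitude`.
#' @param smin,smax Search range bounds (Hz).
#' @return Cadence estimate in Hz.
#' @export
estimate_cadence <- function(magnitude, freqs, smin = 1.2, smax = 4.0) {
  if (length(magnitude) != length(freqs)) {
    stop("magnitude and freqs must align", call. = FALSE)
  }
  in_range <- freqs >= smin & freqs <= smax
  m <- magnitude[in_range]
  if (!any(is.finite(m))) {
    stop("no finite spectrum magnitudes in cadence search range",
         call. = FALSE)
  }
  if (diff(range(m[is.finite(m)])) == 0) {
    stop("flat spectrum in cadence search range: no identifiable peak",
         call. = FALSE)
  }
  freqs[in_range][which.max(m)]
}

#' Realign a spectrum from the frequency domain to the order domain
#'
#' Rescales the frequency axis by the window's cadence, so the spectrum is
#' indexed by order \eqn{s = f / \mathrm{cadence}} (multiples of the
#' cadence), and linearly interpolates onto a common order grid. Harmonics
#' of walking then align at integer orders across windows and subjects.
#' Orders beyond the realigned support are held at the last observed value
#' with a warning.
#'
#' @param magnitude Numeric spectrum magnitudes on `freqs`.
#' @param freqs Frequency grid (Hz).
#' @param cadence_hz Cadence for this window (Hz, positive).
#' @param grid Target order grid; defaults to [order_grid()].
#' @return Numeric vector of magnitudes on `grid`.
#' @export
to_order_domain <- function(magnitude, freqs, cadence_hz,
                            grid = order_grid()) {
  if (!is.finite(cadence_hz) || cadence_hz <= 0) {
    stop("cadence must be positive", call. = FALSE)
  }
  s <- freqs / cadence_hz
  if (max(grid) > max(s) || min(grid) < min(s)) {
    warning("order grid extends beyond realigned support; ",
            "holding boundary value constant", call. = FALSE)
  }
  stats::approx(s, magnitude, xout = grid, method = "linear", rule = 2)$y
}

#' Aggregate window-level spectra into subject-level features
#'
#' Averages order-domain spectra, cadences, and VMC values across a
#' subject's windows, then scales the average spectrum by its magnitude at
#' the cadence (order 1.0), so each harmonic reads as a ratio to the energy
#' at the cadence. The scaled spectrum equals 1 at the grid point nearest
#' order 1.
#'
#' @param spectra Numeric matrix, one row per window, columns on `grid`.
#' @param cadences Numeric vector of per-window cadence estimates (Hz).
#' @param vmcs Numeric vector of per-window VMC values (g).
#' @param subject_id Identifier carried through to the output.
#' @param grid Order grid the spectra live on.
#' @param scale_at Either `"grid"` (scale by the value at the grid point
#'   nearest order 1, the default) or `"peak"` (scale by the local maximum
#'   within 0.1 order units of 1).
#' @return An object of class `gait_features`: a list with `subject_id`,
#'   `order_grid`, `spectrum` (scaled average), `cadence_hz`, `vmc`, and
#'   `n_windows`.
#' @export
aggregate_subject <- function(spectra, cadences, vmcs, subject_id = NA,
                              grid = order_grid(),
                              scale_at = c("grid", "peak")) {
  scale_at <- match.arg(scale_at)
  spectra <- rbind(spectra)
  if (nrow(spectra) < 1L) stop("need at least one window", call. = FALSE)
  if (ncol(spectra) != length(grid)) {
    stop("spectra columns must match the order grid", call. = FALSE)
  }
  avg <- colMeans(spectra)
  denom <- if (scale_at == "grid") {
    avg[which.min(abs(grid - 1))]
  } else {
    max(avg[abs(grid - 1) <= 0.1])
  }
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate spectrum: zero magnitude at the cadence", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id,
         order_grid = grid,
         spectrum = avg / denom,
         cadence_hz = mean(cadences),
         vmc = mean(vmcs),
         n_windows = nrow(spectra)),
    class = "gait_features"
  )
}

#' @export
print.gait_features <- function(x, ...) {
  cat("<gait_features> subject", x$subject_id,
      sprintf("| cadence %.2f Hz | VMC %.3f g | %d window(s) | %d grid points\n",
              x$cadence_hz, x$vmc, x$n_windows, length(x$order_grid)))
  invisible(x)
}

#' Pre-process one raw walking bout into subject features
#'
#' Runs the full windowed pipeline on one tri-axial bout: vector magnitude,
#' 10 s non-overlapping windows, per-window VMC, Hanning-tapered spectrum,
#' cadence peak detection, order-domain realignment, cross-window averaging,
#' restriction to the order grid, and scaling at the cadence. Windows whose
#' cadence estimation fails (flat in-range spectrum) are dropped; the count
#' of dropped windows is recorded on the result.
#'
#' @param bout A `gait_bout` (see [simulate_bout()]) or any list with
#'   elements `subject_id`, `fs`, `x1`, `x2`, `x3`.
#' @param window_s Window length (s).
#' @param freqs Frequency grid (Hz).
#' @param grid Order grid.
#' @param smin,smax Cadence search range (Hz).
#' @param scale_at Scaling convention passed to [aggregate_subject()].
#' @return A `gait_features` object with an extra `n_dropped` element.
#' @export
process_bout <- function(bout, window_s = 10, freqs = freq_grid(),
                         grid = order_grid(), smin = 1.2, smax = 4.0,
                         scale_at = "grid") {
  vm <- vector_magnitude(bout$x1, bout$x2, bout$x3)
  windows <- split_windows(vm, bout$fs, window_s)
  spectra <- vector("list", length(windows))
  cadences <- vmcs <- rep(NA_real_, length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    mag <- window_spectrum(w, bout$fs, freqs)
    cad <- tryCatch(estimate_cadence(mag, freqs, smin, smax),
                    error = function(e) NA_real_)
    if (is.na(cad)) next
    cadences[i] <- cad
    vmcs[i] <- vmc(w)
    spectra[[i]] <- to_order_domain(mag, freqs, cad, grid)
  }
  ok <- !is.na(cadences)
  if (!any(ok)) {
    stop("no window yielded a cadence estimate for subject ",
         bout$subject_id, call. = FALSE)
  }
  feats <- aggregate_subject(do.call(rbind, spectra[ok]),
                             cadences[ok], vmcs[ok],
                             subject_id = bout$subject_id, grid = grid,
                             scale_at = scale_at)
  feats$n_dropped <- sum(!ok)
  feats
}

#' Collect subject features into a data frame
#'
#' @param features List of `gait_features` objects.
#' @return A data frame with columns `subject_id`, `cadence`, `vmc`, and one
#'   `s_<order>` column per order-grid point.
#' @export
features_to_df <- function(features) {
  grid <- features[[1L]]$order_grid
  spec <- t(vapply(features, function(f) f$spectrum, numeric(length(grid))))
  colnames(spec) <- sprintf("s_%.2f", grid)
  data.frame(
    subject_id = vapply(features, function(f) as.character(f$subject_id), ""),
    cadence = vapply(features, function(f) f$cadence_hz, 0),
    vmc = vapply(features, function(f) f$vmc, 0),
    spec,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}
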