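#' Observables configuration
#'
#' Settings for the BOLD signal-processing pipeline: band-pass filter,
#' sliding-window FCD, and sampling interval. Defaults follow standard
#' resting-state practice: order-2 Butterworth band-pass in 0.01-0.1 Hz,
#' windows of 30 TR samples with 28 samples of overlap (stride 2).
#'
#' @param band low/high band-pass corner frequencies, Hz.
#' @param filter_order Butterworth order.
#' @param window_length FCD window length, samples.
#' @param window_overlap FCD window overlap, samples (< window_length).
#' @param sampling_interval sampling interval of the signals (TR), s.
#' @return An object of class `dmf_obs_config`.
#' @export
observables_config <- function(band = c(0.01, 0.1), filter_order = 2,
                               window_length = 30, window_overlap = 28,
                               sampling_interval = 2) {
  stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2],
            filter_order >= 1, window_overlap < window_length,
            sampling_interval > 0)
  if (band[2] >= 1 / (2 * sampling_interval))
    stop("upper band edge must be below the Nyquist frequency 1/(2 TR)")
  structure(list(band = band, filter_order = filter_order,
                 window_length = as.integer(window_length),
                 window_overlap = as.integer(window_overlap),
                 sampling_interval = sampling_interval),
            class = "dmf_obs_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each region's time series forward and backward (zero phase) with a
#' Butterworth band-pass designed by [signal::butter()]. Series are extended
#' at both ends by odd reflection before filtering and trimmed afterwards;
#' the padding length scales with the transient of the slow corner
#' (9 / (normalized low cutoff) samples, capped at T - 1) so that edge
#' transients of the zero-initial-condition filter are fully absorbed by the
#' padding.
#'
#' @param signals N x T matrix (regions x time).
#' @param config an [observables_config()].
#' @return Filtered N x T matrix.
#' @export
bandpass <- function(signals, config = observables_config()) {
  signals <- as.matrix(signals)
  if (any(!is.finite(signals))) stop("signals must be finite")
  Tn <- ncol(signals)
  if (Tn <= 6 * config$filter_order)
    stop("time series too short for stable filtering")
  fs <- 1 / config$sampling_interval
  bf <- signal::butter(config$filter_order, config$band / (fs / 2),
                       type = "pass")
  w_low <- config$band[1] / (fs / 2)
  pad <- min(Tn - 1L, max(3L * (config$filter_order + 1L),
                          as.integer(ceiling(9 / w_low))))
  out <- t(apply(signals, 1L, function(x) {
    # odd (point-symmetric) reflection padding
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[Tn] - x[seq(Tn - 1, Tn - pad)]
    xp <- c(left, x, right)
    y <- signal::filtfilt(bf, xp)
    y[(pad + 1):(pad + Tn)]
  }))
  dimnames(out) <- dimnames(signals)
  out
}

#' Functional connectivity matrix
#'
#' Pearson correlation between all region pairs. Regions with zero variance
#' are reported in a warning and their correlations set to `NA` rather than
#' silently zeroed.
#'
#' @param signals N x T matrix (regions x time).
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
fc_matrix <- function(signals) {
  signals <- as.matrix(signals)
  v <- apply(signals, 1L, stats::var)
  flat <- which(v == 0 | !is.finite(v))
  if (length(flat) > 0)
    warning("zero-variance region(s): ", paste(flat, collapse = ", "),
            "; correlations set to NA")
  fc <- suppressWarnings(cor(t(signals)))
  diag(fc) <- 1
  fc
}

#' Sliding-window functional connectivity dynamics (FCD)
#'
#' Computes FC over consecutive sliding windows (length and overlap from
#' `config`, stride = length - overlap, starting at the first sample, any
#' trailing partial window dropped), vectorizes each window FC by its strict
#' upper triangle, and correlates the vectors pairwise to obtain the FCD
#' matrix. The strict upper triangle of the FCD is the pooled value sample
#' used by the Kolmogorov-Smirnov fitting objective.
#'
#' @param signals N x T matrix (regions x time); typically band-passed.
#' @param config an [observables_config()].
#' @return An object of class `dmf_fcd`: list with `fcd` (W x W matrix),
#'   `pooled_values` (its strict upper triangle) and `window_count`.
#' @export
fcd_matrix <- function(signals, config = observables_config()) {
  signals <- as.matrix(signals)
  Tn <- ncol(signals)
  wl <- config$window_length
  stride <- wl - config$window_overlap
  if (Tn < wl) stop("time series shorter than one FCD window")
  starts <- seq(1L, Tn - wl + 1L, by = stride)
  vecs <- vapply(starts, function(s) {
    fc <- suppressWarnings(cor(t(signals[, s:(s + wl - 1L), drop = FALSE])))
    fc[upper.tri(fc)]
  }, numeric(sum(upper.tri(diag(nrow(signals))))))
  fcd <- suppressWarnings(cor(vecs))
  diag(fcd) <- 1
  structure(list(fcd = fcd, pooled_values = fcd[upper.tri(fcd)],
                 window_count = length(starts)),
            class = "dmf_fcd")
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' sup |ECDF_a - ECDF_b| over the pooled support. The default operates on the
#' raw samples; `method = "binned"` first histograms both samples on a common
#' equal-width grid and compares the binned CDFs.
#'
#' @param sample_a,sample_b nonempty numeric samples.
#' @param method `"raw"` (default) or `"binned"`.
#' @param bins number of bins for `method = "binned"`.
#' @return K-S statistic in [0, 1].
#' @examples
#' ks_distance(c(1, 2, 3), c(1.5, 2.5, 3.5))  # 1/3
#' @export
ks_distance <- function(sample_a, sample_b, method = c("raw", "binned"),
                        bins = 100) {
  method <- match.arg(method)
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be nonempty")
  if (method == "binned") {
    rng <- range(c(sample_a, sample_b))
    if (rng[1] == rng[2]) return(0)
    brk <- seq(rng[1], rng[2], length.out = bins + 1L)
    ca <- cumsum(tabulate(findInterval(sample_a, brk, all.inside = TRUE),
                          bins)) / length(sample_a)
    cb <- cumsum(tabulate(findInterval(sample_b, brk, all.inside = TRUE),
                          bins)) / length(sample_b)
    return(max(abs(ca - cb)))
  }
  u <- sort(unique(c(sample_a, sample_b)))
  max(abs(ecdf(sample_a)(u) - ecdf(sample_b)(u)))
}

#' Pool FCD values across runs or subjects
#'
#' Concatenates the upper-triangle FCD samples of several [fcd_matrix()]
#' summaries into one pooled sample, the reference distribution for the K-S
#' fitting objective.
#'
#' @param summaries list of `dmf_fcd` objects (at least one).
#' @return Numeric vector of pooled FCD values.
#' @export
pool_fcd <- function(summaries) {
  if (length(summaries) == 0L) stop("need at least one FCD summary")
  unlist(lapply(summaries, function(s) s$pooled_values), use.names = FALSE)
}

#' Firing-rate range check
#'
#' Flags regions whose mean excitatory rate falls outside the
#' neurobiologically plausible range (closed interval, default 3-4 Hz).
#'
#' @param rate_mean per-region mean rates, Hz.
#' @param low,high interval bounds, Hz.
#' @return List with `flags` (logical per region, TRUE = in range), `pass`
#'   (all in range) and `offending` (indices out of range).
#' @export
rate_in_range <- function(rate_mean, low = 3, high = 4) {
  flags <- rate_mean >= low & rate_mean <= high
  list(flags = flags, pass = all(flags), offending = which(!flags))
}
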