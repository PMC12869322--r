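# Construction of FC feature vectors from ROI time series: nuisance
# regression, bandpass filtering, motion scrubbing, run exclusion, and
# Fisher-z correlation features.

#' Construct an ROI run
#'
#' Bundles a frames x regions BOLD signal matrix with its sampling interval
#' and per-frame framewise displacement (FD, mm). The first frame's FD is 0
#' by definition.
#'
#' @param signal numeric matrix, frames x regions; all values finite.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @param fd per-frame framewise displacement in mm; defaults to all zeros.
#' @param run_id,subject_id,site_id optional labels.
#' @return an object of class `roi_run`.
#' @export
roi_run <- function(signal, tr_seconds, fd = NULL,
                    run_id = NA_character_, subject_id = NA_character_,
                    site_id = NA_character_) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || nrow(signal) < 2) {
    stop("signal must be a numeric matrix with at least 2 frames")
  }
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1, tr_seconds > 0)
  if (is.null(fd)) fd <- numeric(nrow(signal))
  if (length(fd) != nrow(signal)) {
    stop("fd length (", length(fd), ") must equal frame count (",
         nrow(signal), ")")
  }
  if (any(!is.finite(fd)) || any(fd < 0)) stop("fd must be finite and >= 0")
  structure(
    list(signal = signal, tr_seconds = tr_seconds, fd = as.numeric(fd),
         run_id = run_id, subject_id = subject_id, site_id = site_id),
    class = "roi_run")
}

#' @export
print.roi_run <- function(x, ...) {
  cat("<roi_run> ", nrow(x$signal), " frames x ", ncol(x$signal),
      " regions, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Regress nuisance signals out of an ROI run
#'
#' Removes the column space of the supplied regressors (plus an intercept)
#' from every region's time course by least squares. With a rank-deficient
#' design the minimum-norm solution is used and a warning is emitted.
#'
#' @param run an [roi_run()].
#' @param regressors frames x k numeric matrix of nuisance time courses
#'   (e.g. motion parameters, global signal, aCompCor components).
#' @return the residualized `roi_run` (dimensions unchanged).
#' @export
regress_nuisance <- function(run, regressors) {
  stopifnot(inherits(run, "roi_run"))
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(run$signal)) {
    stop("regressors have ", nrow(regressors), " rows but run has ",
         nrow(run$signal), " frames")
  }
  if (ncol(regressors) < 1) stop("need at least one regressor column")
  # constant regressor columns are absorbed by the built-in intercept
  const <- apply(regressors, 2, function(col) all(col == col[1]))
  x <- cbind(1, regressors[, !const, drop = FALSE])
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("rank-deficient nuisance design; using minimum-norm solution")
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% run$signal) / sv$d[pos])
  } else {
    beta <- qr.coef(qx, run$signal)
  }
  run$signal <- run$signal - x %*% beta
  run
}

#' Temporal bandpass filter
#'
#' Applies a Butterworth bandpass (default first order, 0.01-0.08 Hz, the
#' canonical rs-fMRI band) to every region's time course. Filtering is run
#' forward and backward (zero phase) so the output is not time-shifted.
#'
#' @param run an [roi_run()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 * tr_seconds)`.
#' @param order filter order.
#' @return the filtered `roi_run`.
#' @export
fc_bandpass <- function(run, low_hz = 0.01, high_hz = 0.08, order = 1) {
  stopifnot(inherits(run, "roi_run"))
  nyquist <- 1 / (2 * run$tr_seconds)
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyquist) {
    stop("high_hz = ", high_hz, " Hz is at or above the Nyquist rate ",
         signif(nyquist, 4), " Hz for TR = ", run$tr_seconds, " s")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  # odd-reflection padding tames the forward-backward IIR edge transients,
  # which decay on the (long) time scale of the low band edge
  n <- nrow(run$signal)
  pad <- min(n - 1, ceiling(3 / (low_hz * run$tr_seconds)))
  run$signal <- apply(run$signal, 2, function(col) {
    head_pad <- 2 * col[1] - col[1 + rev(seq_len(pad))]
    tail_pad <- 2 * col[n] - col[n - seq_len(pad)]
    y <- signal::filtfilt(bf, c(head_pad, col, tail_pad))
    y[pad + seq_len(n)]
  })
  run
}

#' Motion scrubbing by framewise displacement
#'
#' Removes frames whose FD strictly exceeds the threshold (default
#' 0.5 mm).
#'
#' @param run an [roi_run()].
#' @param fd_threshold_mm scrubbing threshold in mm; frames with
#'   `fd > fd_threshold_mm` are censored.
#' @return a list with `run` (the censored `roi_run`) and
#'   `censored_fraction` (removed / total frames).
#' @export
fc_scrub <- function(run, fd_threshold_mm = 0.5) {
  stopifnot(inherits(run, "roi_run"), fd_threshold_mm > 0)
  keep <- run$fd <= fd_threshold_mm
  if (!any(keep)) {
    stop("all ", length(keep), " frames censored at FD > ", fd_threshold_mm,
         " mm; run '", run$run_id, "' should be excluded")
  }
  frac <- mean(!keep)
  run$signal <- run$signal[keep, , drop = FALSE]
  run$fd <- run$fd[keep]
  list(run = run, censored_fraction = frac)
}

#' Run-level exclusion rules
#'
#' Two rules used when assembling a dataset from many runs: exclude runs
#' whose censored fraction exceeds the mean + 3 SD across runs
#' (`"mean3sd"`), or runs whose retained data falls below a minimum
#' duration (`"min_duration"`, default 4 minutes).
#'
#' @param censored_fraction per-run censored fractions.
#' @param mode `"mean3sd"` or `"min_duration"`.
#' @param retained_frames per-run retained frame counts (required for
#'   `"min_duration"`).
#' @param tr_seconds sampling interval (required for `"min_duration"`).
#' @param min_minutes minimum retained duration in minutes.
#' @return logical vector, `TRUE` = keep the run.
#' @export
exclusion_flags <- function(censored_fraction,
                            mode = c("mean3sd", "min_duration"),
                            retained_frames = NULL, tr_seconds = NULL,
                            min_minutes = 4) {
  mode <- match.arg(mode)
  if (mode == "mean3sd") {
    if (length(censored_fraction) < 2) {
      stop("mean3sd mode needs at least 2 runs")
    }
    cutoff <- mean(censored_fraction) + 3 * stats::sd(censored_fraction)
    censored_fraction <= cutoff  # strict inequality excludes
  } else {
    if (is.null(retained_frames) || is.null(tr_seconds)) {
      stop("min_duration mode needs retained_frames and tr_seconds")
    }
    retained_frames * tr_seconds >= min_minutes * 60
  }
}

#' Fisher-z FC feature vector of a run
#'
#' Pearson correlations between every pair of region time courses,
#' Fisher-z transformed (`atanh`), in the package's fixed lower-triangle
#' feature order.
#'
#' @param run an [roi_run()] with at least 3 frames.
#' @param tolerant if `TRUE`, correlations at exactly +/-1 are clipped to
#'   `+/-(1 - 1e-7)` before `atanh`; the default is to error, because a
#'   perfect correlation almost always signals a degenerate input.
#' @return named numeric vector of length `R(R-1)/2`.
#' @export
fc_vector <- function(run, tolerant = FALSE) {
  stopifnot(inherits(run, "roi_run"))
  if (nrow(run$signal) < 3) stop("need at least 3 retained frames")
  sds <- apply(run$signal, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ", paste(which(sds == 0), collapse = ", "))
  }
  cc <- stats::cor(run$signal)
  r <- cc[lower.tri(cc)]
  hit <- abs(r) >= 1 - .Machine$double.eps
  if (any(hit)) {
    if (!tolerant) {
      pr <- inverse_pair_index(which(hit)[1], ncol(run$signal))
      stop("correlation is +/-1 (infinite Fisher z) for pair (",
           pr[1, "i"], ",", pr[1, "j"], "); use tolerant = TRUE to clip")
    }
    r[hit] <- sign(r[hit]) * (1 - 1e-7)
  }
  z <- atanh(r)
  names(z) <- fc_pair_names(ncol(run$signal))
  z
}
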