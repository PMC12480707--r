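#' Detect artifact beats by local-median thresholding
#'
#' A beat is flagged when its relative deviation from the median of its 11
#' nearest not-yet-flagged neighbours (by beat index) exceeds `threshold`.
#' The scan is a single deterministic left-to-right pass, so an already
#' flagged ectopic no longer contaminates its neighbours' reference medians.
#'
#' @param x An [rr_series()].
#' @param threshold Relative deviation triggering a flag, in (0, 1);
#'   default 0.20.
#' @param neighbors Number of reference neighbours (default 11).
#' @return Logical vector, `TRUE` for flagged beats.
#' @export
detect_artifacts <- function(x, threshold = 0.20, neighbors = 11L) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (nrow(x) < 12) abort("series too short for artifact detection (< 12 beats)")
  as.logical(detect_artifacts_cpp(x$rr, threshold, as.integer(neighbors)))
}

#' Correct flagged beats by cubic-spline interpolation
#'
#' Flagged RR values are replaced by a cubic spline fitted through the
#' unflagged `(t, rr)` points; flagged runs extending past the first or last
#' unflagged beat fall back to linear extrapolation from the two nearest
#' unflagged beats (recorded in the report). Timestamps are rebuilt by
#' cumulative sum so the series invariant holds; the number of beats never
#' changes.
#'
#' @param x An [rr_series()].
#' @param flags Logical vector from [detect_artifacts()].
#' @return List with `series` (corrected [rr_series()], corrected beats
#'   flagged `"corrected"`) and `report` (a one-row tibble: beat counts,
#'   corrected fraction, boundary-extrapolation indicator and the corrected
#'   indices as a list column).
#' @export
correct_beats <- function(x, flags) {
  n <- nrow(x)
  if (length(flags) != n) abort("flags not aligned to beats")
  if (mean(flags) > 0.5) abort("more than 50% of beats flagged; interpolation meaningless")
  rr <- x$rr
  boundary <- FALSE
  if (any(flags)) {
    good <- which(!flags)
    bad <- which(flags)
    inner <- bad[bad > good[1] & bad < good[length(good)]]
    outer <- setdiff(bad, inner)
    if (length(inner)) {
      # interpolate in the beat-index domain: collinear runs of beats are
      # restored exactly, and flagged timestamps (which are themselves
      # corrupted by the artifact) never enter the abscissa
      sf <- splinefun(good, rr[good], method = "fmm")
      rr[inner] <- sf(inner)
    }
    if (length(outer)) {
      boundary <- TRUE
      # linear extrapolation from the two nearest unflagged beats at each end
      lo <- good[1:2]; hi <- good[c(length(good) - 1, length(good))]
      for (i in outer) {
        pts <- if (i < good[1]) lo else hi
        sl <- (rr[pts[2]] - rr[pts[1]]) / (pts[2] - pts[1])
        rr[i] <- rr[pts[1]] + sl * (i - pts[1])
      }
    }
    rr <- pmax(rr, 1)
  }
  flag <- ifelse(flags, "corrected", "normal")
  t_new <- cumsum(rr) / 1000 - rr[1] / 1000 + x$t[1]
  out <- rr_series(t = t_new, rr = rr, flag = flag,
                   subject_id = attr(x, "subject_id"), meta = attr(x, "meta"),
                   validate = FALSE)
  report <- tibble::tibble(
    subject_id = attr(x, "subject_id"),
    n_beats = n, n_flagged = sum(flags), n_corrected = sum(flags),
    corrected_fraction = mean(flags),
    boundary_extrapolated = boundary,
    corrected_indices = list(which(flags)))
  list(series = out, report = report)
}

#' Recording rejection rule
#'
#' A recording is excluded when the corrected share of beats exceeds
#' `max_fraction` (strict inequality; the default 5% mirrors excluding
#' recordings needing correction of more than 5% of total beats).
#'
#' @param report Correction report from [correct_beats()].
#' @param max_fraction Rejection threshold (default 0.05).
#' @return `TRUE` when the recording should be rejected.
#' @export
apply_rejection_rule <- function(report, max_fraction = 0.05) {
  report$corrected_fraction > max_fraction
}

#' Smoothness-priors detrending
#'
#' Removes the slow nonstationary trend by subtracting the smoother
#' `z_hat = (I + lambda^2 D2' D2)^(-1) z`, where `D2` is the second-difference
#' operator. Constants and straight lines lie in the smoother's null space, so
#' the detrended output of any affine input is (numerically) zero; the
#' operation is linear in its input.
#'
#' @param z Numeric vector (a segment of RR values or resampled RR), length
#'   at least 3.
#' @param lambda Smoothing parameter (default 500, the method's customary
#'   value for 4 Hz-resampled RR data).
#' @return Numeric vector, the detrended (zero-trend) component.
#' @export
detrend_smoothness_priors <- function(z, lambda = 500) {
  if (lambda < 0) abort("lambda must be non-negative")
  n <- length(z)
  if (n < 3) abort("segment too short to detrend (need >= 3 points)")
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + (lambda^2) * Matrix::crossprod(D2)
  zhat <- as.numeric(Matrix::solve(A, z))
  z - zhat
}

#' Select one low-artifact 5-minute window per hour
#'
#' Slides a `window_s`-second window in `stride_s` steps through each clock
#' hour of the recording and keeps, per hour, the candidate minimizing
#' (artifact count, then a stationarity score, then earliest start). The
#' stationarity score is `|mean(first half) - mean(second half)| / SD(segment)`.
#' Hours with less than `window_s` seconds of data are reported missing;
#' windows that could not be made artifact-free are marked.
#'
#' @param x An [rr_series()] (typically after [correct_beats()]).
#' @param flags Logical per-beat artifact indicator used for the artifact
#'   count; defaults to `x$flag != "normal"`.
#' @param window_s Window length in seconds (default 300).
#' @param stride_s Search stride in seconds (default 30).
#' @return Tibble with one row per hour 0..23: `hour`, `start_s`, `end_s`,
#'   `n_beats`, `artifact_count`, `stationarity`, `clean`, `missing`.
#' @export
select_hourly_windows <- function(x, flags = NULL, window_s = 300,
                                  stride_s = 30) {
  if (is.null(flags)) flags <- x$flag != "normal"
  tmax <- x$t[nrow(x)]
  cum_flag <- c(0, cumsum(as.numeric(flags)))
  cum_rr <- c(0, cumsum(x$rr))
  cum_rr2 <- c(0, cumsum(x$rr^2))
  # all candidate windows of all hours at once
  h0 <- (0:23) * 3600
  avail <- pmin(h0 + 3600, tmax) - h0
  n_cand <- ifelse(avail >= window_s, floor((avail - window_s) / stride_s) + 1, 0L)
  cc <- tibble::tibble(
    hour = rep(0:23, n_cand),
    start = rep(h0, n_cand) + (sequence(n_cand) - 1) * stride_s)
  i0 <- findInterval(cc$start, x$t, left.open = TRUE)
  i1 <- findInterval(cc$start + window_s, x$t, left.open = TRUE)
  im <- findInterval(cc$start + window_s / 2, x$t, left.open = TRUE)
  k <- i1 - i0
  kh <- im - i0
  nf <- cum_flag[i1 + 1] - cum_flag[i0 + 1]
  s1 <- cum_rr[i1 + 1] - cum_rr[i0 + 1]
  s2 <- cum_rr2[i1 + 1] - cum_rr2[i0 + 1]
  sh <- cum_rr[im + 1] - cum_rr[i0 + 1]
  m1 <- sh / kh
  m2 <- (s1 - sh) / (k - kh)
  v <- (s2 - s1^2 / pmax(k, 1)) / pmax(k - 1, 1)
  sc <- ifelse(v > 0, abs(m1 - m2) / sqrt(v), ifelse(m1 == m2, 0, Inf))
  sc[k < 2 | kh < 1 | kh >= k] <- Inf
  nf[k < 2] <- NA
  # per hour keep the candidate minimizing (artifacts, stationarity, start)
  ord <- order(cc$hour, nf, sc, cc$start)
  first <- ord[!duplicated(cc$hour[ord])]
  idx <- match(0:23, cc$hour[first])
  sel <- first[idx]
  tibble::tibble(
    hour = 0:23,
    start_s = cc$start[sel],
    end_s = cc$start[sel] + window_s,
    n_beats = as.integer(k[sel]),
    artifact_count = as.integer(nf[sel]),
    stationarity = sc[sel],
    clean = nf[sel] == 0,
    missing = is.na(idx))
}

#' Extract the beats of a selected window
#'
#' @param x An [rr_series()].
#' @param start_s,end_s Window bounds in seconds; beats with
#'   `start_s <= t < end_s` are returned.
#' @return Numeric vector of RR intervals (ms).
#' @export
window_rr <- function(x, start_s, end_s) {
  # x$t is sorted, so slice by binary search
  i0 <- findInterval(start_s, x$t, left.open = TRUE)
  i1 <- findInterval(end_s, x$t, left.open = TRUE)
  if (i1 <= i0) return(numeric(0))
  x$rr[(i0 + 1):i1]
}
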