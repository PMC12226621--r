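# ---- registration evaluation ----------------------------------------------

#' Mean projection error between two poses
#'
#' Projects the eight corners of the volume's world-space bounding box (the
#' "hypercube" fiducials) under the reference and the estimated pose and
#' averages the Euclidean detector-plane distances. Default unit is detector
#' pixels; \code{unit = "mm"} multiplies by the detector pixel spacing.
#'
#' @param t_ref,t_reg \code{rigid_transform}s: reference standard and
#'   estimated registration.
#' @param volume \code{volume_grid} defining the fiducial corners (or an
#'   explicit n x 3 matrix of world points via \code{points}).
#' @param geom A \code{carm_geometry}.
#' @param unit \code{"px"} or \code{"mm"}.
#' @param points optional explicit fiducial points (world mm), overriding the
#'   bounding-box corners.
#' @return Non-negative scalar. Errors if any fiducial falls at or behind
#'   the X-ray source under either pose.
#' @export
mpe <- function(t_ref, t_reg, volume, geom, unit = c("px", "mm"),
                points = NULL) {
  unit <- match.arg(unit)
  pts <- if (is.null(points)) volume_corners(volume) else rbind2mat(points)
  pr <- withCallingHandlers(project_points(pts, t_ref, geom),
                            warning = function(w) stop(conditionMessage(w)))
  pg <- withCallingHandlers(project_points(pts, t_reg, geom),
                            warning = function(w) stop(conditionMessage(w)))
  err <- mean(sqrt(rowSums((pr - pg)^2)))
  if (unit == "mm") err * geom$pixel_spacing else err
}

#' Fraction of successful registrations
#'
#' @param mpes numeric vector of projection errors.
#' @param threshold positive success threshold (same unit as \code{mpes}).
#' @return Fraction in [0, 1] of values strictly below the threshold.
#' @export
success_rate <- function(mpes, threshold) {
  if (length(mpes) == 0L) stop("success_rate needs at least one value")
  stopifnot(threshold > 0)
  mean(mpes < threshold)
}

#' Equal-count capture-range histogram
#'
#' Sorts the registration records by their pre-registration error and splits
#' them into \code{n_bins} contiguous equal-count bins (when the count is not
#' divisible, earlier bins take one extra record); each bin reports the
#' median post-registration error. With 10 bins each bin holds 10 percent of
#' the registrations.
#'
#' @param records data.frame with columns \code{mpe_before}, \code{mpe_after}
#'   (and optionally \code{case_id}).
#' @param n_bins number of bins (>= 1, and at most the number of records).
#' @return data.frame with columns \code{bin}, \code{lo}, \code{hi} (range of
#'   \code{mpe_before} in the bin), \code{median_after}, \code{count}.
#' @export
capture_range_histogram <- function(records, n_bins = 10) {
  stopifnot(is.data.frame(records), n_bins >= 1)
  if (nrow(records) < n_bins)
    stop("fewer records than bins")
  if (any(records$mpe_before < 0) || any(records$mpe_after < 0))
    stop("projection errors must be non-negative")
  ord <- records[order(records$mpe_before), , drop = FALSE]
  n <- nrow(ord)
  base <- n %/% n_bins; extra <- n %% n_bins
  counts <- rep(base, n_bins) + c(rep(1, extra), rep(0, n_bins - extra))
  stops <- cumsum(counts)
  starts <- c(1, utils::head(stops, -1) + 1)
  data.frame(bin = seq_len(n_bins),
             lo = ord$mpe_before[starts],
             hi = ord$mpe_before[stops],
             median_after = vapply(seq_len(n_bins), function(b)
               stats::median(ord$mpe_after[starts[b]:stops[b]]), 0),
             count = counts)
}

#' Divergence point of a capture-range histogram
#'
#' The capture range ends where registration stops succeeding: the left edge
#' of the first bin whose median post-registration error exceeds
#' \code{success_level} with every later bin exceeding it too. A transient
#' spike followed by recovery is not a divergence. Returns \code{Inf} when no
#' bin diverges.
#'
#' @param histogram data.frame from \code{\link{capture_range_histogram}}.
#' @param success_level error threshold defining success.
#' @return Scalar in \code{mpe_before} units (a bin left edge, or \code{Inf}).
#' @export
divergence_point <- function(histogram, success_level) {
  above <- histogram$median_after > success_level
  if (!any(above)) return(Inf)
  tail_all_above <- rev(cumprod(rev(above))) > 0
  if (!tail_all_above[length(tail_all_above)]) return(Inf)
  histogram$lo[which(tail_all_above)[1]]
}

# ---- reader-study tallying -------------------------------------------------

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Zeros are dropped; ties receive average ranks. The null distribution of
#' the positive-rank sum is computed exactly by dynamic programming over the
#' (possibly tied, hence half-integer) ranks, which stays exact for n up to
#' 25; beyond that a normal approximation with tie correction is used.
#'
#' @param x numeric vector of paired differences.
#' @return list with \code{statistic} (positive-rank sum), \code{n_nonzero}
#'   and \code{p_value} (two-sided).
#' @export
signed_rank_test <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) return(list(statistic = NA_real_, n_nonzero = 0L, p_value = 1))
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= 25L) {
    d <- as.integer(round(2 * r))            # doubled ranks are integers
    total <- sum(d)
    pmf <- numeric(total + 1)                # index i -> doubled sum i - 1
    pmf[1] <- 1
    for (di in d) {
      shifted <- c(rep(0, di), pmf[seq_len(total + 1 - di)])
      pmf <- (pmf + shifted) / 2
    }
    wd <- round(2 * w)
    p_le <- sum(pmf[seq_len(wd + 1)])
    p_ge <- sum(pmf[(wd + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum((table(r)^3 - table(r)) / 48)
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, n_nonzero = n, p_value = p)
}

#' Tally blinded two-way reader preferences
#'
#' Each record scores one left/right comparison on a 5-point scale: 1-2
#' count as a preference for the left method, 4-5 for the right, 3 as a tie.
#' Preferences are totaled per method; for every ordered method pair a
#' two-sided signed-rank test on the centered scores (score - 3) asks whether
#' the reader systematically favored one side.
#'
#' @param records data.frame with columns \code{left_method},
#'   \code{right_method} (labels) and \code{score} (integers 1-5).
#' @param methods optional character vector of the known method labels; an
#'   unknown label in the records raises an error.
#' @return list with \code{preferred} (named counts per method), \code{ties},
#'   \code{n_comparisons}, and \code{tests}: a data.frame per method pair
#'   with the signed-rank statistic and p-value (positive scores favor the
#'   right method).
#' @export
tally_preferences <- function(records, methods = NULL) {
  stopifnot(is.data.frame(records),
            all(c("left_method", "right_method", "score") %in% names(records)))
  if (!all(records$score %in% 1:5))
    stop("scores must be integers in 1..5")
  labels <- unique(c(records$left_method, records$right_method))
  if (!is.null(methods)) {
    bad <- setdiff(labels, methods)
    if (length(bad)) stop("unknown method label(s): ", paste(bad, collapse = ", "))
    labels <- methods
  }
  preferred <- stats::setNames(numeric(length(labels)), labels)
  ties <- 0L
  for (i in seq_len(nrow(records))) {
    s <- records$score[i]
    if (s <= 2) preferred[records$left_method[i]] <- preferred[records$left_method[i]] + 1
    else if (s >= 4) preferred[records$right_method[i]] <- preferred[records$right_method[i]] + 1
    else ties <- ties + 1L
  }
  pairs <- unique(records[, c("left_method", "right_method")])
  tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    sel <- records$left_method == pairs$left_method[k] &
           records$right_method == pairs$right_method[k]
    tst <- signed_rank_test(records$score[sel] - 3)
    data.frame(left_method = pairs$left_method[k],
               right_method = pairs$right_method[k],
               n = sum(sel), statistic = tst$statistic, p_value = tst$p_value)
  }))
  list(preferred = preferred, ties = ties, n_comparisons = nrow(records),
       tests = tests)
}
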