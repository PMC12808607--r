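#' Sliding-window dynamic functional connectivity
#'
#' Computes a Fisher z connectivity matrix in a rectangular window of
#' `window_length_s` shifted by `step_samples`. The adopted window-count
#' convention is `n_windows = floor((n_t - W) / step)` for step >= 1 — an
#' 80-minute run at TR = 1 s with a 300-s window stepped by one TR yields
#' exactly 4500 windows (the final sample is never a window start);
#' `n_t == W` is an error.
#'
#' @param signal `n_roi` x `n_t` matrix.
#' @param window_length_s window length in seconds (default 300).
#' @param step_samples step between window starts, in samples (default 1).
#' @param tr_s sampling interval in seconds.
#' @return object of class `dfc_stack`: list with `z` (array
#'   `n_roi` x `n_roi` x `n_windows`, `NA` diagonal),
#'   `window_start_times_s`, `window_length_s`, `step_samples`, `tr_s`.
#' @export
sliding_window_dfc <- function(signal, window_length_s = 300,
                               step_samples = 1, tr_s = 1) {
  n_t <- ncol(signal)
  W <- as.integer(round(window_length_s / tr_s))
  if (W < 4) stop("window too short")
  if (n_t <= W) stop("series must be longer than the window (n_t > W)")
  starts <- seq(1L, n_t - W, by = step_samples)
  n_roi <- nrow(signal)
  z <- array(NA_real_, dim = c(n_roi, n_roi, length(starts)))
  for (w in seq_along(starts)) {
    sl <- signal[, starts[w]:(starts[w] + W - 1L), drop = FALSE]
    r <- suppressWarnings(stats::cor(t(sl)))
    r[abs(r) >= 1 - 1e-7] <- sign(r[abs(r) >= 1 - 1e-7]) * (1 - 1e-7)
    zz <- atanh(r)
    diag(zz) <- NA_real_
    z[, , w] <- zz
  }
  structure(list(z = z, window_start_times_s = (starts - 1L) * tr_s,
                 window_length_s = window_length_s,
                 step_samples = step_samples, tr_s = tr_s,
                 roi_labels = rownames(signal)),
            class = "dfc_stack")
}

#' Apply a function to each sliding window without storing the stack
#'
#' Streaming companion to [sliding_window_dfc()] for large ROI counts: the
#' full window stack is never materialized.
#'
#' @inheritParams sliding_window_dfc
#' @param fun function of a z-space matrix (NA diagonal), called per window.
#' @return list of `fun` results, one per window, with attribute
#'   `window_start_times_s`.
#' @export
dfc_apply <- function(signal, fun, window_length_s = 300, step_samples = 1,
                      tr_s = 1) {
  n_t <- ncol(signal)
  W <- as.integer(round(window_length_s / tr_s))
  if (n_t <= W) stop("series must be longer than the window (n_t > W)")
  starts <- seq(1L, n_t - W, by = step_samples)
  out <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    sl <- signal[, starts[w]:(starts[w] + W - 1L), drop = FALSE]
    r <- suppressWarnings(stats::cor(t(sl)))
    r[abs(r) >= 1 - 1e-7] <- sign(r[abs(r) >= 1 - 1e-7]) * (1 - 1e-7)
    zz <- atanh(r)
    diag(zz) <- NA_real_
    out[[w]] <- fun(zz)
  }
  attr(out, "window_start_times_s") <- (starts - 1L) * tr_s
  out
}

#' Per-ROI global connectivity time course
#'
#' Global FC of ROI `r` in window `w` is the sum of its Fisher z
#' connectivity with all other ROIs in that window's matrix — a whole-brain
#' coupling-strength index. `NaN` edges are excluded with a warning count.
#'
#' @param stack a `dfc_stack`.
#' @return matrix `n_roi` x `n_windows` with attribute
#'   `window_start_times_s`.
#' @export
global_fc <- function(stack) {
  z <- stack$z
  n_bad <- sum(is.nan(z))
  if (n_bad > 0) warning(n_bad, " NaN edge value(s) excluded from global FC")
  out <- apply(z, 3, function(m) rowSums(m, na.rm = TRUE))
  out <- matrix(out, nrow = dim(z)[1])
  rownames(out) <- stack$roi_labels
  attr(out, "window_start_times_s") <- stack$window_start_times_s
  out
}

#' Group global-FC time courses
#'
#' Streams the sliding-window analysis per animal and returns per-animal
#' global-FC matrices plus the group mean and SEM per ROI and window.
#'
#' @param tsset a [roi_ts_set()].
#' @inheritParams sliding_window_dfc
#' @return list with `per_animal` (named list of `n_roi` x `n_windows`
#'   matrices), `mean`, `sem`, `window_start_times_s`.
#' @export
global_fc_series <- function(tsset, window_length_s = 300, step_samples = 1) {
  per <- lapply(tsset$animals, function(a) {
    res <- dfc_apply(a$signal, function(z) rowSums(z, na.rm = TRUE),
                     window_length_s = window_length_s,
                     step_samples = step_samples, tr_s = tsset$tr_s)
    m <- do.call(cbind, res)
    rownames(m) <- tsset$roi_labels
    attr(m, "window_start_times_s") <- attr(res, "window_start_times_s")
    m
  })
  gs <- group_mean_sem(lapply(per, function(m) unclass(m)))
  list(per_animal = per, mean = gs$mean, sem = gs$sem,
       window_start_times_s = attr(per[[1]], "window_start_times_s"))
}

#' Time course of a single edge
#'
#' Interval mode returns the Fisher z connectivity of the edge in each
#' consecutive interval (8 points per animal under the default 20/30/30-min
#' design); windowed mode returns the sliding-window z trace.
#'
#' @param tsset a [roi_ts_set()].
#' @param segmentation a [segment_conditions()] result (interval mode).
#' @param edge length-2 vector of ROI labels or indices.
#' @param mode `"interval"` or `"windowed"`.
#' @inheritParams sliding_window_dfc
#' @return list with `per_animal` (matrix animals x points), `mean`, `sem`,
#'   `times_s`, `genotype` (per animal).
#' @export
edge_timecourse <- function(tsset, segmentation, edge,
                            mode = c("interval", "windowed"),
                            window_length_s = 300, step_samples = 1) {
  mode <- match.arg(mode)
  idx <- edge
  if (is.character(edge)) {
    idx <- match(edge, tsset$roi_labels)
    if (any(is.na(idx))) stop("unknown ROI label(s): ",
                              paste(edge[is.na(idx)], collapse = ", "))
  }
  stopifnot(length(idx) == 2, all(idx >= 1), all(idx <= length(tsset$roi_labels)))
  if (mode == "interval") {
    fcints <- interval_fc_matrices(tsset, segmentation)
    per <- t(vapply(fcints, function(zl)
      vapply(zl, function(z) unclass(z)[idx[1], idx[2]], numeric(1)),
      numeric(nrow(segmentation))))
    colnames(per) <- segmentation$label
    times <- segmentation$start_s + attr(segmentation, "interval_length_s") / 2
  } else {
    times <- NULL
    traces <- lapply(tsset$animals, function(a) {
      res <- dfc_apply(a$signal, function(z) z[idx[1], idx[2]],
                       window_length_s = window_length_s,
                       step_samples = step_samples, tr_s = tsset$tr_s)
      times <<- attr(res, "window_start_times_s")
      unlist(res)
    })
    per <- do.call(rbind, traces)
  }
  gs <- group_mean_sem(lapply(seq_len(nrow(per)), function(i) per[i, ]))
  list(per_animal = per, mean = gs$mean, sem = gs$sem, times_s = times,
       genotype = vapply(tsset$animals, `[[`, "", "genotype"))
}
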