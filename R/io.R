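#' ROI time-series set
#'
#' The pipeline's central data container: one signal matrix per animal
#' (rows = ROIs, columns = samples) together with shared ROI labels,
#' sampling interval and injection timing.
#'
#' @param animals named list of animal records, each a list with `id`,
#'   `genotype` (`"WT"` or `"KO"`), `signal` (`n_roi` x `n_t` matrix) and
#'   optionally `nuisance` (`n_reg` x `n_t` matrix).
#' @param roi_labels character vector of length `n_roi`.
#' @param tr_s sampling interval (seconds).
#' @param duration_s run duration; must equal `n_t * tr_s`.
#' @param vehicle_onset_s,drug_onset_s injection times (seconds).
#' @return object of class `roi_ts_set`.
#' @export
roi_ts_set <- function(animals, roi_labels, tr_s, duration_s,
                       vehicle_onset_s, drug_onset_s) {
  stopifnot(length(animals) >= 1)
  n_roi <- length(roi_labels)
  n_t <- ncol(animals[[1]]$signal)
  for (a in animals) {
    stopifnot(is.matrix(a$signal), nrow(a$signal) == n_roi,
              ncol(a$signal) == n_t, a$genotype %in% c("WT", "KO"))
  }
  if (abs(n_t * tr_s - duration_s) > 1e-9)
    stop("n_t * tr_s must equal duration_s")
  if (is.null(names(animals)))
    names(animals) <- vapply(animals, `[[`, "", "id")
  structure(list(animals = animals, roi_labels = roi_labels, tr_s = tr_s,
                 duration_s = duration_s, vehicle_onset_s = vehicle_onset_s,
                 drug_onset_s = drug_onset_s),
            class = "roi_ts_set")
}

#' @export
print.roi_ts_set <- function(x, ...) {
  gt <- table(vapply(x$animals, `[[`, "", "genotype"))
  cat("roi_ts_set:", length(x$animals), "animals (",
      paste(names(gt), gt, collapse = ", "), "),",
      length(x$roi_labels), "ROIs x", ncol(x$animals[[1]]$signal),
      "samples at TR", x$tr_s, "s\n")
  cat("  vehicle at", x$vehicle_onset_s, "s, drug at", x$drug_onset_s, "s\n")
  invisible(x)
}

#' Subset a cohort by genotype
#' @param tsset a [roi_ts_set()].
#' @param genotype `"WT"` or `"KO"`.
#' @return a [roi_ts_set()] containing only that genotype's animals.
#' @export
subset_genotype <- function(tsset, genotype) {
  keep <- vapply(tsset$animals, function(a) a$genotype == genotype, logical(1))
  if (!any(keep)) stop("no animals of genotype ", genotype)
  out <- tsset
  out$animals <- tsset$animals[keep]
  out
}

#' Read an exported cohort back from disk
#'
#' Reads a directory written by [export_cohort()] (either format, as
#' recorded in the JSON sidecar) into a [roi_ts_set()].
#'
#' @param path directory containing `cohort.json`.
#' @return a [roi_ts_set()].
#' @export
read_cohort <- function(path) {
  sidecar <- file.path(path, "cohort.json")
  if (!file.exists(sidecar)) stop("no cohort.json sidecar in ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  roi_labels <- meta$roi_labels
  atlas <- if (identical(meta$format, "volume"))
    RNifti::readNifti(file.path(path, meta$atlas_file)) else NULL
  recs <- meta$animals
  if (is.data.frame(recs)) recs <- split(recs, seq_len(nrow(recs)))
  animals <- lapply(recs, function(a) {
    if (identical(meta$format, "table")) {
      tab <- utils::read.delim(file.path(path, a$file), check.names = FALSE)
      sig <- t(as.matrix(tab))
    } else {
      vol <- RNifti::readNifti(file.path(path, a$file))
      sig <- extract_roi_timeseries(vol, atlas)
    }
    rownames(sig) <- NULL
    nuis <- NULL
    nf <- a$nuisance_file
    if (!is.null(nf) && length(nf) == 1 && !is.na(nf) && nzchar(nf))
      nuis <- t(as.matrix(utils::read.delim(file.path(path, nf),
                                            check.names = FALSE)))
    list(id = a$id, genotype = a$genotype, signal = unname(sig),
         nuisance = if (is.null(nuis)) NULL else unname(nuis))
  })
  names(animals) <- vapply(animals, `[[`, "", "id")
  roi_ts_set(animals, roi_labels = roi_labels, tr_s = meta$tr_s,
             duration_s = meta$duration_s,
             vehicle_onset_s = meta$vehicle_onset_s,
             drug_onset_s = meta$drug_onset_s)
}

#' Extract mean ROI time series from a labeled 4D volume
#'
#' Row `r` of the result is the spatial mean, at each time point, over
#' voxels carrying the `r`-th smallest positive label in the atlas.
#'
#' @param volume_4d 4D array (x, y, z, t) or NIfTI image.
#' @param label_atlas 3D integer-valued array or NIfTI image on the same
#'   spatial grid; 0 = background.
#' @return `n_roi` x `n_t` matrix with rownames = label values.
#' @export
extract_roi_timeseries <- function(volume_4d, label_atlas) {
  vol <- unclass(as.array(volume_4d))
  atl <- unclass(as.array(label_atlas))
  if (length(dim(atl)) == 2) dim(atl) <- c(dim(atl), 1L)
  dv <- dim(vol)
  if (length(dv) != 4) stop("volume must be 4-dimensional (x, y, z, t)")
  if (!all(dv[1:3] == dim(atl)))
    stop("volume and atlas spatial grids differ")
  if (max(abs(atl - round(atl))) > 1e-6)
    stop("label atlas must be integer-valued")
  atl <- as.integer(round(atl))
  labels <- sort(unique(atl[atl > 0]))
  if (!length(labels)) stop("atlas contains no positive labels")
  n_t <- dv[4]
  vmat <- matrix(vol, nrow = prod(dv[1:3]), ncol = n_t)
  out <- matrix(NA_real_, length(labels), n_t)
  for (k in seq_along(labels)) {
    idx <- which(atl == labels[k])
    out[k, ] <- if (length(idx) == 1) vmat[idx, ] else colMeans(vmat[idx, , drop = FALSE])
  }
  rownames(out) <- labels
  out
}

#' Temporal preprocessing of a cohort
#'
#' Applies, per ROI and in this order: polynomial detrending, least-squares
#' regression of nuisance series, and zero-phase band-pass filtering
#' (forward-backward 4th-order Butterworth) in the stated band. Detrending
#' and nuisance regression are carried out as a single least-squares
#' projection so the nuisance fit is not confounded by drift.
#'
#' @param tsset a [roi_ts_set()].
#' @param nuisance `"stored"` to use each animal's own nuisance matrix (if
#'   any), `NULL` for none, or a list of `n_reg` x `n_t` matrices named by
#'   animal id.
#' @param band numeric length-2 band-pass edges in Hz (default
#'   `c(0.008, 0.1)`); `NULL` skips filtering.
#' @param detrend_order polynomial detrend order (default 1, linear).
#' @return the preprocessed [roi_ts_set()] (each series ~zero mean).
#' @export
preprocess <- function(tsset, nuisance = "stored", band = c(0.008, 0.1),
                       detrend_order = 1) {
  n_t <- ncol(tsset$animals[[1]]$signal)
  fs <- 1 / tsset$tr_s
  if (!is.null(band)) {
    if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
      stop("band must lie strictly inside (0, Nyquist)")
    bf <- signal::butter(2, band / (fs / 2), type = "pass")
  }
  tbasis <- cbind(1, stats::poly(seq_len(n_t), degree = max(detrend_order, 0)))
  out <- tsset
  for (nm in names(tsset$animals)) {
    a <- tsset$animals[[nm]]
    nuis <- NULL
    if (identical(nuisance, "stored")) nuis <- a$nuisance
    else if (is.list(nuisance)) nuis <- nuisance[[nm]]
    X <- tbasis
    if (!is.null(nuis)) {
      if (!all(is.finite(nuis))) stop("nuisance regressors must be finite")
      X <- cbind(X, scale(t(nuis)))
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      warning("dropping ", ncol(X) - qrX$rank,
              " collinear nuisance column(s) for animal ", nm)
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
      qrX <- qr(X)
    }
    res <- t(qr.resid(qrX, t(a$signal)))
    if (!is.null(band))
      res <- t(apply(res, 1, function(x) signal::filtfilt(bf, x)))
    if (!all(is.finite(res)))
      stop("non-finite values after preprocessing for animal ", nm)
    out$animals[[nm]]$signal <- res
  }
  attr(out, "preprocessed") <- TRUE
  out
}

#' Segment a run into consecutive condition intervals
#'
#' Splits the run into `baseline` (start to vehicle onset), `vehicle`
#' (vehicle to drug onset) and `drug` (drug onset to end) conditions, each
#' divided into consecutive intervals of `interval_length_s`. Under the
#' default 20/30/30-minute design with 10-minute intervals this yields
#' 2 baseline + 3 vehicle + 3 drug intervals. Sample ranges are half-open:
#' the sample acquired at an injection time belongs to the post-injection
#' interval.
#'
#' @param tsset a [roi_ts_set()] (or any list with `tr_s`, `duration_s`,
#'   `vehicle_onset_s`, `drug_onset_s`).
#' @param interval_length_s interval length in seconds (default 600).
#' @return object of class `condition_segmentation`: a data frame with
#'   columns `condition`, `interval` (index within condition), `label`
#'   (e.g. `"drug1"`), `start_s`, and 1-based sample indices
#'   `start_sample`..`end_sample` (inclusive).
#' @export
segment_conditions <- function(tsset, interval_length_s = 600) {
  spans <- c(baseline = tsset$vehicle_onset_s,
             vehicle = tsset$drug_onset_s - tsset$vehicle_onset_s,
             drug = tsset$duration_s - tsset$drug_onset_s)
  if (any(spans <= 0)) stop("condition spans must be positive")
  k <- spans / interval_length_s
  if (any(abs(k - round(k)) > 1e-9))
    stop("condition spans (", paste(spans, collapse = ", "),
         " s) are not divisible by interval_length_s = ", interval_length_s)
  k <- stats::setNames(as.integer(round(k)), names(spans))
  w <- as.integer(round(interval_length_s / tsset$tr_s))
  rows <- list()
  start <- 0
  for (cdn in names(spans)) {
    for (i in seq_len(k[[cdn]])) {
      s0 <- as.integer(round(start / tsset$tr_s))
      rows[[length(rows) + 1]] <- data.frame(
        condition = cdn, interval = i, label = paste0(cdn, i),
        start_s = start, start_sample = s0 + 1L, end_sample = s0 + w)
      start <- start + interval_length_s
    }
  }
  seg <- do.call(rbind, rows)
  attr(seg, "interval_length_s") <- interval_length_s
  attr(seg, "tr_s") <- tsset$tr_s
  class(seg) <- c("condition_segmentation", "data.frame")
  seg
}

#' Samples of one or more segmentation intervals
#' @param segmentation a [segment_conditions()] result.
#' @param labels interval labels (e.g. `"drug1"`).
#' @return integer vector of 1-based sample indices.
#' @export
interval_samples <- function(segmentation, labels) {
  rows <- segmentation[segmentation$label %in% labels, , drop = FALSE]
  if (nrow(rows) != length(labels)) stop("unknown interval label(s)")
  unlist(lapply(seq_len(nrow(rows)),
                function(r) seq(rows$start_sample[r], rows$end_sample[r])))
}

#' Samples belonging to a condition
#' @param segmentation a [segment_conditions()] result.
#' @param condition `"baseline"`, `"vehicle"` or `"drug"`.
#' @return integer vector of 1-based sample indices.
#' @export
condition_samples <- function(segmentation, condition) {
  rows <- segmentation[segmentation$condition == condition, , drop = FALSE]
  if (!nrow(rows)) stop("no intervals for condition ", condition)
  unlist(lapply(seq_len(nrow(rows)),
                function(r) seq(rows$start_sample[r], rows$end_sample[r])))
}
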