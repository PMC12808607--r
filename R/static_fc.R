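#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlation between ROI time series over an interval.
#'
#' @param signal `n_roi` x `n_t` matrix (an interval slice).
#' @param roi_labels optional dimnames.
#' @param provenance optional list (animal, condition, interval) attached as
#'   an attribute.
#' @return symmetric correlation matrix of class `fc_matrix` with attribute
#'   `space = "r"` and unit diagonal. Constant ROIs yield `NaN` entries with
#'   a warning.
#' @export
fc_matrix <- function(signal, roi_labels = NULL, provenance = NULL) {
  if (ncol(signal) < 4) stop("interval must contain at least 4 samples")
  sds <- apply(signal, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(t(signal)))
  if (any(const)) {
    warning(sum(const), " constant ROI(s); correlations set to NaN")
    r[const, ] <- NaN; r[, const] <- NaN
  }
  diag(r) <- 1
  if (!is.null(roi_labels)) dimnames(r) <- list(roi_labels, roi_labels)
  structure(r, class = c("fc_matrix", "matrix"), space = "r",
            provenance = provenance)
}

#' Fisher z transformation of an FC matrix
#'
#' Applies `atanh` elementwise off the diagonal; the diagonal is excluded
#' (set to `NA`). Correlations with `|r| >= 1 - 1e-7` are clamped to
#' `+/-(1 - 1e-7)` before the transform, with a warning.
#'
#' @param fc an r-space `fc_matrix`.
#' @return z-space `fc_matrix` (attribute `space = "z"`, `NA` diagonal).
#' @export
fisher_z <- function(fc) {
  if (!identical(attr(fc, "space"), "r")) stop("input must be in r space")
  r <- unclass(fc)
  clamp <- abs(r) >= 1 - 1e-7
  diag(clamp) <- FALSE
  if (any(clamp, na.rm = TRUE)) {
    warning(sum(clamp, na.rm = TRUE), " correlation(s) clamped before atanh")
    r[clamp] <- sign(r[clamp]) * (1 - 1e-7)
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  structure(z, class = c("fc_matrix", "matrix"), space = "z",
            provenance = attr(fc, "provenance"))
}

#' Inverse Fisher transformation
#' @param fc a z-space `fc_matrix`.
#' @return r-space `fc_matrix` with unit diagonal.
#' @export
inverse_fisher_z <- function(fc) {
  if (!identical(attr(fc, "space"), "z")) stop("input must be in z space")
  r <- tanh(unclass(fc))
  diag(r) <- 1
  structure(r, class = c("fc_matrix", "matrix"), space = "r",
            provenance = attr(fc, "provenance"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("fc_matrix (", attr(x, "space"), "space ):", nrow(x), "x", ncol(x), "\n")
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))])
  invisible(x)
}

#' Interval-wise z-space FC matrices for every animal
#'
#' @param tsset a [roi_ts_set()].
#' @param segmentation a [segment_conditions()] result.
#' @return named list (by animal id) of named lists (by interval label,
#'   e.g. `"drug1"`) of z-space `fc_matrix` objects.
#' @export
interval_fc_matrices <- function(tsset, segmentation) {
  lapply(tsset$animals, function(a) {
    out <- lapply(seq_len(nrow(segmentation)), function(r) {
      idx <- seq(segmentation$start_sample[r], segmentation$end_sample[r])
      fisher_z(fc_matrix(a$signal[, idx, drop = FALSE],
                         roi_labels = tsset$roi_labels,
                         provenance = list(animal = a$id,
                                           condition = segmentation$condition[r],
                                           interval = segmentation$interval[r])))
    })
    names(out) <- segmentation$label
    out
  })
}

#' Difference between consecutive interval FC matrices
#'
#' Elementwise `curr - prev` between two FC matrices in the same space,
#' quantifying interval-to-interval connectivity change.
#'
#' @param curr,prev `fc_matrix` objects in the same space.
#' @return plain difference matrix.
#' @export
interval_difference <- function(curr, prev) {
  if (!identical(attr(curr, "space"), attr(prev, "space")))
    stop("FC matrices are in different spaces")
  if (!all(dim(curr) == dim(prev))) stop("dimension mismatch")
  d <- unclass(curr) - unclass(prev)
  attr(d, "space") <- NULL
  attr(d, "provenance") <- NULL
  d
}

#' Mean FC matrix across animals/intervals
#'
#' Averages z-space matrices elementwise, excluding `NaN` edges pairwise;
#' warns with a count when any edge had missing values.
#'
#' @param fc_list list of z-space `fc_matrix` objects.
#' @return z-space `fc_matrix` of means.
#' @export
mean_fc <- function(fc_list) {
  stopifnot(length(fc_list) >= 1)
  arr <- simplify2array(lapply(fc_list, unclass))
  m <- apply(arr, c(1, 2), function(v) mean(v[is.finite(v)]))
  missing_off <- sum(!is.finite(arr)) - length(fc_list) * nrow(m)
  if (missing_off > 0)
    warning(missing_off, " non-finite off-diagonal value(s) excluded from mean")
  diag(m) <- NA_real_
  structure(m, class = c("fc_matrix", "matrix"), space = "z")
}

#' Genotype baseline contrast map
#'
#' Mean KO minus mean WT edgewise, on z-space baseline-interval matrices.
#'
#' @param wt,ko lists of z-space `fc_matrix` objects (animals x intervals,
#'   flattened).
#' @return difference matrix (KO - WT).
#' @export
genotype_baseline_contrast <- function(wt, ko) {
  if (!length(wt) || !length(ko)) stop("both genotype groups must be non-empty")
  unclass(mean_fc(ko)) - unclass(mean_fc(wt))
}

#' Per-animal FC variability within a condition
#'
#' Variability is the population variance (denominator N) of the pooled
#' off-diagonal upper-triangle Fisher z values over all of the condition's
#' interval matrices — one scalar per animal. This pooled-variance reading
#' of "FC variability" matches a per-animal scalar entering a two-sample
#' genotype comparison with df = n1 + n2 - 2.
#'
#' @param fc_by_interval one animal's named list of z-space matrices (an
#'   element of [interval_fc_matrices()]).
#' @param segmentation a [segment_conditions()] result.
#' @param condition `"baseline"`, `"vehicle"` or `"drug"`.
#' @return scalar variance.
#' @export
fc_variability <- function(fc_by_interval, segmentation, condition) {
  labs <- segmentation$label[segmentation$condition == condition]
  if (!length(labs)) stop("condition has no intervals")
  vals <- unlist(lapply(fc_by_interval[labs], function(z) {
    m <- unclass(z)
    m[upper.tri(m)]
  }))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("all edges are NaN")
  mean((vals - mean(vals))^2)
}

#' Cohort FC-variability summary and genotype comparison
#'
#' @param tsset a [roi_ts_set()].
#' @param segmentation a [segment_conditions()] result.
#' @return data frame with one row per animal x condition (`animal`,
#'   `genotype`, `condition`, `variability`), with an attribute `tests`: a
#'   data frame of per-condition two-sample t-tests (WT vs KO, pooled
#'   variance, df = n1 + n2 - 2).
#' @export
fc_variability_table <- function(tsset, segmentation) {
  fcints <- interval_fc_matrices(tsset, segmentation)
  conds <- unique(segmentation$condition)
  rows <- list()
  for (nm in names(fcints)) {
    g <- tsset$animals[[nm]]$genotype
    for (cd in conds)
      rows[[length(rows) + 1]] <- data.frame(
        animal = nm, genotype = g, condition = cd,
        variability = fc_variability(fcints[[nm]], segmentation, cd))
  }
  tab <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(conds, function(cd) {
    wt <- tab$variability[tab$condition == cd & tab$genotype == "WT"]
    ko <- tab$variability[tab$condition == cd & tab$genotype == "KO"]
    if (length(wt) < 2 || length(ko) < 2)
      return(data.frame(condition = cd, t = NA, df = NA, p = NA))
    tt <- stats::t.test(ko, wt, var.equal = TRUE)
    data.frame(condition = cd, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  attr(tab, "tests") <- tests
  tab
}

#' Group mean and SEM across a list of equally-shaped arrays
#'
#' SEM uses the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`.
#'
#' @param xs list of numeric vectors/matrices of identical shape.
#' @return list with elements `mean`, `sem`, `n`.
#' @export
group_mean_sem <- function(xs) {
  stopifnot(length(xs) >= 1)
  arr <- simplify2array(xs)
  nd <- length(dim(arr))
  if (nd == 1 || is.null(dim(arr))) {
    m <- mean(arr); s <- stats::sd(arr) / sqrt(length(arr))
    return(list(mean = m, sem = s, n = length(xs)))
  }
  margins <- seq_len(nd - 1)
  n <- length(xs)
  m <- apply(arr, margins, mean)
  s <- apply(arr, margins, stats::sd) / sqrt(n)
  list(mean = m, sem = s, n = n)
}
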