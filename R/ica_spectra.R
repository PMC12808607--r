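#' Symmetric FastICA by negentropy maximization
#'
#' Fixed-point FastICA with the logcosh contrast and symmetric
#' decorrelation, operating on pre-whitened data. Deterministic given the
#' seed (random orthonormal initialisation).
#'
#' @param Z whitened data, `n_comp` x `n_samples` (unit covariance rows).
#' @param seed integer seed for the initial unmixing matrix.
#' @param maxit,tol iteration cap and convergence tolerance on the change
#'   of the unmixing matrix.
#' @return list with `W` (orthogonal unmixing matrix, `n_comp` x `n_comp`),
#'   `converged`, `iterations`.
#' @keywords internal
fastica_core <- function(Z, seed = 1, maxit = 200, tol = 1e-5) {
  k <- nrow(Z); n <- ncol(Z)
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  sym_decor <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decor(W)
  it <- 0; conv <- FALSE
  while (it < maxit) {
    it <- it + 1
    S <- W %*% Z
    G <- tanh(S)
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { conv <- TRUE; break }
  }
  if (!conv) warning("FastICA did not converge in ", maxit, " iterations")
  list(W = W, converged = conv, iterations = it)
}

#' Group spatial ICA on temporally concatenated runs
#'
#' Animal runs are centered per ROI and concatenated in time; the ROI
#' dimension is whitened to `n_comp` principal dimensions and unmixed by
#' negentropy-maximizing FastICA. Each component consists of a spatial map
#' over the ROI features (column of the mixing matrix, unit-normalized,
#' sign fixed so the maximum-magnitude feature is positive) and per-animal
#' time courses obtained by back-projection (applying the unmixing to each
#' animal's run). Components are ranked by explained variance
#' (mixing-column energy).
#'
#' @param tsset a [roi_ts_set()] (all animals share the ROI grid).
#' @param n_comp number of components (default 20); reduced with a warning
#'   if it exceeds the data rank.
#' @param seed seed for the ICA initialisation (deterministic output).
#' @return object of class `component_set`: list with `spatial_maps`
#'   (`n_comp` x `n_roi`), `time_courses` (named list per animal,
#'   `n_comp` x `n_t`), `explained_variance` (per component, fraction of
#'   total), `n_comp`, `roi_labels`, `converged`.
#' @export
group_ica <- function(tsset, n_comp = 20, seed = 1) {
  X <- do.call(cbind, lapply(tsset$animals, function(a) {
    a$signal - rowMeans(a$signal)
  }))
  n_roi <- nrow(X); n_tot <- ncol(X)
  C <- tcrossprod(X) / n_tot
  e <- eigen(C, symmetric = TRUE)
  pos <- sum(e$values > max(e$values) * 1e-10)
  if (n_comp > pos) {
    warning("n_comp reduced from ", n_comp, " to data rank ", pos)
    n_comp <- pos
  }
  K <- diag(1 / sqrt(e$values[seq_len(n_comp)]), n_comp) %*%
       t(e$vectors[, seq_len(n_comp), drop = FALSE])
  Z <- K %*% X
  fit <- fastica_core(Z, seed = seed)
  S <- fit$W %*% Z                      # unit-variance sources
  A <- tcrossprod(X, S) / n_tot         # mixing: X ~ A %*% S
  energy <- colSums(A^2)
  ord <- order(energy, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; S <- S[ord, , drop = FALSE]
  energy <- energy[ord]
  # sign convention: max-|value| feature positive; maps unit-normalized
  flips <- vapply(seq_len(n_comp), function(kk) {
    s <- sign(A[which.max(abs(A[, kk])), kk])
    if (s == 0) 1 else s
  }, numeric(1))
  A <- sweep(A, 2, flips, `*`)
  S <- S * flips
  norms <- sqrt(colSums(A^2))
  maps <- t(A) / norms
  colnames(maps) <- tsset$roi_labels
  unmix <- (fit$W %*% K)[ord, , drop = FALSE] * flips
  tcs <- lapply(tsset$animals, function(a)
    unmix %*% (a$signal - rowMeans(a$signal)))
  total_var <- sum(e$values[seq_len(pos)])
  structure(list(spatial_maps = maps, time_courses = tcs,
                 explained_variance = energy / (total_var + (total_var == 0)),
                 n_comp = n_comp, roi_labels = tsset$roi_labels,
                 converged = fit$converged),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("component_set:", x$n_comp, "components over", length(x$roi_labels),
      "ROI features;", length(x$time_courses), "animal time courses\n")
  cat("  explained variance:",
      paste0(round(100 * x$explained_variance[seq_len(min(5, x$n_comp))], 1),
             "%", collapse = ", "),
      if (x$n_comp > 5) "..." else "", "\n")
  invisible(x)
}

#' Automatic component screening
#'
#' Replaces the visual identification of meaningful networks with two
#' stated criteria: a component is excluded if its time course correlates
#' more than `nuisance_r` in absolute value with any nuisance regressor, or
#' if its spatial map is dominated by a single feature (more than
#' `dominance` of the map energy).
#'
#' @param cs a [group_ica()] result.
#' @param nuisance named list (by animal id) of `n_reg` x `n_t` matrices,
#'   or `NULL`.
#' @param nuisance_r correlation threshold (default 0.6).
#' @param dominance single-feature energy threshold (default 0.5).
#' @return logical vector, `TRUE` = keep, with attribute `reason`.
#' @export
flag_components <- function(cs, nuisance = NULL, nuisance_r = 0.6,
                            dominance = 0.5) {
  keep <- rep(TRUE, cs$n_comp)
  reason <- rep("", cs$n_comp)
  dom <- apply(cs$spatial_maps^2, 1, max)
  keep[dom > dominance] <- FALSE
  reason[dom > dominance] <- "single-feature dominated"
  if (!is.null(nuisance)) {
    for (nm in names(cs$time_courses)) {
      nu <- nuisance[[nm]]
      if (is.null(nu)) next
      rc <- abs(stats::cor(t(cs$time_courses[[nm]]), t(nu)))
      hit <- apply(rc, 1, max) > nuisance_r
      reason[hit & keep] <- "nuisance-correlated"
      keep[hit] <- FALSE
    }
  }
  attr(keep, "reason") <- reason
  keep
}

#' Component time-course amplitude per condition
#'
#' Amplitude is the standard deviation of the component time course within
#' each condition's samples (RMS about zero available as an alternative).
#'
#' @param time_course numeric vector on the run's sample grid.
#' @param segmentation a [segment_conditions()] result.
#' @param method `"sd"` (default) or `"rms"`.
#' @return named numeric vector, one amplitude per condition.
#' @export
condition_amplitude <- function(time_course, segmentation,
                                method = c("sd", "rms")) {
  method <- match.arg(method)
  conds <- unique(segmentation$condition)
  vapply(conds, function(cd) {
    x <- time_course[condition_samples(segmentation, cd)]
    if (!length(x)) stop("empty condition ", cd)
    if (method == "sd") stats::sd(x) else sqrt(mean(x^2))
  }, numeric(1))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the series is split into
#' `segment_length_s` segments with fractional `overlap`, each segment is
#' mean-removed, tapered (Hann by default), and its one-sided periodogram
#' (signal^2 / Hz) accumulated. Series shorter than one segment fall back
#' to a single full-length segment with a warning.
#'
#' @param x numeric time series.
#' @param tr_s sampling interval (seconds).
#' @param segment_length_s Welch segment length (default 256 s, resolving
#'   ~0.004 Hz).
#' @param overlap fractional segment overlap (default 0.5).
#' @param taper `"hann"` or `"rectangular"`.
#' @return object of class `psd_estimate`: list with `freq_hz`, `power`,
#'   `band_powers` (slow-5/4/3 via [band_power()]), `segment_length_s`,
#'   `overlap`, `taper`, `n_segments`.
#' @export
welch_psd <- function(x, tr_s, segment_length_s = 256, overlap = 0.5,
                      taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  fs <- 1 / tr_s
  L <- as.integer(round(segment_length_s / tr_s))
  n <- length(x)
  if (n < L) {
    warning("series shorter than one Welch segment; using a single segment")
    L <- n
  }
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- if (taper == "hann")
    0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L)) else rep(1, L)
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (fs * U)
    half <- sp[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when L is even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    acc <- acc + half * dbl
  }
  power <- acc / length(starts)
  freq <- (seq_len(nf) - 1) * fs / L
  est <- structure(list(freq_hz = freq, power = power,
                        segment_length_s = L * tr_s, overlap = overlap,
                        taper = taper, n_segments = length(starts)),
                   class = "psd_estimate")
  est$band_powers <- vapply(slow_bands(), function(b) band_power(est, b),
                            numeric(1))
  est
}

#' Canonical slow BOLD frequency bands
#'
#' @return named list of `c(lo, hi)` Hz: slow-5 (0.01-0.027),
#'   slow-4 (0.027-0.073), slow-3 (0.073-0.1).
#' @export
slow_bands <- function() {
  list(slow5 = c(0.01, 0.027), slow4 = c(0.027, 0.073),
       slow3 = c(0.073, 0.1))
}

#' Band-integrated spectral power
#'
#' Trapezoidal integral of the PSD over a frequency band, with linear
#' interpolation at the band edges.
#'
#' @param psd a [welch_psd()] result.
#' @param band length-2 numeric `c(lo, hi)` in Hz, inside the PSD grid.
#' @return scalar power (signal^2).
#' @export
band_power <- function(psd, band) {
  f <- psd$freq_hz; p <- psd$power
  if (band[1] < min(f) - 1e-12 || band[2] > max(f) + 1e-12)
    stop("band outside the PSD frequency grid")
  inside <- f > band[1] & f < band[2]
  fe <- c(band[1], f[inside], band[2])
  pe <- c(stats::approx(f, p, xout = band[1])$y, p[inside],
          stats::approx(f, p, xout = band[2])$y)
  pracma::trapz(fe, pe)
}

#' Slow-band power statistics per genotype
#'
#' For a chosen component, estimates each animal's Welch PSD separately in
#' the vehicle and drug condition segments, integrates the slow-5/4/3
#' bands, and compares vehicle vs drug per genotype with a paired t-test
#' (df = n - 1).
#'
#' @param cs a [group_ica()] result.
#' @param component component index.
#' @param tsset the [roi_ts_set()] the ICA was fit on (for genotypes).
#' @param segmentation a [segment_conditions()] result.
#' @param segment_length_s Welch segment length (default 256 s).
#' @return list with `per_animal` (data frame: animal, genotype, band,
#'   vehicle, drug) and `tests` (data frame: genotype, band, t, df, p,
#'   mean_ratio).
#' @export
band_power_analysis <- function(cs, component, tsset, segmentation,
                                segment_length_s = 256) {
  rows <- list()
  for (nm in names(cs$time_courses)) {
    tc <- cs$time_courses[[nm]][component, ]
    for (cd in c("vehicle", "drug")) {
      psd <- welch_psd(tc[condition_samples(segmentation, cd)], tsset$tr_s,
                       segment_length_s = segment_length_s)
      for (b in names(psd$band_powers))
        rows[[length(rows) + 1]] <- data.frame(
          animal = nm, genotype = tsset$animals[[nm]]$genotype,
          band = b, condition = cd, power = psd$band_powers[[b]])
    }
  }
  long <- do.call(rbind, rows)
  per <- stats::reshape(long, idvar = c("animal", "genotype", "band"),
                        timevar = "condition", direction = "wide")
  names(per) <- sub("^power\\.", "", names(per))
  tests <- do.call(rbind, lapply(split(per, list(per$genotype, per$band)),
    function(d) {
      if (nrow(d) < 2) return(NULL)
      tt <- paired_t(d$drug - d$vehicle)
      data.frame(genotype = d$genotype[1], band = d$band[1],
                 t = tt$t, df = tt$df, p = tt$p,
                 mean_ratio = mean(d$drug) / mean(d$vehicle))
    }))
  rownames(tests) <- NULL
  list(per_animal = per, tests = tests)
}
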