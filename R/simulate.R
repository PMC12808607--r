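#' Simulation configuration for a pharmacological fMRI cohort
#'
#' Describes a two-genotype cohort of synthetic multi-ROI BOLD runs with a
#' mid-scan vehicle injection and a later drug injection. Baseline
#' connectivity follows a block-community structure; in the responder
#' genotype a configurable set of edges is transiently modulated after drug
#' onset with an exponential-rise / exponential-decay envelope (the decay
#' half-life defaults to 780 s, the circulating half-life of a fast-acting
#' satiation hormone such as amylin). Both genotypes additionally receive an
#' injection artifact after *both* injections: a brief (<= 120 s) global
#' amplitude transient plus a fixed set of spurious edge shifts lasting one
#' analysis interval. Band-limited oscillators emulate condition-dependent
#' slow-band (slow-5/4/3) power changes.
#'
#' Signals are built by mixing latent band-limited factors with time-varying
#' loadings, so the instantaneous target covariance is positive
#' semi-definite by construction and every ROI has unit signal variance
#' before drift, nuisance and measurement noise are added.
#'
#' @param n_animals_per_genotype animals per genotype (default 7).
#' @param n_roi number of regions (default 30).
#' @param tr_s repetition time in seconds (default 1).
#' @param duration_s run length in seconds (default 4800, i.e. 80 min).
#' @param vehicle_onset_s vehicle injection time (default 1200 s).
#' @param drug_onset_s drug injection time (default 3000 s).
#' @param block_sizes integer vector of community sizes summing to `n_roi`;
#'   default splits the ROIs into (nearly) equal blocks of ~6.
#' @param within_block_r,between_block_r baseline Pearson correlation within
#'   and between communities.
#' @param drug_effect_edges data frame with columns `i`, `j`, `delta`
#'   (signed correlation change at envelope peak), applied in the responder
#'   genotype only. `NULL` selects a default set of cross-block edges with
#'   `delta` +/-0.7 — an effect scale at which a paired t-test (df = 6) can
#'   clear an FDR threshold of 0.01 over all edges, as the original
#'   experimental design requires of any detectable effect.
#' @param drug_onset_tau_s exponential rise constant of the drug envelope.
#' @param drug_decay_halflife_s decay half-life of the drug envelope.
#' @param artifact_edges data frame (`i`, `j`, `delta`) of spurious edges
#'   perturbed for `artifact_duration_s` after *each* injection in *both*
#'   genotypes. `NULL` selects a default cross-block set; use
#'   `data.frame(i=integer(), j=integer(), delta=numeric())` for none.
#' @param artifact_duration_s duration of the spurious edge shifts (default
#'   600 s, one analysis interval).
#' @param artifact_global_amplitude,artifact_global_tau_s,artifact_global_maxdur_s
#'   amplitude, decay constant and hard cutoff of the multiplicative global
#'   transient following each injection.
#' @param oscillators data frame with columns `band` (slow5/slow4/slow3),
#'   `freq_hz`, `amplitude` (in signal SD units), `gain_wt_drug`,
#'   `gain_ko_drug` (multiplicative *power* gains applied during the drug
#'   condition). `NULL` gives one oscillator per band on the last community;
#'   an empty data frame disables oscillators.
#' @param noise_sd SD of white measurement noise added on top of the
#'   unit-variance physiological signal.
#' @param drift_amplitude SD of the per-ROI linear drift over the run.
#' @param drift_order polynomial order of the drift (default 1).
#' @param spike_rate_hz,spike_amplitude rate and amplitude of global
#'   motion-like spikes (default off).
#' @param nuisance_amplitude amplitude of two pseudo WM/CSF confound series
#'   added to every ROI (and returned per animal for nuisance regression).
#' @param lowpass_hz band limit of the latent physiological factors.
#' @param responder_genotype genotype carrying the drug effect ("WT").
#' @param seed root random seed; each animal derives a child stream from it,
#'   shared between genotypes so the cohorts are identical except for the
#'   genotype-conditional effects.
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [simulate_cohort()], [drug_envelope()]
#' @export
simulation_config <- function(n_animals_per_genotype = 7,
                              n_roi = 30,
                              tr_s = 1,
                              duration_s = 4800,
                              vehicle_onset_s = 1200,
                              drug_onset_s = 3000,
                              block_sizes = NULL,
                              within_block_r = 0.25,
                              between_block_r = 0.1,
                              drug_effect_edges = NULL,
                              drug_onset_tau_s = 60,
                              drug_decay_halflife_s = 780,
                              artifact_edges = NULL,
                              artifact_duration_s = 600,
                              artifact_global_amplitude = 0.5,
                              artifact_global_tau_s = 30,
                              artifact_global_maxdur_s = 120,
                              oscillators = NULL,
                              noise_sd = 0.2,
                              drift_amplitude = 0.5,
                              drift_order = 1,
                              spike_rate_hz = 0,
                              spike_amplitude = 0,
                              nuisance_amplitude = 0.3,
                              lowpass_hz = 0.1,
                              responder_genotype = "WT",
                              seed = 1) {
  if (is.null(block_sizes)) {
    n_block <- max(1L, round(n_roi / 6))
    block_sizes <- rep(n_roi %/% n_block, n_block)
    rem <- n_roi - sum(block_sizes)
    if (rem > 0) block_sizes[seq_len(rem)] <- block_sizes[seq_len(rem)] + 1L
  }
  block_of <- rep(seq_along(block_sizes), block_sizes)
  if (is.null(drug_effect_edges) || is.null(artifact_edges)) {
    reserve <- if (length(block_sizes) > 1) max(block_of) else 0L
    avail <- which(block_of != reserve)
    pairs <- .pick_cross_block_pairs(avail, block_of, 11L)
    n_drug <- min(8L, nrow(pairs))
    if (is.null(drug_effect_edges)) {
      deltas <- rep(c(0.7, 0.7, 0.7, -0.7), length.out = n_drug)
      drug_effect_edges <- data.frame(i = pairs$i[seq_len(n_drug)],
                                      j = pairs$j[seq_len(n_drug)],
                                      delta = deltas)
    }
    if (is.null(artifact_edges)) {
      left <- pairs[-seq_len(n_drug), , drop = FALSE]
      n_art <- min(3L, nrow(left))
      artifact_edges <- data.frame(i = left$i[seq_len(n_art)],
                                   j = left$j[seq_len(n_art)],
                                   delta = rep(0.7, n_art))
    }
  }
  if (is.null(oscillators)) {
    osc_rois <- which(block_of == max(block_of))
    oscillators <- data.frame(
      band = c("slow5", "slow4", "slow3"),
      freq_hz = c(0.018, 0.050, 0.085),
      amplitude = c(0.6, 0.4, 0.3),
      gain_wt_drug = c(2.5, 1, 1),
      gain_ko_drug = c(1, 1, 1)
    )
    attr(oscillators, "rois") <- osc_rois
  }
  cfg <- structure(list(
    n_animals_per_genotype = as.integer(n_animals_per_genotype),
    n_roi = as.integer(n_roi), tr_s = tr_s, duration_s = duration_s,
    vehicle_onset_s = vehicle_onset_s, drug_onset_s = drug_onset_s,
    block_sizes = as.integer(block_sizes), block_of = block_of,
    within_block_r = within_block_r, between_block_r = between_block_r,
    drug_effect_edges = drug_effect_edges,
    drug_onset_tau_s = drug_onset_tau_s,
    drug_decay_halflife_s = drug_decay_halflife_s,
    artifact_edges = artifact_edges,
    artifact_duration_s = artifact_duration_s,
    artifact_global_amplitude = artifact_global_amplitude,
    artifact_global_tau_s = artifact_global_tau_s,
    artifact_global_maxdur_s = artifact_global_maxdur_s,
    oscillators = oscillators,
    oscillator_rois = attr(oscillators, "rois") %||%
      which(block_of == max(block_of)),
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    drift_order = as.integer(drift_order),
    spike_rate_hz = spike_rate_hz, spike_amplitude = spike_amplitude,
    nuisance_amplitude = nuisance_amplitude, lowpass_hz = lowpass_hz,
    responder_genotype = responder_genotype, seed = as.integer(seed)
  ), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic greedy pairing of ROIs across distinct blocks
.pick_cross_block_pairs <- function(avail, block_of, n_pairs) {
  used <- logical(length(block_of))
  out_i <- integer(0); out_j <- integer(0)
  for (i in avail) {
    if (length(out_i) >= n_pairs) break
    if (used[i]) next
    for (j in avail[avail > i]) {
      if (!used[j] && block_of[j] != block_of[i]) {
        out_i <- c(out_i, i); out_j <- c(out_j, j)
        used[i] <- used[j] <- TRUE
        break
      }
    }
  }
  data.frame(i = out_i, j = out_j)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", 2L * x$n_animals_per_genotype, "animals (",
      x$n_animals_per_genotype, "per genotype ),", x$n_roi, "ROIs,",
      x$duration_s / x$tr_s, "samples at TR", x$tr_s, "s\n")
  cat("  injections: vehicle", x$vehicle_onset_s, "s, drug",
      x$drug_onset_s, "s; responder:", x$responder_genotype, "\n")
  cat("  drug edges:", nrow(x$drug_effect_edges),
      " artifact edges:", nrow(x$artifact_edges),
      " oscillators:", nrow(x$oscillators), "\n")
  invisible(x)
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_animals_per_genotype >= 1, cfg$n_roi >= 2, cfg$tr_s > 0,
            cfg$duration_s > 0)
  if (abs(cfg$duration_s / cfg$tr_s - round(cfg$duration_s / cfg$tr_s)) > 1e-9)
    stop("duration_s must be an integer multiple of tr_s")
  if (!(cfg$vehicle_onset_s > 0 && cfg$drug_onset_s > cfg$vehicle_onset_s &&
        cfg$drug_onset_s < cfg$duration_s))
    stop("onsets must satisfy 0 < vehicle_onset_s < drug_onset_s < duration_s")
  if (sum(cfg$block_sizes) != cfg$n_roi)
    stop("block_sizes must sum to n_roi")
  rng <- c(cfg$within_block_r, cfg$between_block_r)
  if (any(rng <= -1 | rng >= 1)) stop("correlations must lie in (-1, 1)")
  if (cfg$between_block_r > cfg$within_block_r)
    stop("between_block_r must not exceed within_block_r")
  if (cfg$between_block_r < 0)
    stop("the factor construction requires between_block_r >= 0")
  ed <- rbind(cfg$drug_effect_edges[c("i", "j")], cfg$artifact_edges[c("i", "j")])
  if (nrow(ed)) {
    if (any(ed$i < 1 | ed$j < 1 | ed$i > cfg$n_roi | ed$j > cfg$n_roi | ed$i == ed$j))
      stop("effect/artifact edges must index distinct ROIs within 1..n_roi")
    deltas <- abs(c(cfg$drug_effect_edges$delta, cfg$artifact_edges$delta))
    if (any(deltas >= 1)) stop("edge deltas must lie in (-1, 1)")
    load <- numeric(cfg$n_roi)
    for (k in seq_len(nrow(ed)))
      load[c(ed$i[k], ed$j[k])] <- load[c(ed$i[k], ed$j[k])] + deltas[k]
    if (any(1 - cfg$within_block_r - load < 0))
      stop("target covariance is not positive semi-definite: ",
           "per-ROI effect loadings exceed the available unique variance")
  }
  invisible(cfg)
}

#' Drug-response envelope
#'
#' Normalized exponential-rise / exponential-decay envelope describing the
#' transient pharmacological effect: zero before onset, rising with time
#' constant `tau_s`, decaying with half-life `halflife_s`, scaled so the
#' peak equals 1. The peak occurs at
#' `t* = -tau * log((log(2)/h) / (1/tau + log(2)/h))` after onset; well after
#' the peak the envelope halves every `halflife_s`.
#'
#' @param t_since_onset_s time since drug onset (vector, seconds); negative
#'   values give 0.
#' @param tau_s rise time constant (s).
#' @param halflife_s decay half-life (s).
#' @return envelope values in `[0, 1]`.
#' @export
drug_envelope <- function(t_since_onset_s, tau_s, halflife_s) {
  raw <- function(t) (1 - exp(-t / tau_s)) * 2^(-t / halflife_s)
  a <- (log(2) / halflife_s) / (1 / tau_s + log(2) / halflife_s)
  t_peak <- -tau_s * log(a)
  peak <- raw(t_peak)
  out <- numeric(length(t_since_onset_s))
  pos <- t_since_onset_s > 0
  out[pos] <- raw(t_since_onset_s[pos]) / peak
  out
}

#' Peak time of the drug-response envelope
#' @inheritParams drug_envelope
#' @return seconds after onset at which [drug_envelope()] attains 1.
#' @export
drug_envelope_peak_time <- function(tau_s, halflife_s) {
  a <- (log(2) / halflife_s) / (1 / tau_s + log(2) / halflife_s)
  -tau_s * log(a)
}

#' Analytic target correlation matrix at a given time
#'
#' The instantaneous correlation targeted by the generator's latent-factor
#' construction (block baseline plus drug-edge modulation and spurious
#' injection edges), excluding the oscillator, nuisance, drift and
#' measurement-noise contributions.
#'
#' @param config a [simulation_config()].
#' @param genotype "WT" or "KO" (drug edges apply to the responder only).
#' @param t_s time in seconds.
#' @return `n_roi` x `n_roi` correlation matrix.
#' @export
analytic_target_corr <- function(config, genotype, t_s) {
  n <- config$n_roi
  R <- matrix(config$between_block_r, n, n)
  same <- outer(config$block_of, config$block_of, "==")
  R[same] <- config$within_block_r
  diag(R) <- 1
  if (identical(genotype, config$responder_genotype) &&
      nrow(config$drug_effect_edges)) {
    env <- drug_envelope(t_s - config$drug_onset_s,
                         config$drug_onset_tau_s,
                         config$drug_decay_halflife_s)
    for (k in seq_len(nrow(config$drug_effect_edges))) {
      i <- config$drug_effect_edges$i[k]; j <- config$drug_effect_edges$j[k]
      d <- config$drug_effect_edges$delta[k] * env
      R[i, j] <- R[i, j] + d; R[j, i] <- R[i, j]
    }
  }
  art <- nrow(config$artifact_edges) > 0 && any(
    (t_s >= c(config$vehicle_onset_s, config$drug_onset_s)) &
    (t_s < c(config$vehicle_onset_s, config$drug_onset_s) + config$artifact_duration_s))
  if (art) {
    for (k in seq_len(nrow(config$artifact_edges))) {
      i <- config$artifact_edges$i[k]; j <- config$artifact_edges$j[k]
      R[i, j] <- R[i, j] + config$artifact_edges$delta[k]; R[j, i] <- R[i, j]
    }
  }
  R
}

# child RNG seed for animal k, shared between genotypes
.child_seed <- function(root, k) {
  as.integer((as.double(root %% 2147483647L) * 1009 + k * 9973) %% 2147483646) + 1L
}

.lowpass_rows <- function(m, cutoff_hz, fs) {
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  out <- t(apply(m, 1, function(x) signal::filtfilt(bf, x)))
  sds <- apply(out, 1, stats::sd)
  (out - rowMeans(out)) / sds
}

#' Simulate a two-genotype pharmacological fMRI cohort
#'
#' Generates one ROI x time BOLD-like matrix per animal (both genotypes),
#' with the connectivity and spectral structure described by the
#' configuration, and returns the ground truth needed to validate recovery.
#' The same root seed always yields bit-identical output; animal `k` of the
#' WT and KO cohorts share latent draws and differ only in the
#' genotype-conditional effects.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `tsset` (a [roi_ts_set()]) and `truth`
#'   (class `synthetic_ground_truth`: `modulated_edges`, `artifact_edges`,
#'   `band_gain_table`, `oscillator_rois`, `block_of`, `baseline_corr`).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  fs <- 1 / cfg$tr_s
  n_t <- as.integer(round(cfg$duration_s / cfg$tr_s))
  n <- cfg$n_roi
  tt <- (seq_len(n_t) - 1L) * cfg$tr_s
  n_block <- length(cfg$block_sizes)
  drug <- cfg$drug_effect_edges
  art <- cfg$artifact_edges
  n_drug <- nrow(drug); n_art <- nrow(art)
  osc <- cfg$oscillators; n_osc <- nrow(osc)

  a_g <- sqrt(cfg$between_block_r)
  a_w <- sqrt(cfg$within_block_r - cfg$between_block_r)

  env <- drug_envelope(tt - cfg$drug_onset_s, cfg$drug_onset_tau_s,
                       cfg$drug_decay_halflife_s)
  art_on <- (tt >= cfg$vehicle_onset_s & tt < cfg$vehicle_onset_s + cfg$artifact_duration_s) |
            (tt >= cfg$drug_onset_s & tt < cfg$drug_onset_s + cfg$artifact_duration_s)

  # multiplicative global transient after each injection (<= maxdur)
  gmod <- rep(1, n_t)
  for (on in c(cfg$vehicle_onset_s, cfg$drug_onset_s)) {
    d <- tt - on
    w <- d >= 0 & d < cfg$artifact_global_maxdur_s
    gmod[w] <- gmod[w] + cfg$artifact_global_amplitude * exp(-d[w] / cfg$artifact_global_tau_s)
  }

  cond <- condition_of_sample(tt, cfg$vehicle_onset_s, cfg$drug_onset_s)

  # per-ROI squared loading consumed by effect factors, per genotype
  effect_load2 <- function(genotype) {
    L2 <- matrix(0, n, n_t)
    if (identical(genotype, cfg$responder_genotype) && n_drug) {
      for (k in seq_len(n_drug)) {
        l2 <- abs(drug$delta[k]) * env
        L2[drug$i[k], ] <- L2[drug$i[k], ] + l2
        L2[drug$j[k], ] <- L2[drug$j[k], ] + l2
      }
    }
    if (n_art) {
      for (k in seq_len(n_art)) {
        l2 <- abs(art$delta[k]) * as.numeric(art_on)
        L2[art$i[k], ] <- L2[art$i[k], ] + l2
        L2[art$j[k], ] <- L2[art$j[k], ] + l2
      }
    }
    L2
  }
  L2_by_geno <- list(WT = effect_load2("WT"), KO = effect_load2("KO"))

  osc_gain <- function(genotype) {
    # power gain per oscillator per sample (1 outside the drug condition)
    g <- matrix(1, n_osc, n_t)
    if (n_osc) {
      gains <- if (identical(genotype, "WT")) osc$gain_wt_drug else osc$gain_ko_drug
      g[, cond == "drug"] <- gains
    }
    g
  }
  gain_by_geno <- list(WT = osc_gain("WT"), KO = osc_gain("KO"))

  animals <- list()
  for (k in seq_len(cfg$n_animals_per_genotype)) {
    set.seed(.child_seed(cfg$seed, k))
    n_fac <- 1L + n_block + n_drug + n_art + n
    fac <- .lowpass_rows(matrix(stats::rnorm(n_fac * n_t), n_fac, n_t),
                         cfg$lowpass_hz, fs)
    g_fac <- fac[1, ]
    b_fac <- fac[1 + seq_len(n_block), , drop = FALSE]
    d_fac <- fac[1 + n_block + seq_len(n_drug), , drop = FALSE]
    a_fac <- fac[1 + n_block + n_drug + seq_len(n_art), , drop = FALSE]
    u_fac <- fac[1 + n_block + n_drug + n_art + seq_len(n), , drop = FALSE]
    phases <- stats::runif(max(n_osc, 1), 0, 2 * pi)
    nuis <- NULL
    if (cfg$nuisance_amplitude > 0)
      nuis <- .lowpass_rows(matrix(stats::rnorm(2 * n_t), 2, n_t), cfg$lowpass_hz, fs)
    drift_coef <- matrix(stats::rnorm(n * cfg$drift_order), n, cfg$drift_order)
    n_spike <- if (cfg$spike_rate_hz > 0)
      stats::rpois(1, cfg$spike_rate_hz * cfg$duration_s) else 0L
    spike_at <- if (n_spike > 0) sample.int(n_t, n_spike) else integer(0)
    spike_sgn <- if (n_spike > 0) sample(c(-1, 1), n_spike, replace = TRUE) else numeric(0)
    noise <- matrix(stats::rnorm(n * n_t), n, n_t)

    for (geno in c("WT", "KO")) {
      x <- a_g * matrix(g_fac, n, n_t, byrow = TRUE) +
           a_w * b_fac[cfg$block_of, , drop = FALSE]
      is_resp <- identical(geno, cfg$responder_genotype)
      if (n_drug && is_resp) {
        for (e in seq_len(n_drug)) {
          l <- sqrt(abs(drug$delta[e]) * env)
          x[drug$i[e], ] <- x[drug$i[e], ] + l * d_fac[e, ]
          x[drug$j[e], ] <- x[drug$j[e], ] + sign(drug$delta[e]) * l * d_fac[e, ]
        }
      }
      if (n_art) {
        for (e in seq_len(n_art)) {
          l <- sqrt(abs(art$delta[e]) * as.numeric(art_on))
          x[art$i[e], ] <- x[art$i[e], ] + l * a_fac[e, ]
          x[art$j[e], ] <- x[art$j[e], ] + sign(art$delta[e]) * l * a_fac[e, ]
        }
      }
      u2 <- 1 - a_g^2 - a_w^2 - L2_by_geno[[geno]]
      x <- x + sqrt(pmax(u2, 0)) * u_fac
      if (n_osc) {
        gains <- gain_by_geno[[geno]]
        for (o in seq_len(n_osc)) {
          s <- osc$amplitude[o] * sqrt(gains[o, ]) *
               sin(2 * pi * osc$freq_hz[o] * tt + phases[o])
          x[cfg$oscillator_rois, ] <-
            x[cfg$oscillator_rois, , drop = FALSE] +
            matrix(s, length(cfg$oscillator_rois), n_t, byrow = TRUE)
        }
      }
      x <- x * matrix(gmod, n, n_t, byrow = TRUE)
      if (cfg$drift_amplitude > 0) {
        tpoly <- stats::poly(tt, cfg$drift_order, raw = FALSE)
        x <- x + cfg$drift_amplitude * sqrt(n_t) * (drift_coef %*% t(tpoly))
      }
      if (n_spike > 0)
        x[, spike_at] <- x[, spike_at] +
          cfg$spike_amplitude * matrix(spike_sgn, n, n_spike, byrow = TRUE)
      if (!is.null(nuis))
        x <- x + cfg$nuisance_amplitude *
          matrix(colSums(nuis), n, n_t, byrow = TRUE)
      x <- x + cfg$noise_sd * noise
      id <- sprintf("%s%02d", geno, k)
      animals[[id]] <- list(id = id, genotype = geno, signal = x,
                            nuisance = nuis)
    }
  }
  # stable order: all WT then all KO
  ord <- c(grep("^WT", names(animals)), grep("^KO", names(animals)))
  animals <- animals[ord]

  roi_labels <- sprintf("ROI%02d", seq_len(n))
  tsset <- roi_ts_set(animals, roi_labels = roi_labels, tr_s = cfg$tr_s,
                      duration_s = cfg$duration_s,
                      vehicle_onset_s = cfg$vehicle_onset_s,
                      drug_onset_s = cfg$drug_onset_s)

  band_gain <- do.call(rbind, lapply(c("WT", "KO"), function(g) {
    do.call(rbind, lapply(c("baseline", "vehicle", "drug"), function(cd) {
      if (n_osc == 0) return(NULL)
      gains <- if (cd == "drug") {
        if (g == "WT") osc$gain_wt_drug else osc$gain_ko_drug
      } else rep(1, n_osc)
      data.frame(genotype = g, condition = cd, band = osc$band, gain = gains)
    }))
  }))
  truth <- structure(list(
    modulated_edges = if (n_drug) data.frame(
      i = drug$i, j = drug$j, delta = drug$delta,
      onset_s = cfg$drug_onset_s, tau_s = cfg$drug_onset_tau_s,
      halflife_s = cfg$drug_decay_halflife_s,
      genotype = cfg$responder_genotype
    ) else data.frame(i = integer(), j = integer(), delta = numeric()),
    artifact_edges = art,
    band_gain_table = band_gain,
    oscillator_rois = cfg$oscillator_rois,
    block_of = cfg$block_of,
    baseline_corr = analytic_target_corr(cfg, "KO", 0),
    config = cfg
  ), class = "synthetic_ground_truth")
  list(tsset = tsset, truth = truth)
}

#' Condition label of each sample
#'
#' @param t_s vector of sample times (seconds).
#' @param vehicle_onset_s,drug_onset_s injection times (seconds).
#' @return character vector in `{baseline, vehicle, drug}`; the sample at an
#'   injection time belongs to the post-injection condition.
#' @export
condition_of_sample <- function(t_s, vehicle_onset_s, drug_onset_s) {
  ifelse(t_s < vehicle_onset_s, "baseline",
         ifelse(t_s < drug_onset_s, "vehicle", "drug"))
}

#' Export a cohort to disk
#'
#' Table format writes one delimited file per animal (rows = time, columns =
#' ROI, header = ROI labels), optional per-animal nuisance regressors, and a
#' JSON sidecar with timing, labels and genotypes. Volume format writes one
#' 4D NIfTI per animal plus a shared integer label atlas in which each ROI
#' occupies a distinct label; extraction with [extract_roi_timeseries()]
#' recovers the table within float tolerance.
#'
#' @param tsset a [roi_ts_set()].
#' @param path output directory (created if missing).
#' @param format `"table"` or `"volume"`.
#' @param sep field separator for table format (default tab).
#' @return invisibly, the sidecar path.
#' @export
export_cohort <- function(tsset, path, format = c("table", "volume"),
                          sep = "\t") {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(tr_s = tsset$tr_s, duration_s = tsset$duration_s,
               vehicle_onset_s = tsset$vehicle_onset_s,
               drug_onset_s = tsset$drug_onset_s,
               roi_labels = tsset$roi_labels, format = format,
               animals = lapply(tsset$animals, function(a) {
                 list(id = a$id, genotype = a$genotype,
                      file = paste0(a$id, if (format == "table") ".tsv" else ".nii"),
                      nuisance_file = if (!is.null(a$nuisance))
                        paste0(a$id, "_nuisance.tsv") else NULL)
               }))
  n_roi <- length(tsset$roi_labels)
  if (format == "volume") {
    atlas <- array(0L, dim = c(n_roi, 2L, 1L))
    atlas[, 1, 1] <- seq_len(n_roi); atlas[, 2, 1] <- seq_len(n_roi)
    RNifti::writeNifti(RNifti::asNifti(atlas), file.path(path, "atlas.nii"))
    meta$atlas_file <- "atlas.nii"
  }
  for (a in tsset$animals) {
    if (format == "table") {
      tab <- t(a$signal)
      colnames(tab) <- tsset$roi_labels
      utils::write.table(tab, file.path(path, paste0(a$id, ".tsv")),
                         sep = sep, row.names = FALSE, quote = FALSE)
    } else {
      n_t <- ncol(a$signal)
      vol <- array(0, dim = c(n_roi, 2L, 1L, n_t))
      vol[, 1, 1, ] <- a$signal; vol[, 2, 1, ] <- a$signal
      img <- RNifti::asNifti(vol)
      RNifti::pixdim(img) <- c(1, 1, 1, tsset$tr_s)
      RNifti::writeNifti(img, file.path(path, paste0(a$id, ".nii")))
    }
    if (!is.null(a$nuisance)) {
      nt <- t(a$nuisance)
      colnames(nt) <- paste0("nuis", seq_len(ncol(nt)))
      utils::write.table(nt, file.path(path, paste0(a$id, "_nuisance.tsv")),
                         sep = sep, row.names = FALSE, quote = FALSE)
    }
  }
  sidecar <- file.path(path, "cohort.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}
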