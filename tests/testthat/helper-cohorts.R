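# Shared fixtures, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.cohort_cache <- new.env(parent = emptyenv())

# Full default-design cohort (7 animals/genotype, 30 ROIs, 80 min).
default_sim <- function() {
  if (is.null(.cohort_cache$sim))
    .cohort_cache$sim <- simulate_cohort(simulation_config(seed = 42))
  .cohort_cache$sim
}

default_preprocessed <- function() {
  if (is.null(.cohort_cache$pp))
    .cohort_cache$pp <- preprocess(default_sim()$tsset)
  .cohort_cache$pp
}

default_segmentation <- function() {
  segment_conditions(default_preprocessed())
}

# Config with no effects and no confounds: stationary block structure only.
clean_null_config <- function(...) {
  args <- utils::modifyList(list(
    drug_effect_edges = data.frame(i = integer(), j = integer(),
                                   delta = numeric()),
    artifact_edges = data.frame(i = integer(), j = integer(),
                                delta = numeric()),
    artifact_global_amplitude = 0,
    oscillators = data.frame(band = character(), freq_hz = numeric(),
                             amplitude = numeric(), gain_wt_drug = numeric(),
                             gain_ko_drug = numeric()),
    noise_sd = 0, drift_amplitude = 0, nuisance_amplitude = 0),
    list(...))
  do.call(simulation_config, args)
}

# Minimal hand-built cohort container.
make_tsset <- function(signals, tr_s = 1, vehicle_onset_s = NULL,
                       drug_onset_s = NULL, genotypes = NULL,
                       nuisance = NULL) {
  n_t <- ncol(signals[[1]])
  if (is.null(vehicle_onset_s)) vehicle_onset_s <- floor(n_t / 4) * tr_s
  if (is.null(drug_onset_s)) drug_onset_s <- floor(n_t / 2) * tr_s
  if (is.null(genotypes)) genotypes <- rep("WT", length(signals))
  animals <- lapply(seq_along(signals), function(k) {
    list(id = sprintf("%s%02d", genotypes[k], k), genotype = genotypes[k],
         signal = signals[[k]],
         nuisance = if (is.null(nuisance)) NULL else nuisance[[k]])
  })
  names(animals) <- vapply(animals, `[[`, "", "id")
  roi_ts_set(animals, roi_labels = sprintf("R%02d", seq_len(nrow(signals[[1]]))),
             tr_s = tr_s, duration_s = n_t * tr_s,
             vehicle_onset_s = vehicle_onset_s, drug_onset_s = drug_onset_s)
}

# z-space fc_matrix from a plain matrix (for hand-built examples).
as_z_matrix <- function(m, labels = NULL) {
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  diag(m) <- NA_real_
  structure(m, class = c("fc_matrix", "matrix"), space = "z")
}

# Map truth edges to edge-table keys.
truth_edge_keys <- function(edges, roi_labels) {
  paste(roi_labels[pmin(edges$i, edges$j)],
        roi_labels[pmax(edges$i, edges$j)], sep = "~")
}

table_edge_keys <- function(tab) paste(tab$roi_i, tab$roi_j, sep = "~")
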