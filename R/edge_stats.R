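#' Edge list of an ROI set
#'
#' All unordered ROI pairs in column-major upper-triangle order — the
#' canonical edge ordering used throughout the package.
#'
#' @param roi_labels character vector.
#' @return data frame with columns `i`, `j` (indices, `i < j`), `roi_i`,
#'   `roi_j`.
#' @export
edge_index <- function(roi_labels) {
  n <- length(roi_labels)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = ut[, 1], j = ut[, 2],
             roi_i = roi_labels[ut[, 1]], roi_j = roi_labels[ut[, 2]])
}

#' Paired contrast values per edge and animal
#'
#' For each animal and edge, extracts `x` = z of the `first` interval and
#' `y` = mean z over the `terminal` intervals. The drug contrast used to
#' isolate drug-specific effects compares the first post-drug interval
#' against the mean of the terminal vehicle and terminal drug intervals;
#' the mirrored vehicle contrast (for injection-artifact detection)
#' compares the first post-vehicle interval against the mean of the
#' terminal baseline and terminal vehicle intervals.
#'
#' @param fcints result of [interval_fc_matrices()] (one genotype).
#' @param first interval label, e.g. `"drug1"`.
#' @param terminal character vector of interval labels, e.g.
#'   `c("vehicle3", "drug3")`.
#' @return list with `x`, `y`, `diff` — matrices `n_edges` x `n_animals` —
#'   and `edges` (the [edge_index()] frame).
#' @export
contrast_values <- function(fcints, first, terminal) {
  z1 <- fcints[[1]][[first]]
  if (is.null(z1)) stop("missing interval ", first)
  labels <- rownames(unclass(z1)) %||% as.character(seq_len(nrow(z1)))
  ed <- edge_index(labels)
  ut <- upper.tri(unclass(z1))
  get_ut <- function(m) unclass(m)[ut]
  x <- vapply(fcints, function(zl) get_ut(zl[[first]]), numeric(nrow(ed)))
  y <- vapply(fcints, function(zl) {
    ms <- lapply(terminal, function(lb) {
      if (is.null(zl[[lb]])) stop("missing interval ", lb)
      get_ut(zl[[lb]])
    })
    Reduce(`+`, ms) / length(ms)
  }, numeric(nrow(ed)))
  x <- matrix(x, nrow = nrow(ed)); y <- matrix(y, nrow = nrow(ed))
  list(x = x, y = y, diff = x - y, edges = ed)
}

#' Paired t-test on per-animal differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a two-sided p
#' from the t distribution. Zero variance with a nonzero mean is flagged
#' degenerate (p -> 0); all-zero differences give `t = 0, p = 1`.
#'
#' @param diffs numeric vector of paired differences (one per animal).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
paired_t <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 2) stop("need at least 2 finite paired differences")
  m <- mean(diffs); s <- stats::sd(diffs)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1, degenerate = FALSE))
    return(list(t = sign(m) * Inf, df = n - 1, p = 0, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1),
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1). `NA`/`NaN` entries are
#' excluded from the adjustment (m = number of finite p-values) and
#' returned as `NA`, with a warning count.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length/order as `p`.
#' @export
fdr_bh <- function(p) {
  bad <- !is.finite(p)
  if (any(!bad & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (any(bad)) warning(sum(bad), " non-finite p-value(s) excluded from FDR")
  out <- rep(NA_real_, length(p))
  out[!bad] <- stats::p.adjust(p[!bad], method = "BH")
  out
}

#' Edge-wise paired contrast table
#'
#' Runs [paired_t()] per edge on a paired contrast, applies [fdr_bh()], and
#' assembles the per-edge statistics table.
#'
#' @param cv result of [contrast_values()].
#' @param alpha FDR significance threshold (default 0.01 for edge
#'   discovery; 0.05 is the conventional alternative).
#' @param description free-text contrast description.
#' @return data frame of class `edge_contrast_table` with columns `roi_i`,
#'   `roi_j`, `mean_diff_z`, `t_stat`, `df`, `p_raw`, `p_fdr`, `direction`,
#'   `degenerate`, `artifact_flag`, `significant`; attributes `alpha` and
#'   `description`.
#' @export
edge_contrast_table <- function(cv, alpha = 0.01, description = "") {
  ed <- cv$edges
  stats_l <- lapply(seq_len(nrow(ed)), function(e) paired_t(cv$diff[e, ]))
  tab <- data.frame(
    roi_i = ed$roi_i, roi_j = ed$roi_j,
    mean_diff_z = rowMeans(cv$diff),
    t_stat = vapply(stats_l, `[[`, numeric(1), "t"),
    df = vapply(stats_l, `[[`, numeric(1), "df"),
    p_raw = vapply(stats_l, `[[`, numeric(1), "p"),
    degenerate = vapply(stats_l, `[[`, logical(1), "degenerate"))
  tab$p_fdr <- fdr_bh(tab$p_raw)
  tab$direction <- ifelse(tab$mean_diff_z >= 0, "increase", "decrease")
  tab$artifact_flag <- FALSE
  tab$significant <- !is.na(tab$p_fdr) & tab$p_fdr < alpha
  attr(tab, "alpha") <- alpha
  attr(tab, "description") <- description
  class(tab) <- c("edge_contrast_table", "data.frame")
  tab
}

#' Exclude injection-mediated effects
#'
#' Edges significant after *both* injections with matching direction are
#' injection artifacts, not drug effects: in the drug table they get
#' `artifact_flag = TRUE` and `significant = FALSE`. Direction matching is
#' required — an edge moving opposite ways after the two injections is not
#' flagged.
#'
#' @param drug_table drug-contrast [edge_contrast_table()].
#' @param vehicle_table mirrored vehicle-contrast table on the same edges.
#' @return the drug table with artifact flags applied.
#' @export
flag_injection_artifacts <- function(drug_table, vehicle_table) {
  key <- function(t) paste(t$roi_i, t$roi_j, sep = "~")
  if (!identical(key(drug_table), key(vehicle_table)))
    stop("edge sets of the two tables differ")
  art <- drug_table$significant & vehicle_table$significant &
         drug_table$direction == vehicle_table$direction
  drug_table$artifact_flag <- art
  drug_table$significant[art] <- FALSE
  drug_table
}

#' Full drug-specific edge analysis for one genotype
#'
#' Builds the drug contrast (first post-drug interval vs mean of terminal
#' vehicle and drug intervals) and the mirrored vehicle contrast (first
#' post-vehicle interval vs mean of terminal baseline and vehicle
#' intervals), tests every edge, FDR-corrects, and excludes
#' injection-common effects.
#'
#' @param tsset a single-genotype [roi_ts_set()] (see [subset_genotype()]).
#' @param segmentation a [segment_conditions()] result; conditions must
#'   have >= 1 (baseline, drug) and >= 1 vehicle interval.
#' @param alpha FDR threshold (default 0.01).
#' @return drug-contrast [edge_contrast_table()] with artifact flags; the
#'   vehicle table is attached as attribute `vehicle_table`.
#' @export
amylin_edge_analysis <- function(tsset, segmentation, alpha = 0.01) {
  fcints <- interval_fc_matrices(tsset, segmentation)
  last_of <- function(cd) {
    labs <- segmentation$label[segmentation$condition == cd]
    if (!length(labs)) stop("no ", cd, " intervals")
    labs[length(labs)]
  }
  first_of <- function(cd) segmentation$label[segmentation$condition == cd][1]
  drug_cv <- contrast_values(fcints, first_of("drug"),
                             c(last_of("vehicle"), last_of("drug")))
  veh_cv <- contrast_values(fcints, first_of("vehicle"),
                            c(last_of("baseline"), last_of("vehicle")))
  drug_tab <- edge_contrast_table(drug_cv, alpha = alpha,
    description = "first drug interval vs mean(terminal vehicle, terminal drug)")
  veh_tab <- edge_contrast_table(veh_cv, alpha = alpha,
    description = "first vehicle interval vs mean(terminal baseline, terminal vehicle)")
  out <- flag_injection_artifacts(drug_tab, veh_tab)
  attr(out, "vehicle_table") <- veh_tab
  out
}

#' Export an edge-contrast table
#'
#' Writes the full table as CSV plus a significant-edge list
#' (`source, target, direction, p_fdr`) consumable by connectogram and
#' brain-rendering tools. Rows are ordered lexicographically by ROI labels
#' for deterministic output.
#'
#' @param table an [edge_contrast_table()].
#' @param path output CSV path; the significant-edge list is written
#'   alongside with suffix `_significant.csv`.
#' @return invisibly, the two paths.
#' @export
export_edges <- function(table, path) {
  ord <- order(table$roi_i, table$roi_j)
  full <- as.data.frame(table)[ord, , drop = FALSE]
  utils::write.csv(full, path, row.names = FALSE)
  sig <- full[full$significant, c("roi_i", "roi_j", "direction", "p_fdr"),
              drop = FALSE]
  names(sig) <- c("source", "target", "direction", "p_fdr")
  sig_path <- sub("\\.csv$", "_significant.csv", path)
  if (identical(sig_path, path)) sig_path <- paste0(path, "_significant.csv")
  utils::write.csv(sig, sig_path, row.names = FALSE)
  invisible(c(path, sig_path))
}
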