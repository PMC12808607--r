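test_that("contrast values pair the first interval against the terminal mean", {
  labs <- c("A", "B")
  mk <- function(v) as_z_matrix(matrix(c(0, v, v, 0), 2, 2), labs)
  fcints <- list(an1 = list(vehicle3 = mk(0.2), drug1 = mk(0.9),
                            drug3 = mk(0.4)))
  cv <- contrast_values(fcints, "drug1", c("vehicle3", "drug3"))
  expect_equal(cv$x[1, 1], 0.9)
  expect_equal(cv$y[1, 1], 0.3)
  expect_equal(cv$diff[1, 1], 0.6)
  # first interval equal to the terminal mean -> zero difference
  fcints2 <- list(an1 = list(vehicle3 = mk(0.2), drug1 = mk(0.3),
                             drug3 = mk(0.4)))
  expect_equal(contrast_values(fcints2, "drug1",
                               c("vehicle3", "drug3"))$diff[1, 1], 0)
  expect_error(contrast_values(fcints, "drug2", "drug3"), "missing interval")
})

test_that("paired_t matches the textbook formula and handles degeneracies", {
  d <- c(0.3, 0.1, 0.4, 0.2, 0.5, 0.1, 0.2)
  res <- paired_t(d)
  n <- 7
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  expect_equal(res$t, m / (s / sqrt(n)), tolerance = 1e-10)
  expect_equal(res$df, 6)
  expect_equal(res$p, 2 * stats::pt(-abs(res$t), 6), tolerance = 1e-12)
  # degenerate: zero variance, nonzero mean
  deg <- paired_t(c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  # symmetric pair: t = 0, p = 1
  sym <- paired_t(c(-1, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_false(sym$degenerate)
  expect_equal(paired_t(c(0, 0, 0))$p, 1)
  expect_error(paired_t(c(1)), "at least 2")
})

test_that("paired_t significance agrees with the df = 6 critical value 2.447", {
  set.seed(30)
  for (rep in 1:50) {
    d <- rnorm(7, mean = runif(1, -0.5, 0.5), sd = runif(1, 0.1, 1))
    res <- paired_t(d)
    expect_equal(res$p <= 0.05, abs(res$t) >= 2.446912,
                 info = paste("t =", res$t))
  }
})

test_that("fdr_bh matches a hand step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
      prev <- min(prev, m * p[o[i]] / i)
      adj[o[i]] <- prev
    }
    pmin(adj, 1)
  }
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)),
               bh_oracle(c(0.01, 0.02, 0.03, 0.04)))
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04)) < 0.05))
  set.seed(31)
  p <- runif(200)^2
  expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-12)
  expect_true(all(fdr_bh(p) >= p))
  # m = 1: adjusted equals raw
  expect_equal(fdr_bh(0.037), 0.037)
  expect_warning(out <- fdr_bh(c(0.01, NA, 0.5)), "excluded")
  expect_true(is.na(out[2]))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("injection-common edges are flagged and removed from significance", {
  labs <- sprintf("R%02d", 1:4)
  mk_tab <- function(sig, dir) {
    ed <- edge_index(labs)
    tab <- data.frame(roi_i = ed$roi_i, roi_j = ed$roi_j,
                      mean_diff_z = ifelse(dir == "increase", 0.5, -0.5),
                      t_stat = 5, df = 6, p_raw = 0.001, degenerate = FALSE,
                      p_fdr = ifelse(sig, 0.005, 0.5), direction = dir,
                      artifact_flag = FALSE, significant = sig)
    class(tab) <- c("edge_contrast_table", "data.frame")
    tab
  }
  sig_d <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  dir_d <- c("increase", "decrease", "increase", "increase", "increase",
             "increase")
  sig_v <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  dir_v <- c("increase", "increase", "increase", "increase", "increase",
             "increase")
  out <- flag_injection_artifacts(mk_tab(sig_d, dir_d), mk_tab(sig_v, dir_v))
  # edge 1: significant in both, same direction -> flagged
  expect_true(out$artifact_flag[1]); expect_false(out$significant[1])
  # edge 2: both significant but opposite directions -> retained
  expect_false(out$artifact_flag[2]); expect_true(out$significant[2])
  # edge 4: drug-only -> retained
  expect_false(out$artifact_flag[4]); expect_true(out$significant[4])
  # empty vehicle significance set leaves the drug table unchanged
  out2 <- flag_injection_artifacts(mk_tab(sig_d, dir_d),
                                   mk_tab(rep(FALSE, 6), dir_v))
  expect_equal(out2$significant, sig_d)
  expect_false(any(out2$artifact_flag))
  # mismatched edge sets are rejected
  bad <- mk_tab(sig_v, dir_v)
  bad$roi_j[1] <- "R99"
  expect_error(flag_injection_artifacts(mk_tab(sig_d, dir_d), bad),
               "edge sets")
})

test_that("edge export writes deterministic CSVs that round-trip", {
  set.seed(32)
  diffs <- matrix(rnorm(6 * 5, sd = 0.1), 6, 5)
  diffs[2, ] <- diffs[2, ] + 2  # one strong edge
  cv <- list(x = diffs, y = matrix(0, 6, 5), diff = diffs,
             edges = edge_index(sprintf("R%02d", 1:4)))
  tab <- edge_contrast_table(cv, alpha = 0.05)
  path <- file.path(withr::local_tempdir(), "edges.csv")
  export_edges(tab, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 6)
  ord <- order(tab$roi_i, tab$roi_j)
  expect_equal(back$mean_diff_z, tab$mean_diff_z[ord], tolerance = 1e-12)
  sig <- utils::read.csv(sub("\\.csv$", "_significant.csv", path))
  expect_equal(nrow(sig), sum(tab$significant))
  expect_named(sig, c("source", "target", "direction", "p_fdr"))
  # empty table -> header-only significant file
  tab0 <- tab; tab0$significant <- FALSE
  export_edges(tab0, path)
  expect_equal(nrow(utils::read.csv(sub("\\.csv$", "_significant.csv",
                                        path))), 0)
})

test_that("the drug contrast recovers modulated edges and excludes artifacts", {
  pp <- default_preprocessed()
  seg <- default_segmentation()
  sim <- default_sim()
  labs <- pp$roi_labels
  tab <- amylin_edge_analysis(subset_genotype(pp, "WT"), seg, alpha = 0.01)
  keys <- table_edge_keys(tab)
  drug_keys <- truth_edge_keys(sim$truth$modulated_edges, labs)
  art_keys <- truth_edge_keys(sim$truth$artifact_edges, labs)
  # most injected edges recovered, directions correct
  hit <- tab$significant[keys %in% drug_keys]
  expect_gte(sum(hit), 6)
  rec <- tab[keys %in% drug_keys & tab$significant, ]
  tr <- sim$truth$modulated_edges
  tr_dir <- ifelse(tr$delta > 0, "increase", "decrease")
  names(tr_dir) <- truth_edge_keys(tr, labs)
  expect_equal(rec$direction, unname(tr_dir[table_edge_keys(rec)]))
  # artifact edges flagged, not significant
  art_rows <- tab[keys %in% art_keys, ]
  expect_true(all(art_rows$artifact_flag))
  expect_false(any(art_rows$significant))
  # vehicle table attached and shows the artifact edges
  veh <- attr(tab, "vehicle_table")
  expect_true(all(veh$significant[table_edge_keys(veh) %in% art_keys]))
})
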