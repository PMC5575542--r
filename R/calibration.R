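# Null-calibration and signal-recovery studies for the enrichment scan:
# simulate alignments on a fixed ladder tree, reconstruct ancestors, scan
# all (region, window) combinations, and summarize rejection rates.

#' Fixed study design for calibration and power experiments
#'
#' A ladder tree whose internal spine provides six nested ancestors (hence
#' five phylogenetic windows), every branch set to `branch_length`; nine
#' region column sets tiling the alignment (the first takes
#' `region_fraction` of the columns and is the implant target, the other
#' eight split the remainder evenly); the implanted branch is the spine
#' branch inside the middle window.
#'
#' @param n_leaves Leaves on the ladder tree (>= 7 so five windows exist).
#' @param seq_length Alignment columns.
#' @param branch_length Length of every branch (substitutions/site).
#' @param region_fraction Fraction of columns in the implant-target region.
#' @return List: `tree`, `windows` ([define_windows()] table), `region_map`,
#'   `implanted_region`, `implanted_window`, `multiplier_branch`,
#'   `region_columns`.
#' @export
calibration_setup <- function(n_leaves = 8, seq_length = 400,
                              branch_length = 0.4, region_fraction = 0.2) {
  if (n_leaves < 7)
    stop_pe("config_error", "need >= 7 leaves for five windows")
  tree <- gen_tree(n_leaves, "ladder", branch_length, seed = 1)
  tree$edge.length <- rep(branch_length, nrow(tree$edge))
  ancestors <- setNames(
    lapply(1:6, function(k) paste0("L", seq_len(n_leaves - k + 1))),
    paste0("anc", 1:6))
  windows <- define_windows(tree, ancestors)
  n_imp <- round(region_fraction * seq_length)
  region_cols <- seq_len(n_imp)
  rest <- setdiff(seq_len(seq_length), region_cols)
  blocks <- split(rest, cut(seq_along(rest), 8, labels = FALSE))
  cols <- c(list(region_cols), unname(blocks))
  rmap <- region_map(setNames(cols, REGION_LABELS),
                     provenance = list(design = "calibration tiling"))
  list(tree = tree, windows = windows, region_map = rmap,
       implanted_region = REGION_LABELS[1],
       implanted_window = windows$name[3],
       multiplier_branch = windows$end_node[3],
       region_columns = region_cols)
}

#' Replicated enrichment study under a known simulation regime
#'
#' For each replicate: evolve an alignment on the study tree (rate
#' multiplier `m` on the implanted branch for the implanted region columns;
#' `m = 1` is the null), reconstruct ancestors (marginal posteriors + Fitch
#' + ML sequences, under the generating model), and run the enrichment scan
#' over all nine regions and five windows.
#'
#' @param n_reps Number of replicates.
#' @param m Rate multiplier on the implanted (region, branch) combination.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param n_leaves,seq_length,branch_length,region_fraction Passed to
#'   [calibration_setup()].
#' @param gamma_shape,n_rate_categories Simulation/reconstruction model.
#' @param use_asr If `FALSE`, scan the recorded true ancestors instead of
#'   reconstructed ones (faster; isolates the scan from reconstruction).
#' @param indel_column_fraction Fraction of presence/absence columns.
#' @return List of class `calibration_study`: `summary` (rejection_rate
#'   over all cells, implanted_rate, median implanted odds ratio) and
#'   `cells` (data.frame: rep, window, region, p_value, odds_ratio,
#'   significant).
#' @export
calibration_study <- function(n_reps, m = 1, seed = 1, n_leaves = 8,
                              seq_length = 400, branch_length = 0.4,
                              region_fraction = 0.2, gamma_shape = 1,
                              n_rate_categories = 4, use_asr = TRUE,
                              indel_column_fraction = 0.05) {
  setup <- calibration_setup(n_leaves, seq_length, branch_length,
                             region_fraction)
  model <- aa_model("WAG", gamma_shape, n_rate_categories)
  seeds <- with_seed(seed, sample.int(2147483646L, n_reps))
  cells <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_leaves = n_leaves, seq_length = seq_length,
                      model_name = "WAG", gamma_shape = gamma_shape,
                      n_rate_categories = n_rate_categories,
                      region_columns = setup$region_columns,
                      multiplier_branches = setup$multiplier_branch,
                      rate_multiplier = m,
                      indel_column_fraction = indel_column_fraction,
                      seed = seeds[r])
    ds <- evolve_alignment(setup$tree, cfg)
    anc <- if (use_asr)
      marginal_ancestral_posteriors(setup$tree, ds$alignment, model)
    else ds$true_ancestors
    scan <- enrichment_scan(anc, setup$windows, setup$region_map)
    cells[[r]] <- data.frame(rep = r, scan[, c("window", "region",
                                               "p_value", "odds_ratio",
                                               "significant")],
                             stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  imp <- cells$window == setup$implanted_window &
    cells$region == setup$implanted_region
  summary <- list(
    n_reps = n_reps, m = m,
    rejection_rate = mean(cells$p_value < 0.05),
    implanted_rate = mean(cells$significant[imp]),
    implanted_or_median = stats::median(
      cells$odds_ratio[imp][is.finite(cells$odds_ratio[imp])]))
  structure(list(summary = summary, cells = cells, setup = setup),
            class = "calibration_study")
}

#' @export
print.calibration_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<calibration_study: %d reps, m = %g; rejection rate ",
                     "%.4f; implanted-cell recovery %.3f (median OR %.2f)>\n"),
              s$n_reps, s$m, s$rejection_rate, s$implanted_rate,
              s$implanted_or_median))
  invisible(x)
}
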