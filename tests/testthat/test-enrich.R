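# Substitution counting, Fisher's exact test, odds ratios, windows, scan.

test_that("four-category counting handles the worked example, identity and
           gap exclusion", {
  # 100 columns, 10-column region, 2 in-region + 3 out-of-region changes
  s <- rep("A", 100)
  e <- rep("A", 100)
  e[c(1, 5)] <- "R"          # in-region changes
  e[c(20, 40, 90)] <- "K"    # out-of-region changes
  tab <- count_substitutions(s, e, 1:10)
  expect_identical(c(tab$a, tab$b, tab$c, tab$d, tab$excluded),
                   c(2L, 8L, 3L, 87L, 0L))
  expect_equal(odds_ratio(tab), (2 * 87) / (8 * 3))
  # identical sequences
  t0 <- count_substitutions(s, s, 1:10)
  expect_identical(c(t0$a, t0$c), c(0L, 0L))
  expect_identical(t0$b + t0$d, 100L)
  # gap on either side excludes the site
  e2 <- e
  e2[3] <- "-"              # in-region gap
  s2 <- s
  s2[50] <- "-"             # out-of-region gap
  t2 <- count_substitutions(s2, e2, 1:10)
  expect_identical(t2$excluded, 2L)
  expect_identical(t2$a + t2$b + t2$c + t2$d + t2$excluded, 100L)
  expect_identical(t2$b, 7L)
  expect_error(count_substitutions(s, e[1:99], 1:10), class = "input_error")
})

test_that("fisher_exact equals the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact(c(2, 8, 2, 8)), 1.0)
  expect_equal(fisher_exact(c(5, 5, 10, 80)),
               oracle_fisher(5, 5, 10, 80), tolerance = 1e-12)
  # random spot checks both sided and one-sided
  set.seed(9)
  for (r in 1:25) {
    x <- as.integer(rmultinom(1, sample(10:60, 1), rep(1 / 4, 4)))
    expect_equal(fisher_exact(x, "two.sided"),
                 oracle_fisher(x[1], x[2], x[3], x[4], "two.sided"),
                 tolerance = 1e-12)
    expect_equal(fisher_exact(x, "greater"),
                 oracle_fisher(x[1], x[2], x[3], x[4], "greater"),
                 tolerance = 1e-12)
  }
  # tail identity: P(greater) + P(less) - point = 1
  x <- c(7, 3, 11, 19)
  m <- matrix(x, 2, byrow = TRUE)
  p_g <- fisher_exact(x, "greater")
  p_l <- stats::fisher.test(m, alternative = "less")$p.value
  point <- stats::dhyper(x[1], x[1] + x[2], x[3] + x[4], x[1] + x[3])
  expect_equal(p_g + p_l - point, 1, tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact(c(0, 0, 0, 0)), "all-zero")
  expect_equal(p0, 1)
})

test_that("odds-ratio conventions: arithmetic, infinity, undefined,
           Haldane", {
  expect_equal(odds_ratio(c(5, 5, 10, 80)), 8)
  expect_equal(odds_ratio(c(1, 1, 1, 1)), 1)
  expect_identical(odds_ratio(c(3, 0, 5, 10)), Inf)
  expect_true(is.na(odds_ratio(c(0, 0, 5, 0))))
  expect_equal(odds_ratio(c(3, 0, 5, 10), haldane = TRUE),
               (3.5 * 10.5) / (0.5 * 5.5))
})

test_that("windows resolve MRCAs along a root-to-tip path and reject
           non-nested requests", {
  setup <- calibration_setup(n_leaves = 8)
  expect_identical(nrow(setup$windows), 5L)
  expect_identical(setup$windows$start_node, paste0("N", 1:5))
  expect_identical(setup$windows$end_node, paste0("N", 2:6))
  tr <- tree4()
  w <- define_windows(tr, list(all = c("A", "B", "C", "D"),
                               ab = c("A", "B")))
  expect_identical(w$start_node, "N1")
  expect_identical(w$end_node,
                   paleoenrich:::node_label(tr, ape::getMRCA(tr, c("A", "B"))))
  expect_error(define_windows(tr, list(ab = c("A", "B"),
                                       cd = c("C", "D"))),
               class = "window_error")
  # spec with all leaves resolves to the root
  w2 <- define_windows(tr, list(all = c("A", "B", "C", "D"),
                                a = "A"))
  expect_identical(w2$start_node[1], "N1")
})

test_that("enrichment scan emits one row per (window, region), applies the
           strict significance rule and conserves counts", {
  setup <- calibration_setup()
  cfg <- sim_config(n_leaves = 8, seq_length = 400,
                    region_columns = setup$region_columns,
                    multiplier_branches = setup$multiplier_branch,
                    rate_multiplier = 5, seed = 13)
  ds <- evolve_alignment(setup$tree, cfg)
  res <- enrichment_scan(ds$true_ancestors, setup$windows,
                         setup$region_map)
  expect_identical(nrow(res), 45L)
  expect_true(all(res$a + res$b + res$c + res$d + res$excluded == 400))
  imp <- res$window == setup$implanted_window &
    res$region == setup$implanted_region
  expect_gt(res$odds_ratio[imp], 1.5)
  expect_lt(res$p_value[imp], 0.05)
  expect_true(res$significant[imp])
  # identical endpoints: nothing substituted, nothing significant
  same <- setNames(lapply(paste0("N", 1:6), function(n)
    ds$true_ancestors$N1), paste0("N", 1:6))
  res0 <- enrichment_scan(same, setup$windows, setup$region_map)
  expect_true(all(res0$a == 0 & res0$c == 0))
  expect_false(any(res0$significant))
})

test_that("significance requires both OR > 1.5 and p < .05 strictly", {
  setup <- calibration_setup(seq_length = 40)
  # hand-build ancestors giving an exact OR of 1.5 in one cell:
  # region 8 cols: a=3,b=5; rest 32: c=8,d=24 -> OR = (3*24)/(5*8) = 1.8
  # use thresholds to probe strictness instead
  s <- rep("A", 40)
  e <- rep("A", 40)
  e[1:3] <- "R"
  e[9:16] <- "K"
  rmapx <- region_map(setNames(c(list(1:8),
                                 lapply(2:9, function(i) integer(0))),
                               REGION_LABELS))
  seqs <- list(N1 = s, N2 = e)
  w <- data.frame(name = "w", start = "a", end = "b",
                  start_node = "N1", end_node = "N2")
  tab <- count_substitutions(s, e, 1:8)
  or <- odds_ratio(tab)
  res <- enrichment_scan(seqs, w, rmapx, or_threshold = or)
  expect_false(res$significant[1])    # OR == threshold: not significant
  res2 <- enrichment_scan(seqs, w, rmapx, or_threshold = or - 1e-9,
                          p_threshold = res$p_value[1])
  expect_false(res2$significant[1])   # p == threshold: not significant
  res3 <- enrichment_scan(seqs, w, rmapx, or_threshold = or - 1e-9,
                          p_threshold = res$p_value[1] + 1e-9)
  expect_true(res3$significant[1])
})

test_that("gap policies: exclusion versus counting presence changes", {
  s <- c("A", "A", "-", "A")
  e <- c("A", "-", "-", "R")
  w <- data.frame(name = "w", start = "x", end = "y",
                  start_node = "N1", end_node = "N2")
  rmapx <- region_map(setNames(c(list(1:2),
                                 lapply(2:9, function(i) integer(0))),
                               REGION_LABELS))
  seqs <- list(N1 = s, N2 = e)
  res_ex <- enrichment_scan(seqs, w, rmapx, gap_policy = "exclude")
  row <- res_ex[res_ex$region == REGION_LABELS[1], ]
  expect_identical(c(row$a, row$b, row$c, row$d, row$excluded),
                   c(0L, 1L, 1L, 0L, 2L))
  res_sub <- enrichment_scan(seqs, w, rmapx, gap_policy = "substitution")
  row2 <- res_sub[res_sub$region == REGION_LABELS[1], ]
  # one-sided gap now counts as substitution; both-gap still excluded
  expect_identical(c(row2$a, row2$b, row2$c, row2$d, row2$excluded),
                   c(1L, 1L, 1L, 0L, 1L))
})
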