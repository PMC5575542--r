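# Synthetic-data generator: determinism, degenerate limits, stationarity,
# implanted-signal behaviour.

test_that("simulation is deterministic given the config seed", {
  tr <- gen_tree(6, "yule", 0.3, seed = 1)
  cfg <- sim_config(n_leaves = 6, seq_length = 80, seed = 99)
  d1 <- evolve_alignment(tr, cfg)
  d2 <- evolve_alignment(tr, cfg)
  expect_identical(unclass(d1$alignment), unclass(d2$alignment))
  expect_identical(d1$true_ancestors, d2$true_ancestors)
  d3 <- evolve_alignment(tr, sim_config(n_leaves = 6, seq_length = 80,
                                        seed = 100))
  expect_false(identical(unclass(d1$alignment), unclass(d3$alignment)))
})

test_that("zero branch lengths copy the root everywhere", {
  tr <- gen_tree(5, "ladder", 0.2, seed = 2)
  tr$edge.length[] <- 0
  ds <- evolve_alignment(tr, sim_config(n_leaves = 5, seq_length = 60,
                                        indel_column_fraction = 0,
                                        seed = 5))
  root_seq <- ds$true_ancestors$N1
  for (s in ds$true_ancestors) expect_identical(s, root_seq)
  for (i in seq_len(nrow(ds$alignment)))
    expect_identical(unname(unclass(ds$alignment)[i, ]), root_seq)
})

test_that("root draws match the model's stationary frequencies", {
  tr <- gen_tree(2, "ladder", 0.1, seed = 3)
  cfg <- sim_config(n_leaves = 2, seq_length = 10000,
                    indel_column_fraction = 0, seed = 7)
  ds <- evolve_alignment(tr, cfg)
  m <- aa_model("WAG")
  f <- table(factor(ds$true_ancestors$N1, levels = AA_CODES)) / 10000
  se <- sqrt(m$pi * (1 - m$pi) / 10000)
  expect_true(all(abs(f - m$pi) < 3 * se + 1e-9))
})

test_that("with m = 1 region and non-region columns are statistically
           indistinguishable", {
  tr <- gen_tree(2, "ladder", 0.4, seed = 4)
  region <- 1:30
  per_col_subs <- matrix(0, 0, 2)
  subs_in <- subs_out <- numeric(250)
  for (r in 1:250) {
    ds <- evolve_alignment(tr, sim_config(
      n_leaves = 2, seq_length = 60, region_columns = region,
      multiplier_branches = "L1", rate_multiplier = 1,
      indel_column_fraction = 0, n_rate_categories = 1, seed = 1000 + r))
    root <- ds$true_ancestors$N1
    leaf <- unclass(ds$alignment)["L1", ]
    subs_in[r] <- sum(root[region] != leaf[region])
    subs_out[r] <- sum(root[-region] != leaf[-region])
  }
  p <- stats::t.test(subs_in, subs_out, paired = TRUE)$p.value
  expect_gt(p, 0.001)
})

test_that("with m = 5 the multiplier branch accumulates more substitutions
           per column in-region than out", {
  setup <- calibration_setup()
  cfg <- sim_config(n_leaves = 8, seq_length = 400,
                    region_columns = setup$region_columns,
                    multiplier_branches = setup$multiplier_branch,
                    rate_multiplier = 5, indel_column_fraction = 0,
                    seed = 21)
  ds <- evolve_alignment(setup$tree, cfg)
  start <- ds$true_ancestors[[setup$windows$start_node[3]]]
  end <- ds$true_ancestors[[setup$windows$end_node[3]]]
  reg <- setup$region_columns
  rate_in <- mean(start[reg] != end[reg])
  rate_out <- mean(start[-reg] != end[-reg])
  expect_gt(rate_in, rate_out)
  # and on a non-multiplier branch the rates are comparable
  s2 <- ds$true_ancestors[[setup$windows$start_node[1]]]
  e2 <- ds$true_ancestors[[setup$windows$end_node[1]]]
  expect_lt(abs(mean(s2[reg] != e2[reg]) - mean(s2[-reg] != e2[-reg])), 0.15)
})

test_that("indel columns evolve and appear as gaps in leaves and ancestors", {
  tr <- gen_tree(8, "yule", 0.5, seed = 6)
  cfg <- sim_config(n_leaves = 8, seq_length = 100,
                    indel_column_fraction = 0.3, indel_rate = 1, seed = 9)
  ds <- evolve_alignment(tr, cfg)
  expect_length(ds$indel_columns, 30)
  gaps <- unclass(ds$alignment) == "-"
  expect_true(any(gaps))
  expect_true(all(which(colSums(gaps) > 0) %in% ds$indel_columns))
  # the recorded presence maps agree with the emitted gaps
  for (tax in rownames(ds$alignment))
    expect_identical(unname(unclass(ds$alignment)[tax, ] == "-"),
                     unname(!ds$true_presence[[tax]]))
})

test_that("fixture bundles round-trip and are byte-deterministic", {
  cfg <- sim_config(n_leaves = 8, seq_length = 120, seed = 11)
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  m1 <- gen_fixture_bundle(cfg, d1)
  m2 <- gen_fixture_bundle(cfg, d2)
  expect_gte(length(m1$files), 5)
  expect_identical(m1$seed, cfg$seed)
  expect_identical(readLines(file.path(d1, "alignment.fasta")),
                   readLines(file.path(d2, "alignment.fasta")))
  expect_identical(readLines(file.path(d1, "tree.nwk")),
                   readLines(file.path(d2, "tree.nwk")))
  # all files parse with their respective readers
  expect_s3_class(read_fasta(file.path(d1, "alignment.fasta")),
                  "protein_alignment")
  expect_s3_class(ape::read.tree(file.path(d1, "tree.nwk")), "phylo")
  expect_s3_class(read_structure(file.path(d1, "query_dimer.pdb")),
                  "structure_model")
  expect_s3_class(read_region_map(file.path(d1, "regions_truth.tsv")),
                  "region_map")
  expect_true(jsonlite::validate(paste(readLines(
    file.path(d1, "manifest.json")), collapse = "\n")))
})
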