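# Structural module: PDB round-trips, Kabsch superposition, interface and
# subdomain rules, region-map construction and invariances.

rigid_move <- function(model, angle = 0.7, axis = c(0, 0, 1),
                       shift = c(5, -3, 2)) {
  # rotation about z by `angle` plus translation
  ca <- cos(angle); sa <- sin(angle)
  R <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}

test_that("toy fixtures are read back with expected chains and residues,
           waters dropped, modified residues renamed", {
  f <- gen_toy_dimer(6, rbind(c(2, 2)), cutoff = 5)
  s <- read_structure(f)
  expect_setequal(unique(s$chain), c("A", "B"))
  expect_length(residue_keys(s, "A"), 6)
  expect_length(residue_keys(s, "B"), 6)
  # append a water HETATM and a modified lysine
  lines <- readLines(f)
  het <- c(
    "HETATM 9001  O   HOH A 900      99.000  99.000  99.000  1.00  0.00           O",
    "HETATM 9002  CA  KCX A 901      90.000  90.000  90.000  1.00  0.00           C")
  writeLines(c(head(lines, -1), het, "END"), f)
  s2 <- read_structure(f)
  expect_false(any(s2$resid == "HOH"))
  expect_true(any(s2$resid == "LYS" & s2$resno == 901))
})

test_that("extract_dimer keeps exactly the requested chains", {
  f <- gen_toy_dimer(5, NULL, partner_contacts = list(C = 2L, S = 3L))
  s <- read_structure(f)
  expect_setequal(unique(s$chain), c("A", "B", "C", "S"))
  d <- extract_dimer(s, c("A", "B"))
  expect_setequal(unique(d$chain), c("A", "B"))
  expect_identical(nrow(extract_dimer(d, c("A", "B"))), nrow(d))
  expect_error(extract_dimer(s, c("A", "Z")), class = "input_error")
})

test_that("Kabsch superposition recovers rigid motions and matches the
           brute-force oracle", {
  f <- gen_toy_dimer(6, rbind(c(2, 2)))
  s <- read_structure(f)
  expect_lt(superimpose(s, s)$rmsd, 1e-9)
  s2 <- rigid_move(s, angle = pi / 2, shift = c(5, 0, 0))
  sup <- superimpose(s2, s)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  back <- apply_transform(s2, sup)
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                    as.matrix(s[, c("x", "y", "z")]))), 1e-6)
  # perturbed asymmetric point set: RMSD equals numeric minimization
  set.seed(12)
  X <- matrix(rnorm(12, sd = 4), 4, 3)
  Y <- X + matrix(rnorm(12, sd = 0.3), 4, 3)
  mk <- function(M, chain) {
    data.frame(chain = chain, resno = seq_len(nrow(M)), resid = "ALA",
               atom = "CA", element = "C", x = M[, 1], y = M[, 2],
               z = M[, 3])
  }
  sup2 <- superimpose(structure(mk(X, "A"), class = c("structure_model",
                                                      "data.frame")),
                      structure(mk(Y, "A"), class = c("structure_model",
                                                      "data.frame")))
  expect_equal(sup2$rmsd, oracle_min_rmsd(X, Y), tolerance = 1e-6)
  # bio3d as an independent library cross-check
  fit <- bio3d::fit.xyz(fixed = as.vector(t(Y)), mobile = as.vector(t(X)),
                        fixed.inds = 1:12, mobile.inds = 1:12)
  rmsd_bio3d <- sqrt(mean(colSums(matrix((fit - as.vector(t(Y)))^2, 3))))
  expect_equal(sup2$rmsd, rmsd_bio3d, tolerance = 1e-6)
  # degenerate input: collinear points
  Z <- cbind(1:4, 0, 0)
  expect_error(superimpose(structure(mk(Z, "A"),
                                     class = c("structure_model",
                                               "data.frame")),
                           structure(mk(Z, "A"),
                                     class = c("structure_model",
                                               "data.frame"))),
               class = "geometry_error")
})

test_that("the strict heavy-atom cutoff rule detects 4.9 A contacts,
           rejects 5.1 A and ignores hydrogens", {
  f49 <- gen_toy_dimer(8, rbind(c(3, 3)), cutoff = 5)
  s49 <- read_structure(f49)
  expect_identical(interface_residues(s49, "A", "B", 5), "A:3")
  expect_identical(interface_residues(s49, "B", "A", 5), "B:3")
  # the same construction against a smaller cutoff: 4.9 >= 4.8 -> out
  expect_identical(interface_residues(s49, "A", "B", 4.8), character(0))
  # contact built at 5.1 A (cutoff_build 5.2) vs the 5 A rule -> out
  f51 <- gen_toy_dimer(8, rbind(c(3, 3)), cutoff = 5.2)
  s51 <- read_structure(f51)
  expect_identical(interface_residues(s51, "A", "B", 5), character(0))
  # hydrogen-only contact is invisible to the heavy-atom rule
  fh <- gen_toy_dimer(8, NULL, cutoff = 5, hydrogen_pair = c(4, 4))
  sh <- read_structure(fh)
  expect_identical(interface_residues(sh, "A", "B", 5), character(0))
  # but it is a real contact geometrically: dropping the hydrogen rule
  # would find it (sanity check on the fixture itself)
  h <- sh[sh$element == "H", ]
  bca <- sh[sh$chain == "B" & sh$resno == 4 & sh$atom == "CA", ]
  expect_lt(sqrt(sum((c(h$x, h$y, h$z) - c(bca$x, bca$y, bca$z))^2)), 5)
  # empty pair list: nothing anywhere
  f0 <- gen_toy_dimer(8, NULL, cutoff = 5)
  expect_identical(interface_residues(read_structure(f0), "A", "B", 5),
                   character(0))
})

test_that("interface and near sets grow monotonically with the cutoff", {
  f <- gen_toy_dimer(8, rbind(c(2, 2), c(5, 5)), cutoff = 5)
  s <- read_structure(f)
  sizes <- vapply(c(3, 5, 21, 41), function(cc)
    length(interface_residues(s, "A", "B", cc)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  near_sizes <- vapply(c(0, 5, 21, 41), function(cc)
    length(near_set(s, c("A:4"), cc)), numeric(1))
  expect_true(all(diff(near_sizes) >= 0))
  expect_identical(near_set(s, "A:4", 0), character(0))
  # core members never appear in their own near set
  big <- near_set(s, "A:4", 25)
  expect_false("A:4" %in% big)
  expect_true("A:3" %in% big)   # 20 A neighbor
})

test_that("cross-model interfaces: identical query reproduces the
           reference's own interface; empty partners give empty sets", {
  f <- gen_toy_dimer(8, NULL, partner_contacts = list(C = c(2L, 6L)))
  ref <- read_structure(f)
  q <- extract_dimer(ref, c("A", "B"))
  got <- cross_model_interface(q, ref, "C")
  own <- interface_residues(ref, residue_keys(ref, c("A", "B")),
                            residue_keys(ref, "C"), 5)
  expect_identical(got, own)
  expect_identical(sort(paleoenrich:::key_resno(got)), c(2L, 6L))
  expect_identical(cross_model_interface(q, ref, character(0)), character(0))
  # rigid motion of the query does not change the result
  q2 <- rigid_move(q)
  expect_identical(cross_model_interface(q2, ref, "C"), got)
})

test_that("nearest-Calpha subdomain transfer maps a reference onto itself
           and is rigid-motion invariant", {
  f <- gen_toy_dimer(9, NULL)
  s <- read_structure(f)
  sub <- c("A:2", "A:3", "A:7")
  expect_identical(subdomain_by_nearest_ca(s, s, sub), sort(sub))
  s2 <- rigid_move(s, angle = 1.1, shift = c(-4, 8, 1))
  expect_identical(subdomain_by_nearest_ca(s2, s, sub), sort(sub))
})

test_that("residue-to-alignment mapping handles gaps, mismatches and
           degenerate rows", {
  map <- map_residues_to_alignment(c("A", "C", "D", "E"),
                                   c("A", "C", "-", "D", "E"))
  expect_identical(map$column, c(1L, 2L, 4L, 5L))
  expect_true(all(map$match))
  expect_error(map_residues_to_alignment(c("A"), c("-", "-")),
               class = "mapping_error")
  # one mismatch in 20 residues is tolerated but flagged
  sq <- rep("A", 20)
  row <- sq
  row[7] <- "V"
  m2 <- map_residues_to_alignment(sq, row)
  expect_false(m2$match[7])
  expect_true(all(m2$match[-7]))
  expect_error(map_residues_to_alignment(sq, rep("V", 20)),
               class = "mapping_error")
})

test_that("build_region_map reproduces the constructed truth table and is
           invariant to rigid motion of the query", {
  cfg <- sim_config(n_leaves = 8, seq_length = 120, seed = 11)
  d <- file.path(tempdir(), "regions_fx")
  man <- gen_fixture_bundle(cfg, d)
  aln <- read_fasta(file.path(d, "alignment.fasta"))
  rc <- region_config(
    cutoff = 5,
    formI = list(model = file.path(d, "formI_reference.pdb"),
                 partner_ll_chains = "C", partner_ls_chains = "S"),
    formIII = list(model = file.path(d, "formIII_reference.pdb"),
                   partner_chains = "D"),
    subdomain = c(list(model = file.path(d, "query_dimer.pdb")),
                  man$subdomains))
  q <- read_structure(file.path(d, "query_dimer.pdb"))
  got <- build_region_map(rc, q, aln, man$reference_row)
  truth <- read_region_map(file.path(d, "regions_truth.tsv"))
  expect_identical(got$columns, truth$columns)
  # rigid-motion invariance of the full map
  got2 <- build_region_map(rc, rigid_move(q), aln, man$reference_row)
  expect_identical(got2$columns, got$columns)
  # empty subdomain lists empty those regions only
  rc0 <- rc
  rc0$subdomain$barrel_strands <- integer(0)
  rc0$subdomain$loop6 <- integer(0)
  got3 <- build_region_map(rc0, q, aln, man$reference_row)
  expect_identical(got3$columns$barrel_strands, integer(0))
  expect_identical(got3$columns$loop6, integer(0))
  expect_identical(got3$columns$FormI_LS_interface,
                   got$columns$FormI_LS_interface)
})
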