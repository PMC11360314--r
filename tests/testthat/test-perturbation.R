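# Rotamer sampling and side-chain perturbation.

test_that("measure/apply chi round trips at 1e-6 degrees", {
  p <- make_peptide("GALSKYEWR", "extended")
  set.seed(4)
  for (i in perturbable_residues(p)) {
    nchi <- n_chi(gatddg:::get_residue(p, i)$type3)
    target <- wrap_angle(stats::runif(nchi, -180, 180))
    p2 <- apply_side_chain_torsions(p, i, target)
    expect_lt(max(abs(wrap_angle(measure_chi_angles(p2, i) - target))), 1e-6)
  }
})

test_that("applying the measured chi leaves coordinates unchanged", {
  p <- make_peptide("MKVL", "alpha")
  for (i in perturbable_residues(p)) {
    chi <- measure_chi_angles(p, i)
    p2 <- apply_side_chain_torsions(p, i, chi)
    expect_lt(max(abs(gatddg:::get_residue(p2, i)$xyz -
                      gatddg:::get_residue(p, i)$xyz)), 1e-9)
  }
})

test_that("chi rotation moves exactly the distal atoms and preserves bonds", {
  p <- make_peptide("ALA", "alpha")  # sequence A, L, A
  r0 <- gatddg:::get_residue(p, 1)
  chi <- measure_chi_angles(p, 1)
  p2 <- apply_side_chain_torsions(p, 1, chi + c(120, 0))
  r1 <- gatddg:::get_residue(p2, 1)
  fixed <- c("N", "CA", "C", "O", "CB")
  expect_identical(max(abs(r1$xyz[fixed, ] - r0$xyz[fixed, ])), 0)
  for (a in c("CG", "CD1", "CD2")) {
    expect_gt(gatddg:::vnorm(r1$xyz[a, ] - r0$xyz[a, ]), 0.1)
  }
  d <- function(r, a, b) gatddg:::vnorm(r$xyz[a, ] - r$xyz[b, ])
  expect_lt(abs(d(r1, "CB", "CG") - d(r0, "CB", "CG")), 1e-9)
  expect_lt(abs(d(r1, "CG", "CD1") - d(r0, "CG", "CD1")), 1e-9)
  expect_error(apply_side_chain_torsions(p, 1, 30), "chi length")
})

test_that("GLY and ALA perturbations are identity with zero displacements", {
  p <- make_peptide("GAG", "extended")
  for (i in 0:2) {
    set.seed(i + 1)
    out <- perturb_residue(p, i)
    expect_identical(coord_matrix(out$structure), coord_matrix(p))
    expect_true(all(out$record$displacement == 0))
  }
  expect_identical(measure_chi_angles(p, 0), numeric(0))
})

test_that("SER chi1 flip displaces OG by the analytic circle chord", {
  p <- make_peptide("GSG", "extended")
  p60 <- apply_side_chain_torsions(p, 1, 60)
  p180 <- apply_side_chain_torsions(p, 1, 180)
  ser <- gatddg:::get_residue(p60, 1)
  # radius of OG's rotation circle about the CA-CB axis
  ca <- ser$xyz["CA", ]; cb <- ser$xyz["CB", ]; og <- ser$xyz["OG", ]
  ax <- (cb - ca) / gatddg:::vnorm(cb - ca)
  radial <- (og - cb) - sum((og - cb) * ax) * ax
  chord <- 2 * gatddg:::vnorm(radial) * sin(abs(wrap_angle(180 - 60)) / 2 * pi / 180)
  moved <- gatddg:::vnorm(gatddg:::get_residue(p180, 1)$xyz["OG", ] - og)
  expect_equal(moved, chord, tolerance = 1e-9)
})

test_that("perturbation is local: backbone, CB and other residues never move", {
  p <- make_peptide("GKYLSW", "alpha")
  set.seed(12)
  for (rep_i in 1:5) {
    i <- sample(perturbable_residues(p), 1)
    out <- perturb_residue(p, i)
    t0 <- atom_table(p); t1 <- atom_table(out$structure)
    other <- t0$residue_index != i
    expect_identical(max(abs(as.matrix(t1[other, c("x", "y", "z")]) -
                             as.matrix(t0[other, c("x", "y", "z")]))), 0)
    disp <- out$record$displacement
    expect_true(all(disp[c("N", "CA", "C", "O", "CB")] == 0))
    expect_true(all(disp >= 0))
  }
})

test_that("displacements are invariant under rigid-body transforms", {
  p <- make_peptide("GKYLSW", "alpha")
  pr <- random_rotate_structure(p, seed = 5)
  set.seed(77)
  d0 <- perturb_residue(p, 2)$record$displacement
  set.seed(77)
  d1 <- perturb_residue(pr, 2)$record$displacement
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("a degenerate single-rotamer library always returns its mean", {
  lib <- structure(list(backbone_dependent = FALSE,
                        rotamers = list(SER = list(list(prob = 1, mean = 180,
                                                        sigma = 0)))),
                   class = "RotamerLibrary")
  set.seed(1)
  for (k in 1:5) expect_identical(sample_rotamer(lib, "SER"), 180)
  expect_error(sample_rotamer(lib, "GLY"), "no chi")
  expect_error(sample_rotamer(lib, "LEU"), "no rotamers")
})

test_that("rotamer draws follow library probabilities", {
  lib0 <- default_rotamer_library()
  # two-rotamer 0.9/0.1 check
  lib <- structure(list(backbone_dependent = FALSE,
                        rotamers = list(SER = list(list(prob = 0.9, mean = -65, sigma = 0),
                                                   list(prob = 0.1, mean = 62, sigma = 0)))),
                   class = "RotamerLibrary")
  set.seed(8)
  draws <- replicate(1e4, sample_rotamer(lib, "SER"))
  expect_lt(abs(mean(draws == -65) - 0.9), 0.02)
  # chi-square on a 3-rotamer residue with well-separated chi1 means
  rots <- gatddg:::get_rotamers(lib0, "LYS")
  probs <- vapply(rots, `[[`, 0, "prob")
  means <- vapply(rots, function(r) r$mean[1], 0)
  set.seed(9)
  ch1 <- replicate(1e4, sample_rotamer(lib0, "LYS")[1])
  nearest <- vapply(ch1, function(x) which.min(abs(wrap_angle(x - means))), 0L)
  counts <- tabulate(nearest, nbins = length(means))
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.01)
})

test_that("backbone-dependent libraries use the nearest (phi, psi) bin", {
  tf <- withr::local_tempfile(fileext = ".lib")
  rows <- c(
    paste("SER", -60, -40, 10, 1, 0, 0, 0, 0.7, 62, 0, 0, 0, 5, 0, 0, 0),
    paste("SER", -60, -40, 10, 2, 0, 0, 0, 0.3, -65, 0, 0, 0, 5, 0, 0, 0),
    paste("SER", 60, 40, 10, 1, 0, 0, 0, 1.0, 180, 0, 0, 0, 5, 0, 0, 0))
  writeLines(rows, tf)
  lib <- read_rotamer_library(tf)
  expect_true(lib$backbone_dependent)
  # exactly on a bin center
  r <- gatddg:::get_rotamers(lib, "SER", phi = 60, psi = 40)
  expect_identical(r[[1]]$mean, 180)
  # nearest bin
  r2 <- gatddg:::get_rotamers(lib, "SER", phi = -55, psi = -45)
  expect_identical(length(r2), 2L)
  expect_equal(sum(vapply(r2, `[[`, 0, "prob")), 1)
})

test_that("the shipped library is normalized and matches chi counts", {
  lib <- default_rotamer_library()
  for (res in names(lib$rotamers)) {
    expect_equal(sum(vapply(lib$rotamers[[res]], `[[`, 0, "prob")), 1,
                 tolerance = 1e-6)
    for (r in lib$rotamers[[res]]) expect_length(r$mean, n_chi(res))
  }
})

test_that("perturbation datasets have the right size and are reproducible", {
  peps <- list(make_peptide("GKYLS", "alpha"), make_peptide("MKVL", "extended"),
               make_peptide("AGWE", "alpha"))
  set.seed(31)
  d1 <- make_perturbation_dataset(peps, 5)
  expect_length(d1, 15)
  set.seed(31)
  d2 <- make_perturbation_dataset(peps, 5)
  expect_identical(lapply(d1, function(s) s$record$chi_sampled),
                   lapply(d2, function(s) s$record$chi_sampled))
  expect_warning(make_perturbation_dataset(list(make_peptide("GAG", "alpha")), 3),
                 "no perturbable")
  expect_identical(n_perturbation_samples(5238, 2000), 10476000)
  expect_identical(n_perturbation_samples(3, 5), 15)
})
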