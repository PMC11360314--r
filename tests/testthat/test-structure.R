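# Structure I/O, secondary structure, and solvent accessibility.

test_that("PDB write/read round trip preserves atoms and coordinates", {
  p <- make_peptide("ASLKYEGW", "alpha")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, tf)
  lines <- readLines(tf)
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  expect_gte(length(atom_lines), 4 * length(p))
  serials <- as.integer(substr(atom_lines, 7, 11))
  expect_identical(serials, seq_along(serials))
  p2 <- read_pdb(tf)
  expect_identical(length(p2), length(p))
  expect_identical(atom_table(p2)$atom, atom_table(p)$atom)
  expect_lt(max(abs(coord_matrix(p2) - coord_matrix(p))), 5e-4 + 1e-9)
  expect_true(all(atom_table(p2)$element %in% c("C", "N", "O", "S")))
})

test_that("read_pdb keeps only the first alternate location", {
  p <- make_peptide("AS", "extended")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, tf)
  lines <- readLines(tf)
  og <- grep("OG  SER", lines)
  expect_length(og, 1)
  # duplicate the SER OG line as altloc B with shifted coordinates
  a_line <- lines[og]
  substr(a_line, 17, 17) <- "B"
  substr(a_line, 31, 38) <- sprintf("%8.3f", 99.0)
  lines <- append(lines, a_line, after = og)
  substr(lines[og], 17, 17) <- "A"
  writeLines(lines, tf)
  p2 <- read_pdb(tf)
  ser <- gatddg:::get_residue(p2, 1)
  expect_lt(abs(ser$xyz["OG", 1] - gatddg:::get_residue(p, 1)$xyz["OG", 1]), 5e-4)
})

test_that("read_pdb rejects or skips unknown residues and incomplete ones", {
  p <- make_peptide("AGA", "extended")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, tf)
  lines <- readLines(tf)
  lines <- sub("GLY", "UNK", lines)
  writeLines(lines, tf)
  expect_error(read_pdb(tf), "unsupported residue")
  p3 <- read_pdb(tf, skip_unknown = TRUE)
  expect_identical(length(p3), 2L)
  # drop one side-chain atom -> residue dropped with warning
  write_pdb(make_peptide("ASA", "extended"), tf)
  lines <- readLines(tf)
  writeLines(lines[!grepl("OG  SER", lines)], tf)
  expect_warning(p4 <- read_pdb(tf), "incomplete")
  expect_identical(length(p4), 2L)
})

test_that("ideal alpha helix interior is labelled H, short/extended chains '-'", {
  p <- make_peptide(strrep("A", 12), "alpha")
  ss <- assign_secondary_structure(p)
  expect_true(all(ss[3:10] == "H"))
  expect_identical(assign_secondary_structure(make_peptide("AAA", "extended")),
                   rep("-", 3))
  ext <- assign_secondary_structure(make_peptide(strrep("A", 12), "extended"))
  expect_false(any(ext %in% c("H", "G", "I")))
})

test_that("secondary-structure override is returned verbatim", {
  p <- make_peptide("AAAAA", "alpha")
  expect_identical(assign_secondary_structure(p, override = c("H", "H", "H", "H", "-")),
                   c("H", "H", "H", "H", "-"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(0:4, c("H", "H", "E", "E", "-"), sep = "\t"), tf)
  expect_identical(assign_secondary_structure(p, override = tf),
                   c("H", "H", "E", "E", "-"))
  expect_error(assign_secondary_structure(p, override = c("H", "H")), "one label")
})

test_that("ss8 assignment is invariant under rigid-body transforms", {
  p <- make_peptide("GAYLKSEW", "alpha")
  pr <- random_rotate_structure(p, seed = 99)
  expect_identical(assign_secondary_structure(p), assign_secondary_structure(pr))
})

test_that("SASA matches the closed form for a lone sphere", {
  tab <- data.frame(residue_index = 0L, type3 = "ALA", resno = 1L, atom = "CB",
                    element = "C", x = 0, y = 0, z = 0)
  expect_equal(compute_sasa(tab), 4 * pi * (1.70 + 1.4)^2, tolerance = 0.02)
  expect_error(compute_sasa(tab, n_points = 6), ">= 12")
})

test_that("two nearly coincident atoms expose about one lone-sphere area", {
  tab <- data.frame(residue_index = c(0L, 0L), type3 = "ALA", resno = 1L,
                    atom = c("CA", "CB"), element = "C",
                    x = c(0, 0.1), y = 0, z = 0)
  total <- sum(compute_sasa(tab, n_points = 500))
  lone <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(total, lone, tolerance = 0.05)
})

test_that("an atom caged by 12 contacting neighbors is fully buried", {
  # icosahedron vertices at distance 2.0 A occlude the center C completely
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v <- v / sqrt(1 + phi^2) * 2.0
  tab <- data.frame(residue_index = 0L, type3 = "ALA", resno = 1L,
                    atom = paste0("C", 1:13), element = "C",
                    x = c(0, v[, 1]), y = c(0, v[, 2]), z = c(0, v[, 3]))
  s <- compute_sasa(tab, n_points = 400)
  expect_identical(s[1], 0)
})

test_that("SASA is invariant under rigid rotation and translation", {
  p <- make_peptide("GAYLKS", "alpha")
  s0 <- compute_sasa(p)
  s1 <- compute_sasa(random_rotate_structure(p, seed = 7))
  expect_lt(max(abs(s1 - s0) / pmax(1, s0)), 1e-6)
})

test_that("structure invariants hold after parsing", {
  p <- make_peptide("WYHRKM", "alpha")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, tf)
  p2 <- read_pdb(tf)
  tab <- atom_table(p2)
  expect_true(all(tab$element %in% c("C", "N", "O", "S")))
  for (r in p2$residues) expect_false(anyDuplicated(r$atom_names) > 0)
})
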