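# Mutant construction, atom sets, pooling, featurization, standardization.

test_that("mutant construction replaces only the side chain", {
  p <- make_peptide("GKYLS", "alpha")
  m <- build_mutant_structure(p, 2, "Y", "G")
  mr <- gatddg:::get_residue(m, 2)
  expect_identical(mr$type3, "GLY")
  expect_identical(mr$atom_names, c("N", "CA", "C", "O"))
  # backbone identical everywhere
  t0 <- atom_table(p); t1 <- atom_table(m)
  bb0 <- t0[t0$atom %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
  bb1 <- t1[t1$atom %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
  expect_identical(unname(as.matrix(bb0)), unname(as.matrix(bb1)))
  # errors
  expect_error(build_mutant_structure(p, 2, "V", "V"), "identical")
  expect_error(build_mutant_structure(p, 2, "W", "G"), "mismatch")
  # bulky replacement carries the full topology at the top rotamer
  m2 <- build_mutant_structure(p, 0, "G", "W")
  wr <- gatddg:::get_residue(m2, 0)
  expect_identical(wr$atom_names, residue_topology("TRP")$atoms)
  expect_equal(measure_chi_angles(m2, 0),
               gatddg:::top_rotamer(default_rotamer_library(), "TRP"),
               tolerance = 1e-6)
})

test_that("atom sets partition each graph with the mutated residue first", {
  p <- make_peptide("GKYLS", "alpha")
  m <- build_mutant_structure(p, 2, "Y", "A")
  g_wt <- build_graph(p, 2, annotate_structure(p))
  g_mut <- build_graph(m, 2, annotate_structure(m))
  sets <- define_atom_sets(g_wt, g_mut, 2)
  expect_length(sets$A_mo, nrow(gatddg:::get_residue(p, 2)$xyz))
  expect_length(sets$A_mm, 5)  # ALA heavy atoms
  expect_setequal(c(sets$A_mo, sets$A_no), seq_len(g_wt$n))
  expect_length(intersect(sets$A_mo, sets$A_no), 0)
  # brute-force membership oracle
  expect_identical(sets$A_mo, which(g_wt$atoms$residue_index == 2))
  expect_identical(sets$A_no, which(g_wt$atoms$residue_index != 2))
  expect_error(define_atom_sets(g_wt, g_mut, 1), "centered")
})

test_that("pooling equals the explicit-loop oracle", {
  expect_equal(pool_block(matrix(c(1, 3, 5, 2), 2, 2), 1:2), c(3, 5, 2, 3.5),
               tolerance = 1e-15)
  one <- matrix(c(0.5, -1, 2), 1, 3)
  expect_equal(pool_block(one, 1), c(one[1, ], one[1, ]), tolerance = 1e-15)
  set.seed(4)
  M <- matrix(stats::rnorm(160), 20, 8)
  idx <- sample(20, 9)
  mx <- numeric(8); mn <- numeric(8)
  for (j in 1:8) {
    mx[j] <- -Inf
    for (i in idx) {
      mx[j] <- max(mx[j], M[i, j])
      mn[j] <- mn[j] + M[i, j]
    }
    mn[j] <- mn[j] / length(idx)
  }
  expect_equal(pool_block(M, idx), c(mx, mn), tolerance = 1e-12)
  expect_error(pool_block(M, integer(0)), "empty")
})

test_that("feature vectors have length 24 x layer width with exact difference blocks", {
  st <- tiny_encoder()
  p <- make_peptide("GKYLS", "alpha")
  v <- featurize(st, p, 2, "Y", "A")
  w <- st$config$n_heads * st$config$head_dim
  expect_length(v, 24 * w)
  # difference blocks recomputed independently
  blk <- function(v, layer, piece) {
    v[(layer - 1) * 12 * w + (piece - 1) * 2 * w + seq_len(2 * w)]
  }
  for (L in 1:2) {
    expect_equal(blk(v, L, 3), blk(v, L, 1) - blk(v, L, 2), tolerance = 1e-12)
    expect_equal(blk(v, L, 6), blk(v, L, 4) - blk(v, L, 5), tolerance = 1e-12)
  }
})

test_that("self-mutation surrogate collapses mutant blocks onto wild type", {
  st <- tiny_encoder()
  p <- make_peptide("GKYLS", "alpha")
  v <- featurize(st, p, 2, "Y", "A", mut_structure = p)
  w <- st$config$n_heads * st$config$head_dim
  blk <- function(v, layer, piece) {
    v[(layer - 1) * 12 * w + (piece - 1) * 2 * w + seq_len(2 * w)]
  }
  for (L in 1:2) {
    expect_identical(blk(v, L, 4), blk(v, L, 1))  # F_mm == F_mo
    expect_identical(blk(v, L, 6), blk(v, L, 3))  # F_mm-nm == F_mo-no
  }
})

test_that("swapping wild-type and mutant swaps the block structure exactly", {
  st <- tiny_encoder()
  p <- make_peptide("GKYLS", "alpha")
  recs <- data.frame(structure_id = "p", chain = "A", wt_aa = "Y",
                     position = 2, mut_aa = "A", ddg_exp = 1.7,
                     stringsAsFactors = FALSE)
  fd <- featurize_dataset(recs, list(p = p), st)
  w <- st$config$n_heads * st$config$head_dim
  direct <- fd$X[1, ]; inverse <- fd$X[2, ]
  blk <- function(v, layer, piece) {
    v[(layer - 1) * 12 * w + (piece - 1) * 2 * w + seq_len(2 * w)]
  }
  for (L in 1:2) {
    expect_identical(blk(inverse, L, 1), blk(direct, L, 4))
    expect_identical(blk(inverse, L, 2), blk(direct, L, 5))
    expect_identical(blk(inverse, L, 3), blk(direct, L, 6))
    expect_identical(blk(inverse, L, 4), blk(direct, L, 1))
  }
  expect_identical(fd$meta$ddg, c(1.7, -1.7))
  expect_identical(fd$meta$pair_id, c(1L, 1L))
})

test_that("featurization is deterministic given weights and structures", {
  st <- tiny_encoder()
  p <- make_peptide("GKYLS", "alpha")
  expect_identical(featurize(st, p, 2, "Y", "A"), featurize(st, p, 2, "Y", "A"))
})

test_that("the scaler standardizes training columns and freezes parameters", {
  set.seed(3)
  X <- cbind(stats::rnorm(30, 5, 2), stats::rnorm(30, -1, 0.5), rep(2, 30))
  sc <- fit_scaler(X)
  Xs <- apply_scaler(sc, X)
  expect_equal(colMeans(Xs[, 1:2]), c(0, 0), tolerance = 1e-9)
  expect_equal(apply(Xs[, 1:2], 2, stats::var), c(1, 1), tolerance = 1e-9)
  expect_identical(unique(Xs[, 3]), 0)  # zero-variance column dropped to 0
  expect_identical(sc$dropped, 3L)
  # held-out transform uses the training mean/sd (no refit)
  held <- apply_scaler(sc, c(5, -1, 100))
  expect_equal(held[1:2], c((5 - sc$mean[1]) / sc$sd[1],
                            (-1 - sc$mean[2]) / sc$sd[2]), tolerance = 1e-12)
  expect_identical(held[3], 0)
  # hand-computed 3x2 example
  H <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2)
  sch <- fit_scaler(H)
  expect_equal(sch$mean, c(2, 30), tolerance = 1e-12)
  expect_equal(sch$sd, c(1, stats::sd(c(10, 20, 60))), tolerance = 1e-12)
  expect_equal(apply_scaler(sch, c(3, 60)),
               c(1, (60 - 30) / stats::sd(c(10, 20, 60))), tolerance = 1e-12)
  expect_error(fit_scaler(H[1, , drop = FALSE]), ">= 2")
})
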