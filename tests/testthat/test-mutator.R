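# Alanine/glycine mutation and restoration, loop-mutant preparation, and
# the toy loop-transition simulator.

test_that("mutation strips the side chain and restore is exact", {
  p <- toy_peptide(c("GLU", "MET", "HIS", "VAL"))
  m <- mutate_to(p, c("A:1", "A:3"), "ALA")
  glu_ala <- get_residue(m$structure, "A", 1)
  expect_equal(nrow(glu_ala), 5L)  # N, CA, C, O, CB
  expect_equal(glu_ala$resid[1], "ALA")
  # backbone untouched
  orig_bb <- get_residue(p, "A", 1)
  orig_bb <- orig_bb[orig_bb$name %in% c("N", "CA", "C", "O"), ]
  new_bb <- glu_ala[glu_ala$name %in% c("N", "CA", "C", "O"), ]
  expect_equal(as.matrix(new_bb[, c("x", "y", "z")]),
               as.matrix(orig_bb[, c("x", "y", "z")]), tolerance = 0)
  r <- restore_residues(m$structure, m$records)
  key <- function(s) s$atoms[order(s$atoms$resno, s$atoms$name),
                             c("name", "resid", "x", "y", "z")]
  expect_equal(key(r), key(p), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mutating ALA to ALA is an identity with empty archive", {
  p <- toy_peptide(c("ALA", "VAL"))
  m <- mutate_to(p, "A:1", "ALA")
  expect_length(m$records[[1]]$atom_names, 0L)
  expect_equal(m$structure$atoms, p$atoms, tolerance = 0)
})

test_that("GLY cannot become ALA and unknown keys error", {
  p <- toy_peptide(c("GLY", "VAL"))
  expect_error(mutate_to(p, "A:1", "ALA"), "GLY")
  expect_error(mutate_to(p, "A:9", "ALA"), "not found")
  m <- mutate_to(p, "A:2", "GLY")
  expect_equal(nrow(get_residue(m$structure, "A", 2)), 4L)
})

test_that("restoration re-anchors side chains on a moved backbone frame", {
  p <- toy_peptide(c("GLU", "MET"))
  m <- mutate_to(p, "A:1", "ALA")
  R <- covflex:::rotation_about_axis(c(1, 1, 0), 35)
  moved <- m$structure
  xyz <- apply_transform(as.matrix(moved$atoms[, c("x", "y", "z")]), R,
                         c(3, -2, 1))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3]
  r <- restore_residues(moved, m$records)
  expected <- apply_transform(as.matrix(p$atoms[, c("x", "y", "z")]), R,
                              c(3, -2, 1))
  got <- as.matrix(r$atoms[order(r$atoms$resno, r$atoms$name),
                           c("x", "y", "z")])
  expect_equal(got, expected[order(p$atoms$resno, p$atoms$name), ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("restoring into a structure without the residue errors", {
  p <- toy_peptide(c("GLU", "MET"))
  m <- mutate_to(p, "A:1", "ALA")
  other <- toy_peptide(c("VAL", "VAL"))
  expect_error(restore_residues(other, m$records), "mismatch|absent")
})

test_that("loop-mutant preparation flags glycine runs and ligand contacts", {
  p <- toy_peptide(c("ALA", "GLY", "GLU", "GLY", "VAL", "GLU"))
  res <- prepare_loop_mutant(p, "A:3")
  expect_equal(get_residue(res$structure, "A", 3)$resid[1], "GLY")
  expect_match(res$report$gly_runs, "A:2-4")
  expect_error(prepare_loop_mutant(p, c("A:3", "A:6"), reactive = "A:6"),
               "reactive")
  # a ligand parked on the GLU side chain triggers the contact warning
  glu <- get_residue(p, "A", 3)
  cd <- glu[glu$name == "CD", c("x", "y", "z")]
  lig <- ligand(data.frame(element = "C", x = cd$x + 1, y = cd$y,
                           z = cd$z),
                data.frame(i = integer(), j = integer(),
                           order = integer()), "probe")
  expect_warning(prepare_loop_mutant(p, "A:3", ligand = lig),
                 "within")
})

test_that("toy loop simulator: degenerate start, determinism, barrier ordering", {
  m <- toy_loop_model(2, "GLY", start = 120)
  expect_equal(simulate_loop_transition(m, 100, seed = 1)$fpt, 0L)
  m2 <- toy_loop_model(2, "X")
  a <- simulate_loop_transition(m2, 2000, seed = 9)
  b <- simulate_loop_transition(m2, 2000, seed = 9)
  expect_identical(a, b)
  expect_error(toy_loop_model(2, "X", barrier_gly = 6, barrier_nongly = 2),
               "below")
  expect_error(simulate_loop_transition(m2, 0), "positive")
  # small paired battery: lower barriers cross faster in most seeds
  cmp <- loop_fpt_comparison(n_seeds = 25, n_steps = 8000, seed = 4)
  expect_gt(mean(cmp$fpt_gly < cmp$fpt_nongly), 0.8)
  expect_lt(median(cmp$fpt_gly), median(cmp$fpt_nongly))
})

test_that("near-zero barriers approach free-diffusion first passage", {
  # independent oracle: re-implementation of the same move set with no
  # potential at all (every move accepted)
  free_fpt <- function(seed, n_res = 1, sigma = 15, n_steps = 20000) {
    set.seed(seed)
    th <- rep(0, 2 * n_res)
    for (s in seq_len(n_steps)) {
      i <- sample.int(length(th), 1)
      th[i] <- covflex:::wrap180(th[i] + rnorm(1, 0, sigma))
      if (all(abs(covflex:::wrap180(th - 120)) <= 40)) return(s)
    }
    n_steps
  }
  m <- toy_loop_model(1, "GLY", barrier_gly = 1e-9, barrier_nongly = 1)
  ours <- vapply(1:40, function(s)
    simulate_loop_transition(m, 20000, seed = s)$fpt, numeric(1))
  ref <- vapply(101:140, free_fpt, numeric(1))
  # same order of magnitude (ratio of medians within 2x)
  expect_lt(abs(log(median(ours) / median(ref))), log(2))
})
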