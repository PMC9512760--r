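# Structure I/O, the atomic data model, and the geometric primitives.

test_that("dihedral handles planar reference cases and sign convention", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)),
               180)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  # reversing the point order preserves the signed torsion
  set.seed(42)
  for (k in 1:20) {
    p <- lapply(1:4, function(i) rnorm(3) * 2)
    expect_equal(dihedral(p[[4]], p[[3]], p[[2]], p[[1]]),
                 dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), tolerance = 1e-9)
  }
})

test_that("dihedral matches the independent bio3d oracle on random input", {
  set.seed(7)
  for (k in 1:100) {
    p <- lapply(1:4, function(i) rnorm(3) * 3)
    ours <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    ref <- oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_lt(abs(covflex:::wrap180(ours - ref)), 1e-6)
  }
})

test_that("place_atom inverts dihedral/angle/length measurement", {
  set.seed(11)
  for (k in 1:50) {
    a <- rnorm(3); b <- a + rnorm(3); c <- b + rnorm(3)
    len <- runif(1, 1, 2); ang <- runif(1, 60, 150)
    dih <- runif(1, -179, 180)
    d <- place_atom(a, b, c, len, ang, dih)
    expect_equal(sqrt(sum((d - c)^2)), len, tolerance = 1e-8)
    expect_equal(angle3(b, c, d), ang, tolerance = 1e-6)
    expect_lt(abs(covflex:::wrap180(dihedral(a, b, c, d) - dih)), 1e-6)
  }
})

test_that("kabsch recovers exact rigid motions and is noise-stable", {
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3)
  self <- kabsch(X, X)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  R <- covflex:::rotation_about_axis(c(0, 0, 1), 90)
  Y <- apply_transform(X, R, c(1, 2, 3))
  fit <- kabsch(Y, X)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(apply_transform(Y, fit$rotation, fit$translation), X,
               tolerance = 1e-9)
  # noisy copies: fitted RMSD tracks the noise scale
  rms <- vapply(1:20, function(s) {
    set.seed(s)
    kabsch(X + matrix(rnorm(30, 0, 0.1), 10, 3), X)$rmsd
  }, numeric(1))
  expect_true(all(rms > 0.05 & rms < 0.35))
  expect_error(kabsch(X[1:2, ], X[1:2, ]), "at least 3")
  Z <- cbind(1:5, 0, 0)
  expect_error(kabsch(Z, Z), "collinear")
})

test_that("kabsch agrees with the closed-form quaternion oracle", {
  set.seed(5)
  for (k in 1:100) {
    X <- matrix(rnorm(24), 8, 3)
    Y <- apply_transform(X, covflex:::rotation_about_axis(rnorm(3), runif(1, 0, 360)),
                         rnorm(3)) + matrix(rnorm(24, 0, 0.2), 8, 3)
    expect_equal(kabsch(Y, X)$rmsd, oracle_fit_rmsd(Y, X),
                 tolerance = 1e-9)
  }
})

test_that("superpose is invariant to pre-applied rigid motions", {
  p <- toy_peptide()
  q <- toy_peptide(c("ALA", "GLY", "SER", "VAL", "THR", "ALA"))
  q$atoms[, c("x", "y", "z")] <- q$atoms[, c("x", "y", "z")] +
    matrix(rnorm(nrow(q$atoms) * 3, 0, 0.3), ncol = 3)
  base <- superpose(q, p)$rmsd
  R <- covflex:::rotation_about_axis(c(1, 2, 3), 77)
  q2 <- q
  xyz <- apply_transform(as.matrix(q$atoms[, c("x", "y", "z")]), R, c(5, -3, 2))
  q2$atoms$x <- xyz[, 1]; q2$atoms$y <- xyz[, 2]; q2$atoms$z <- xyz[, 3]
  expect_equal(superpose(q2, p)$rmsd, base, tolerance = 1e-9)
})

test_that("PDB write/read round-trips the data model", {
  p <- toy_peptide()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, path)
  p2 <- read_pdb(path)
  expect_identical(p2$atoms$name, p$atoms$name)
  expect_identical(p2$atoms$resid, p$atoms$resid)
  expect_identical(p2$atoms$resno, p$atoms$resno)
  expect_identical(p2$atoms$element, p$atoms$element)
  expect_lt(max(abs(as.matrix(p2$atoms[, c("x", "y", "z")]) -
                      as.matrix(p$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("read_pdb errors on missing or record-free files", {
  expect_error(read_pdb(file.path(tempdir(), "no_such_file.pdb")),
               "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), empty)
  expect_error(read_pdb(empty), "ATOM|parse")
})

test_that("altloc records resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   SER A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   SER A   1       1.500   2.400   0.000  1.00  0.00           O",
    "ATOM      5  CB ASER A   1       2.000  -1.000   1.000  0.40  0.00           C",
    "ATOM      6  CB BSER A   1       2.000  -1.000  -1.000  0.60  0.00           C",
    "END"), path)
  expect_warning(p <- read_pdb(path), "alternate-location")
  cb <- p$atoms[p$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$z, -1, tolerance = 1e-6)  # occupancy 0.60 wins
})

test_that("HETATM records follow ATOM records of the same chain on write", {
  p <- toy_peptide(c("ALA", "VAL"))
  het <- p$atoms[1, ]
  het$name <- "MG"; het$element <- "MG"; het$resid <- "MG"
  het$resno <- 900L; het$het <- TRUE
  p$atoms <- rbind(het, p$atoms)  # heteroatom listed first in memory
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, path)
  lines <- readLines(path)
  first_het <- min(grep("^HETATM", lines))
  last_atom <- max(grep("^ATOM", lines))
  expect_gt(first_het, last_atom)
  p2 <- read_pdb(path)
  expect_equal(sum(p2$atoms$het), 1L)
  expect_equal(p2$atoms$element[p2$atoms$het], "MG")
})

test_that("serial numbers beyond the PDB field width wrap with a warning", {
  p <- toy_peptide(rep("GLY", 4))
  big <- p
  idx <- rep(seq_len(nrow(p$atoms)), length.out = 100010)
  big$atoms <- p$atoms[idx, ]
  big$atoms$resno <- rep(seq_len(ceiling(100010 / 4)), each = 4)[seq_len(100010)]
  path <- withr::local_tempfile(fileext = ".pdb")
  expect_warning(write_pdb(big, path), "wrapped")
  expect_gt(length(readLines(path)), 100000)
})

test_that("SDF round trip preserves atoms, bonds and torsion detection", {
  but <- toy_butane()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(but, path, tags = list(c(score = "-1.5")))
  b2 <- read_ligand_sdf(path)
  expect_equal(nrow(b2$atoms), 4L)
  expect_equal(nrow(b2$bonds), 3L)
  expect_lt(max(abs(covflex:::ligand_xyz(b2) - covflex:::ligand_xyz(but))),
            1e-4)
  expect_length(b2$rotatable, 1L)
})

test_that("rotatable torsion detection follows the single/acyclic/non-terminal rule", {
  expect_length(toy_ethane()$rotatable, 0L)
  but <- toy_butane()
  expect_length(but$rotatable, 1L)
  expect_equal(but$rotatable[[1L]], c(1L, 2L, 3L, 4L))
  expect_length(toy_cyclohexane()$rotatable, 0L)
  # a double bond is never rotatable
  ene <- ligand(toy_butane()$atoms,
                data.frame(i = 1:3, j = 2:4, order = c(1, 2, 1)),
                name = "butene")
  expect_length(ene$rotatable, 0L)
})

test_that("2D-flagged SDF input is rejected with 3D advice", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("flat", "  prog            2D", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "  1  2  1  0", "M  END", "$$$$"), path)
  expect_error(read_ligand_sdf(path), "2D")
})

test_that("residue lookup is total and keys must be unique", {
  p <- toy_peptide()
  expect_error(get_residue(p, "A", 99), "not found")
  expect_equal(get_residue(p, "A", 2)$resid[1], "SER")
  bad <- p$atoms
  bad$resid[bad$resno == 2] <- "ALA"
  bad$resid[bad$resno == 2][1] <- "SER"
  expect_error(protein(bad), "not unique")
})
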