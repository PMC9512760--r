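# Side-chain construction, rotamer repacking and continuous refinement.

test_that("build_sidechain inverts chi measurement and honours templates", {
  p <- toy_peptide(c("MET", "LYS", "TYR", "ALA"))
  met <- build_sidechain(get_residue(p, "A", 1), c(55, -170, 100))
  expect_equal(unname(chi_angles(met)), c(55, -170), tolerance = 1e-3)
  expect_equal(unname(covflex:::measure_chis(met)), c(55, -170, 100),
               tolerance = 1e-3)
  # LYS: 5 side-chain heavy atoms beyond the backbone, template bond
  # lengths reproduced
  lys <- build_sidechain(get_residue(p, "A", 2), c(-60, 180, 180, 60))
  sc_names <- setdiff(lys$name, c("N", "CA", "C", "O"))
  expect_setequal(sc_names, c("CB", "CG", "CD", "CE", "NZ"))
  g <- function(n) covflex:::residue_atom_xyz(lys, n)
  lens <- c(sqrt(sum((g("CB") - g("CG"))^2)),
            sqrt(sum((g("CG") - g("CD"))^2)),
            sqrt(sum((g("CD") - g("CE"))^2)),
            sqrt(sum((g("CE") - g("NZ"))^2)))
  expect_equal(lens, c(1.520, 1.520, 1.520, 1.489), tolerance = 1e-3)
  # ALA is a no-op; chi-count mismatches error
  ala <- get_residue(p, "A", 4)
  expect_identical(build_sidechain(ala, numeric(0)), ala)
  expect_error(build_sidechain(get_residue(p, "A", 1), c(60)), "chi")
  expect_error(build_sidechain(ala, c(60)), "no chi")
})

test_that("the rotamer library covers all template types and loads from file", {
  lib <- default_rotamer_library()
  for (ty in names(lib)) {
    expect_gte(nrow(lib[[ty]]$chis), 3L)
    expect_lte(nrow(lib[[ty]]$chis), 9L)
    expect_equal(sum(lib[[ty]]$weights), 1, tolerance = 1e-9)
    expect_equal(ncol(lib[[ty]]$chis), n_chi(ty))
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_type chi1 weight", "SER -65 2", "SER 175 1"), path)
  custom <- load_rotamer_library(path)
  expect_equal(nrow(custom$SER$chis), 2L)
  expect_equal(custom$SER$weights, c(2, 1) / 3)
})

repack_fixture <- function(seed, difficulty = "blocking") {
  sys <- make_minipocket(seed, difficulty)
  adduct <- adduct_form(sys$lig, sys$warhead)
  geo <- covflex:::reactive_sg(sys$receptor, sys$site, sys$truth$chi1)
  pose <- list(xyz = sys$reference_xyz, cys_chi1 = sys$truth$chi1,
               sg = geo$sg, cb = geo$cb,
               reactive_atom = sys$warhead$reactive_atom)
  list(sys = sys, adduct = adduct, pose = pose)
}

test_that("repacking never increases the energy", {
  for (s in c(21, 22, 23)) {
    fx <- repack_fixture(s)
    rp <- repack_site(fx$sys$receptor, fx$pose, fx$adduct, fx$sys$site,
                      seed = s)
    expect_lte(rp$energy_after, rp$energy_before + 1e-9)
  }
})

test_that("repacking an already-repacked site leaves the energy unchanged", {
  # idempotence: once the repacker has chosen its optimum, a second pass
  # from that state finds nothing to improve
  for (s in c(31, 32, 33, 34, 35)) {
    sys <- make_minipocket(s, "easy")
    adduct <- adduct_form(sys$lig, sys$warhead)
    geo <- covflex:::reactive_sg(sys$receptor_open, sys$site,
                                 sys$truth$chi1)
    pose <- list(xyz = sys$reference_xyz, cys_chi1 = sys$truth$chi1,
                 sg = geo$sg, cb = geo$cb,
                 reactive_atom = sys$warhead$reactive_atom)
    rp1 <- repack_site(sys$receptor_open, pose, adduct, sys$site,
                       seed = s, refine = FALSE)
    rp2 <- repack_site(rp1$structure, pose, adduct, sys$site,
                       seed = s + 1, refine = FALSE)
    expect_equal(rp2$energy_after, rp2$energy_before, tolerance = 1e-6)
    expect_lte(rp2$energy_after, rp1$energy_after + 1e-6)
  }
})

test_that("repacking moves a planted blocking rotamer out of the pose", {
  fx <- repack_fixture(24)
  blk <- fx$sys$site$blocking[1]
  pl <- fx$sys$truth$planted[[blk]]
  k <- covflex:::parse_residue_key(blk)
  before <- covflex:::measure_chis(get_residue(fx$sys$receptor, k$chain,
                                               k$resno))
  expect_lt(abs(covflex:::wrap180(before[1] - pl$closed_chis[1])), 1e-3)
  rp <- repack_site(fx$sys$receptor, fx$pose, fx$adduct, fx$sys$site,
                    seed = 24)
  after <- covflex:::measure_chis(get_residue(rp$structure, k$chain,
                                              k$resno))
  # moved away from the closed chi1 toward a non-clashing rotamer
  expect_gt(abs(covflex:::wrap180(after[1] - pl$closed_chis[1])), 30)
  expect_lte(rp$energy_after, rp$energy_before)
})

test_that("small instances reach the exhaustive-enumeration optimum", {
  lib <- default_rotamer_library()
  params <- score_params()
  n_hit <- 0L
  n_tot <- 0L
  for (s in 41:52) {
    sys <- make_minipocket(s, "blocking")
    flex3 <- utils::head(sys$site$flexible, 3)
    site <- binding_site_spec(sys$site$reactive, flex3)
    adduct <- adduct_form(sys$lig, sys$warhead)
    geo <- covflex:::reactive_sg(sys$receptor, sys$site, sys$truth$chi1)
    pose <- list(xyz = sys$reference_xyz, cys_chi1 = sys$truth$chi1,
                 sg = geo$sg, cb = geo$cb,
                 reactive_atom = sys$warhead$reactive_atom)
    got <- repack_exhaustive_gap(sys$receptor, pose, adduct, site, lib,
                                 params, seed = s)
    n_tot <- n_tot + 1L
    if (got$gap <= 1e-6) n_hit <- n_hit + 1L
  }
  expect_gte(n_hit / n_tot, 0.9)
})

test_that("refinement converges near a dense-scan optimum and preserves geometry", {
  fx <- repack_fixture(25, "easy")
  rp <- repack_site(fx$sys$receptor_open, fx$pose, fx$adduct,
                    fx$sys$site, seed = 25, refine = TRUE)
  chk <- check_adduct_geometry(fx$pose$sg, fx$pose$cb,
                               rp$lig_xyz[fx$sys$warhead$reactive_atom, ],
                               fx$sys$warhead)
  expect_true(chk$pass)
  # one-residue dense-scan oracle on a constructed smooth landscape: a
  # lone serine and a single fixed carbon probe placed so that the
  # attraction well has one minimum in chi1. Refinement started 10
  # degrees off must land within 1 degree of a 0.1-degree scan minimum.
  pep <- toy_peptide(c("ALA", "CYS", "SER"), chis = list(NULL, 180, 60))
  ser <- get_residue(pep, "A", 3)
  nn <- covflex:::residue_atom_xyz(ser, "N")
  nca <- covflex:::residue_atom_xyz(ser, "CA")
  ncb <- covflex:::residue_atom_xyz(ser, "CB")
  chi_true <- 37
  og_true <- covflex:::sidechain_xyz(nn, nca, ncb, "SER", chi_true)["OG", ]
  probe_pos <- og_true + 3.3 * covflex:::vunit(og_true - ncb)
  probe <- ligand(data.frame(element = "C", x = probe_pos[1],
                             y = probe_pos[2], z = probe_pos[3]),
                  data.frame(i = integer(), j = integer(),
                             order = integer()), "probe")
  pose <- list(xyz = covflex:::ligand_xyz(probe), reactive_atom = 1L)
  site1 <- binding_site_spec("A:2", "A:3")
  start <- covflex:::set_residue_atoms(pep, "A", 3,
                                       build_sidechain(ser, chi_true + 10))
  scan_obj <- function(v) {
    st <- covflex:::set_residue_atoms(pep, "A", 3,
                                      build_sidechain(ser, v))
    repack_site(st, pose, probe, site1, seed = 1, n_starts = 0,
                n_sweeps = 0, refine = FALSE)$energy_before
  }
  grid <- seq(chi_true - 10, chi_true + 20, by = 0.1)
  scan_best <- grid[which.min(vapply(grid, scan_obj, numeric(1)))]
  rp2 <- refine_continuous(start, pose, probe, site1)
  got <- covflex:::measure_chis(get_residue(rp2$structure, "A", 3))[1]
  expect_lt(abs(covflex:::wrap180(got - scan_best)), 1)
})

test_that("repacking is equivariant under rigid motion of the whole system", {
  fx <- repack_fixture(26)
  rp1 <- repack_site(fx$sys$receptor, fx$pose, fx$adduct, fx$sys$site,
                     seed = 5)
  R <- covflex:::rotation_about_axis(c(2, 1, 3), 63)
  tv <- c(4, -7, 2)
  rec2 <- fx$sys$receptor
  xyz <- apply_transform(as.matrix(rec2$atoms[, c("x", "y", "z")]), R, tv)
  rec2$atoms$x <- xyz[, 1]; rec2$atoms$y <- xyz[, 2]; rec2$atoms$z <- xyz[, 3]
  pose2 <- fx$pose
  pose2$xyz <- apply_transform(fx$pose$xyz, R, tv)
  pose2$sg <- as.vector(R %*% fx$pose$sg + tv)
  pose2$cb <- as.vector(R %*% fx$pose$cb + tv)
  rp2 <- repack_site(rec2, pose2, fx$adduct, fx$sys$site, seed = 5)
  expect_equal(rp2$energy_before, rp1$energy_before, tolerance = 1e-6)
  expect_equal(rp2$energy_after, rp1$energy_after, tolerance = 1e-6)
})
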