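# The synthetic mini-pocket generator: determinism, planted invariants,
# ensemble construction, and on-disk round trips.

test_that("generation is deterministic in the seed", {
  a <- make_minipocket(7, "blocking")
  b <- make_minipocket(7, "blocking")
  expect_identical(a$receptor$atoms, b$receptor$atoms)
  expect_identical(a$reference_xyz, b$reference_xyz)
  expect_identical(a$truth, b$truth)
  c1 <- make_minipocket(8, "blocking")
  expect_false(identical(a$receptor$atoms, c1$receptor$atoms))
})

test_that("difficulty controls the number of planted blocking residues", {
  expect_length(make_minipocket(5, "easy")$site$blocking, 0L)
  expect_length(make_minipocket(5, "blocking")$site$blocking, 1L)
  expect_length(make_minipocket(5, "multiblocking")$site$blocking, 2L)
})

test_that("generated systems satisfy the planted invariants", {
  for (s in c(2, 9, 14)) {
    sys <- make_minipocket(s, "blocking")
    adduct <- adduct_form(sys$lig, sys$warhead)
    hv <- covflex:::heavy_indices(adduct)
    geo <- covflex:::reactive_sg(sys$receptor, sys$site, sys$truth$chi1)
    chk <- check_adduct_geometry(geo$sg, geo$cb,
                                 sys$reference_xyz[sys$warhead$reactive_atom, ],
                                 sys$warhead)
    expect_true(chk$pass)
    # zero repulsion against the open-state receptor
    open_grp <- covflex:::receptor_group(
      covflex:::receptor_context_atoms(sys$receptor_open, sys$site,
                                       include_flexible_sc = TRUE))
    sc <- score_pose(adduct, sys$reference_xyz, open_grp, score_params())
    expect_equal(unname(sc$terms["repulsion"]), 0)
    # the delivered (closed) receptor hard-clashes the reference pose
    blk <- covflex:::parse_residue_key(sys$site$blocking[1])
    res <- get_residue(sys$receptor, blk$chain, blk$resno)
    sc_atoms <- covflex:::sidechain_heavy(res)
    d <- covflex:::cross_dist(as.matrix(sc_atoms[, c("x", "y", "z")]),
                              sys$reference_xyz[hv, , drop = FALSE])
    rsum <- outer(vdw_radius(sc_atoms$element),
                  vdw_radius(adduct$atoms$element[hv]), "+")
    expect_true(any(d < 0.7 * rsum))
    # sizes within the declared envelope
    nres <- nrow(residue_table(sys$receptor))
    expect_gte(nres, 40L)
    expect_lte(nres, 60L)
    nheavy <- length(covflex:::heavy_indices(sys$lig))
    expect_gte(nheavy, 6L)
    expect_lte(nheavy, 20L)
  }
})

test_that("fixture ligands follow the declared torsion envelope", {
  for (s in 1:6) {
    sys <- make_minipocket(s, "easy")
    nt <- length(adduct_form(sys$lig, sys$warhead)$rotatable)
    expect_gte(nt, 0L)
    expect_lte(nt, 4L)
  }
})

test_that("ensembles recover the planted flexible set at default thresholds", {
  ens <- make_ensemble(12, 10)
  rt <- residue_table(ens$system$receptor)
  prof <- profile_ensemble(ens$structures, rt$key)
  flex_found <- prof$key[!is.na(prof$classification) &
                           prof$classification == "flexible"]
  expect_setequal(intersect(flex_found, ens$truth$flexible_keys),
                  ens$truth$flexible_keys)          # sensitivity 1
  expect_length(setdiff(flex_found,
                        c(ens$truth$flexible_keys,
                          ens$system$site$reactive)), 0L)  # no false hits
})

test_that("a jitter-only ensemble classifies everything rigid", {
  sys <- make_minipocket(13, "easy")
  with_jitter <- lapply(1:5, function(k) {
    p <- sys$receptor_open
    set.seed(1000 + k)
    p$atoms[, c("x", "y", "z")] <- p$atoms[, c("x", "y", "z")] +
      matrix(runif(nrow(p$atoms) * 3, -0.05, 0.05), ncol = 3)
    p
  })
  prof <- profile_ensemble(with_jitter, residue_table(sys$receptor)$key)
  expect_true(all(prof$classification == "rigid", na.rm = TRUE))
})

test_that("two identical members make a zero-variance rigid ensemble", {
  sys <- make_minipocket(13, "easy")
  prof <- profile_ensemble(list(sys$receptor_open, sys$receptor_open),
                           residue_table(sys$receptor)$key)
  expect_true(all(prof$classification == "rigid", na.rm = TRUE))
})

test_that("on-disk fixture round trip preserves the system", {
  sys <- make_minipocket(16, "blocking")
  dir <- withr::local_tempdir()
  write_minipocket(sys, dir, prefix = "fx")
  rec <- read_pdb(file.path(dir, "fx_receptor.pdb"))
  expect_equal(nrow(rec$atoms), nrow(sys$receptor$atoms))
  lig <- read_ligand_sdf(file.path(dir, "fx_ligand.sdf"))
  expect_equal(nrow(lig$atoms), nrow(sys$lig$atoms))
  expect_equal(lig$bonds$order, sys$lig$bonds$order)
  site <- read_site_spec(file.path(dir, "fx_site.yaml"))
  expect_equal(site$blocking, sys$site$blocking)
  wh <- read_site_warhead(file.path(dir, "fx_site.yaml"))
  expect_equal(wh$reactive_atom, sys$warhead$reactive_atom)
  ref <- read_ligand_sdf(file.path(dir, "fx_reference.sdf"))
  expect_lt(max(abs(covflex:::ligand_xyz(ref) - sys$reference_xyz)), 1e-4)
  truth <- jsonlite::read_json(file.path(dir, "fx_truth.json"))
  expect_equal(truth$anchor$chi1, sys$truth$chi1)
})

test_that("end-to-end: profiling an ensemble feeds a successful dock", {
  hits <- 0L
  for (s in 17:20) {
    sys <- make_minipocket(s, "blocking")
    ens <- make_ensemble(s, 8, system = sys)
    rt <- residue_table(sys$receptor)
    prof <- profile_ensemble(ens$structures, rt$key)
    flex_found <- prof$key[!is.na(prof$classification) &
                             prof$classification == "flexible"]
    ref_lig <- adduct_form(sys$lig, sys$warhead)
    ref_lig$atoms[, c("x", "y", "z")] <- sys$reference_xyz
    blk <- detect_blocking(ens$structures, list(ref_lig), flex_found)
    site <- binding_site_spec(sys$site$reactive,
                              setdiff(flex_found, sys$site$reactive),
                              blocking = blk$key)
    res <- dock_covalent(sys$receptor, sys$lig,
                         dock_config(site, sys$warhead, seed = s))
    hv <- covflex:::heavy_indices(sys$lig)
    rms <- vapply(res$poses, function(p)
      heavy_rmsd(p$lig_xyz, sys$reference_xyz, hv), numeric(1))
    if (length(rms) && min(rms) <= 2.0) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})
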