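# Covalent pose enumeration, geometry filtering, scoring, clustering and
# the full docking pipeline.

make_dock_cfg <- function(sys, ...) dock_config(sys$site, sys$warhead, ...)

test_that("enumeration count is rotamers x spin grid for a torsion-free ligand", {
  sys <- make_minipocket(1, "easy")
  # butane has one rotatable torsion in its plain form but none through
  # the warhead contract below: use ethane-like two-carbon ligand
  lig <- ligand(data.frame(element = c("C", "C", "C"),
                           x = c(0, 1.52, 2.2), y = c(0, 0, 1.3),
                           z = c(0, 0, 0.2)),
                data.frame(i = c(1, 2), j = c(2, 3), order = 1), "propane")
  wh <- warhead_spec(2L)  # central carbon: two neighbours, no twist axis
  cfg <- dock_config(sys$site, wh, torsion_grid_degrees = 30,
                     n_cys_rotamers = 3)
  empty_rec <- sys$receptor
  empty_rec$atoms <- empty_rec$atoms[empty_rec$atoms$resno == 3, ,
                                     drop = FALSE]
  cands <- enumerate_poses(empty_rec, lig, cfg)
  expect_equal(attr(cands, "n_enumerated"), 3L * 12L)
  expect_gt(length(cands), 0L)
})

test_that("pre-filter retains all candidates against an atom-free pocket and drops all in a filled one", {
  sys <- make_minipocket(2, "easy")
  cfg <- make_dock_cfg(sys)
  cands_open <- enumerate_poses(sys$receptor, sys$lig, cfg)
  expect_gt(length(cands_open), 0L)
  # fill the pocket with a dense carbon slab around the anchor
  k <- covflex:::parse_residue_key(sys$site$reactive)
  ca <- covflex:::residue_atom_xyz(get_residue(sys$receptor, k$chain,
                                               k$resno), "CA")
  grid <- expand.grid(x = seq(-8, 8, 1.2), y = seq(-8, 8, 1.2),
                      z = seq(-8, 8, 1.2))
  slab <- data.frame(name = "C", resid = "UNK", chain = "Z",
                     resno = 999L, ins = "", x = ca[1] + grid$x,
                     y = ca[2] + grid$y, z = ca[3] + grid$z,
                     element = "C", het = FALSE)
  filled <- sys$receptor
  filled$atoms <- rbind(filled$atoms, slab)
  cands_blocked <- enumerate_poses(filled, sys$lig, cfg)
  expect_length(cands_blocked, 0L)
  expect_equal(attr(cands_blocked, "diagnostic"), "pocket blocked")
})

test_that("adduct geometry checks pass at target and fail off-tolerance", {
  wh <- warhead_spec(1L)  # targets 1.81 A / 100 deg, tol 0.3 / 20
  cb <- c(0, 0, 0)
  sg <- c(1.81, 0, 0)
  at_target <- sg + 1.81 * c(cos(pi * (180 - 100) / 180),
                             sin(pi * (180 - 100) / 180), 0)
  chk <- check_adduct_geometry(sg, cb, at_target, wh)
  expect_true(chk$pass)
  expect_equal(chk$bond_length, 1.81, tolerance = 1e-6)
  expect_equal(chk$bond_angle, 100, tolerance = 1e-6)
  far <- sg + 3.0 * c(cos(pi * 80 / 180), sin(pi * 80 / 180), 0)
  expect_false(check_adduct_geometry(sg, cb, far, wh)$pass)
  bad_angle <- sg + 1.81 * c(cos(pi * (180 - 140) / 180),
                             sin(pi * (180 - 140) / 180), 0)
  expect_false(check_adduct_geometry(sg, cb, bad_angle, wh)$pass)
})

test_that("score decomposes exactly and matches a brute-force double loop", {
  sys <- make_minipocket(3, "easy")
  adduct <- adduct_form(sys$lig, sys$warhead)
  k <- covflex:::parse_residue_key(sys$site$reactive)
  ctx <- covflex:::receptor_context_atoms(sys$receptor, sys$site,
                                          include_flexible_sc = TRUE)
  grp <- covflex:::receptor_group(ctx)
  params <- score_params()
  brute <- function(lg) {
    rep_t <- 0
    attr_rows <- numeric(nrow(lg$xyz))
    hb <- 0
    for (i in seq_len(nrow(lg$xyz))) for (j in seq_len(nrow(grp$xyz))) {
      d <- sqrt(sum((lg$xyz[i, ] - grp$xyz[j, ])^2))
      d_on <- params$clash_onset_fraction * (lg$radius[i] + grp$radius[j])
      if (d < d_on) rep_t <- rep_t + (d_on - d)^2
      else {
        r <- (params$attr_range - d) / (params$attr_range - d_on)
        attr_rows[i] <- attr_rows[i] + min(max(r, 0), 1)
      }
      ang_ok <- function(root, don, acc)
        !all(is.finite(root)) || angle3(root, don, acc) > params$hb_angle_min
      if (lg$donor[i] && grp$acceptor[j] &&
          d >= params$hb_distance_range[1] &&
          d <= params$hb_distance_range[2] &&
          ang_ok(lg$root[i, ], lg$xyz[i, ], grp$xyz[j, ])) hb <- hb + 1
      if (grp$donor[j] && lg$acceptor[i] &&
          d >= params$hb_distance_range[1] &&
          d <= params$hb_distance_range[2] &&
          ang_ok(grp$root[j, ], grp$xyz[j, ], lg$xyz[i, ])) hb <- hb + 1
    }
    c(rep_t, -sum(pmin(attr_rows, params$attr_atom_cap)), -hb)
  }
  set.seed(31)
  for (trial in 1:20) {
    xyz <- covflex:::ligand_xyz(adduct)
    xyz <- sweep(xyz, 2, rnorm(3, 0, 4), "+")
    sc <- score_pose(adduct, xyz, grp, params)
    ref <- brute(covflex:::ligand_group(adduct, xyz))
    expect_equal(unname(sc$terms[c("repulsion", "attraction", "hbond")]),
                 ref, tolerance = 1e-9)
    expect_equal(sc$total,
                 params$w_rep * sc$terms[["repulsion"]] +
                   params$w_attr * sc$terms[["attraction"]] +
                   params$w_hb * sc$terms[["hbond"]] +
                   params$w_tors * sc$terms[["torsion"]],
                 tolerance = 1e-12)
  }
})

test_that("a distant ligand scores only its torsion strain", {
  sys <- make_minipocket(4, "easy")
  adduct <- adduct_form(sys$lig, sys$warhead)
  grp <- covflex:::receptor_group(
    covflex:::receptor_context_atoms(sys$receptor, sys$site,
                                     include_flexible_sc = TRUE))
  xyz <- covflex:::ligand_xyz(adduct)
  xyz[, 1] <- xyz[, 1] + 50
  sc <- score_pose(adduct, xyz, grp, score_params())
  expect_equal(unname(sc$terms[c("repulsion", "attraction", "hbond")]),
               c(0, 0, 0))
})

test_that("repulsion is exactly zero at the clash-onset boundary", {
  params <- score_params()
  A <- covflex:::make_group(matrix(c(0, 0, 0), 1), "C", FALSE, FALSE)
  d_on <- params$clash_onset_fraction * (1.7 + 1.7)
  B <- covflex:::make_group(matrix(c(d_on, 0, 0), 1), "C", FALSE, FALSE)
  it <- covflex:::interaction_terms(A, B, params)
  expect_equal(it$repulsion, 0)
  B2 <- covflex:::make_group(matrix(c(d_on - 0.01, 0, 0), 1), "C", FALSE,
                             FALSE)
  expect_gt(covflex:::interaction_terms(A, B2, params)$repulsion, 0)
})

test_that("translating a ligand into a receptor atom never decreases repulsion", {
  params <- score_params()
  A <- covflex:::make_group(matrix(c(0, 0, 0), 1), "C", FALSE, FALSE)
  reps <- vapply(seq(4, 0.2, by = -0.2), function(d) {
    B <- covflex:::make_group(matrix(c(d, 0, 0), 1), "C", FALSE, FALSE)
    covflex:::interaction_terms(B, A, params)$repulsion
  }, numeric(1))
  expect_true(all(diff(reps) >= 0))
})

test_that("greedy leader clustering matches a brute-force oracle", {
  set.seed(12)
  base <- matrix(rnorm(15), 5, 3)
  xyzs <- lapply(1:50, function(k) base + matrix(rnorm(15, 0, 1.2), 5, 3))
  scores <- rnorm(50)
  cl <- cluster_poses(xyzs, scores, cutoff = 1.5)
  # oracle: literal greedy leader pass
  ord <- order(scores, seq_along(scores))
  leaders <- integer(0)
  ref <- integer(50)
  for (i in ord) {
    hit <- 0L
    for (li in seq_along(leaders)) {
      if (sqrt(mean(rowSums((xyzs[[i]] - xyzs[[leaders[li]]])^2))) <= 1.5) {
        hit <- li
        break
      }
    }
    if (hit == 0L) {
      leaders <- c(leaders, i)
      hit <- length(leaders)
    }
    ref[i] <- hit
  }
  expect_identical(cl$cluster, ref)
  # representatives pairwise farther apart than the cutoff
  reps <- which(cl$representative)
  for (a in seq_along(reps)) for (b in seq_along(reps)) {
    if (a >= b) next
    expect_gt(sqrt(mean(rowSums((xyzs[[reps[a]]] - xyzs[[reps[b]]])^2))),
              1.5)
  }
  expect_equal(cluster_poses(xyzs[1], scores[1], 1.5)$cluster, 1L)
  expect_identical(cluster_poses(list(base, base), c(0, 1), 1.5)$cluster,
                   c(1L, 1L))
})

test_that("a fully substituted warhead carbon yields a geometry-infeasible diagnosis", {
  sys <- make_minipocket(5, "easy")
  # neopentane-like: central carbon with four substituents
  lig <- ligand(data.frame(element = rep("C", 5),
                           x = c(0, 1.5, -1.5, 0, 0),
                           y = c(0, 0, 0, 1.5, -1.5),
                           z = c(0, 0.5, 0.5, -0.5, -0.6)),
                data.frame(i = rep(1, 4), j = 2:5, order = 1), "neo")
  cfg <- dock_config(sys$site, warhead_spec(1L))
  res <- dock_covalent(sys$receptor, lig, cfg)
  expect_length(res$poses, 0L)
  expect_equal(res$report$diagnostic, "geometry infeasible")
})

test_that("every emitted pose satisfies the warhead geometry contract", {
  for (s in 11:13) {
    sys <- make_minipocket(s, "blocking")
    res <- dock_system(sys, n_refine = 10, n_continuous = 2)
    expect_gt(length(res$poses), 0L)
    for (p in res$poses) {
      expect_lte(abs(p$bond_length - sys$warhead$bond_length_target),
                 sys$warhead$bond_length_tol)
      expect_lte(abs(p$bond_angle - sys$warhead$bond_angle_target),
                 sys$warhead$bond_angle_tol)
    }
    # ranks are 1..n and scores non-decreasing
    expect_identical(vapply(res$poses, `[[`, 0L, "rank"),
                     seq_along(res$poses))
    expect_true(!is.unsorted(vapply(res$poses, `[[`, 0, "score_total")))
  }
})

test_that("docking is deterministic for identical inputs and seed", {
  sys <- make_minipocket(6, "blocking")
  r1 <- dock_system(sys, seed = 77, n_refine = 6, n_continuous = 2)
  r2 <- dock_system(sys, seed = 77, n_refine = 6, n_continuous = 2)
  expect_equal(length(r1$poses), length(r2$poses))
  for (i in seq_along(r1$poses)) {
    expect_identical(r1$poses[[i]]$lig_xyz, r2$poses[[i]]$lig_xyz)
    expect_identical(r1$poses[[i]]$score_total, r2$poses[[i]]$score_total)
  }
})

test_that("masking the blocking residue never reduces clash-filter survivors", {
  for (s in 7:9) {
    sys <- make_minipocket(s, "blocking")
    cfg <- make_dock_cfg(sys)
    cfg_rigid <- make_dock_cfg(sys, mode = "rigid")
    masked <- mutate_to(sys$receptor, sys$site$blocking, "ALA")$structure
    n_masked <- length(enumerate_poses(masked, sys$lig, cfg))
    n_closed <- length(enumerate_poses(sys$receptor, sys$lig, cfg_rigid))
    expect_gte(n_masked, n_closed)
  }
})
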