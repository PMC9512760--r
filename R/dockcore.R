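# Covalent docking engine. Anchor-first sampling: for each canonical
# cysteine chi1 rotamer the SG is placed from the backbone, the warhead
# carbon is positioned at the target adduct geometry, and ligand
# orientations are enumerated over rotation about the nascent S-C bond and
# a grid over internal rotatable torsions. Candidates clashing with the
# rigid part of the receptor are discarded, survivors are scored, the best
# are repacked/refined (flexible mode), clustered and ranked.
#
# Flexible mode mirrors the two workflow modifications for flexible
# pockets: blocking residues are mutated to alanine before enumeration and
# restored afterwards, and flexible side chains are repacked around each
# candidate pose. Rigid mode disables both (conventional covalent-docking
# baseline).

#' Docking job configuration
#'
#' @param site A [binding_site_spec()].
#' @param warhead A [warhead_spec()].
#' @param score [score_params()].
#' @param n_cys_rotamers Number of canonical cysteine chi1 rotamers
#'   (1-3, from -60/180/60).
#' @param torsion_grid_degrees Grid step for ligand torsions and for the
#'   rotation about the nascent S-C bond; must divide 360.
#' @param max_poses_out Maximum ranked poses emitted (default 20, matching
#'   top-20 evaluation).
#' @param n_refine Candidates carried into repacking after pre-scoring.
#' @param n_continuous Repacked candidates (best by energy) additionally
#'   polished by continuous torsional refinement.
#' @param cluster_rmsd_cutoff Greedy leader clustering cutoff, A.
#' @param seed Integer seed (repack multi-starts).
#' @param mode "flex" (blocking-residue mutation + repacking) or "rigid".
#' @param context_radius Receptor atoms beyond this distance from the
#'   reactive CB are ignored by scoring/filtering, A.
#' @param refine Logical: run continuous torsional refinement.
#' @return Object of class `dock_config`.
#' @export
dock_config <- function(site, warhead, score = score_params(),
                        n_cys_rotamers = 3, torsion_grid_degrees = 120,
                        max_poses_out = 20, n_refine = 20,
                        n_continuous = 5, cluster_rmsd_cutoff = 1.0,
                        seed = 1, mode = c("flex", "rigid"),
                        context_radius = 14, refine = TRUE) {
  mode <- match.arg(mode)
  if (max_poses_out < 1) stop("max_poses_out must be >= 1")
  if (360 %% torsion_grid_degrees != 0)
    stop("torsion_grid_degrees must divide 360")
  if (n_cys_rotamers < 1 || n_cys_rotamers > 3)
    stop("n_cys_rotamers must be 1..3")
  structure(list(site = site, warhead = warhead, score = score,
                 n_cys_rotamers = n_cys_rotamers,
                 torsion_grid_degrees = torsion_grid_degrees,
                 max_poses_out = max_poses_out, n_refine = n_refine,
                 n_continuous = n_continuous,
                 cluster_rmsd_cutoff = cluster_rmsd_cutoff, seed = seed,
                 mode = mode, context_radius = context_radius,
                 refine = refine), class = "dock_config")
}

CYS_CHI1_ROTAMERS <- c(-60, 180, 60)

# SG position for the reactive residue at a given chi1 (works on the
# alanine-masked residue: only N, CA, CB are needed)
reactive_sg <- function(receptor, site, chi1) {
  k <- parse_residue_key(site$reactive)
  res <- get_residue(receptor, k$chain, k$resno)
  n <- residue_atom_xyz(res, "N")
  ca <- residue_atom_xyz(res, "CA")
  cb <- residue_atom_xyz(res, "CB")
  if (is.null(cb)) {
    c_ <- residue_atom_xyz(res, "C")
    if (is.null(n) || is.null(ca) || is.null(c_)) return(NULL)
    cb <- ideal_cb(n, ca, c_)
  }
  if (is.null(n) || is.null(ca)) return(NULL)
  sg <- place_atom(n, ca, cb, 1.808, 113.8, chi1)
  list(n = n, ca = ca, cb = cb, sg = sg)
}

#' Check covalent adduct geometry
#'
#' @param sg,cb Cysteine SG and CB positions.
#' @param reactive_xyz Position of the ligand's reactive carbon.
#' @param warhead A [warhead_spec()].
#' @return List with `pass`, `bond_length` (SG-C, A) and `bond_angle`
#'   (CB-SG-C, degrees).
#' @export
check_adduct_geometry <- function(sg, cb, reactive_xyz, warhead) {
  bl <- vnorm(reactive_xyz - sg)
  ba <- angle3(cb, sg, reactive_xyz)
  list(pass = abs(bl - warhead$bond_length_target) <= warhead$bond_length_tol &&
         abs(ba - warhead$bond_angle_target) <= warhead$bond_angle_tol,
       bond_length = bl, bond_angle = ba)
}

# receptor atom subset used for clash filtering / scoring.
# include_flexible_sc: include side chains (beyond CB) of flexible
# residues. The reactive residue's side chain (CB/SG...) is always
# excluded (covalently bonded); waters are always excluded; other
# heteroatoms (nucleotide, ions) are rigid context.
receptor_context_atoms <- function(receptor, site, include_flexible_sc,
                                   center = NULL, radius = Inf) {
  a <- receptor$atoms
  a <- a[!(a$het & a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  a <- a[a$element != "H", , drop = FALSE]
  rk <- parse_residue_key(site$reactive)
  is_reactive <- !a$het & a$chain == rk$chain & a$resno == rk$resno
  a <- a[!(is_reactive & !a$name %in% BACKBONE_NAMES), , drop = FALSE]
  if (!include_flexible_sc && length(site$flexible)) {
    fk <- parse_residue_key(site$flexible)
    flex <- !a$het & paste(a$chain, a$resno) %in% paste(fk$chain, fk$resno)
    a <- a[!(flex & !a$name %in% c(BACKBONE_NAMES, "OXT", "CB")), ,
           drop = FALSE]
  }
  if (!is.null(center) && is.finite(radius)) {
    d <- sqrt((a$x - center[1L])^2 + (a$y - center[2L])^2 +
                (a$z - center[3L])^2)
    a <- a[d <= radius, , drop = FALSE]
  }
  a
}

# direction of the free valence at the reactive atom: opposite the mean of
# the existing bond directions; for a singly-bonded reactive carbon a
# tetrahedral (109.5 deg) direction with a deterministic azimuth (the
# azimuth is then sampled via the twist dimension). NULL when no usable
# direction exists (fully/symmetrically substituted carbon).
attachment_vector <- function(xyz, ra, nbrs) {
  if (length(nbrs) == 1L) {
    u <- vunit(xyz[nbrs, ] - xyz[ra, ])
    p <- c(0, 0, 1)
    if (abs(sum(p * u)) > 0.9) p <- c(1, 0, 0)
    p <- vunit(p - sum(p * u) * u)
    cos(109.5 / DEG) * u + sin(109.5 / DEG) * p
  } else {
    v <- -rowSums(vapply(nbrs, function(nb) vunit(xyz[nb, ] - xyz[ra, ]),
                         numeric(3)))
    if (vnorm(v) < 0.2) return(NULL)
    vunit(v)
  }
}

# Place a torsion-set conformer onto the covalent anchor: reactive atom at
# the target bond geometry (anti to CA about CB-SG), free valence aligned
# back along the nascent S-C bond, then `twist` about the reactive-carbon
# bond axis (single-neighbour carbons only) and `spin` about the S-C axis.
place_candidate <- function(adduct, ra, nbrs, base_xyz, geo, warhead,
                            torsions = numeric(0), spin = 0, twist = 0) {
  xyz <- base_xyz
  tors <- adduct$rotatable
  for (tk in seq_along(torsions))
    xyz <- set_torsion(adduct, xyz, tors[[tk]], torsions[tk])
  c_anchor <- place_atom(geo$ca, geo$cb, geo$sg, warhead$bond_length_target,
                         warhead$bond_angle_target, 180)
  u_cs <- vunit(geo$sg - c_anchor)
  v <- attachment_vector(xyz, ra, nbrs)
  if (is.null(v)) return(NULL)
  R <- rotation_between(v, u_cs)
  placed <- t(R %*% t(sweep(xyz, 2, xyz[ra, ])))
  placed <- sweep(placed, 2, c_anchor, "+")
  if (twist != 0 && length(nbrs) == 1L)
    placed <- rotate_about_line(placed, placed[ra, ],
                                placed[nbrs, ] - placed[ra, ], twist)
  if (spin != 0)
    placed <- rotate_about_line(placed, c_anchor, u_cs, spin)
  placed
}

#' Enumerate covalent pose candidates
#'
#' For each cysteine chi1 rotamer the warhead carbon is anchored at the
#' target bond geometry (anti to CA about the CB-SG axis); the ligand is
#' aligned so its free valence at the reactive carbon points back along
#' the nascent S-C bond, then rotated about that bond and over a grid of
#' internal torsion combinations. Candidates with any heavy-atom distance
#' below the clash onset against the non-flexible receptor context are
#' discarded (flexible side chains are excluded from this hard filter in
#' flex mode because repacking may move them).
#'
#' @param receptor A [protein()] (blocking residues may already be
#'   alanine-masked).
#' @param lig A [ligand()] in its SDF (pre-reaction) form.
#' @param config A [dock_config()].
#' @return List of candidate poses (`xyz`, `cys_chi1`, `spin`,
#'   `torsions`, `index`, `bond_length`, `bond_angle`), with attributes
#'   `n_enumerated` and `n_clash_pass`.
#' @export
enumerate_poses <- function(receptor, lig, config) {
  warhead <- config$warhead
  adduct <- adduct_form(lig, warhead)
  ra <- warhead$reactive_atom
  g <- ligand_graph(adduct)
  nbrs <- as.integer(igraph::neighbors(g, ra))
  empty <- function(reason) {
    out <- list()
    attr(out, "n_enumerated") <- 0L
    attr(out, "n_clash_pass") <- 0L
    attr(out, "diagnostic") <- reason
    out
  }
  if (length(nbrs) == 0 || length(nbrs) >= 4)
    return(empty("geometry infeasible"))
  chi1s <- CYS_CHI1_ROTAMERS[seq_len(config$n_cys_rotamers)]
  gstep <- config$torsion_grid_degrees
  grid_vals <- seq(-180 + gstep, 180, by = gstep)
  tors <- adduct$rotatable
  tor_grid <- if (length(tors))
    as.matrix(expand.grid(rep(list(grid_vals), length(tors))))
  else matrix(numeric(0), 1, 0)
  # receptor clash context (empty receptor -> no filtering)
  rk <- parse_residue_key(config$site$reactive)
  anchor_res <- tryCatch(get_residue(receptor, rk$chain, rk$resno),
                         error = function(e) NULL)
  if (is.null(anchor_res)) return(empty("geometry infeasible"))
  center <- residue_atom_xyz(anchor_res, "CA")
  ctx <- receptor_context_atoms(receptor, config$site,
                                include_flexible_sc = config$mode == "rigid",
                                center = center,
                                radius = config$context_radius +
                                  max(cross_dist(ligand_xyz(lig),
                                                 ligand_xyz(lig))) / 1)
  ctx_xyz <- as.matrix(ctx[, c("x", "y", "z")])
  ctx_rad <- if (nrow(ctx)) vdw_radius(ctx$element) else numeric(0)
  hv <- heavy_indices(adduct)
  lig_rad <- vdw_radius(adduct$atoms$element[hv])
  f <- config$score$clash_onset_fraction
  base_xyz <- ligand_xyz(adduct)
  twist_vals <- if (length(nbrs) == 1L) grid_vals else 0
  out <- list()
  n_enum <- 0L
  rsum_f <- if (nrow(ctx)) f * outer(lig_rad, ctx_rad, "+") else NULL
  for (chi1 in chi1s) {
    geo <- reactive_sg(receptor, config$site, chi1)
    if (is.null(geo)) next
    c_anchor <- place_atom(geo$ca, geo$cb, geo$sg, warhead$bond_length_target,
                           warhead$bond_angle_target, 180)
    u_cs <- vunit(geo$sg - c_anchor)
    for (ti in seq_len(nrow(tor_grid))) {
      tvals <- if (ncol(tor_grid)) tor_grid[ti, ] else numeric(0)
      placed0 <- place_candidate(adduct, ra, nbrs, base_xyz, geo, warhead,
                                 torsions = tvals)
      if (is.null(placed0)) next
      for (twist in twist_vals) {
        ptw <- if (twist != 0 && length(nbrs) == 1L)
          rotate_about_line(placed0, placed0[ra, ],
                            placed0[nbrs, ] - placed0[ra, ], twist)
        else placed0
        for (spin in grid_vals) {
          pxyz <- if (spin != 0)
            rotate_about_line(ptw, c_anchor, u_cs, spin) else ptw
          n_enum <- n_enum + 1L
          chk <- check_adduct_geometry(geo$sg, geo$cb, pxyz[ra, ], warhead)
          if (!chk$pass) next
          if (nrow(ctx)) {
            d <- cross_dist(pxyz[hv, , drop = FALSE], ctx_xyz)
            if (any(d < rsum_f)) next
          }
          out[[length(out) + 1L]] <- list(
            xyz = pxyz, cys_chi1 = chi1, spin = spin, twist = twist,
            torsions = tvals, sg = geo$sg, cb = geo$cb,
            bond_length = chk$bond_length, bond_angle = chk$bond_angle,
            index = n_enum)
        }
      }
    }
  }
  attr(out, "n_enumerated") <- n_enum
  attr(out, "n_clash_pass") <- length(out)
  attr(out, "diagnostic") <- if (n_enum == 0L) "geometry infeasible"
    else if (length(out) == 0L) "pocket blocked" else "ok"
  out
}

#' Greedy leader clustering of poses by ligand RMSD
#'
#' Poses are visited by ascending score; a pose joins the first cluster
#' whose leader lies within `cutoff` heavy-atom RMSD (identity atom
#' mapping, shared receptor frame, no re-superposition), else founds a new
#' cluster. The representative of each cluster is its lowest-score member.
#'
#' @param xyz_list List of ligand coordinate matrices (same atom order).
#' @param scores Numeric scores (lower better).
#' @param cutoff RMSD cutoff, A.
#' @param heavy Integer rows used for the RMSD (default all rows).
#' @return List with `cluster` (integer ids, input order) and
#'   `representative` (logical, input order).
#' @export
cluster_poses <- function(xyz_list, scores, cutoff,
                          heavy = seq_len(nrow(xyz_list[[1L]]))) {
  stopifnot(length(xyz_list) >= 1, length(scores) == length(xyz_list))
  ord <- order(scores, seq_along(scores))
  leaders <- integer(0)
  cl <- integer(length(xyz_list))
  for (i in ord) {
    assigned <- FALSE
    for (li in seq_along(leaders)) {
      r <- sqrt(mean(rowSums((xyz_list[[i]][heavy, , drop = FALSE] -
                                xyz_list[[leaders[li]]][heavy, , drop = FALSE])^2)))
      if (r <= cutoff) {
        cl[i] <- li
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      leaders <- c(leaders, i)
      cl[i] <- length(leaders)
    }
  }
  rep_flag <- logical(length(xyz_list))
  rep_flag[leaders] <- TRUE
  list(cluster = cl, representative = rep_flag)
}

#' Covalent docking of one ligand into one receptor
#'
#' Full pipeline: (flex mode) mask blocking residues as alanine ->
#' enumerate anchored candidates against the opened pocket -> restore
#' identities -> pre-score -> repack flexible side chains and refine the
#' best `n_refine` candidates -> cluster -> rank -> truncate. Rigid mode
#' skips masking and repacking. Deterministic given `config$seed`.
#'
#' @param receptor A [protein()] containing the reactive cysteine.
#' @param lig A [ligand()] (pre-reaction form with declared warhead).
#' @param config A [dock_config()].
#' @param rotamer_library Library for repacking (default
#'   [default_rotamer_library()]).
#' @return Object of class `dock_result`: `poses` (ranked list of covalent
#'   poses), `receptor` (restored input receptor), `report` (stage
#'   counters and diagnostic), `config`.
#' @export
dock_covalent <- function(receptor, lig, config,
                          rotamer_library = default_rotamer_library()) {
  stopifnot(inherits(config, "dock_config"))
  site <- config$site
  adduct <- adduct_form(lig, config$warhead)
  ra <- config$warhead$reactive_atom
  hv <- heavy_indices(adduct)
  mut_records <- list()
  work <- receptor
  if (config$mode == "flex" && length(site$blocking)) {
    masked <- mutate_to(receptor, site$blocking, "ALA")
    work <- masked$structure
    mut_records <- masked$records
  }
  cands <- enumerate_poses(work, lig, config)
  report <- list(n_enumerated = attr(cands, "n_enumerated"),
                 n_clash_pass = attr(cands, "n_clash_pass"),
                 diagnostic = attr(cands, "diagnostic"))
  restored <- if (length(mut_records))
    restore_residues(work, mut_records) else work
  if (!length(cands)) {
    return(structure(list(poses = list(), receptor = restored,
                          report = c(report, n_refined = 0L,
                                     n_clusters = 0L, n_emitted = 0L),
                          config = config), class = "dock_result"))
  }
  # geometry filter (every candidate must satisfy the warhead contract)
  geom_ok <- vapply(cands, function(cd)
    check_adduct_geometry(cd$sg, cd$cb, cd$xyz[ra, ], config$warhead)$pass,
    logical(1))
  cands <- cands[geom_ok]
  report$n_geometry_pass <- sum(geom_ok)
  if (!length(cands)) {
    report$diagnostic <- "geometry infeasible"
    return(structure(list(poses = list(), receptor = restored,
                          report = c(report, n_refined = 0L,
                                     n_clusters = 0L, n_emitted = 0L),
                          config = config), class = "dock_result"))
  }
  # pre-score against the rigid context (flexible side chains excluded in
  # flex mode: they are about to be repacked)
  k <- parse_residue_key(site$reactive)
  center <- residue_atom_xyz(get_residue(restored, k$chain, k$resno), "CA")
  ctx_atoms <- receptor_context_atoms(restored, site,
                                      include_flexible_sc =
                                        config$mode == "rigid",
                                      center = center,
                                      radius = config$context_radius + 8)
  rec_grp <- receptor_group(ctx_atoms)
  pre <- vapply(cands, function(cd)
    score_pose(adduct, cd$xyz, rec_grp, config$score)$total, numeric(1))
  keep <- order(pre, vapply(cands, `[[`, 0L, "index"))
  keep <- keep[seq_len(min(config$n_refine, length(keep)))]
  cands <- cands[keep]
  pre <- pre[keep]
  report$n_refined <- length(cands)
  poses <- with_seed(config$seed, {
    out <- lapply(seq_along(cands), function(i) {
      cd <- cands[[i]]
      if (config$mode == "flex") {
        rp <- repack_site(restored, list(xyz = cd$xyz, cys_chi1 = cd$cys_chi1,
                                         sg = cd$sg, cb = cd$cb,
                                         reactive_atom = ra),
                          adduct, site, rotamer_library, config$score,
                          seed = config$seed + 7L * i, refine = FALSE)
        list(cand = cd, xyz = rp$lig_xyz, receptor = rp$structure,
             score = rp$energy_after, repack = rp)
      } else {
        list(cand = cd, xyz = cd$xyz, receptor = restored,
             score = pre[i], repack = NULL)
      }
    })
    # continuous torsional polish for the best repacked candidates
    if (config$mode == "flex" && config$refine && length(out)) {
      sc <- vapply(out, `[[`, numeric(1), "score")
      top <- order(sc)[seq_len(min(config$n_continuous, length(out)))]
      for (i in top) {
        cd <- out[[i]]$cand
        rp <- repack_site(restored, list(xyz = cd$xyz,
                                         cys_chi1 = cd$cys_chi1,
                                         sg = cd$sg, cb = cd$cb,
                                         reactive_atom = ra),
                          adduct, site, rotamer_library, config$score,
                          seed = config$seed + 7L * i, refine = TRUE)
        out[[i]] <- list(cand = cd, xyz = rp$lig_xyz,
                         receptor = rp$structure,
                         score = rp$energy_after, repack = rp)
      }
    }
    out
  })
  scores <- vapply(poses, `[[`, numeric(1), "score")
  clus <- cluster_poses(lapply(poses, `[[`, "xyz"), scores,
                        config$cluster_rmsd_cutoff, heavy = hv)
  reps <- which(clus$representative)
  reps <- reps[order(scores[reps],
                     vapply(poses[reps], function(p) p$cand$index, 0L))]
  reps <- reps[seq_len(min(config$max_poses_out, length(reps)))]
  report$n_clusters <- max(clus$cluster)
  report$n_emitted <- length(reps)
  final <- lapply(seq_along(reps), function(rnk) {
    p <- poses[[reps[rnk]]]
    chk <- check_adduct_geometry(p$cand$sg, p$cand$cb, p$xyz[ra, ],
                                 config$warhead)
    sc <- score_pose(adduct, p$xyz,
                     if (config$mode == "flex")
                       receptor_group(receptor_context_atoms(
                         p$receptor, site, include_flexible_sc = TRUE,
                         center = center,
                         radius = config$context_radius + 8))
                     else rec_grp,
                     config$score)
    structure(list(lig_xyz = p$xyz, cys_chi1 = p$cand$cys_chi1,
                   bond_length = chk$bond_length,
                   bond_angle = chk$bond_angle,
                   score_total = p$score, score_terms = sc$terms,
                   cluster_id = clus$cluster[reps[rnk]], rank = rnk,
                   receptor = p$receptor,
                   energy_before = if (!is.null(p$repack))
                     p$repack$energy_before else NA_real_,
                   energy_after = if (!is.null(p$repack))
                     p$repack$energy_after else NA_real_),
              class = "covalent_pose")
  })
  structure(list(poses = final, receptor = restored, report = report,
                 config = config), class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<dock_result> %s mode: %d enumerated, %d clash-pass, %d refined, %d clusters, %d emitted (%s)\n",
              x$config$mode, r$n_enumerated, r$n_clash_pass,
              r$n_refined, r$n_clusters, r$n_emitted, r$diagnostic))
  if (length(x$poses))
    cat(sprintf("  best score %.3f (rank 1, cys chi1 %.0f)\n",
                x$poses[[1L]]$score_total, x$poses[[1L]]$cys_chi1))
  invisible(x)
}
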