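# Synthetic mini-pocket systems with known ground truth. A small receptor
# (two strands, a helix and a loop framing a concave site around a
# reactive cysteine) is built from ideal backbone templates and caged
# around a grammar-generated acrylamide-warhead ligand placed at exact
# covalent-anchor geometry. Blocking residues are planted with an "open"
# rotamer (clash-free with the reference pose) and a "closed" rotamer
# (hard-clashing it); the receptor is delivered in the closed state, which
# is what makes the fixture a receptor-flexibility test. Everything is
# deterministic in the seed.

FIXTURE_TERMINALS <- c("methyl", "ethyl", "isopropyl", "hydroxymethyl",
                       "phenyl")

#' Build a fixture ligand from the fragment grammar
#'
#' Acrylamide warhead (reactive beta-carbon C1, olefin C1=C2, carbonyl,
#' amide N) plus an N-substituent: 0-1 methylene linkers and a terminal
#' fragment, with an optional N-methyl. Coordinates are adduct-like 3D
#' (ideal internal geometry, staggered torsions); the SDF form carries the
#' C1=C2 double bond, reduced to single on adduct formation.
#'
#' @param terminal One of methyl, ethyl, isopropyl, hydroxymethyl, phenyl.
#' @param linkers 0 or 1 methylene linkers (phenyl requires 0).
#' @param n_methyl Logical: add an N-methyl substituent.
#' @param name Ligand name.
#' @return List with `lig` (a [ligand()], SDF form) and `warhead`
#'   (a [warhead_spec()] for atom 1).
#' @export
fixture_ligand <- function(terminal = "methyl", linkers = 0,
                           n_methyl = FALSE, name = "FXL") {
  terminal <- match.arg(terminal, FIXTURE_TERMINALS)
  if (terminal == "phenyl") linkers <- 0
  el <- c("C", "C", "C", "O", "N")
  dummy <- c(0, 1, 0)
  c1 <- c(0, 0, 0)
  c2 <- c(1.52, 0, 0)
  c3 <- place_atom(dummy, c1, c2, 1.52, 112, 180)
  o1 <- place_atom(c1, c2, c3, 1.23, 121, 0)
  n1 <- place_atom(c1, c2, c3, 1.34, 115, 180)
  xyz <- rbind(c1, c2, c3, o1, n1)
  bonds <- data.frame(i = c(1, 2, 3, 3), j = c(2, 3, 4, 5),
                      order = c(2, 1, 2, 1))
  prev3 <- list(c2, c3, n1)  # (a, b, c) for the next chain atom
  att <- 5L  # attachment atom index
  add_atom <- function(elem, p) {
    el <<- c(el, elem)
    xyz <<- rbind(xyz, p)
    nrow(xyz)
  }
  add_bond <- function(i, j, order = 1)
    bonds <<- rbind(bonds, data.frame(i = i, j = j, order = order))
  chain_extend <- function(elem, len, ang, dih) {
    p <- place_atom(prev3[[1L]], prev3[[2L]], prev3[[3L]], len, ang, dih)
    idx <- add_atom(elem, p)
    add_bond(att, idx)
    prev3 <<- list(prev3[[2L]], prev3[[3L]], p)
    att <<- idx
    idx
  }
  for (l in seq_len(linkers)) chain_extend("C", 1.46, 114, 180)
  if (terminal == "methyl") {
    chain_extend("C", 1.46, 116, 180)
  } else if (terminal == "ethyl") {
    chain_extend("C", 1.46, 116, 180)
    chain_extend("C", 1.52, 111, 180)
  } else if (terminal == "hydroxymethyl") {
    chain_extend("C", 1.46, 116, 180)
    chain_extend("O", 1.41, 109, 180)
  } else if (terminal == "isopropyl") {
    ci <- chain_extend("C", 1.46, 116, 180)
    a <- prev3[[1L]]; b <- prev3[[2L]]; cc <- prev3[[3L]]
    m1 <- add_atom("C", place_atom(a, b, cc, 1.52, 111, -60))
    add_bond(ci, m1)
    m2 <- add_atom("C", place_atom(a, b, cc, 1.52, 111, 60))
    add_bond(ci, m2)
  } else if (terminal == "phenyl") {
    ipso <- chain_extend("C", 1.40, 120, 180)
    a <- prev3[[1L]]; b <- prev3[[2L]]; cc <- prev3[[3L]]
    o1r <- add_atom("C", place_atom(a, b, cc, 1.39, 120, 90))
    o2r <- add_atom("C", place_atom(a, b, cc, 1.39, 120, -90))
    m1r <- add_atom("C", place_atom(b, cc, xyz[o1r, ], 1.39, 120, 180))
    m2r <- add_atom("C", place_atom(b, cc, xyz[o2r, ], 1.39, 120, 180))
    pr <- add_atom("C", place_atom(cc, xyz[o1r, ], xyz[m1r, ], 1.39, 120, 0))
    for (bp in list(c(ipso, o1r), c(ipso, o2r), c(o1r, m1r), c(o2r, m2r),
                    c(m1r, pr), c(m2r, pr)))
      add_bond(bp[1L], bp[2L], order = 4)
  }
  if (n_methyl) {
    m <- add_atom("C", place_atom(xyz[2L, ], xyz[3L, ], xyz[5L, ],
                                  1.46, 118, 0))
    add_bond(5L, m)
  }
  atoms <- data.frame(element = el, x = xyz[, 1L], y = xyz[, 2L],
                      z = xyz[, 3L], stringsAsFactors = FALSE)
  lig <- ligand(atoms, bonds, name = name)
  list(lig = lig,
       warhead = warhead_spec(1L, modified_bonds = list(c(1, 2, 1))))
}

# hard-clash test between two heavy-atom coordinate sets
has_clash <- function(xyz1, rad1, xyz2, rad2, fraction = 0.7) {
  if (!nrow(xyz1) || !nrow(xyz2)) return(FALSE)
  d <- cross_dist(as.matrix(xyz1), as.matrix(xyz2))
  any(d < fraction * outer(rad1, rad2, "+"))
}

atoms_xyz <- function(a) as.matrix(a[, c("x", "y", "z")])
atoms_rad <- function(a) if (nrow(a)) vdw_radius(a$element) else numeric(0)

# count of ligand heavy atoms overlapped by the single worst side-chain atom
max_overlap_count <- function(sc_xyz, sc_rad, lig_xyz, lig_rad,
                              fraction = 0.7) {
  if (!nrow(sc_xyz)) return(0L)
  d <- cross_dist(sc_xyz, lig_xyz)
  max(rowSums(d < fraction * outer(sc_rad, lig_rad, "+")))
}

# principal axis of a coordinate matrix (unit vector)
principal_axis <- function(xyz) {
  s <- svd(sweep(xyz, 2, colMeans(xyz)))
  v <- s$v[, 1L]
  if (v[1L] < 0) v <- -v
  v
}

# rigid-place a segment atom df: align its CA principal axis to `axis`,
# move centroid to `center`, then rotate about `axis` by `roll` degrees
place_segment <- function(df, axis, center, roll = 0) {
  ca <- atoms_xyz(df[df$name == "CA", , drop = FALSE])
  R1 <- rotation_between(principal_axis(ca), axis)
  xyz <- t(R1 %*% t(sweep(atoms_xyz(df), 2, colMeans(ca))))
  if (roll != 0) xyz <- t(rotation_about_axis(axis, roll) %*% t(xyz))
  xyz <- sweep(xyz, 2, center, "+")
  df$x <- xyz[, 1L]; df$y <- xyz[, 2L]; df$z <- xyz[, 3L]
  df
}

# side-chain atoms (beyond CB) of residues listed in `keys` are dropped
strip_flex_sidechains <- function(df, resnos) {
  drop <- df$resno %in% resnos &
    !df$name %in% c(BACKBONE_NAMES, "OXT", "CB")
  df[!drop, , drop = FALSE]
}

# rotamers of `type` whose side chain is clash-free against the given
# context coordinate sets; returns indices into the library matrix
clashfree_rotamers <- function(type, n, ca, cb, lib, contexts,
                               fraction = 0.7) {
  chis <- lib[[type]]$chis
  ok <- logical(nrow(chis))
  for (r in seq_len(nrow(chis))) {
    sc <- sidechain_xyz(n, ca, cb, type, chis[r, ])
    rad <- vdw_radius(element_from_name(rownames(sc)))
    ok[r] <- !any(vapply(contexts, function(ctx)
      has_clash(sc, rad, ctx$xyz, ctx$rad, fraction), logical(1)))
  }
  which(ok)
}

# Mutate one rigid wall residue to serine with its OG placed 2.7-3.2 A
# from `target` (a polar atom of the reference pose), clash-free against
# the receptor and the rest of the ligand. Returns the updated atom df or
# NULL if no placement exists.
plant_hb_probe <- function(all_df, target, lig_hx, lig_hr,
                           forbidden = integer(0)) {
  cbs <- all_df[all_df$name == "CB" & !all_df$resno %in% forbidden, ,
                drop = FALSE]
  if (!nrow(cbs)) return(NULL)
  dcb <- sqrt((cbs$x - target[1L])^2 + (cbs$y - target[2L])^2 +
                (cbs$z - target[3L])^2)
  for (ci in order(dcb)) {
    if (dcb[ci] < 2.8 || dcb[ci] > 7.0) next
    rk <- cbs$resno[ci]
    res <- all_df[all_df$resno == rk, , drop = FALSE]
    probe_type <- if (res$resid[1L] == "THR") "THR" else "SER"
    og_name <- if (probe_type == "THR") "OG1" else "OG"
    nn <- as.numeric(res[res$name == "N", c("x", "y", "z")])
    nca <- as.numeric(res[res$name == "CA", c("x", "y", "z")])
    ncb <- as.numeric(res[res$name == "CB", c("x", "y", "z")])
    ctx <- all_df[!all_df$resno %in% (rk + (-1:1)), , drop = FALSE]
    ctx_xyz <- atoms_xyz(ctx)
    ctx_rad <- atoms_rad(ctx)
    for (chi in seq(-180, 178, by = 2)) {
      og <- sidechain_xyz(nn, nca, ncb, probe_type, chi)[og_name, ]
      d <- vnorm(og - target)
      if (d < 2.55 || d > 3.45) next
      if (angle3(ncb, og, target) <= 121) next
      if (has_clash(matrix(og, 1), 1.52, ctx_xyz, ctx_rad)) next
      dl <- sqrt(colSums((t(lig_hx) - og)^2))
      if (any(dl < 0.7 * (1.52 + lig_hr))) next
      new_res <- build_sidechain(res, chi, probe_type)
      ridx <- which(all_df$resno == rk)
      out <- rbind(all_df[seq_len(min(ridx) - 1L), , drop = FALSE], new_res,
                   all_df[setdiff(seq(min(ridx), nrow(all_df)), ridx), ,
                          drop = FALSE])
      return(out)
    }
  }
  NULL
}

# Plant rotamer states for one residue: a clash-free "native" (open)
# rotamer, at least one receptor-compatible alternative differing in chi1,
# and (for blocking residues) a "closed" rotamer whose worst side-chain
# atom overlaps >= 2 ligand heavy atoms. The residue's own and adjacent
# residues are excluded from the steric context (bonded proximity).
# Returns NULL when infeasible.
plant_one <- function(res, ctx_df, lig_hx, lig_hr, lib,
                      need_closed = FALSE) {
  ty <- res$resid[1L]
  rk <- res$resno[1L]
  nn <- as.numeric(res[res$name == "N", c("x", "y", "z")])
  nca <- as.numeric(res[res$name == "CA", c("x", "y", "z")])
  ncb <- as.numeric(res[res$name == "CB", c("x", "y", "z")])
  cdf <- ctx_df[!ctx_df$resno %in% (rk + (-1:1)), , drop = FALSE]
  rigid_ctx <- list(list(xyz = atoms_xyz(cdf), rad = atoms_rad(cdf)))
  lig_ctx <- list(list(xyz = lig_hx, rad = lig_hr))
  free_rec <- clashfree_rotamers(ty, nn, nca, ncb, lib, rigid_ctx)
  free_both <- clashfree_rotamers(ty, nn, nca, ncb, lib,
                                  c(rigid_ctx, lig_ctx))
  if (!length(free_both)) return(NULL)
  native <- free_both[1L]
  chis <- lib[[ty]]$chis
  alts <- setdiff(free_rec, native)
  alts <- alts[abs(wrap180(chis[alts, 1L] - chis[native, 1L])) >= 60]
  if (!length(alts)) return(NULL)
  closed <- NA_integer_
  if (need_closed) {
    cand <- setdiff(free_rec, free_both)
    cand <- cand[abs(wrap180(chis[cand, 1L] - chis[native, 1L])) >= 60]
    best_ov <- 0L
    for (ci in cand) {
      sc <- sidechain_xyz(nn, nca, ncb, ty, chis[ci, ])
      ov <- max_overlap_count(sc,
                              vdw_radius(element_from_name(rownames(sc))),
                              lig_hx, lig_hr)
      if (ov > best_ov) {
        best_ov <- ov
        closed <- ci
      }
    }
    if (best_ov < 2L) return(NULL)
  }
  list(resno = rk, type = ty, native = native, alts = alts,
       closed = closed,
       native_chis = chis[native, seq_len(n_chi(ty))],
       closed_chis = if (!is.na(closed))
         chis[closed, seq_len(n_chi(ty))] else NULL)
}

#' Generate a synthetic mini-pocket system
#'
#' Deterministic in `seed`. `difficulty` controls the number of planted
#' blocking residues: "easy" (0), "blocking" (1), "multiblocking" (2).
#' The generator retries internally (bounded) until the system invariants
#' hold: the reference pose passes the adduct geometry check and has zero
#' repulsion against the open-rotamer receptor, and each planted blocking
#' residue's closed rotamer hard-clashes the reference pose. Failure to
#' satisfy the invariants raises an error rather than easing the fixture.
#'
#' @param seed Integer seed.
#' @param difficulty "easy", "blocking" or "multiblocking".
#' @return Object of class `minipocket`: `receptor` (delivered state:
#'   blocking residues closed), `receptor_open`, `lig`, `warhead`, `site`,
#'   `reference_xyz` (ground-truth adduct coordinates), `truth` (planted
#'   rotamer states and anchor parameters), `seed`, `difficulty`.
#' @export
make_minipocket <- function(seed,
                            difficulty = c("easy", "blocking",
                                           "multiblocking")) {
  difficulty <- match.arg(difficulty)
  n_block <- switch(difficulty, easy = 0L, blocking = 1L,
                    multiblocking = 2L)
  with_seed(seed * 131 + n_block, {
    for (attempt in seq_len(100)) {
      sys <- try(build_minipocket_once(seed, difficulty, n_block),
                 silent = TRUE)
      if (!inherits(sys, "try-error") && !is.null(sys)) return(sys)
    }
    stop("mini-pocket generation failed: invariants unsatisfiable ",
         "within the retry budget (seed ", seed, ", ", difficulty, ")")
  })
}

build_minipocket_once <- function(seed, difficulty, n_block) {
  lib <- default_rotamer_library()
  # --- ligand ---
  terminal <- sample(FIXTURE_TERMINALS, 1L)
  linkers <- if (terminal == "phenyl") 0L else sample(0:1, 1L)
  fx <- fixture_ligand(terminal, linkers, n_methyl = stats::runif(1) < 0.3,
                       name = sprintf("FXL_s%d", seed))
  lig <- fx$lig
  warhead <- fx$warhead
  adduct <- adduct_form(lig, warhead)
  nt <- length(adduct$rotatable)
  # --- strand 1 with the reactive cysteine ---
  s1_seq <- c("VAL", "ALA", "CYS", "VAL", "THR", "ALA", "VAL", "SER")
  s1 <- build_backbone(matrix(rep(c(-120, 120), 8), ncol = 2, byrow = TRUE),
                       s1_seq, start_resno = 1L)
  prot <- protein(s1, sprintf("minipocket_s%d_%s", seed, difficulty))
  site0 <- binding_site_spec("A:3", character(0))
  ra <- warhead$reactive_atom
  nbrs <- as.integer(igraph::neighbors(ligand_graph(adduct), ra))
  hv <- heavy_indices(adduct)
  lig_hr <- vdw_radius(adduct$atoms$element[hv])
  # the reference pose must not clash the cysteine strand itself (side
  # chains of non-reactive strand residues included); resample the truth
  # orientation a few times before giving up on this attempt
  s1_ctx <- s1[!(s1$resno == 3 & !s1$name %in% BACKBONE_NAMES), ,
               drop = FALSE]
  ref_xyz <- NULL
  for (draw in seq_len(8L)) {
    truth_chi1 <- sample(c(-60, 180, 60), 1L)
    truth_twist <- sample(c(-60, 60, 180), 1L)
    truth_spin <- sample(c(-60, 60, 180), 1L)
    truth_tors <- if (nt) sample(c(-60, 60, 180), nt, replace = TRUE)
                  else numeric(0)
    geo <- reactive_sg(prot, site0, truth_chi1)
    cand <- place_candidate(adduct, ra, nbrs, ligand_xyz(adduct), geo,
                            warhead, torsions = truth_tors,
                            spin = truth_spin, twist = truth_twist)
    if (is.null(cand)) next
    if (!has_clash(cand[hv, , drop = FALSE], lig_hr, atoms_xyz(s1_ctx),
                   atoms_rad(s1_ctx))) {
      ref_xyz <- cand
      break
    }
  }
  if (is.null(ref_xyz)) stop("reference pose clashes the anchor strand")
  lig_hx <- ref_xyz[hv, , drop = FALSE]
  # --- pocket frame ---
  c_lig <- colMeans(lig_hx)
  e1 <- principal_axis(atoms_xyz(s1[s1$name == "CA", ]))
  w <- c_lig - geo$ca
  n_hat <- w - sum(w * e1) * e1
  if (vnorm(n_hat) < 0.5) stop("degenerate pocket frame")
  n_hat <- vunit(n_hat)
  m_hat <- vcross(e1, n_hat)
  # --- helix with flexible/blocking positions ---
  helix_len <- 16L
  face <- c(6L, 9L, 10L, 13L)  # pocket-facing positions (i, i+3, i+4, i+7)
  block_pos <- face[seq_len(n_block)]
  flex_pos <- face[seq_len(min(4L, n_block + sample(2:3, 1L)))]
  h_seq <- rep("ALA", helix_len)
  h_seq[sample(c(2L, 4L, 15L), 2L)] <- "VAL"
  for (bp in block_pos) h_seq[bp] <- sample(c("MET", "GLN"), 1L)
  for (fp in setdiff(flex_pos, block_pos))
    h_seq[fp] <- sample(c("SER", "VAL", "LEU", "MET"), 1L)
  helix <- build_backbone(matrix(rep(c(-57, -47), helix_len), ncol = 2,
                                 byrow = TRUE), h_seq, start_resno = 21L)
  # roll the helix so the first face residue's CB points toward the pocket
  ca_h <- atoms_xyz(helix[helix$name == "CA", ])
  ax_h <- principal_axis(ca_h)
  bres <- helix[helix$resno == 20L + face[1L], , drop = FALSE]
  cb_dir <- atoms_xyz(bres[bres$name == "CB", , drop = FALSE])[1L, ] -
    colMeans(ca_h)
  placed_helix <- NULL
  for (d in seq(5.5, 11, by = 0.5)) {
    for (roll_extra in sample(seq(0, 330, by = 30))) {
      hp <- place_segment(helix, e1, c_lig + d * n_hat, roll = roll_extra)
      # rigid part must not clash the pose or strand 1
      hp_rigid <- strip_flex_sidechains(hp, 20L + flex_pos)
      if (has_clash(lig_hx, lig_hr, atoms_xyz(hp_rigid),
                    atoms_rad(hp_rigid))) next
      if (has_clash(atoms_xyz(hp_rigid), atoms_rad(hp_rigid),
                    atoms_xyz(s1), atoms_rad(s1))) next
      # need pocket contact
      if (min(cross_dist(lig_hx, atoms_xyz(hp_rigid))) > 5.5) next
      # blocking residues must admit both an open and a closed rotamer
      # against the partial (strand + helix) context
      part_ctx <- rbind(s1, hp_rigid)
      feasible <- all(vapply(block_pos, function(bp) {
        res <- hp[hp$resno == 20L + bp, , drop = FALSE]
        !is.null(plant_one(res, part_ctx, lig_hx, lig_hr, lib,
                           need_closed = TRUE))
      }, logical(1)))
      if (!feasible) next
      placed_helix <- hp
      break
    }
    if (!is.null(placed_helix)) break
  }
  if (is.null(placed_helix)) stop("no helix placement found")
  helix <- placed_helix
  # --- loop and far strand ---
  loop_seq <- c("GLY", "ALA", "SER", "ALA", "GLY", "THR", "ALA", "GLY",
                "ALA", "ALA")
  loop <- build_backbone(matrix(rep(c(-80, 120), 10), ncol = 2,
                                byrow = TRUE), loop_seq, start_resno = 41L)
  s2 <- build_backbone(matrix(rep(c(-120, 120), 8), ncol = 2, byrow = TRUE),
                       c("VAL", "THR", "ALA", "VAL", "ALA", "THR", "VAL",
                         "ALA"), start_resno = 61L)
  fixed_ctx <- rbind(s1, strip_flex_sidechains(helix, 20L + flex_pos))
  place_far <- function(df, dir_hat) {
    for (d in seq(5.5, 13, by = 0.5)) {
      for (roll in seq(0, 330, by = 60)) {
        pp <- place_segment(df, e1, c_lig + d * dir_hat, roll = roll)
        if (has_clash(lig_hx, lig_hr, atoms_xyz(pp), atoms_rad(pp))) next
        if (has_clash(atoms_xyz(pp), atoms_rad(pp), atoms_xyz(fixed_ctx),
                      atoms_rad(fixed_ctx))) next
        return(pp)
      }
    }
    NULL
  }
  loop <- place_far(loop, m_hat)
  if (is.null(loop)) stop("no loop placement found")
  fixed_ctx <- rbind(fixed_ctx, loop)
  s2 <- place_far(s2, -m_hat)
  if (is.null(s2)) stop("no far-strand placement found")
  all_df <- rbind(s1, helix, loop, s2)
  # --- hydrogen-bond probes anchoring the reference pose ---
  # rigid serine hydroxyls are engineered complementary to the polar atoms
  # of the ground-truth pose; they reward the true orientation the way a
  # real pocket's specific interactions do
  polar <- hv[adduct$atoms$element[hv] %in% c("N", "O")]
  polar <- setdiff(polar, ra)
  n_probes <- 0L
  for (tgt in polar) {
    if (n_probes >= 3L) break
    res_planted <- plant_hb_probe(all_df, ref_xyz[tgt, ], lig_hx, lig_hr,
                                  forbidden = c(3L, 20L + flex_pos))
    if (!is.null(res_planted)) {
      all_df <- res_planted
      n_probes <- n_probes + 1L
    }
  }
  if (n_probes < 2L) {
    # fewer than two engineered probes is acceptable only when the pose
    # is already well anchored by hydrogen bonds (probes included):
    # one probe plus a backbone bond, or three backbone bonds
    rg <- receptor_group(strip_flex_sidechains(all_df, 20L + flex_pos))
    hb <- -interaction_terms(ligand_group(adduct, ref_xyz), rg,
                             score_params())$hbond
    if (!(n_probes >= 1L && hb >= 2) && hb < 3)
      stop("could not anchor the pose with polar probes")
  }
  # --- plant rotamer states ---
  rigid_ctx_df <- strip_flex_sidechains(all_df, 20L + flex_pos)
  flex_keys <- sprintf("A:%d", 20L + flex_pos)
  planted <- list()
  for (fp in flex_pos) {
    rk <- 20L + fp
    res <- all_df[all_df$resno == rk, , drop = FALSE]
    pl <- plant_one(res, rigid_ctx_df, lig_hx, lig_hr, lib,
                    need_closed = fp %in% block_pos)
    if (is.null(pl)) stop("no plantable rotamer state for residue ", rk)
    planted[[sprintf("A:%d", rk)]] <- pl
  }
  # --- assemble receptors: open (all native) and delivered (closed) ---
  set_flex <- function(df, state) {
    for (key in names(planted)) {
      pl <- planted[[key]]
      ridx <- which(df$resno == pl$resno)
      res <- df[ridx, , drop = FALSE]
      rot <- if (state == "closed" && !is.na(pl$closed)) pl$closed
             else pl$native
      new_res <- build_sidechain(res, lib[[pl$type]]$chis[rot,
                                   seq_len(n_chi(pl$type))], pl$type)
      df <- rbind(df[seq_len(min(ridx) - 1L), , drop = FALSE], new_res,
                  df[setdiff(seq(min(ridx), nrow(df)), ridx), , drop = FALSE])
    }
    df
  }
  open_df <- set_flex(all_df, "open")
  closed_df <- set_flex(all_df, "closed")
  receptor_open <- protein(open_df, prot$source_id)
  receptor <- protein(closed_df, prot$source_id)
  # --- invariants ---
  chk <- check_adduct_geometry(geo$sg, geo$cb, ref_xyz[ra, ], warhead)
  if (!chk$pass) stop("reference pose fails the adduct geometry check")
  # the pocket must be snug: the reference pose needs a healthy number of
  # near contacts with the rigid receptor, or pose ranking is meaningless
  d_ctx <- cross_dist(lig_hx, atoms_xyz(rigid_ctx_df))
  if (sum(d_ctx < 4.5) < 20L)
    stop("reference pose is not snug in the pocket")
  open_ctx <- receptor_context_atoms(receptor_open,
                                     binding_site_spec("A:3", flex_keys),
                                     include_flexible_sc = TRUE)
  if (has_clash(lig_hx, lig_hr, atoms_xyz(open_ctx), atoms_rad(open_ctx)))
    stop("reference pose clashes the open-state receptor")
  for (key in names(planted)) {
    pl <- planted[[key]]
    if (is.na(pl$closed)) next
    res <- get_residue(receptor, "A", pl$resno)
    sc <- sidechain_heavy(res)
    if (!has_clash(atoms_xyz(sc), atoms_rad(sc), lig_hx, lig_hr))
      stop("closed rotamer does not clash the reference pose")
  }
  site <- binding_site_spec("A:3", flex_keys,
                            blocking = sprintf("A:%d", 20L + block_pos))
  structure(list(receptor = receptor, receptor_open = receptor_open,
                 lig = lig, warhead = warhead, site = site,
                 reference_xyz = ref_xyz,
                 truth = list(chi1 = truth_chi1, twist = truth_twist,
                              spin = truth_spin, torsions = truth_tors,
                              planted = planted),
                 seed = seed, difficulty = difficulty),
            class = "minipocket")
}

#' @export
print.minipocket <- function(x, ...) {
  cat(sprintf("<minipocket> seed %d (%s): %d residues, ligand %s (%d heavy, %d torsions), %d flexible / %d blocking\n",
              x$seed, x$difficulty, nrow(residue_table(x$receptor)),
              x$lig$name, length(heavy_indices(x$lig)),
              length(adduct_form(x$lig, x$warhead)$rotatable),
              length(x$site$flexible), length(x$site$blocking)))
  invisible(x)
}

#' Generate a structure ensemble from a mini-pocket
#'
#' Ensemble members resample each planted flexible residue among its
#' planted rotamers (round-robin with a seeded offset, so every planted
#' rotamer appears) and jitter all other atoms by at most `jitter`
#' per-coordinate. The returned truth lists which residues are flexible.
#'
#' @param seed Integer seed.
#' @param n_structures Number of members (>= 2).
#' @param system Optional [make_minipocket()] system; generated from
#'   `seed` ("blocking") when absent.
#' @param jitter Maximum absolute per-coordinate displacement, A.
#' @return List with `structures`, `system`, and `truth`
#'   (`flexible_keys`, `rigid_keys`).
#' @export
make_ensemble <- function(seed, n_structures, system = NULL,
                          jitter = 0.05) {
  if (n_structures < 2) stop("an ensemble needs at least 2 members")
  if (is.null(system)) system <- make_minipocket(seed, "blocking")
  lib <- default_rotamer_library()
  planted <- system$truth$planted
  with_seed(seed * 977 + n_structures, {
    structures <- lapply(seq_len(n_structures), function(k) {
      df <- system$receptor_open$atoms
      for (pi in seq_along(planted)) {
        pl <- planted[[pi]]
        rots <- c(pl$native, pl$alts, if (!is.na(pl$closed)) pl$closed)
        rots <- unique(rots)
        rot <- rots[1L + (k + pi) %% length(rots)]
        ridx <- which(df$resno == pl$resno)
        res <- df[ridx, , drop = FALSE]
        new_res <- build_sidechain(res,
                                   lib[[pl$type]]$chis[rot,
                                     seq_len(n_chi(pl$type))], pl$type)
        df <- rbind(df[seq_len(min(ridx) - 1L), , drop = FALSE], new_res,
                    df[setdiff(seq(min(ridx), nrow(df)), ridx), ,
                       drop = FALSE])
      }
      jit <- matrix(stats::runif(3 * nrow(df), -jitter, jitter),
                    ncol = 3)
      df$x <- df$x + jit[, 1L]
      df$y <- df$y + jit[, 2L]
      df$z <- df$z + jit[, 3L]
      protein(df, sprintf("%s_m%02d", system$receptor$source_id, k))
    })
    rt <- residue_table(system$receptor)
    flex_keys <- names(planted)
    list(structures = structures, system = system,
         truth = list(flexible_keys = flex_keys,
                      rigid_keys = setdiff(rt$key, c(flex_keys,
                                                     system$site$reactive))))
  })
}

#' Generate a cross-docking family of mini-pockets
#'
#' `n_systems` variants sharing one receptor scaffold: each system gets
#' its own ligand (varying tail length/terminal) and its own planted
#' flexible-rotamer state, self-consistent with its cognate reference
#' pose; planted blocking residues are closed wherever the closed rotamer
#' tolerates the cognate ligand (short tails) and open otherwise. Docking
#' ligand j into receptor i (i != j) then reproduces the non-cognate
#' blocking scenario.
#'
#' @param seed Integer seed.
#' @param n_systems Number of family members (>= 2).
#' @return List of `minipocket` objects with shared residue keys.
#' @export
make_family <- function(seed, n_systems = 4) {
  # anchor the family on a scaffold caged around a reasonably large
  # ligand, so the smaller variants fit the open pocket
  base <- NULL
  for (k2 in 0:9) {
    cand <- make_minipocket(seed + 101L * k2, "blocking")
    if (length(heavy_indices(cand$lig)) >= 9L || k2 == 9L) {
      base <- cand
      break
    }
  }
  site <- base$site
  with_seed(seed * 7717 + n_systems, {
    out <- vector("list", n_systems)
    out[[1L]] <- base
    for (k in seq(2L, length.out = n_systems - 1L)) {
      ok <- FALSE
      for (attempt in seq_len(40)) {
        fx <- fixture_ligand(sample(c("methyl", "ethyl", "hydroxymethyl"),
                                    1L),
                             linkers = sample(0:1, 1L),
                             n_methyl = FALSE,
                             name = sprintf("FXL_s%d_%d", seed, k))
        adduct <- adduct_form(fx$lig, fx$warhead)
        nt <- length(adduct$rotatable)
        # keep the warhead amide overlaid on the base pose (the family
        # shares the anchoring polar probes); only tail torsions vary
        tors <- if (nt) sample(c(-60, 60, 180), nt, replace = TRUE)
                else numeric(0)
        if (nt >= 1 && length(base$truth$torsions) >= 1)
          tors[1L] <- base$truth$torsions[1L]
        spin <- base$truth$spin
        twist <- base$truth$twist
        geo <- reactive_sg(base$receptor_open, site, base$truth$chi1)
        ra <- fx$warhead$reactive_atom
        nbrs <- as.integer(igraph::neighbors(ligand_graph(adduct), ra))
        rx <- place_candidate(adduct, ra, nbrs, ligand_xyz(adduct), geo,
                              fx$warhead, torsions = tors, spin = spin,
                              twist = twist)
        if (is.null(rx)) next
        hv <- heavy_indices(adduct)
        lig_hx <- rx[hv, , drop = FALSE]
        lig_hr <- vdw_radius(adduct$atoms$element[hv])
        # must fit the open-state scaffold
        open_ctx <- receptor_context_atoms(base$receptor_open, site,
                                           include_flexible_sc = TRUE)
        if (has_clash(lig_hx, lig_hr, atoms_xyz(open_ctx),
                      atoms_rad(open_ctx))) next
        # per-system receptor: blocking closed where tolerated
        df <- base$receptor_open$atoms
        for (key in names(base$truth$planted)) {
          pl <- base$truth$planted[[key]]
          if (is.na(pl$closed)) next
          res0 <- df[df$resno == pl$resno, , drop = FALSE]
          closed_res <- build_sidechain(res0, pl$closed_chis, pl$type)
          sc <- sidechain_heavy(closed_res)
          if (!has_clash(atoms_xyz(sc), atoms_rad(sc), lig_hx, lig_hr)) {
            ridx <- which(df$resno == pl$resno)
            df <- rbind(df[seq_len(min(ridx) - 1L), , drop = FALSE],
                        closed_res,
                        df[setdiff(seq(min(ridx), nrow(df)), ridx), ,
                           drop = FALSE])
          }
        }
        rec <- protein(df, sprintf("minipocket_s%d_f%d", seed, k))
        out[[k]] <- structure(list(receptor = rec,
                                   receptor_open = base$receptor_open,
                                   lig = fx$lig, warhead = fx$warhead,
                                   site = site, reference_xyz = rx,
                                   truth = list(chi1 = base$truth$chi1,
                                                twist = twist, spin = spin,
                                                torsions = tors,
                                                planted =
                                                  base$truth$planted),
                                   seed = seed, difficulty = "family"),
                              class = "minipocket")
        ok <- TRUE
        break
      }
      if (!ok) stop("family generation failed for member ", k)
    }
    out
  })
}

#' Write a mini-pocket system to disk
#'
#' Emits `receptor.pdb`, `ligand.sdf`, `reference.sdf` (adduct-form
#' ground-truth pose), `site.yaml`, `truth.json` and a one-row benchmark
#' `manifest.csv`.
#'
#' @param system A `minipocket`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest row as a data.frame.
#' @export
write_minipocket <- function(system, dir, prefix = "fx") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, paste0(prefix, "_receptor.pdb"))
  lp <- file.path(dir, paste0(prefix, "_ligand.sdf"))
  fp <- file.path(dir, paste0(prefix, "_reference.sdf"))
  sp <- file.path(dir, paste0(prefix, "_site.yaml"))
  tp <- file.path(dir, paste0(prefix, "_truth.json"))
  write_pdb(system$receptor, rp)
  write_ligand_sdf(system$lig, lp)
  adduct <- adduct_form(system$lig, system$warhead)
  write_ligand_sdf(adduct, fp, coords = list(system$reference_xyz))
  write_site_spec(system$site, sp, warhead = system$warhead)
  jsonlite::write_json(list(seed = system$seed,
                            difficulty = system$difficulty,
                            anchor = system$truth[c("chi1", "twist",
                                                    "spin", "torsions")],
                            warhead_reactive_atom =
                              system$warhead$reactive_atom),
                       tp, auto_unbox = TRUE, digits = NA)
  manifest <- data.frame(system_id = prefix, receptor = rp, ligand = lp,
                         reference = fp, cognate = TRUE,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write a cross-docking family to disk with a benchmark manifest
#'
#' @param systems List of `minipocket` objects (from [make_family()]).
#' @param dir Output directory.
#' @return Invisibly, the manifest data.frame (also written as
#'   `manifest.csv`; the shared `site.yaml` carries the residue lists and
#'   warhead).
#' @export
write_family <- function(systems, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(systems), function(k) {
    write_minipocket(systems[[k]], dir, prefix = sprintf("sys%02d", k))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  write_site_spec(systems[[1L]]$site, file.path(dir, "site.yaml"),
                  warhead = systems[[1L]]$warhead)
  invisible(manifest)
}
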