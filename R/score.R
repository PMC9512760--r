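# Empirical pairwise scoring of candidate poses. This is the package's own
# transparent surrogate energy: softened-core repulsion beyond a vdW clash
# onset, a capped short-range attractive well, a geometric hydrogen-bond
# bonus, and a ligand torsion-strain penalty. Lower is better; the terms
# are purely pairwise and deterministic.

#' Scoring parameters
#'
#' @param w_rep,w_attr,w_hb,w_tors Non-negative term weights.
#' @param clash_onset_fraction Fraction of the summed vdW radii at which
#'   repulsion begins (also the hard pre-filter threshold), in (0, 1].
#' @param hb_distance_range Donor-acceptor heavy-atom distance window, A.
#' @param hb_angle_min Minimum antecedent-donor-acceptor angle, degrees.
#' @param attr_range Outer cutoff of the attractive well, A.
#' @param attr_atom_cap Maximum attraction collected by any single atom
#'   (saturating burial; dimensionless well units).
#' @return Object of class `score_params`.
#' @export
score_params <- function(w_rep = 10, w_attr = 0.25, w_hb = 1.5,
                         w_tors = 0.5, clash_onset_fraction = 0.7,
                         hb_distance_range = c(2.5, 3.5),
                         hb_angle_min = 120, attr_range = 4.5,
                         attr_atom_cap = 3) {
  if (any(c(w_rep, w_attr, w_hb, w_tors) < 0))
    stop("score weights must be non-negative")
  if (clash_onset_fraction <= 0 || clash_onset_fraction > 1)
    stop("clash_onset_fraction must lie in (0, 1]")
  structure(list(w_rep = w_rep, w_attr = w_attr, w_hb = w_hb,
                 w_tors = w_tors,
                 clash_onset_fraction = clash_onset_fraction,
                 hb_distance_range = hb_distance_range,
                 hb_angle_min = hb_angle_min, attr_range = attr_range,
                 attr_atom_cap = attr_atom_cap),
            class = "score_params")
}

# An "interaction group": coordinates plus per-atom typing used by the
# pairwise energy. `root` holds the position of each atom's bonded
# antecedent (for the donor angle test; NA rows disable the test).
make_group <- function(xyz, element, donor, acceptor, root = NULL) {
  xyz <- as.matrix(xyz)
  if (is.null(root)) root <- matrix(NA_real_, nrow(xyz), 3)
  list(xyz = xyz, radius = vdw_radius(element), donor = donor,
       acceptor = acceptor, root = as.matrix(root))
}

# group from receptor atom rows (heavy atoms assumed); donor/acceptor
# typing from element and atom name; antecedent = nearest atom of the same
# residue within bonding distance.
receptor_group <- function(atoms) {
  if (!nrow(atoms))
    return(make_group(matrix(numeric(0), 0, 3), character(0), logical(0),
                      logical(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- atoms$element
  hydroxyl <- el == "O" & atoms$name %in% c("OG", "OG1", "OH")
  donor <- el == "N" | hydroxyl
  acceptor <- el == "O" |
    (el == "N" & atoms$resid == "HIS" & atoms$name %in% c("ND1", "NE2"))
  root <- matrix(NA_real_, nrow(atoms), 3)
  rkey <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$het, sep = "|")
  for (i in which(donor)) {
    same <- which(rkey == rkey[i])
    same <- setdiff(same, i)
    if (!length(same)) next
    d <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[i, ])^2))
    j <- same[which.min(d)]
    if (min(d) < 1.9) root[i, ] <- xyz[j, ]
  }
  make_group(xyz, el, donor, acceptor, root)
}

# group from a ligand's heavy atoms at given coordinates (typing and
# antecedent indices come from the cached topology)
ligand_group <- function(lig, xyz = ligand_xyz(lig)) {
  tp <- lig$topology
  if (is.null(tp)) {
    lig <- cache_ligand_topology(lig)
    tp <- lig$topology
  }
  root <- matrix(NA_real_, length(tp$heavy), 3)
  has_root <- tp$donor & !is.na(tp$root_idx)
  root[has_root, ] <- xyz[tp$root_idx[has_root], , drop = FALSE]
  list(xyz = xyz[tp$heavy, , drop = FALSE], radius = tp$radius,
       donor = tp$donor, acceptor = tp$acceptor, root = root)
}

# full pairwise distance matrix between two coordinate sets (rows)
cross_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  a2 <- rowSums(A * A)
  b2 <- rowSums(B * B)
  d2 <- a2 + rep(b2, each = length(a2)) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# hydrogen-bond count from donors of `don_grp` to acceptors of `acc_grp`
hb_count_onesided <- function(don_grp, acc_grp, d, params) {
  di <- which(don_grp$donor)
  ai <- which(acc_grp$acceptor)
  if (!length(di) || !length(ai)) return(0L)
  cnt <- 0L
  rng <- params$hb_distance_range
  for (i in di) {
    ok <- ai[d[i, ai] >= rng[1L] & d[i, ai] <= rng[2L]]
    if (!length(ok)) next
    if (all(is.finite(don_grp$root[i, ]))) {
      ang <- vapply(ok, function(j)
        angle3(don_grp$root[i, ], don_grp$xyz[i, ], acc_grp$xyz[j, ]),
        numeric(1))
      ok <- ok[ang > params$hb_angle_min]
    }
    cnt <- cnt + length(ok)
  }
  cnt
}

# pairwise interaction terms between two groups: repulsion (sum of squared
# overlap beyond the clash onset), capped linear-ramp attraction, and
# hydrogen-bond count (negative term). No torsion component.
interaction_terms <- function(A, B, params) {
  nA <- nrow(A$xyz)
  if (!nA || !nrow(B$xyz))
    return(list(repulsion = 0, attraction = 0, hbond = 0))
  d <- cross_dist(A$xyz, B$xyz)
  d_on <- params$clash_onset_fraction *
    (A$radius + rep(B$radius, each = nA))
  ov <- d_on - d
  pos <- ov > 0
  repulsion <- if (any(pos)) sum(ov[pos]^2) else 0
  ramp <- (params$attr_range - d) / pmax(params$attr_range - d_on, 1e-6)
  ramp[pos] <- 0
  ramp[ramp < 0] <- 0
  ramp[ramp > 1] <- 1
  # burial saturates: each atom of the first group collects at most
  # attr_atom_cap units of attraction
  attraction <- -sum(pmin(.rowSums(ramp, nA, ncol(d)),
                          params$attr_atom_cap))
  hb <- 0
  if ((any(A$donor) && any(B$acceptor)) ||
      (any(B$donor) && any(A$acceptor)))
    hb <- hb_count_onesided(A, B, d, params) +
      hb_count_onesided(B, A, t(d), params)
  list(repulsion = repulsion, attraction = attraction, hbond = -hb)
}

# torsion strain: squared deviation (in 60-degree units) of each rotatable
# torsion from the nearest staggered value (-60, 60, 180)
torsion_strain <- function(lig, xyz) {
  if (!length(lig$rotatable)) return(0)
  tv <- torsion_values(lig, xyz)
  dev <- vapply(tv, function(t)
    min(abs(wrap180(t - c(-60, 60, 180)))), numeric(1))
  sum((dev / 60)^2)
}

#' Score a ligand pose against a receptor context
#'
#' score = w_rep * repulsion + w_attr * attraction + w_hb * (-hbonds) +
#' w_tors * torsion strain; lower is better.
#'
#' @param lig Adduct-form [ligand()] (defines heavy atoms, donors,
#'   torsions).
#' @param xyz Ligand coordinate matrix (all atoms, ligand row order).
#' @param rec_group Receptor interaction group (from the docking engine;
#'   see [dock_covalent()]).
#' @param params [score_params()].
#' @return List with `total` and `terms` (repulsion, attraction, hbond,
#'   torsion).
#' @export
score_pose <- function(lig, xyz, rec_group, params = score_params()) {
  lg <- ligand_group(lig, xyz)
  it <- interaction_terms(lg, rec_group, params)
  tors <- torsion_strain(lig, xyz)
  terms <- c(repulsion = it$repulsion, attraction = it$attraction,
             hbond = it$hbond, torsion = tors)
  total <- params$w_rep * it$repulsion + params$w_attr * it$attraction +
    params$w_hb * it$hbond + params$w_tors * tors
  list(total = total, terms = terms,
       weighted = c(repulsion = params$w_rep * it$repulsion,
                    attraction = params$w_attr * it$attraction,
                    hbond = params$w_hb * it$hbond,
                    torsion = params$w_tors * tors))
}
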