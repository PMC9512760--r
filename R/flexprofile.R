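# Ensemble chi-angle profiling: circular statistics over side-chain
# torsions across a superposed structure ensemble, classification of
# binding-site residues as rigid/flexible, and detection of residues that
# sterically block non-cognate ligand poses.

#' Circular standard deviation of angles in degrees
#'
#' Mean-resultant-length definition: sd = sqrt(-2 ln Rbar), reported in
#' degrees. Invariant to adding multiples of 360 and to rotating all
#' observations by a constant.
#'
#' @param x Numeric angles, degrees; NAs dropped.
#' @return Circular sd in degrees (0 for a single observation).
#' @export
circular_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(if (length(x)) 0 else NA_real_)
  th <- x / DEG
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  rbar <- min(1, rbar)
  sqrt(-2 * log(max(rbar, 1e-12))) * DEG
}

#' Count modes of a circular angle sample
#'
#' Histogram with fixed-width bins over (-180, 180]; modes are runs of
#' adjacent (circularly) local-maximum bins holding at least `min_frac` of
#' the observations.
#'
#' @param x Angles in degrees; NAs dropped.
#' @param bin_width Bin width in degrees (must divide 360).
#' @param min_frac Minimum occupancy fraction for a mode.
#' @return Integer mode count (0 for an empty sample).
#' @export
count_modes <- function(x, bin_width = 30, min_frac = 0.10) {
  x <- x[!is.na(x)]
  if (!length(x)) return(0L)
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  nb <- as.integer(360 / bin_width)
  idx <- as.integer(floor((wrap180(x) + 180) / bin_width)) %% nb + 1L
  counts <- tabulate(idx, nbins = nb)
  left <- counts[c(nb, seq_len(nb - 1L))]
  right <- counts[c(seq(2L, nb), 1L)]
  is_peak <- counts > 0 & counts >= left & counts >= right &
    counts >= min_frac * length(x)
  if (!any(is_peak)) return(0L)
  # merge circularly adjacent peak bins into single modes
  runs <- rle(is_peak)
  n_modes <- sum(runs$values)
  if (is_peak[1L] && is_peak[nb] && n_modes > 1L) n_modes <- n_modes - 1L
  as.integer(n_modes)
}

#' Profile side-chain flexibility across a structure ensemble
#'
#' For each requested binding-site residue, collects chi1/chi2 across the
#' ensemble (structures are assumed superposed into a common frame),
#' computes circular spread and chi1 mode count, the maximum pairwise CA
#' displacement, and classifies the residue as `flexible` when
#' chi1 spread exceeds `chi1_sd_threshold`, OR chi1 is multimodal, OR the
#' CA displacement exceeds `ca_threshold` (this last clause captures
#' mobile-backbone residues such as glycines, which have no chi).
#'
#' @param structures List of [protein()] objects (>= 2), superposed.
#' @param site_residues Character residue keys ("chain:resnum").
#' @param chi1_sd_threshold Degrees; default 30.
#' @param ca_threshold Angstrom; default 1.0.
#' @param bin_width,min_frac Mode-count parameters (see [count_modes()]).
#' @return data.frame with one row per site residue: occupancy, circular
#'   spreads, mode count, CA displacement, and classification
#'   ("rigid"/"flexible", NA when never resolved).
#' @export
profile_ensemble <- function(structures, site_residues,
                             chi1_sd_threshold = 30, ca_threshold = 1.0,
                             bin_width = 30, min_frac = 0.10) {
  if (length(structures) < 2)
    stop("ensemble profiling requires at least 2 structures")
  keys <- parse_residue_key(site_residues)
  n <- length(structures)
  out <- list()
  for (r in seq_len(nrow(keys))) {
    ch <- keys$chain[r]; rn <- keys$resno[r]
    chi1 <- chi2 <- rep(NA_real_, n)
    resolved <- logical(n)
    resname <- NA_character_
    ca <- matrix(NA_real_, n, 3)
    for (s in seq_len(n)) {
      res <- tryCatch(get_residue(structures[[s]], ch, rn),
                      error = function(e) NULL)
      if (is.null(res)) next
      resolved[s] <- TRUE
      resname <- res$resid[1L]
      cc <- chi_angles(res)
      chi1[s] <- cc["chi1"]; chi2[s] <- cc["chi2"]
      cav <- residue_atom_xyz(res, "CA")
      if (!is.null(cav)) ca[s, ] <- cav
    }
    occupancy <- mean(resolved)
    if (occupancy == 0) {
      warning(sprintf("residue %s:%s never resolved in the ensemble", ch, rn))
      out[[r]] <- data.frame(chain = ch, resno = rn, resid = NA_character_,
                             key = residue_key(ch, rn), occupancy = 0,
                             circular_std_chi1 = NA_real_,
                             circular_std_chi2 = NA_real_,
                             n_modes_chi1 = 0L, ca_disp = NA_real_,
                             classification = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    cav <- ca[stats::complete.cases(ca), , drop = FALSE]
    ca_disp <- if (nrow(cav) >= 2)
      max(stats::dist(cav)) else 0
    sd1 <- circular_sd(chi1)
    has_chi1 <- any(!is.na(chi1))
    nm1 <- count_modes(chi1, bin_width, min_frac)
    flex <- (has_chi1 && (sd1 > chi1_sd_threshold || nm1 >= 2)) ||
      ca_disp > ca_threshold
    out[[r]] <- data.frame(chain = ch, resno = rn, resid = resname,
                           key = residue_key(ch, rn), occupancy = occupancy,
                           circular_std_chi1 = if (has_chi1) sd1 else NA_real_,
                           circular_std_chi2 = if (any(!is.na(chi2)))
                             circular_sd(chi2) else NA_real_,
                           n_modes_chi1 = nm1, ca_disp = ca_disp,
                           classification = if (flex) "flexible" else "rigid",
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# heavy side-chain atoms (beyond the backbone) of one residue
sidechain_heavy <- function(res_atoms)
  res_atoms[!res_atoms$name %in% c(BACKBONE_NAMES, "OXT") &
              res_atoms$element != "H", , drop = FALSE]

#' Detect blocking residues against an ensemble of ligand poses
#'
#' A flexible residue is *blocking* when, in at least one ensemble
#' structure, at least one of its side-chain heavy atoms overlaps
#' (distance < `overlap_fraction` x sum of vdW radii) at least
#' `min_clash_atoms` heavy atoms of at least one non-cognate ligand pose.
#' Poses and structures must share a superposed frame.
#'
#' @param structures List of [protein()] objects.
#' @param ligand_poses List of [ligand()] objects (crystallographic poses
#'   in the common frame).
#' @param flexible Character keys of flexible residues (the search set;
#'   output is always a subset of this).
#' @param overlap_fraction Hard-overlap fraction of summed vdW radii.
#' @param min_clash_atoms Minimum ligand atoms one side-chain atom must
#'   overlap.
#' @param pose_source Optional character vector parallel to `ligand_poses`
#'   giving the source structure id of each pose; a pose is skipped for the
#'   structure with the matching `source_id` (cognate pose).
#' @return data.frame `key`, `n_ligands_blocked`, sorted by ligands
#'   blocked (descending).
#' @export
detect_blocking <- function(structures, ligand_poses, flexible,
                            overlap_fraction = 0.7, min_clash_atoms = 2,
                            pose_source = NULL) {
  if (!length(ligand_poses)) stop("empty ligand pose list")
  keys <- parse_residue_key(flexible)
  n_blocked <- integer(nrow(keys))
  for (r in seq_len(nrow(keys))) {
    blocked_poses <- logical(length(ligand_poses))
    for (s in seq_along(structures)) {
      res <- tryCatch(get_residue(structures[[s]], keys$chain[r],
                                  keys$resno[r]), error = function(e) NULL)
      if (is.null(res)) next
      sc <- sidechain_heavy(res)
      if (!nrow(sc)) next
      sc_xyz <- as.matrix(sc[, c("x", "y", "z")])
      sc_r <- vdw_radius(sc$element)
      for (p in seq_along(ligand_poses)) {
        if (blocked_poses[p]) next
        if (!is.null(pose_source) &&
            identical(pose_source[p], structures[[s]]$source_id)) next
        lig <- ligand_poses[[p]]
        hv <- heavy_indices(lig)
        lx <- ligand_xyz(lig)[hv, , drop = FALSE]
        lr <- vdw_radius(lig$atoms$element[hv])
        for (a in seq_len(nrow(sc_xyz))) {
          d <- sqrt(colSums((t(lx) - sc_xyz[a, ])^2))
          if (sum(d < overlap_fraction * (sc_r[a] + lr)) >= min_clash_atoms) {
            blocked_poses[p] <- TRUE
            break
          }
        }
      }
    }
    n_blocked[r] <- sum(blocked_poses)
  }
  out <- data.frame(key = residue_key(keys$chain, keys$resno),
                    n_ligands_blocked = n_blocked,
                    stringsAsFactors = FALSE)
  out <- out[out$n_ligands_blocked > 0, , drop = FALSE]
  out[order(-out$n_ligands_blocked, out$key), , drop = FALSE]
}

#' Binding-site specification
#'
#' The residue lists steering flexible-receptor covalent docking: the
#' reactive cysteine, the flexible residues repacked after docking, and
#' the blocking residues temporarily mutated to alanine beforehand.
#'
#' @param reactive Residue key of the reactive CYS ("chain:resnum").
#' @param flexible Character vector of flexible residue keys.
#' @param blocking Character vector of blocking residue keys; must be a
#'   subset of `flexible` and must not contain `reactive`.
#' @return Object of class `binding_site_spec`.
#' @export
binding_site_spec <- function(reactive, flexible, blocking = character()) {
  stopifnot(length(reactive) == 1)
  parse_residue_key(c(reactive, flexible, blocking))
  if (!all(blocking %in% flexible))
    stop("blocking residues must be a subset of flexible residues")
  if (reactive %in% blocking)
    stop("the reactive residue cannot be a blocking residue")
  structure(list(reactive = reactive, flexible = flexible,
                 blocking = blocking), class = "binding_site_spec")
}

#' Write / read a binding-site spec as YAML
#'
#' The file carries the residue lists and, optionally, the covalent
#' warhead contract so a single config drives a docking run.
#'
#' @param site A [binding_site_spec()]. @param path File path.
#' @param warhead Optional [warhead_spec()] stored alongside.
#' @export
write_site_spec <- function(site, path, warhead = NULL) {
  y <- list(reactive = site$reactive, flexible = as.list(site$flexible),
            blocking = as.list(site$blocking))
  if (!is.null(warhead))
    y$warhead <- list(reactive_atom = warhead$reactive_atom,
                      bond_length_target = warhead$bond_length_target,
                      bond_length_tol = warhead$bond_length_tol,
                      bond_angle_target = warhead$bond_angle_target,
                      bond_angle_tol = warhead$bond_angle_tol,
                      modified_bonds = lapply(warhead$modified_bonds,
                                              as.numeric))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_site_spec
#' @export
read_site_spec <- function(path) {
  y <- yaml::read_yaml(path)
  binding_site_spec(y$reactive, unlist(y$flexible),
                    if (length(y$blocking)) unlist(y$blocking) else character())
}

#' @rdname write_site_spec
#' @export
read_site_warhead <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$warhead)) return(NULL)
  w <- y$warhead
  warhead_spec(w$reactive_atom, w$bond_length_target, w$bond_length_tol,
               w$bond_angle_target, w$bond_angle_tol,
               lapply(w$modified_bonds, unlist))
}

#' Scatter plot of chi1/chi2 distributions per residue
#'
#' One panel per residue with chi1 on x and chi2 on y (chi1-only residues
#' are drawn on the x axis), mirroring ensemble torsion-distribution plots.
#'
#' @param structures List of superposed [protein()] objects.
#' @param site_residues Character residue keys.
#' @param file Optional PDF path; when NULL plots to the active device.
#' @export
plot_chi_distributions <- function(structures, site_residues, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 8)
    on.exit(grDevices::dev.off())
  }
  keys <- parse_residue_key(site_residues)
  nr <- ceiling(sqrt(nrow(keys)))
  graphics::par(mfrow = c(nr, ceiling(nrow(keys) / nr)),
                mar = c(3, 3, 2, 1))
  for (r in seq_len(nrow(keys))) {
    chis <- vapply(structures, function(s) {
      res <- tryCatch(get_residue(s, keys$chain[r], keys$resno[r]),
                      error = function(e) NULL)
      if (is.null(res)) return(c(NA_real_, NA_real_))
      chi_angles(res)
    }, numeric(2))
    graphics::plot(chis[1L, ], ifelse(is.na(chis[2L, ]), 0, chis[2L, ]),
                   xlim = c(-180, 180), ylim = c(-180, 180), pch = 19,
                   cex = 0.7, xlab = "chi1", ylab = "chi2",
                   main = residue_key(keys$chain[r], keys$resno[r]))
  }
  invisible(NULL)
}
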