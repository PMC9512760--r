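# Side-chain repacking around a docked covalent pose: combinatorial
# optimization of flexible-residue rotamers (weight-biased multi-start
# greedy descent plus Metropolis sweeps over precomputed pairwise energy
# tables), followed by continuous torsional refinement of side-chain chis
# and ligand rotatable torsions. The backbone is never moved and the
# covalent bond geometry is preserved throughout.

# per-type side-chain typing cache: element, vdW radius, donor/acceptor
# flags and the antecedent (parent) atom name for the donor angle test
.sc_typing_cache <- new.env(parent = emptyenv())

sidechain_typing <- function(type) {
  hit <- get0(type, envir = .sc_typing_cache)
  if (!is.null(hit)) return(hit)
  tmpl <- .sidechain_templates[[type]]
  nm <- vapply(tmpl, `[[`, "", "name")
  parent <- vapply(tmpl, `[[`, "", "c")
  el <- element_from_name(nm)
  hydroxyl <- el == "O" & nm %in% c("OG", "OG1", "OH")
  donor <- el == "N" | hydroxyl
  acceptor <- el == "O" |
    (el == "N" & type == "HIS" & nm %in% c("ND1", "NE2"))
  out <- list(names = nm, parent = parent, element = el,
              radius = vdw_radius(el), donor = donor, acceptor = acceptor)
  assign(type, out, envir = .sc_typing_cache)
  out
}

# interaction group of one side chain (atoms beyond CB) from template
# coordinates; antecedents come from the template parent atoms.
sidechain_group <- function(type, sc_xyz, cb) {
  ty <- sidechain_typing(type)
  root <- matrix(NA_real_, nrow(sc_xyz), 3)
  for (k in which(ty$donor)) {
    p <- ty$parent[k]
    root[k, ] <- if (p == "CB") cb else sc_xyz[p, ]
  }
  list(xyz = sc_xyz, radius = ty$radius, donor = ty$donor,
       acceptor = ty$acceptor, root = root)
}

weighted_terms <- function(it, params)
  params$w_rep * it$repulsion + params$w_attr * it$attraction +
  params$w_hb * it$hbond

#' Repack flexible side chains around a covalent pose
#'
#' Optimizes the rotamers of all flexible binding-site residues (the
#' reactive cysteine's chi1 is held fixed by the covalent bond) against a
#' pairwise energy over {flexible side chains, ligand, rigid context},
#' then runs cyclic continuous refinement over each flexible chi and each
#' ligand rotatable torsion (bounded window, golden-section line search).
#' The achieved energy never exceeds the input energy.
#'
#' @param receptor A [protein()] with all residues at their current
#'   (restored) identities.
#' @param pose List with `xyz` (ligand coordinates), `cys_chi1`, `sg`,
#'   `cb` (covalent anchor geometry).
#' @param adduct Adduct-form [ligand()] matching `pose$xyz`.
#' @param site A [binding_site_spec()].
#' @param library Rotamer library (see [default_rotamer_library()]).
#' @param params [score_params()].
#' @param seed Integer seed for multi-start sampling.
#' @param n_starts,n_sweeps Multi-start count and Metropolis sweeps per
#'   start.
#' @param refine Logical: run the continuous stage.
#' @param refine_cycles,refine_window Continuous-refinement cycles and
#'   half-window (degrees).
#' @param context_radius Context truncation radius around the ligand, A.
#' @param shift_penalty Energy cost of moving a residue off its input
#'   rotamer (a flat prior toward the crystallographic conformation; it
#'   resists gratuitous induced fit while being negligible against a real
#'   steric clash).
#' @return List: `structure` (repacked receptor), `lig_xyz` (refined
#'   ligand coordinates), `energy_before`, `energy_after`,
#'   `moved_residues` (data.frame of chi changes), `n_sweeps`.
#' @export
repack_site <- function(receptor, pose, adduct, site,
                        library = default_rotamer_library(),
                        params = score_params(), seed = 1L, n_starts = 2,
                        n_sweeps = 40, refine = TRUE, refine_cycles = 2,
                        refine_window = 15, context_radius = 12,
                        shift_penalty = 1) {
  lig_xyz <- as.matrix(pose$xyz)
  hv <- heavy_indices(adduct)
  keys <- parse_residue_key(setdiff(site$flexible, site$reactive))
  # collect workable flexible residues
  flex <- list()
  for (r in seq_len(nrow(keys))) {
    res <- tryCatch(get_residue(receptor, keys$chain[r], keys$resno[r]),
                    error = function(e) NULL)
    if (is.null(res)) next
    ty <- res$resid[1L]
    if (ty %in% c("GLY", "ALA") || !template_supported(ty)) next
    n <- residue_atom_xyz(res, "N"); ca <- residue_atom_xyz(res, "CA")
    c_ <- residue_atom_xyz(res, "C")
    if (is.null(n) || is.null(ca) || is.null(c_)) {
      warning(sprintf("flexible residue %s:%s lacks backbone; skipped",
                      keys$chain[r], keys$resno[r]))
      next
    }
    cb <- residue_atom_xyz(res, "CB")
    if (is.null(cb)) cb <- ideal_cb(n, ca, c_)
    rot <- library[[ty]]
    if (is.null(rot)) next
    chis_cur <- tryCatch(measure_chis(res, ty), error = function(e) NULL)
    rot_chis <- rot$chis
    rot_w <- rot$weights
    if (!is.null(chis_cur)) {
      rot_chis <- rbind(rot_chis, chis_cur)
      rot_w <- c(rot_w, max(rot_w))
      rot_w <- rot_w / sum(rot_w)
    }
    flex[[length(flex) + 1L]] <- list(
      key = residue_key(keys$chain[r], keys$resno[r]),
      chain = keys$chain[r], resno = keys$resno[r], type = ty,
      n = n, ca = ca, c = c_, cb = cb, res = res,
      chis = rot_chis, weights = rot_w,
      current = if (is.null(chis_cur)) NA_integer_ else nrow(rot_chis))
  }
  nf <- length(flex)
  # context: rigid receptor part near the ligand
  center <- colMeans(lig_xyz[hv, , drop = FALSE])
  ctx <- receptor_context_atoms(receptor, site, include_flexible_sc = FALSE,
                                center = center, radius = context_radius + 8)
  ctx_grp <- receptor_group(ctx)
  subset_group <- function(g, keep)
    list(xyz = g$xyz[keep, , drop = FALSE], radius = g$radius[keep],
         donor = g$donor[keep], acceptor = g$acceptor[keep],
         root = g$root[keep, , drop = FALSE])
  lig_grp <- ligand_group(adduct, lig_xyz)
  base_const <- weighted_terms(interaction_terms(lig_grp, ctx_grp, params),
                               params) +
    params$w_tors * torsion_strain(adduct, lig_xyz)
  if (nf == 0) {
    return(list(structure = receptor, lig_xyz = lig_xyz,
                energy_before = base_const, energy_after = base_const,
                moved_residues = data.frame(), n_sweeps = 0L))
  }
  # rotamer groups + energy tables; each residue's steric context excludes
  # its own and adjacent residues (bonded proximity)
  ctx_for <- lapply(flex, function(fi)
    subset_group(ctx_grp, ctx$het | ctx$chain != fi$chain |
                   abs(ctx$resno - fi$resno) > 1))
  groups <- vector("list", nf)
  e_self <- vector("list", nf)
  for (i in seq_len(nf)) {
    fi <- flex[[i]]
    nr <- nrow(fi$chis)
    gi <- vector("list", nr)
    ei <- numeric(nr)
    for (r in seq_len(nr)) {
      sm <- sidechain_xyz(fi$n, fi$ca, fi$cb, fi$type,
                          fi$chis[r, seq_len(n_chi(fi$type))])
      gi[[r]] <- sidechain_group(fi$type, sm, fi$cb)
      gi[[r]]$sc_xyz <- sm
      ei[r] <- weighted_terms(interaction_terms(gi[[r]], ctx_for[[i]],
                                                params), params) +
        weighted_terms(interaction_terms(gi[[r]], lig_grp, params), params)
      if (!is.na(fi$current) && r != fi$current)
        ei[r] <- ei[r] + shift_penalty
    }
    groups[[i]] <- gi
    e_self[[i]] <- ei
  }
  # pairwise rotamer-rotamer tables: one stacked distance computation per
  # residue pair, then block-sliced term evaluation
  e_pair <- vector("list", nf)
  for (i in seq_len(nf)) e_pair[[i]] <- vector("list", nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    if (j <= i) next
    ni <- nrow(flex[[i]]$chis)
    nj <- nrow(flex[[j]]$chis)
    m <- matrix(0, ni, nj)
    if (vnorm(flex[[i]]$cb - flex[[j]]$cb) < 14) {
      ai <- nrow(groups[[i]][[1L]]$xyz)
      aj <- nrow(groups[[j]][[1L]]$xyz)
      Xi <- do.call(rbind, lapply(groups[[i]], `[[`, "xyz"))
      Xj <- do.call(rbind, lapply(groups[[j]], `[[`, "xyz"))
      D <- cross_dist(Xi, Xj)
      ri <- rep(groups[[i]][[1L]]$radius, ni)
      rj <- rep(groups[[j]][[1L]]$radius, nj)
      d_on <- params$clash_onset_fraction * (ri + rep(rj, each = length(ri)))
      ov <- d_on - D
      rep2 <- ifelse(ov > 0, ov^2, 0)
      ramp <- (params$attr_range - D) / pmax(params$attr_range - d_on, 1e-6)
      ramp[ov > 0] <- 0
      ramp[ramp < 0] <- 0
      ramp[ramp > 1] <- 1
      polar <- (any(groups[[i]][[1L]]$donor) &&
                  any(groups[[j]][[1L]]$acceptor)) ||
        (any(groups[[j]][[1L]]$donor) && any(groups[[i]][[1L]]$acceptor))
      for (r in seq_len(ni)) for (s in seq_len(nj)) {
        rows <- (r - 1L) * ai + seq_len(ai)
        cols <- (s - 1L) * aj + seq_len(aj)
        rsub <- ramp[rows, cols, drop = FALSE]
        e <- params$w_rep * sum(rep2[rows, cols]) +
          params$w_attr * (-sum(pmin(.rowSums(rsub, ai, aj),
                                     params$attr_atom_cap)))
        if (polar) {
          dsub <- D[rows, cols, drop = FALSE]
          hb <- hb_count_onesided(groups[[i]][[r]], groups[[j]][[s]], dsub,
                                  params) +
            hb_count_onesided(groups[[j]][[s]], groups[[i]][[r]], t(dsub),
                              params)
          e <- e - params$w_hb * hb
        }
        m[r, s] <- e
      }
    }
    e_pair[[i]][[j]] <- m
  }
  pair_e <- function(i, r, j, s)
    if (i < j) e_pair[[i]][[j]][r, s] else e_pair[[j]][[i]][s, r]
  total_e <- function(assign) {
    e <- 0
    for (i in seq_len(nf)) {
      e <- e + e_self[[i]][assign[i]]
      if (i < nf) for (j in seq((i + 1L), nf))
        e <- e + pair_e(i, assign[i], j, assign[j])
    }
    e
  }
  delta_vec <- function(i, assign) {
    # energy of every rotamer of residue i given the others
    ev <- e_self[[i]]
    for (j in seq_len(nf)) {
      if (j == i) next
      ev <- ev + if (i < j) e_pair[[i]][[j]][, assign[j]]
                 else e_pair[[j]][[i]][assign[j], ]
    }
    ev
  }
  start_assign <- vapply(seq_len(nf), function(i) {
    if (!is.na(flex[[i]]$current)) flex[[i]]$current
    else which.min(e_self[[i]])
  }, integer(1))
  energy_before <- total_e(start_assign) + base_const
  best_assign <- start_assign
  best_e <- total_e(start_assign)
  run_start <- function(assign) {
    repeat {
      improved <- FALSE
      for (i in seq_len(nf)) {
        ev <- delta_vec(i, assign)
        b <- which.min(ev)
        if (ev[b] + 1e-12 < ev[assign[i]]) {
          assign[i] <- b
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    e_cur <- total_e(assign)
    e_loc_best <- e_cur
    a_loc_best <- assign
    for (sw in seq_len(n_sweeps)) {
      for (i in sample.int(nf)) {
        prop <- sample.int(nrow(flex[[i]]$chis), 1L)
        if (prop == assign[i]) next
        ev <- delta_vec(i, assign)
        du <- ev[prop] - ev[assign[i]]
        if (du <= 0 || stats::runif(1) < exp(-du)) {
          assign[i] <- prop
          e_cur <- e_cur + du
          if (e_cur < e_loc_best) {
            e_loc_best <- e_cur
            a_loc_best <- assign
          }
        }
      }
    }
    list(e = e_loc_best, a = a_loc_best)
  }
  with_seed(seed, {
    for (st in seq_len(n_starts)) {
      init <- if (st == 1L) start_assign else
        vapply(seq_len(nf), function(i)
          sample.int(nrow(flex[[i]]$chis), 1L, prob = flex[[i]]$weights),
          integer(1))
      res <- run_start(init)
      if (res$e < best_e) {
        best_e <- res$e
        best_assign <- res$a
      }
    }
  })
  # apply best assignment
  cur_groups <- lapply(seq_len(nf), function(i) groups[[i]][[best_assign[i]]])
  cur_chis <- lapply(seq_len(nf), function(i) {
    fi <- flex[[i]]
    if (!is.na(fi$current) && best_assign[i] == fi$current)
      measure_chis(fi$res, fi$type)
    else fi$chis[best_assign[i], seq_len(n_chi(fi$type))]
  })
  energy_after <- best_e + base_const
  # ---- continuous torsional refinement ----
  if (refine) {
    resid_term <- function(i, grp) {
      e <- weighted_terms(interaction_terms(grp, ctx_for[[i]], params),
                          params) +
        weighted_terms(interaction_terms(grp, lig_grp, params), params)
      for (j in seq_len(nf)) if (j != i)
        e <- e + weighted_terms(interaction_terms(grp, cur_groups[[j]],
                                                  params), params)
      e
    }
    lig_term <- function(lg, xyz) {
      e <- weighted_terms(interaction_terms(lg, ctx_grp, params), params) +
        params$w_tors * torsion_strain(adduct, xyz)
      for (j in seq_len(nf))
        e <- e + weighted_terms(interaction_terms(lg, cur_groups[[j]],
                                                  params), params)
      e
    }
    for (cyc in seq_len(refine_cycles)) {
      for (i in seq_len(nf)) {
        fi <- flex[[i]]
        nchi <- n_chi(fi$type)
        for (k in seq_len(nchi)) {
          cur <- cur_chis[[i]]
          obj <- function(v) {
            ch <- cur
            ch[k] <- v
            sm <- sidechain_xyz(fi$n, fi$ca, fi$cb, fi$type, ch)
            resid_term(i, sidechain_group(fi$type, sm, fi$cb))
          }
          e0 <- resid_term(i, cur_groups[[i]])
          opt <- stats::optimize(obj, tol = 0.2, c(cur[k] - refine_window,
                                        cur[k] + refine_window))
          if (opt$objective < e0 - 1e-9) {
            cur_chis[[i]][k] <- wrap180(opt$minimum)
            sm <- sidechain_xyz(fi$n, fi$ca, fi$cb, fi$type, cur_chis[[i]])
            cur_groups[[i]] <- sidechain_group(fi$type, sm, fi$cb)
            cur_groups[[i]]$sc_xyz <- sm
            energy_after <- energy_after - (e0 - opt$objective)
          }
        }
      }
      # ligand internal torsions (branch not containing the reactive atom
      # moves, so the covalent anchor stays fixed) and spin about S-C
      ridx <- reactive_index(adduct, pose)
      for (t4 in adduct$rotatable) {
        t4m <- t4
        mv <- setdiff(branch_atoms(adduct, t4m[2L], t4m[3L]), t4m[3L])
        if (ridx %in% mv) t4m <- rev(t4)
        mv <- setdiff(branch_atoms(adduct, t4m[2L], t4m[3L]), t4m[3L])
        if (ridx %in% mv) next
        cur_val <- dihedral(lig_xyz[t4m[1L], ], lig_xyz[t4m[2L], ],
                            lig_xyz[t4m[3L], ], lig_xyz[t4m[4L], ])
        obj <- function(v) {
          xz <- set_torsion(adduct, lig_xyz, t4m, v)
          lig_term(ligand_group(adduct, xz), xz)
        }
        e0 <- lig_term(lig_grp, lig_xyz)
        opt <- stats::optimize(obj, tol = 0.2, c(cur_val - refine_window,
                                      cur_val + refine_window))
        if (opt$objective < e0 - 1e-9) {
          lig_xyz <- set_torsion(adduct, lig_xyz, t4m, wrap180(opt$minimum))
          lig_grp <- ligand_group(adduct, lig_xyz)
          energy_after <- energy_after - (e0 - opt$objective)
        }
      }
      if (!is.null(pose$sg)) {
        axis <- lig_xyz[ridx, ] - pose$sg
        obj <- function(v) {
          xz <- rotate_about_line(lig_xyz, pose$sg, axis, v)
          lig_term(ligand_group(adduct, xz), xz)
        }
        e0 <- lig_term(lig_grp, lig_xyz)
        opt <- stats::optimize(obj, tol = 0.2, c(-refine_window, refine_window))
        if (opt$objective < e0 - 1e-9) {
          lig_xyz <- rotate_about_line(lig_xyz, pose$sg, axis, opt$minimum)
          lig_grp <- ligand_group(adduct, lig_xyz)
          energy_after <- energy_after - (e0 - opt$objective)
        }
      }
    }
  }
  # write repacked side chains into the structure
  out <- receptor
  moved <- list()
  for (i in seq_len(nf)) {
    fi <- flex[[i]]
    old_chis <- tryCatch(measure_chis(fi$res, fi$type),
                         error = function(e) rep(NA_real_, n_chi(fi$type)))
    new_res <- build_sidechain(fi$res, cur_chis[[i]], fi$type)
    out <- set_residue_atoms(out, fi$chain, fi$resno, new_res)
    moved[[i]] <- data.frame(key = fi$key, type = fi$type,
                             chi1_old = old_chis[1L],
                             chi1_new = cur_chis[[i]][1L],
                             changed = !isTRUE(all.equal(old_chis,
                                                         cur_chis[[i]],
                                                         tolerance = 1e-6)),
                             stringsAsFactors = FALSE)
  }
  list(structure = out, lig_xyz = lig_xyz, energy_before = energy_before,
       energy_after = energy_after,
       moved_residues = do.call(rbind, moved), n_sweeps = n_sweeps)
}

reactive_index <- function(adduct, pose) {
  # reactive atom: declared on the pose, else the atom nearest the SG
  if (!is.null(pose$reactive_atom)) return(pose$reactive_atom)
  which.min(sqrt(colSums((t(as.matrix(pose$xyz)) - pose$sg)^2)))
}

# measure the full chi vector of a residue (errors if atoms missing)
measure_chis <- function(res_atoms, resname = res_atoms$resid[1L]) {
  resname <- toupper(resname)
  nc <- n_chi(resname)
  if (nc == 0) return(numeric(0))
  tmpl <- .sidechain_templates[[resname]]
  chain_names <- c("N", "CA", "CB")
  # chi k is the dihedral over atoms (k-3..k) of the chi chain
  chi_chain <- switch(resname,
    SER = c("OG"), CYS = c("SG"), THR = c("OG1"), VAL = c("CG1"),
    LEU = c("CG", "CD1"), ILE = c("CG1", "CD1"), ASP = c("CG", "OD1"),
    ASN = c("CG", "OD1"), PHE = c("CG", "CD1"), TYR = c("CG", "CD1"),
    HIS = c("CG", "ND1"), GLU = c("CG", "CD", "OE1"),
    GLN = c("CG", "CD", "OE1"), MET = c("CG", "SD", "CE"),
    LYS = c("CG", "CD", "CE", "NZ"), ARG = c("CG", "CD", "NE", "CZ"),
    stop("unsupported type ", resname))
  full <- c(chain_names, chi_chain)
  pos <- lapply(full, function(nm) residue_atom_xyz(res_atoms, nm))
  if (any(vapply(pos, is.null, logical(1))))
    stop("incomplete side chain for ", resname)
  vapply(seq_len(nc), function(k)
    dihedral(pos[[k]], pos[[k + 1L]], pos[[k + 2L]], pos[[k + 3L]]),
    numeric(1))
}

#' Continuous torsional refinement of a repacked pose
#'
#' Thin wrapper over the refinement stage of [repack_site()] (rotamer
#' optimization disabled, continuous stage only).
#'
#' @inheritParams repack_site
#' @return As [repack_site()].
#' @export
refine_continuous <- function(receptor, pose, adduct, site,
                              params = score_params(), refine_cycles = 2,
                              refine_window = 15) {
  repack_site(receptor, pose, adduct, site,
              library = default_rotamer_library(), params = params,
              seed = 1L, n_starts = 0L, n_sweeps = 0L, refine = TRUE,
              refine_cycles = refine_cycles, refine_window = refine_window)
}
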