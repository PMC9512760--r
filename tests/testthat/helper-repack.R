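# Exhaustive-enumeration oracle for the repacker: builds its own
# self/pair energy tables from the package's pairwise terms and searches
# ALL rotamer combinations, then reports the gap between the repacker's
# achieved assignment and the global optimum. The search (exhaustive vs
# greedy + Metropolis) is what is independent here.

repack_exhaustive_gap <- function(receptor, pose, adduct, site, lib,
                                  params, seed = 1) {
  wt <- function(it) params$w_rep * it$repulsion +
    params$w_attr * it$attraction + params$w_hb * it$hbond
  keys <- covflex:::parse_residue_key(setdiff(site$flexible,
                                              site$reactive))
  flex <- list()
  for (r in seq_len(nrow(keys))) {
    res <- get_residue(receptor, keys$chain[r], keys$resno[r])
    ty <- res$resid[1L]
    if (ty %in% c("GLY", "ALA") || !covflex:::template_supported(ty)) next
    flex[[length(flex) + 1L]] <- list(chain = keys$chain[r],
                                      resno = keys$resno[r], type = ty,
                                      res = res)
  }
  nf <- length(flex)
  stopifnot(nf >= 1, nf <= 3)
  lig_grp <- covflex:::ligand_group(adduct, pose$xyz)
  ctx <- covflex:::receptor_context_atoms(receptor, site,
                                          include_flexible_sc = FALSE)
  grp_of <- function(fi, rot) {
    nn <- covflex:::residue_atom_xyz(fi$res, "N")
    nca <- covflex:::residue_atom_xyz(fi$res, "CA")
    ncb <- covflex:::residue_atom_xyz(fi$res, "CB")
    if (is.null(ncb))
      ncb <- covflex:::ideal_cb(nn, nca,
                                covflex:::residue_atom_xyz(fi$res, "C"))
    chis <- lib[[fi$type]]$chis[rot, seq_len(n_chi(fi$type))]
    sm <- covflex:::sidechain_xyz(nn, nca, ncb, fi$type, chis)
    covflex:::sidechain_group(fi$type, sm, ncb)
  }
  groups <- lapply(flex, function(fi)
    lapply(seq_len(nrow(lib[[fi$type]]$chis)), function(r) grp_of(fi, r)))
  e_self <- lapply(seq_len(nf), function(i) {
    fi <- flex[[i]]
    sub <- ctx[!(ctx$chain == fi$chain & !ctx$het &
                   abs(ctx$resno - fi$resno) <= 1), , drop = FALSE]
    sub_grp <- covflex:::receptor_group(sub)
    vapply(groups[[i]], function(g)
      wt(covflex:::interaction_terms(g, sub_grp, params)) +
        wt(covflex:::interaction_terms(g, lig_grp, params)), numeric(1))
  })
  e_pair <- array(list(), dim = c(nf, nf))
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    if (j <= i) next
    m <- matrix(0, length(groups[[i]]), length(groups[[j]]))
    for (r in seq_len(nrow(m))) for (s2 in seq_len(ncol(m)))
      m[r, s2] <- wt(covflex:::interaction_terms(groups[[i]][[r]],
                                                 groups[[j]][[s2]],
                                                 params))
    e_pair[[i, j]] <- m
  }
  energy_of <- function(assign) {
    e <- sum(vapply(seq_len(nf), function(i) e_self[[i]][assign[i]],
                    numeric(1)))
    for (i in seq_len(nf)) for (j in seq_len(nf)) {
      if (j <= i) next
      e <- e + e_pair[[i, j]][assign[i], assign[j]]
    }
    e
  }
  combos <- as.matrix(expand.grid(lapply(flex, function(fi)
    seq_len(nrow(lib[[fi$type]]$chis)))))
  energies <- apply(combos, 1, energy_of)
  e_min <- min(energies)
  # repacker run under the same conditions (no shift prior, no continuous
  # stage, rotamer search only)
  sub_site <- binding_site_spec(site$reactive,
                                vapply(flex, function(fi)
                                  sprintf("%s:%d", fi$chain, fi$resno), ""))
  rp <- repack_site(receptor, pose, adduct, sub_site, library = lib,
                    params = params, seed = seed, refine = FALSE,
                    shift_penalty = 0)
  achieved <- vapply(seq_len(nf), function(i) {
    fi <- flex[[i]]
    got <- covflex:::measure_chis(get_residue(rp$structure, fi$chain,
                                              fi$resno))
    chis <- lib[[fi$type]]$chis[, seq_len(n_chi(fi$type)), drop = FALSE]
    diffs <- apply(chis, 1, function(row)
      max(abs(covflex:::wrap180(row - got))))
    which.min(diffs)
  }, integer(1))
  list(gap = energy_of(achieved) - e_min, e_min = e_min,
       e_achieved = energy_of(achieved))
}
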