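# Residue mutation and restoration. Blocking residues are temporarily
# mutated to alanine so the opened pocket can be docked into, then restored
# before refinement; the glycine variant prepares loop-mutant receptors for
# downstream free-energy engines.
#
# Archived side chains are stored in the local backbone frame (origin CA,
# axes from N and C), so restoration re-anchors rigidly even if the residue
# drifted during docking-stage refinement.

backbone_frame <- function(n, ca, c_) {
  x <- vunit(n - ca)
  z <- vunit(vcross(x, c_ - ca))
  y <- vcross(z, x)
  rbind(x, y, z)  # rows are frame axes
}

to_frame <- function(xyz, frame, origin)
  t(frame %*% t(sweep(as.matrix(xyz), 2, origin)))

from_frame <- function(local, frame, origin)
  sweep(t(t(frame) %*% t(as.matrix(local))), 2, origin, "+")

#' Mutate residues to alanine or glycine
#'
#' Side-chain atoms beyond CB (beyond CA for glycine) are removed and
#' archived in the local backbone frame; the residue is renamed. Backbone
#' coordinates (and CB, for alanine) are untouched.
#'
#' @param structure A [protein()].
#' @param residues Character residue keys ("chain:resnum").
#' @param target "ALA" or "GLY".
#' @return List with `structure` (mutated) and `records` (list of
#'   mutation records consumed by [restore_residues()]).
#' @export
mutate_to <- function(structure, residues, target = c("ALA", "GLY")) {
  target <- match.arg(target)
  keys <- parse_residue_key(residues)
  records <- list()
  for (r in seq_len(nrow(keys))) {
    res <- get_residue(structure, keys$chain[r], keys$resno[r])
    orig <- res$resid[1L]
    if (orig == "GLY" && target == "ALA")
      stop("cannot mutate GLY to ALA: no CB anchor to keep")
    keep_names <- if (target == "ALA") c(BACKBONE_NAMES, "OXT", "CB")
                  else c(BACKBONE_NAMES, "OXT")
    removed <- res[!res$name %in% keep_names, , drop = FALSE]
    kept <- res[res$name %in% keep_names, , drop = FALSE]
    n <- residue_atom_xyz(res, "N"); ca <- residue_atom_xyz(res, "CA")
    c_ <- residue_atom_xyz(res, "C")
    if (is.null(n) || is.null(ca) || is.null(c_))
      stop(sprintf("residue %s:%s lacks a complete backbone frame",
                   keys$chain[r], keys$resno[r]))
    frame <- backbone_frame(n, ca, c_)
    local <- if (nrow(removed))
      to_frame(removed[, c("x", "y", "z")], frame, ca) else
        matrix(numeric(0), 0, 3)
    kept$resid <- target
    structure <- set_residue_atoms(structure, keys$chain[r], keys$resno[r],
                                   kept)
    records[[length(records) + 1L]] <- list(
      key = residue_key(keys$chain[r], keys$resno[r]),
      original_name = orig, mutant_name = target,
      atom_names = removed$name, atom_elements = removed$element,
      local_coords = local)
  }
  list(structure = structure, records = records)
}

#' Restore mutated residues to their original identities
#'
#' Archived side-chain atoms are re-inserted, rigidly re-anchored on the
#' residue's current local backbone frame; if the backbone has not moved,
#' original coordinates are reproduced exactly.
#'
#' @param structure A [protein()] whose residues were mutated by
#'   [mutate_to()].
#' @param records Mutation records from [mutate_to()].
#' @return The restored [protein()].
#' @export
restore_residues <- function(structure, records) {
  for (rec in records) {
    k <- parse_residue_key(rec$key)
    res <- tryCatch(get_residue(structure, k$chain, k$resno),
                    error = function(e)
                      stop("mutation record refers to absent residue ",
                           rec$key, call. = FALSE))
    if (res$resid[1L] != rec$mutant_name)
      stop(sprintf("record/residue mismatch at %s: expected %s, found %s",
                   rec$key, rec$mutant_name, res$resid[1L]))
    n <- residue_atom_xyz(res, "N"); ca <- residue_atom_xyz(res, "CA")
    c_ <- residue_atom_xyz(res, "C")
    frame <- backbone_frame(n, ca, c_)
    res$resid <- rec$original_name
    if (length(rec$atom_names)) {
      world <- from_frame(rec$local_coords, frame, ca)
      proto <- res[1L, ]
      add <- do.call(rbind, lapply(seq_along(rec$atom_names), function(i) {
        row <- proto
        row$name <- rec$atom_names[i]
        row$element <- rec$atom_elements[i]
        row$x <- world[i, 1L]; row$y <- world[i, 2L]; row$z <- world[i, 3L]
        row
      }))
      res <- rbind(res, add)
    }
    structure <- set_residue_atoms(structure, k$chain, k$resno, res)
  }
  structure
}

#' Prepare a glycine loop-mutant receptor
#'
#' Mutates the requested residues to glycine for use in downstream
#' free-energy calculations, where glycine backbones cross conformational
#' barriers faster. The report flags (a) any run of 3+ consecutive
#' glycines created by the mutations and (b) any mutated residue whose
#' removed side chain lay within `contact_cutoff` of ligand heavy atoms
#' (such contacts violate the assumption that the mutation does not
#' perturb relative binding).
#'
#' @param structure A [protein()].
#' @param mutations Character residue keys; the classic switch-II set is
#'   glutamates 62/63/76 plus tyrosine 64.
#' @param reactive Optional reactive-residue key; requesting its mutation
#'   is an error.
#' @param ligand Optional [ligand()] whose heavy atoms are scanned for
#'   side-chain contacts before mutation.
#' @param contact_cutoff Angstrom; default 4.0.
#' @return List with `structure`, `records`, and `report` (data.frame of
#'   mutated residues with contact flags, plus `gly_runs`).
#' @export
prepare_loop_mutant <- function(structure, mutations, reactive = NULL,
                                ligand = NULL, contact_cutoff = 4.0) {
  if (!is.null(reactive) && reactive %in% mutations)
    stop("refusing to mutate the reactive residue ", reactive)
  keys <- parse_residue_key(mutations)
  contacts <- logical(nrow(keys))
  if (!is.null(ligand)) {
    hv <- heavy_indices(ligand)
    lx <- ligand_xyz(ligand)[hv, , drop = FALSE]
    for (r in seq_len(nrow(keys))) {
      res <- get_residue(structure, keys$chain[r], keys$resno[r])
      sc <- sidechain_heavy(res)
      sc <- sc[sc$name != "CB", , drop = FALSE]
      if (!nrow(sc)) next
      dmin <- min(apply(as.matrix(sc[, c("x", "y", "z")]), 1, function(p)
        min(sqrt(colSums((t(lx) - p)^2)))))
      contacts[r] <- dmin < contact_cutoff
      if (contacts[r])
        warning(sprintf("mutated residue %s side chain within %.1f A of ligand",
                        residue_key(keys$chain[r], keys$resno[r]),
                        contact_cutoff))
    }
  }
  mut <- mutate_to(structure, mutations, "GLY")
  # scan for runs of >= 3 consecutive glycines
  rt <- residue_table(mut$structure)
  gly_runs <- character()
  for (ch in unique(rt$chain)) {
    sub <- rt[rt$chain == ch, ]
    sub <- sub[order(sub$resno), ]
    is_g <- sub$resid == "GLY"
    consec <- c(TRUE, diff(sub$resno) == 1)
    run_id <- cumsum(!(is_g & consec))
    for (g in split(seq_len(nrow(sub)), run_id)) {
      g <- g[is_g[g]]
      if (length(g) >= 3)
        gly_runs <- c(gly_runs,
                      sprintf("%s:%d-%d (%d consecutive glycines)", ch,
                              sub$resno[g[1L]], sub$resno[g[length(g)]],
                              length(g)))
    }
  }
  report <- data.frame(key = residue_key(keys$chain, keys$resno),
                       original = vapply(mut$records, `[[`, "",
                                         "original_name"),
                       ligand_contact = contacts, stringsAsFactors = FALSE)
  list(structure = mut$structure, records = mut$records,
       report = list(mutations = report, gly_runs = gly_runs))
}
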