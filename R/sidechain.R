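# Ideal-geometry side-chain templates, chi-angle definitions, side-chain
# construction from internal coordinates, a compact backbone-independent
# rotamer library, and an ideal-geometry backbone builder.
#
# Template rows place one heavy atom from three previously placed atoms
# (NeRF): dihedrals are either tied to a chi variable (with an offset, for
# branches like VAL CG2) or fixed (ring closure, sp2 groups).

# chi-defining atoms: chi1 = N-CA-CB-Xg, chi2 = CA-CB-Xg-Xd
.chi_gamma <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                TRP = "CG", TYR = "CG", VAL = "CG1")
.chi_delta <- c(ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD", GLU = "CD",
                HIS = "ND1", ILE = "CD1", LEU = "CD1", LYS = "CD", MET = "SD",
                PHE = "CD1", PRO = "CD", TRP = "CD1", TYR = "CD1")

# row: name, a, b, c, len, ang, dih ("chiK", "chiK+120", "chiK-120",
# "chiK+180", or a fixed numeric as character)
.sc_row <- function(name, a, b, c, len, ang, dih)
  list(name = name, a = a, b = b, c = c, len = len, ang = ang, dih = dih)

.sidechain_templates <- list(
  SER = list(.sc_row("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = list(.sc_row("SG", "N", "CA", "CB", 1.808, 113.8, "chi1")),
  THR = list(.sc_row("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
             .sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120")),
  VAL = list(.sc_row("CG1", "N", "CA", "CB", 1.527, 110.5, "chi1"),
             .sc_row("CG2", "N", "CA", "CB", 1.527, 110.5, "chi1-120")),
  LEU = list(.sc_row("CG", "N", "CA", "CB", 1.530, 116.3, "chi1"),
             .sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
             .sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2+120")),
  ILE = list(.sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, "chi1"),
             .sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120"),
             .sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2")),
  ASP = list(.sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             .sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
             .sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180")),
  ASN = list(.sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             .sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
             .sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  GLU = list(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             .sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             .sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
             .sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180")),
  GLN = list(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             .sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             .sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
             .sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")),
  LYS = list(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             .sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             .sc_row("CE", "CB", "CG", "CD", 1.520, 111.3, "chi3"),
             .sc_row("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4")),
  ARG = list(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             .sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             .sc_row("NE", "CB", "CG", "CD", 1.461, 111.7, "chi3"),
             .sc_row("CZ", "CG", "CD", "NE", 1.330, 124.2, "chi4"),
             .sc_row("NH1", "CD", "NE", "CZ", 1.330, 120.0, "0"),
             .sc_row("NH2", "CD", "NE", "CZ", 1.330, 120.0, "180")),
  MET = list(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             .sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
             .sc_row("CE", "CB", "CG", "SD", 1.791, 100.8, "chi3")),
  PHE = list(.sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
             .sc_row("CD1", "CA", "CB", "CG", 1.391, 120.8, "chi2"),
             .sc_row("CD2", "CA", "CB", "CG", 1.391, 120.8, "chi2+180"),
             .sc_row("CE1", "CB", "CG", "CD1", 1.391, 120.8, "180"),
             .sc_row("CE2", "CB", "CG", "CD2", 1.391, 120.8, "180"),
             .sc_row("CZ", "CG", "CD1", "CE1", 1.391, 120.0, "0")),
  TYR = list(.sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
             .sc_row("CD1", "CA", "CB", "CG", 1.391, 120.8, "chi2"),
             .sc_row("CD2", "CA", "CB", "CG", 1.391, 120.8, "chi2+180"),
             .sc_row("CE1", "CB", "CG", "CD1", 1.391, 120.8, "180"),
             .sc_row("CE2", "CB", "CG", "CD2", 1.391, 120.8, "180"),
             .sc_row("CZ", "CG", "CD1", "CE1", 1.391, 120.0, "0"),
             .sc_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, "180")),
  HIS = list(.sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
             .sc_row("ND1", "CA", "CB", "CG", 1.378, 122.7, "chi2"),
             .sc_row("CD2", "CA", "CB", "CG", 1.354, 129.7, "chi2+180"),
             .sc_row("CE1", "CB", "CG", "ND1", 1.320, 109.3, "180"),
             .sc_row("NE2", "CB", "CG", "CD2", 1.374, 107.2, "180"))
)

#' Number of chi angles per residue type (template-supported types)
#' @param resname 3-letter residue code(s).
#' @return Integer vector (0 for GLY/ALA).
#' @export
n_chi <- function(resname) {
  tab <- c(GLY = 0, ALA = 0, SER = 1, CYS = 1, THR = 1, VAL = 1,
           LEU = 2, ILE = 2, ASP = 2, ASN = 2, PHE = 2, TYR = 2, HIS = 2,
           GLU = 3, GLN = 3, MET = 3, LYS = 4, ARG = 4)
  out <- tab[toupper(resname)]
  if (anyNA(out))
    stop("no side-chain template for residue type(s): ",
         paste(unique(resname[is.na(out)]), collapse = ", "))
  unname(out)
}

template_supported <- function(resname)
  toupper(resname) %in% c("GLY", "ALA", names(.sidechain_templates))

#' Measure chi1/chi2 of a residue
#'
#' chi1 = dihedral(N, CA, CB, Xg) and chi2 = dihedral(CA, CB, Xg, Xd) with
#' the standard per-type defining-atom table. A missing defining atom gives
#' `NA` (absence is a value, not an error).
#'
#' @param res_atoms data.frame of one residue's atoms (as from
#'   [get_residue()]).
#' @param resname Residue type; defaults to the residue's `resid`.
#' @return Named numeric vector `c(chi1, chi2)` in degrees, `NA` where
#'   undefined.
#' @export
chi_angles <- function(res_atoms, resname = res_atoms$resid[1L]) {
  resname <- toupper(resname)
  out <- c(chi1 = NA_real_, chi2 = NA_real_)
  g_name <- .chi_gamma[resname]
  if (is.na(g_name)) return(out)
  n <- residue_atom_xyz(res_atoms, "N")
  ca <- residue_atom_xyz(res_atoms, "CA")
  cb <- residue_atom_xyz(res_atoms, "CB")
  xg <- residue_atom_xyz(res_atoms, unname(g_name))
  if (is.null(n) || is.null(ca) || is.null(cb) || is.null(xg)) return(out)
  out["chi1"] <- dihedral(n, ca, cb, xg)
  d_name <- .chi_delta[resname]
  if (!is.na(d_name)) {
    xd <- residue_atom_xyz(res_atoms, unname(d_name))
    if (!is.null(xd)) out["chi2"] <- dihedral(ca, cb, xg, xd)
  }
  out
}

resolve_template_dih <- function(dih, chis) {
  if (grepl("^chi", dih)) {
    k <- as.integer(substr(dih, 4, 4))
    off <- 0
    if (nchar(dih) > 4) off <- as.numeric(substr(dih, 5, nchar(dih)))
    if (k > length(chis)) stop("chi count mismatch for template")
    wrap180(chis[k] + off)
  } else as.numeric(dih)
}

# coordinates of side-chain atoms beyond CB for `resname` at chi values,
# given backbone N/CA and CB positions. Returns matrix with rownames.
sidechain_xyz <- function(n, ca, cb, resname, chis) {
  resname <- toupper(resname)
  tmpl <- .sidechain_templates[[resname]]
  if (is.null(tmpl)) stop("no side-chain template for ", resname)
  if (length(chis) != n_chi(resname))
    stop(sprintf("%s expects %d chi angle(s), got %d", resname,
                 n_chi(resname), length(chis)))
  pos <- list(N = n, CA = ca, CB = cb)
  out <- matrix(NA_real_, length(tmpl), 3,
                dimnames = list(vapply(tmpl, `[[`, "", "name"), NULL))
  for (row in tmpl) {
    p <- place_atom(pos[[row$a]], pos[[row$b]], pos[[row$c]], row$len,
                    row$ang, resolve_template_dih(row$dih, chis))
    pos[[row$name]] <- p
    out[row$name, ] <- p
  }
  out
}

# ideal CB from backbone N, CA, C (L-configuration; the improper
# dihedral C-N-CA-CB of L-amino acids is about -122.5 degrees)
ideal_cb <- function(n, ca, c) place_atom(c, n, ca, 1.53, 110.5, -122.5)

#' Rebuild a residue's side chain at given chi angles
#'
#' Replaces all side-chain heavy atoms beyond CB with ideal-geometry atoms
#' at the requested chi values. Backbone and CB are untouched (CB is built
#' from ideal geometry if absent). GLY/ALA are a no-op for zero chis.
#'
#' @param res_atoms data.frame of one residue's atoms.
#' @param chis Numeric chi angles, degrees; length must match the type.
#' @param resname Residue type; defaults to the residue's `resid`.
#' @return The residue data.frame with the rebuilt side chain.
#' @export
build_sidechain <- function(res_atoms, chis, resname = res_atoms$resid[1L]) {
  resname <- toupper(resname)
  if (resname %in% c("GLY", "ALA")) {
    if (length(chis)) stop(resname, " has no chi angles")
    return(res_atoms)
  }
  n <- residue_atom_xyz(res_atoms, "N")
  ca <- residue_atom_xyz(res_atoms, "CA")
  c_ <- residue_atom_xyz(res_atoms, "C")
  if (is.null(n) || is.null(ca))
    stop("residue lacks backbone atoms needed to build a side chain")
  cb <- residue_atom_xyz(res_atoms, "CB")
  if (is.null(cb)) {
    if (is.null(c_)) stop("cannot rebuild CB without backbone C")
    cb <- ideal_cb(n, ca, c_)
  }
  sc <- sidechain_xyz(n, ca, cb, resname, chis)
  keep <- res_atoms[res_atoms$name %in% c(BACKBONE_NAMES, "OXT"), ,
                    drop = FALSE]
  proto <- keep[1L, ]
  add <- do.call(rbind, lapply(rownames(sc), function(nm) {
    row <- proto
    row$name <- nm
    row$element <- element_from_name(nm)
    row$x <- sc[nm, 1L]; row$y <- sc[nm, 2L]; row$z <- sc[nm, 3L]
    row
  }))
  cbrow <- proto
  cbrow$name <- "CB"; cbrow$element <- "C"
  cbrow$x <- cb[1L]; cbrow$y <- cb[2L]; cbrow$z <- cb[3L]
  out <- rbind(keep, cbrow, add)
  out$resid <- resname
  rownames(out) <- NULL
  out
}

#' Compact backbone-independent rotamer library
#'
#' Canonical staggered chi combinations per residue type (gauche-, trans,
#' gauche+ for aliphatic chis; +/-90 for aromatic chi2), 3-9 rotamers per
#' type, with mildly non-uniform normalized prior weights. chi3/chi4 are
#' held trans. A richer library can be loaded with
#' [load_rotamer_library()].
#'
#' @return Named list per residue type: list(chis = matrix, weights).
#' @export
default_rotamer_library <- function() {
  stag <- c(-60, 180, 60)
  wstag <- c(0.40, 0.35, 0.25)
  lib <- list()
  for (ty in names(.sidechain_templates)) {
    nc <- n_chi(ty)
    if (nc == 1) {
      chis <- matrix(stag, ncol = 1)
      w <- wstag
    } else {
      chi2_vals <- if (ty %in% c("PHE", "TYR", "HIS")) c(90, -90) else stag
      chi2_w <- if (ty %in% c("PHE", "TYR", "HIS")) c(0.55, 0.45) else wstag
      grid <- expand.grid(chi1 = stag, chi2 = chi2_vals)
      w <- apply(expand.grid(w1 = wstag, w2 = chi2_w), 1, prod)
      chis <- as.matrix(grid)
      if (nc > 2) chis <- cbind(chis, matrix(180, nrow(chis), nc - 2))
    }
    colnames(chis) <- paste0("chi", seq_len(ncol(chis)))
    lib[[ty]] <- list(chis = chis, weights = w / sum(w))
  }
  lib
}

#' Load a rotamer library from a tabular file
#'
#' Whitespace/tab-delimited columns: residue_type chi1 [chi2 chi3 chi4]
#' weight. Missing chis for a type are written as NA. Weights are
#' normalized per type.
#'
#' @param path File path.
#' @return Library in the format of [default_rotamer_library()].
#' @export
load_rotamer_library <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"residue_type" %in% names(tab) || !"weight" %in% names(tab))
    stop("rotamer library needs residue_type and weight columns")
  lib <- list()
  for (ty in unique(tab$residue_type)) {
    sub <- tab[tab$residue_type == ty, , drop = FALSE]
    nc <- n_chi(ty)
    cols <- paste0("chi", seq_len(nc))
    if (!all(cols %in% names(sub)))
      stop("library lacks ", paste(cols, collapse = ","), " for ", ty)
    chis <- as.matrix(sub[, cols, drop = FALSE])
    if (anyNA(chis)) stop("NA chi values for ", ty)
    lib[[toupper(ty)]] <- list(chis = chis,
                               weights = sub$weight / sum(sub$weight))
  }
  lib
}

# ---- ideal-geometry backbone builder (used by the fixture generator) ----

# Build an extended chain of residues with given phi/psi (n x 2 matrix) and
# sequence (3-letter codes). Side chains are built at the given chi list
# (list of numeric vectors, NULL -> all trans). Returns a bare atom df.
build_backbone <- function(phi_psi, seq3, chain = "A", start_resno = 1L,
                           chis = NULL) {
  nres <- nrow(phi_psi)
  stopifnot(length(seq3) == nres)
  # seed triad for residue 1
  n_prev <- c(0, 0, 0)
  ca_prev <- c(1.458, 0, 0)
  c_prev <- place_atom(c(0, 1, 0), n_prev, ca_prev, 1.525, 111.2,
                       phi_psi[1L, 1L])
  rows <- list()
  add_atom <- function(resno, resid, name, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resid = resid, chain = chain, resno = resno, ins = "",
      x = p[1L], y = p[2L], z = p[3L], element = element_from_name(name),
      het = FALSE, stringsAsFactors = FALSE)
  }
  n_cur <- n_prev; ca_cur <- ca_prev; c_cur <- c_prev
  for (i in seq_len(nres)) {
    resno <- start_resno + i - 1L
    resid <- toupper(seq3[i])
    if (i > 1) {
      n_cur <- place_atom(n_prev, ca_prev, c_prev, 1.329, 116.2,
                          phi_psi[i - 1L, 2L])
      ca_cur <- place_atom(ca_prev, c_prev, n_cur, 1.458, 121.7, 180)
      c_cur <- place_atom(c_prev, n_cur, ca_cur, 1.525, 111.2,
                          phi_psi[i, 1L])
    }
    o_cur <- place_atom(n_cur, ca_cur, c_cur, 1.231, 120.5,
                        wrap180(phi_psi[i, 2L] + 180))
    add_atom(resno, resid, "N", n_cur)
    add_atom(resno, resid, "CA", ca_cur)
    add_atom(resno, resid, "C", c_cur)
    add_atom(resno, resid, "O", o_cur)
    if (resid != "GLY") {
      cb <- ideal_cb(n_cur, ca_cur, c_cur)
      add_atom(resno, resid, "CB", cb)
      if (resid != "ALA") {
        ch <- if (!is.null(chis) && !is.null(chis[[i]])) chis[[i]]
              else rep(180, n_chi(resid))
        sc <- sidechain_xyz(n_cur, ca_cur, cb, resid, ch)
        for (nm in rownames(sc)) add_atom(resno, resid, nm, sc[nm, ])
      }
    }
    n_prev <- n_cur; ca_prev <- ca_cur; c_prev <- c_cur
  }
  do.call(rbind, rows)
}
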