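# Small-molecule model: atoms, bond graph, rotatable torsions, the covalent
# warhead contract, and SDF/MOL V2000 I/O.

#' Construct a ligand
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (hydrogens
#'   may be present; they are excluded from scoring and RMSD).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2 or 3).
#' @param name Identifier.
#' @return Object of class `ligand` with detected `rotatable` torsions
#'   (list of 4-atom index vectors).
#' @export
ligand <- function(atoms, bonds, name = "LIG") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds)
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    stop("ligand atoms need columns element, x, y, z")
  if (!all(c("i", "j", "order") %in% names(bonds)))
    stop("ligand bonds need columns i, j, order")
  if (nrow(bonds) && (max(bonds$i, bonds$j) > nrow(atoms) ||
                      min(bonds$i, bonds$j) < 1))
    stop("bond indices out of range")
  atoms$element <- toupper(trimws(atoms$element))
  bad <- !is_known_element(atoms$element)
  if (any(bad)) stop("unknown element(s): ",
                     paste(unique(atoms$element[bad]), collapse = ", "))
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(atoms) - igraph::vcount(g)))
  if (nrow(atoms) > 1 && !igraph::is_connected(g))
    stop("ligand bond graph is not connected")
  obj <- structure(list(atoms = atoms, bonds = bonds, name = name,
                        rotatable = list()), class = "ligand")
  obj$rotatable <- detect_rotatable(obj)
  obj <- cache_ligand_topology(obj)
  obj
}

# Precompute per-ligand topology reused heavily by scoring and torsion
# moves: moving-atom sets per rotatable bond and heavy-atom donor/acceptor
# typing with bonded-antecedent indices.
cache_ligand_topology <- function(lig) {
  g <- ligand_graph(lig)
  branch <- list()
  for (t4 in lig$rotatable) {
    i <- t4[2L]; j <- t4[3L]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    comp <- igraph::components(g2)
    branch[[paste(i, j)]] <- which(comp$membership == comp$membership[j])
  }
  hv <- which(lig$atoms$element != "H")
  heavy <- lig$atoms$element != "H"
  el <- lig$atoms$element[hv]
  root_idx <- rep(NA_integer_, length(hv))
  for (k in seq_along(hv)) {
    nb <- as.integer(igraph::neighbors(g, hv[k]))
    nb <- nb[heavy[nb]]
    if (length(nb)) root_idx[k] <- nb[1L]
  }
  lig$topology <- list(
    branch = branch, heavy = hv,
    donor = el == "N", acceptor = el %in% c("N", "O"),
    radius = vdw_radius(el), root_idx = root_idx)
  lig
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand> %s: %d atoms (%d heavy), %d bonds, %d rotatable torsions\n",
              x$name, nrow(x$atoms), sum(x$atoms$element != "H"),
              nrow(x$bonds), length(x$rotatable)))
  invisible(x)
}

ligand_graph <- function(lig) {
  g <- igraph::graph_from_edgelist(as.matrix(lig$bonds[, c("i", "j")]),
                                   directed = FALSE)
  igraph::add_vertices(g, max(0, nrow(lig$atoms) - igraph::vcount(g)))
}

heavy_indices <- function(lig) which(lig$atoms$element != "H")

ligand_xyz <- function(lig) as.matrix(lig$atoms[, c("x", "y", "z")])

#' Detect rotatable torsions of a ligand
#'
#' A bond defines a rotatable torsion when it is a single bond, acyclic
#' (a bridge of the bond graph), and both of its atoms have at least one
#' further heavy-atom neighbour (non-terminal). The reported 4-tuple uses
#' the lowest-index heavy neighbour on each side.
#'
#' @param lig A [ligand()].
#' @return List of integer 4-vectors (a, i, j, d).
#' @export
detect_rotatable <- function(lig) {
  if (nrow(lig$bonds) == 0) return(list())
  g <- ligand_graph(lig)
  bridge_ids <- igraph::bridges(g)
  heavy <- lig$atoms$element != "H"
  out <- list()
  for (b in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[b]; j <- lig$bonds$j[b]
    if (lig$bonds$order[b] != 1) next
    if (!heavy[i] || !heavy[j]) next
    eid <- igraph::get_edge_ids(g, c(i, j))
    if (!eid %in% as.integer(bridge_ids)) next
    ni <- setdiff(as.integer(igraph::neighbors(g, i)), j)
    nj <- setdiff(as.integer(igraph::neighbors(g, j)), i)
    ni <- ni[heavy[ni]]; nj <- nj[heavy[nj]]
    if (!length(ni) || !length(nj)) next
    out[[length(out) + 1L]] <- c(min(ni), i, j, min(nj))
  }
  out
}

#' Covalent warhead specification
#'
#' Declares which ligand atom forms the covalent bond to the cysteine SG
#' after Michael addition, the target adduct geometry, and the bond-order
#' changes upon adduct formation (for acrylamide, C=C reduced to C-C).
#'
#' @param reactive_atom 1-based index of the ligand carbon bonding to SG.
#' @param bond_length_target,bond_length_tol SG-C bond length target and
#'   tolerance, Angstrom.
#' @param bond_angle_target,bond_angle_tol CB-SG-C angle target and
#'   tolerance, degrees.
#' @param modified_bonds list of `c(i, j, new_order)` bond-order changes
#'   applied when forming the adduct.
#' @return Object of class `warhead_spec`.
#' @export
warhead_spec <- function(reactive_atom, bond_length_target = 1.81,
                         bond_length_tol = 0.3, bond_angle_target = 100,
                         bond_angle_tol = 20, modified_bonds = list()) {
  stopifnot(length(reactive_atom) == 1, reactive_atom >= 1)
  if (bond_length_tol <= 0 || bond_angle_tol <= 0)
    stop("warhead tolerances must be strictly positive")
  structure(list(reactive_atom = as.integer(reactive_atom),
                 bond_length_target = bond_length_target,
                 bond_length_tol = bond_length_tol,
                 bond_angle_target = bond_angle_target,
                 bond_angle_tol = bond_angle_tol,
                 modified_bonds = modified_bonds), class = "warhead_spec")
}

#' Apply warhead bond-order changes (adduct form of a ligand)
#' @param lig A [ligand()]. @param warhead A [warhead_spec()].
#' @return The ligand with modified bond orders and re-detected torsions.
#' @export
adduct_form <- function(lig, warhead) {
  if (warhead$reactive_atom > nrow(lig$atoms))
    stop("warhead reactive_atom index out of range")
  for (mb in warhead$modified_bonds) {
    hit <- which((lig$bonds$i == mb[1L] & lig$bonds$j == mb[2L]) |
                   (lig$bonds$i == mb[2L] & lig$bonds$j == mb[1L]))
    if (!length(hit)) stop("modified bond not present in ligand")
    lig$bonds$order[hit] <- mb[3L]
  }
  lig$rotatable <- detect_rotatable(lig)
  cache_ligand_topology(lig)
}

#' Read a V2000 SDF/MOL ligand
#'
#' Parsed with ChemmineR. A file whose header declares 2D coordinates is
#' rejected with advice to supply 3D input.
#'
#' @param path Path to an SDF or MOL V2000 file.
#' @param name Identifier; defaults to the SDF title or file name.
#' @return A [ligand()].
#' @export
read_ligand_sdf <- function(path, name = NULL) {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e) stop("SDF parse error in '", path,
                                              "': ", conditionMessage(e),
                                              call. = FALSE))
  sdf <- sdfset[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(element = toupper(elements),
                      x = ab[, 1L], y = ab[, 2L], z = ab[, 3L],
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  bonds <- data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                      order = as.integer(bb[, 3L]))
  hdr2 <- tryCatch(ChemmineR::sdf2str(sdf)[2L], error = function(e) "")
  if (grepl("2D", hdr2, fixed = TRUE) && all(abs(atoms$z) < 1e-6))
    stop("SDF '", path, "' declares 2D coordinates; supply 3D input")
  if (is.null(name)) {
    hdr <- ChemmineR::header(sdf)[["Molecule_Name"]]
    name <- if (!is.null(hdr) && nzchar(trimws(hdr))) trimws(hdr)
            else basename(path)
  }
  ligand(atoms, bonds, name = name)
}

#' Write ligands to a V2000 SDF file
#'
#' @param ligs A [ligand()] or list of ligands.
#' @param path Output path.
#' @param tags Optional list (parallel to `ligs`) of named character/numeric
#'   vectors written as SDF data fields per record.
#' @param coords Optional list of n x 3 matrices overriding each ligand's
#'   coordinates (used to write docked poses).
#' @export
write_ligand_sdf <- function(ligs, path, tags = NULL, coords = NULL) {
  if (inherits(ligs, "ligand")) ligs <- list(ligs)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ligs)) {
    lig <- ligs[[k]]
    xyz <- if (!is.null(coords)) as.matrix(coords[[k]]) else ligand_xyz(lig)
    writeLines(c(lig$name, "  covflex          3D", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(lig$atoms), nrow(lig$bonds)), con)
    for (i in seq_len(nrow(lig$atoms))) {
      el <- lig$atoms$element[i]
      el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], el), con)
    }
    for (b in seq_len(nrow(lig$bonds)))
      writeLines(sprintf("%3d%3d%3d  0", lig$bonds$i[b], lig$bonds$j[b],
                         lig$bonds$order[b]), con)
    writeLines("M  END", con)
    if (!is.null(tags) && length(tags) >= k && length(tags[[k]])) {
      tg <- tags[[k]]
      for (nm in names(tg))
        writeLines(c(sprintf(">  <%s>", nm), as.character(tg[[nm]]), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

# Current value (degrees) of each rotatable torsion given coordinates.
torsion_values <- function(lig, xyz = ligand_xyz(lig)) {
  vapply(lig$rotatable, function(t4)
    dihedral(xyz[t4[1L], ], xyz[t4[2L], ], xyz[t4[3L], ], xyz[t4[4L], ]),
    numeric(1))
}

# Atoms on the j-side of bond (i, j): the moving set when the torsion about
# i-j is rotated (the bond must be a bridge). Uses the cached topology
# when available.
branch_atoms <- function(lig, i, j) {
  br <- lig$topology$branch
  if (!is.null(br)) {
    hit <- br[[paste(i, j)]]
    if (!is.null(hit)) return(hit)
    rev_hit <- br[[paste(j, i)]]
    if (!is.null(rev_hit)) return(setdiff(seq_len(nrow(lig$atoms)), rev_hit))
  }
  g <- igraph::delete_edges(ligand_graph(lig),
                            igraph::get_edge_ids(ligand_graph(lig), c(i, j)))
  comp <- igraph::components(g)
  which(comp$membership == comp$membership[j])
}

# Set torsion (a,i,j,d) of coordinate matrix to `target` degrees by rotating
# the j-side branch about the i-j axis.
set_torsion <- function(lig, xyz, t4, target) {
  cur <- dihedral(xyz[t4[1L], ], xyz[t4[2L], ], xyz[t4[3L], ], xyz[t4[4L], ])
  mv <- branch_atoms(lig, t4[2L], t4[3L])
  mv <- setdiff(mv, t4[3L])
  axis <- xyz[t4[3L], ] - xyz[t4[2L], ]
  xyz[mv, ] <- rotate_about_line(xyz[mv, , drop = FALSE], xyz[t4[3L], ],
                                 axis, cur - target)
  xyz
}
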