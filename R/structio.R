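# Protein structure model and PDB I/O.
#
# The atomic model is deliberately flat, bio3d-style: one data frame of atoms
# with chain / residue bookkeeping columns, wrapped in a light S3 class.
# Heavy-atom model for the receptor: hydrogens are dropped on read.

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Construct a protein structure
#'
#' @param atoms data.frame with columns `name`, `resid` (3-letter residue
#'   code), `chain`, `resno`, `ins` (insertion code, "" if none), `x`, `y`,
#'   `z`, `element`, `het` (logical, TRUE for heteroatoms).
#' @param source_id Free-text provenance, e.g. a PDB code or file name.
#' @return An object of class `protein`.
#' @export
protein <- function(atoms, source_id = "") {
  need <- c("name", "resid", "chain", "resno", "ins", "x", "y", "z",
            "element", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  bad <- !is_known_element(atoms$element)
  if (any(bad))
    stop("unknown element symbol(s): ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  prot <- atoms[!atoms$het, , drop = FALSE]
  if (nrow(prot)) {
    key <- paste(prot$chain, prot$resno, prot$ins, sep = "|")
    # a residue key must map to a single residue name
    if (anyDuplicated(unique(data.frame(key, resid = prot$resid))$key))
      stop("residue (chain, resnum) keys are not unique")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id), class = "protein")
}

#' @export
print.protein <- function(x, ...) {
  prot <- x$atoms[!x$atoms$het, ]
  nres <- length(unique(paste(prot$chain, prot$resno, prot$ins)))
  cat(sprintf("<protein> %s: %d residues, %d protein atoms, %d heteroatoms\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              nres, nrow(prot), sum(x$atoms$het)))
  invisible(x)
}

# parse "A:95" style keys into chain/resno
parse_residue_key <- function(key) {
  parts <- strsplit(as.character(key), ":", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed residue key(s): ",
                     paste(key[bad], collapse = ", "), " (expected 'chain:resnum')")
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resno = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

residue_key <- function(chain, resno) paste0(chain, ":", resno)

#' Residue table of a protein
#'
#' @param structure A `protein`.
#' @return data.frame with one row per (chain, resno, ins) residue:
#'   `chain`, `resno`, `ins`, `resid`, `key`.
#' @export
residue_table <- function(structure) {
  prot <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  idx <- !duplicated(paste(prot$chain, prot$resno, prot$ins, sep = "|"))
  out <- prot[idx, c("chain", "resno", "ins", "resid")]
  out$key <- residue_key(out$chain, out$resno)
  rownames(out) <- NULL
  out
}

#' Extract the atoms of one residue
#'
#' Lookup is total over contained residues: an unknown key is an error.
#'
#' @param structure A `protein`.
#' @param chain Chain identifier.
#' @param resno Residue number (author numbering).
#' @return data.frame of the residue's atoms.
#' @export
get_residue <- function(structure, chain, resno) {
  a <- structure$atoms
  sel <- !a$het & a$chain == chain & a$resno == resno
  if (!any(sel))
    stop(sprintf("residue %s:%s not found in structure", chain, resno))
  a[sel, , drop = FALSE]
}

residue_atom_xyz <- function(res_atoms, name) {
  i <- match(name, res_atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(res_atoms[i, c("x", "y", "z")])
}

# replace the atoms of residue (chain, resno) with new_atoms rows
set_residue_atoms <- function(structure, chain, resno, new_atoms) {
  a <- structure$atoms
  sel <- !a$het & a$chain == chain & a$resno == resno
  if (!any(sel)) stop(sprintf("residue %s:%s not found", chain, resno))
  first <- which(sel)[1L]
  keep_before <- a[seq_len(first - 1L), , drop = FALSE]
  keep_before <- keep_before[!(!keep_before$het & keep_before$chain == chain &
                                 keep_before$resno == resno), , drop = FALSE]
  keep_after <- a[seq(first, nrow(a)), , drop = FALSE]
  keep_after <- keep_after[!(!keep_after$het & keep_after$chain == chain &
                               keep_after$resno == resno), , drop = FALSE]
  structure$atoms <- rbind(keep_before, new_atoms, keep_after)
  rownames(structure$atoms) <- NULL
  structure
}

#' Read a PDB file
#'
#' Fixed-column PDB v3.3 ATOM/HETATM records, parsed with bio3d. Receptor
#' hydrogens are dropped (heavy-atom model); for alternate locations only
#' the highest-occupancy altloc is kept (ties broken alphabetically) with a
#' warning; HETATM records are carried as heteroatoms.
#'
#' @param path Path to a PDB file.
#' @param source_id Provenance label; defaults to the file name.
#' @return A [protein()] object.
#' @export
read_pdb <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0 || !any(at$type == "ATOM"))
    stop("PDB file '", path, "' contains no ATOM records")
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                   element_from_name(at$elety), at$elesy)))
  # altloc resolution: keep highest occupancy, ties -> first alphabetically
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    akey <- paste(at$type, at$chain, at$resno, at$ins, at$elety, sep = "|")
    ord <- order(akey, -occ, alt)
    keep <- ord[!duplicated(akey[ord])]
    dropped <- nrow(at) - length(keep)
    at <- at[sort(keep), , drop = FALSE]
    warning(sprintf("%d alternate-location atom(s) dropped (kept highest occupancy)",
                    dropped))
  }
  is_het <- at$type == "HETATM"
  is_h <- at$elem == "H"
  at <- at[!(is_h & !is_het), , drop = FALSE]  # receptor hydrogens dropped
  atoms <- data.frame(
    name = trimws(at$elety), resid = trimws(at$resid), chain = at$chain,
    resno = at$resno, ins = at$ins, x = at$x, y = at$y, z = at$z,
    element = at$elem, het = at$type == "HETATM", stringsAsFactors = FALSE)
  # warn about truncated backbones
  prot <- atoms[!atoms$het, , drop = FALSE]
  if (nrow(prot)) {
    keys <- unique(paste(prot$chain, prot$resno, prot$ins, sep = "|"))
    for (k in keys) {
      res <- prot[paste(prot$chain, prot$resno, prot$ins, sep = "|") == k, ]
      missing_bb <- setdiff(c("N", "CA", "C"), res$name)
      if (length(missing_bb))
        warning(sprintf("residue %s:%s missing backbone atom(s) %s",
                        res$chain[1L], res$resno[1L],
                        paste(missing_bb, collapse = ",")))
      else if (!"O" %in% res$name)
        warning(sprintf("residue %s:%s missing backbone O", res$chain[1L],
                        res$resno[1L]))
    }
  }
  protein(atoms, source_id = source_id)
}

pdb_atom_name_field <- function(name, element) {
  # PDB columns 13-16: element right-justified in 13-14 for 1-letter elements
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         ifelse(nchar(element) == 2, sprintf("%-4s", name),
                sprintf(" %-3s", name)))
}

#' Write a PDB file
#'
#' Emits fixed-column PDB v3.3 ATOM/HETATM records. Per chain, ATOM records
#' come first followed by TER and then that chain's HETATM records. Serial
#' numbers above 99999 wrap with a warning.
#'
#' @param structure A [protein()] object.
#' @param path Output file path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure")
  blocks <- character(0)
  serial0 <- 0L
  wrapped <- FALSE
  fmt_block <- function(rec, sub) {
    n <- nrow(sub)
    serials <- serial0 + seq_len(n)
    serial0 <<- serial0 + n
    if (any(serials > 99999L)) {
      serials <- serials %% 100000L
      wrapped <<- TRUE
    }
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serials, pdb_atom_name_field(sub$name, sub$element), " ",
            substr(sub$resid, 1, 3), sub$chain, sub$resno,
            ifelse(nzchar(sub$ins), sub$ins, " "), sub$x, sub$y, sub$z,
            1, 0, sub$element)
  }
  for (ch in unique(a$chain)) {
    pa <- a[a$chain == ch & !a$het, , drop = FALSE]
    if (nrow(pa)) blocks <- c(blocks, fmt_block("ATOM", pa), "TER")
    ha <- a[a$chain == ch & a$het, , drop = FALSE]
    if (nrow(ha)) blocks <- c(blocks, fmt_block("HETATM", ha))
  }
  writeLines(c(blocks, "END"), path)
  if (wrapped) warning("atom serial numbers exceeded 99999 and were wrapped")
  invisible(path)
}

#' Superpose one structure onto another
#'
#' Least-squares rigid superposition (Kabsch) over paired atoms shared by
#' both structures, by default the C-alpha atoms matched on
#' (chain, resno, ins, atom name).
#'
#' @param mobile,reference [protein()] objects.
#' @param atom_names Atom names used for pairing (default `"CA"`).
#' @return List with `rotation`, `translation`, `rmsd`, `n_pairs` and
#'   `mobile` (the transformed mobile structure).
#' @export
superpose <- function(mobile, reference, atom_names = "CA") {
  ma <- mobile$atoms[!mobile$atoms$het & mobile$atoms$name %in% atom_names, ]
  ra <- reference$atoms[!reference$atoms$het &
                          reference$atoms$name %in% atom_names, ]
  mk <- paste(ma$chain, ma$resno, ma$ins, ma$name, sep = "|")
  rk <- paste(ra$chain, ra$resno, ra$ins, ra$name, sep = "|")
  shared <- intersect(mk, rk)
  if (length(shared) < 3)
    stop("superposition requires at least 3 shared paired atoms")
  mi <- ma[match(shared, mk), c("x", "y", "z")]
  ri <- ra[match(shared, rk), c("x", "y", "z")]
  fit <- kabsch(as.matrix(mi), as.matrix(ri))
  out <- mobile
  xyz <- apply_transform(as.matrix(mobile$atoms[, c("x", "y", "z")]),
                         fit$rotation, fit$translation)
  out$atoms$x <- xyz[, 1L]; out$atoms$y <- xyz[, 2L]; out$atoms$z <- xyz[, 3L]
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, n_pairs = length(shared), mobile = out)
}
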