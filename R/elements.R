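# Element-keyed van der Waals radii (Bondi-style), Angstrom.
# Scoring and clash detection need per-element radii; a compact table of the
# elements seen in protein/ligand work is shipped rather than a force field.

.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, B = 1.92, SE = 1.90,
  MG = 1.73, ZN = 1.39, MN = 1.73, FE = 1.73, "NA" = 2.27, K = 2.75,
  CA = 2.31, LI = 1.82, CU = 1.40, NI = 1.63, CO = 1.73, CD = 1.58
)

#' Van der Waals radius of an element
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(element))
  r <- .vdw_table[key]
  if (anyNA(r))
    stop("unknown element symbol(s): ",
         paste(unique(key[is.na(r)]), collapse = ", "))
  unname(r)
}

is_known_element <- function(element) {
  toupper(trimws(element)) %in% names(.vdw_table)
}

# Infer the element symbol from a PDB atom name when the element column is
# blank: two-letter elements only for names like "MG", "CL" etc.
element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- substr(nm, 1, 1)
  known2 <- two %in% c("CL", "BR", "MG", "ZN", "FE", "MN", "SE", "NA", "LI")
  out[known2] <- two[known2]
  # leading digits in hydrogen names like "1HB"
  dig <- grepl("^[0-9]", out)
  out[dig] <- substr(sub("^[0-9]+", "", nm[dig]), 1, 1)
  out
}
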