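# Shared in-code fixtures: tiny molecules, a toy peptide, and independent
# oracle implementations used across the test files.

heavy_rmsd <- function(a, b, hv) {
  sqrt(mean(rowSums((as.matrix(a)[hv, , drop = FALSE] -
                       as.matrix(b)[hv, , drop = FALSE])^2)))
}

toy_butane <- function() {
  ligand(data.frame(element = c("C", "C", "C", "C"),
                    x = c(0, 1.52, 2.2, 3.72), y = c(0, 0.3, 1.62, 1.92),
                    z = c(0, 0.11, 0.2, 0.45)),
         data.frame(i = 1:3, j = 2:4, order = 1), name = "butane")
}

toy_ethane <- function() {
  ligand(data.frame(element = c("C", "C"), x = c(0, 1.54), y = c(0, 0.1),
                    z = c(0, 0.05)),
         data.frame(i = 1, j = 2, order = 1), name = "ethane")
}

toy_cyclohexane <- function() {
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  ligand(data.frame(element = "C", x = 1.5 * cos(th), y = 1.5 * sin(th),
                    z = rep(c(0.25, -0.25), 3)),
         data.frame(i = 1:6, j = c(2:6, 1), order = 1),
         name = "cyclohexane")
}

# a short ideal-geometry peptide as a protein object
toy_peptide <- function(seq3 = c("MET", "SER", "LEU", "LYS", "VAL", "HIS"),
                        phi = -57, psi = -47, chis = NULL) {
  pp <- matrix(rep(c(phi, psi), length(seq3)), ncol = 2, byrow = TRUE)
  protein(covflex:::build_backbone(pp, seq3, chis = chis), "toy")
}

# independent dihedral oracle: bio3d's torsion routine
oracle_dihedral <- function(p1, p2, p3, p4) {
  as.numeric(bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4))
}

# independent superposition oracle: Horn's closed-form quaternion method
# (different algorithm from the Kabsch/SVD route in the package)
oracle_fit_rmsd <- function(mobile, reference) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# independent automorphism oracle: exhaustive DFS with element labels and
# adjacency (bond-order) preservation
oracle_automorphisms <- function(lig) {
  hv <- which(lig$atoms$element != "H")
  n <- length(hv)
  el <- lig$atoms$element[hv]
  adj <- matrix(0L, n, n)
  for (b in seq_len(nrow(lig$bonds))) {
    i <- match(lig$bonds$i[b], hv)
    j <- match(lig$bonds$j[b], hv)
    if (is.na(i) || is.na(j)) next
    adj[i, j] <- adj[j, i] <- as.integer(lig$bonds$order[b])
  }
  out <- list()
  perm <- integer(n)
  used <- logical(n)
  recurse <- function(pos) {
    if (pos > n) {
      out[[length(out) + 1L]] <<- perm
      return(invisible(NULL))
    }
    for (cand in seq_len(n)) {
      if (used[cand] || el[cand] != el[pos]) next
      ok <- TRUE
      for (prev in seq_len(pos - 1L)) {
        if (adj[pos, prev] != adj[cand, perm[prev]]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      perm[pos] <<- cand
      used[cand] <<- TRUE
      recurse(pos + 1L)
      used[cand] <<- FALSE
    }
  }
  recurse(1L)
  out
}

# default-config dock of a mini-pocket system
dock_system <- function(sys, seed = 101, mode = "flex", ...) {
  dock_covalent(sys$receptor, sys$lig,
                dock_config(sys$site, sys$warhead, seed = seed,
                            mode = mode, ...))
}

# session-level cache of generated fixture systems (generation is
# deterministic, so sharing across test files only saves time)
.fixture_cache <- new.env(parent = emptyenv())

cached_minipocket <- function(seed, difficulty) {
  key <- paste(seed, difficulty)
  hit <- get0(key, envir = .fixture_cache)
  if (is.null(hit)) {
    hit <- make_minipocket(seed, difficulty)
    assign(key, hit, envir = .fixture_cache)
  }
  hit
}
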