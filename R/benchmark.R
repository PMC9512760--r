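# Cross-docking evaluation: symmetry-corrected heavy-atom ligand RMSD
# against crystal poses brought into a common frame, all-against-all
# docking matrices, and top-N success curves over RMSD cutoffs.

#' Symmetry-corrected heavy-atom ligand RMSD
#'
#' RMSD between a pose and a reference conformation of the same chemical
#' species, minimized over all chemically equivalent atom mappings (graph
#' automorphisms preserving element and bond pattern), without
#' re-superposing the ligand: both conformations must already share the
#' receptor frame.
#'
#' @param pose_xyz Pose coordinate matrix (all atoms, ligand row order).
#' @param lig The [ligand()] defining atoms and bonds.
#' @param ref_xyz Reference coordinate matrix (same row order).
#' @param symmetry Logical: minimize over automorphisms (TRUE) or use the
#'   identity mapping only.
#' @return List with `rmsd` (symmetry-corrected), `rmsd_identity`, and
#'   `n_mappings` considered.
#' @export
ligand_rmsd <- function(pose_xyz, lig, ref_xyz, symmetry = TRUE) {
  pose_xyz <- as.matrix(pose_xyz)
  ref_xyz <- as.matrix(ref_xyz)
  if (nrow(pose_xyz) != nrow(lig$atoms) || nrow(ref_xyz) != nrow(lig$atoms))
    stop("coordinate matrices must cover all ligand atoms")
  hv <- heavy_indices(lig)
  el <- lig$atoms$element[hv]
  id_rmsd <- sqrt(mean(rowSums((pose_xyz[hv, , drop = FALSE] -
                                  ref_xyz[hv, , drop = FALSE])^2)))
  if (!symmetry)
    return(list(rmsd = id_rmsd, rmsd_identity = id_rmsd, n_mappings = 1L))
  maps <- ligand_automorphisms(lig)
  best <- Inf
  for (mp in maps) {
    r <- sqrt(mean(rowSums((pose_xyz[hv[mp], , drop = FALSE] -
                              ref_xyz[hv, , drop = FALSE])^2)))
    if (r < best) best <- r
  }
  list(rmsd = best, rmsd_identity = id_rmsd, n_mappings = length(maps))
}

#' Heavy-atom graph automorphisms of a ligand
#'
#' All permutations of the heavy atoms preserving element labels and the
#' bond pattern (VF2 with vertex colors = element, edge colors = bond
#' order). Returned as permutations of the heavy-atom index vector.
#'
#' @param lig A [ligand()].
#' @return List of integer permutations (positions into the heavy-atom
#'   ordering); the identity is always included.
#' @export
ligand_automorphisms <- function(lig) {
  hv <- heavy_indices(lig)
  idx <- match(seq_len(nrow(lig$atoms)), hv)
  b <- lig$bonds[lig$atoms$element[lig$bonds$i] != "H" &
                   lig$atoms$element[lig$bonds$j] != "H", , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(idx[b$i], idx[b$j]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(hv) - igraph::vcount(g)))
  vcol <- as.integer(factor(lig$atoms$element[hv]))
  ecol <- as.integer(b$order)
  maps <- igraph::graph.get.isomorphisms.vf2(
    g, g, vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol)
  lapply(maps, as.integer)
}

#' Run an all-against-all cross-docking matrix
#'
#' For every (receptor, ligand) combination from the manifest: the
#' reference complex's receptor is superposed onto the docking receptor on
#' shared C-alpha atoms, the reference ligand pose is carried into that
#' frame, the ligand is docked, and symmetry-corrected RMSDs of all
#' emitted poses are recorded. Per-job seeds derive deterministically from
#' the global seed and the (receptor, ligand) ids, so the matrix is
#' order-independent. Job failures (no poses) are recorded as failures,
#' never aborting the matrix.
#'
#' @param manifest data.frame with columns `system_id`, `receptor`,
#'   `ligand`, `reference` (file paths), `cognate` — or a list of
#'   `minipocket` objects (in-memory mode).
#' @param config A [dock_config()] template (site/warhead taken from it;
#'   per-system warheads from minipocket objects when given).
#' @param mode "flex" or "rigid".
#' @param seed Global seed.
#' @return data.frame of class `benchmark_result`: one row per job with
#'   `receptor_id`, `ligand_id`, `is_self`, `n_poses`, `best_rmsd_top1`,
#'   `best_rmsd_top5`, `best_rmsd_top20`, plus the per-pose RMSD list in
#'   the `rmsds` list-column.
#' @export
run_matrix <- function(manifest, config, mode = c("flex", "rigid"),
                       seed = 1L) {
  mode <- match.arg(mode)
  systems <- load_benchmark_systems(manifest)
  jobs <- list()
  for (i in seq_along(systems)) for (j in seq_along(systems)) {
    rec_sys <- systems[[i]]
    lig_sys <- systems[[j]]
    job_seed <- job_seed_for(seed, rec_sys$id, lig_sys$id)
    cfg <- config
    cfg$mode <- mode
    cfg$seed <- job_seed
    if (!is.null(lig_sys$warhead)) cfg$warhead <- lig_sys$warhead
    ref_in_frame <- lig_sys$reference_xyz
    if (i != j) {
      fit <- tryCatch(superpose(lig_sys$receptor, rec_sys$receptor),
                      error = function(e) NULL)
      if (!is.null(fit))
        ref_in_frame <- apply_transform(ref_in_frame, fit$rotation,
                                        fit$translation)
    }
    rms <- numeric(0)
    res <- tryCatch(dock_covalent(rec_sys$receptor, lig_sys$lig, cfg),
                    error = function(e) NULL)
    if (!is.null(res) && length(res$poses))
      rms <- vapply(res$poses, function(p)
        ligand_rmsd(p$lig_xyz, lig_sys$lig, ref_in_frame)$rmsd, numeric(1))
    jobs[[length(jobs) + 1L]] <- list(
      receptor_id = rec_sys$id, ligand_id = lig_sys$id,
      is_self = rec_sys$id == lig_sys$id, n_poses = length(rms),
      best_rmsd_top1 = if (length(rms)) rms[1L] else NA_real_,
      best_rmsd_top5 = if (length(rms)) min(rms[seq_len(min(5, length(rms)))])
                       else NA_real_,
      best_rmsd_top20 = if (length(rms))
        min(rms[seq_len(min(20, length(rms)))]) else NA_real_,
      rmsds = rms)
  }
  out <- data.frame(
    receptor_id = vapply(jobs, `[[`, "", "receptor_id"),
    ligand_id = vapply(jobs, `[[`, "", "ligand_id"),
    is_self = vapply(jobs, `[[`, TRUE, "is_self"),
    n_poses = vapply(jobs, `[[`, 0L, "n_poses"),
    best_rmsd_top1 = vapply(jobs, `[[`, 0, "best_rmsd_top1"),
    best_rmsd_top5 = vapply(jobs, `[[`, 0, "best_rmsd_top5"),
    best_rmsd_top20 = vapply(jobs, `[[`, 0, "best_rmsd_top20"),
    stringsAsFactors = FALSE)
  out$rmsds <- lapply(jobs, `[[`, "rmsds")
  class(out) <- c("benchmark_result", class(out))
  out
}

# deterministic per-job seed from the global seed and the system ids
job_seed_for <- function(seed, rec_id, lig_id) {
  h <- 0
  for (ch in utf8ToInt(paste(rec_id, lig_id, sep = "|")))
    h <- (h * 31 + ch) %% 1000003
  as.integer((seed * 1009 + h) %% 2147483647)
}

# accept either a list of minipocket systems or a manifest of file paths
load_benchmark_systems <- function(manifest) {
  if (is.list(manifest) && length(manifest) &&
      inherits(manifest[[1L]], "minipocket")) {
    return(lapply(seq_along(manifest), function(k) {
      s <- manifest[[k]]
      list(id = sprintf("sys%02d", k), receptor = s$receptor, lig = s$lig,
           warhead = s$warhead, reference_xyz = s$reference_xyz)
    }))
  }
  manifest <- as.data.frame(manifest)
  need <- c("system_id", "receptor", "ligand", "reference")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(manifest)), function(k) {
    lig <- read_ligand_sdf(manifest$ligand[k])
    ref <- read_ligand_sdf(manifest$reference[k])
    list(id = manifest$system_id[k],
         receptor = read_pdb(manifest$receptor[k]),
         lig = lig, warhead = NULL, reference_xyz = ligand_xyz(ref))
  })
}

#' Success fractions over RMSD cutoffs and pose ranks
#'
#' Fraction of jobs whose best pose among the top N lies at or below each
#' RMSD cutoff. Jobs with no poses count as failures at every (cutoff, N).
#'
#' @param results A `benchmark_result` from [run_matrix()].
#' @param cutoffs RMSD cutoffs in Angstrom.
#' @param Ns Pose-rank depths.
#' @return data.frame with columns `cutoff`, `N`, `n_jobs`, `success`.
#' @export
success_curves <- function(results, cutoffs = c(2.0, 2.5),
                           Ns = c(1, 5, 20)) {
  if (!nrow(results)) stop("empty result set")
  out <- expand.grid(cutoff = cutoffs, N = Ns)
  out$n_jobs <- nrow(results)
  out$success <- NA_real_
  for (r in seq_len(nrow(out))) {
    n <- out$N[r]
    best <- vapply(results$rmsds, function(v)
      if (length(v)) min(v[seq_len(min(n, length(v)))]) else Inf,
      numeric(1))
    out$success[r] <- mean(best <= out$cutoff[r])
  }
  out[order(out$N, out$cutoff), ]
}

#' Write benchmark results as TSV (one row per job)
#' @param results A `benchmark_result`. @param path Output path.
#' @export
write_benchmark_tsv <- function(results, path) {
  flat <- results[, setdiff(names(results), "rmsds")]
  flat$rmsds <- vapply(results$rmsds, function(v)
    paste(sprintf("%.3f", v), collapse = ","), "")
  utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Demo manifest of public KRAS G12C structures
#'
#' Returns the ten public PDB entries of the cross-docking benchmark
#' (receptor, cognate covalent ligand and crystal pose per entry) as a
#' manifest skeleton. Structures are not shipped; fetch them with
#' [fetch_demo_structures()] (network required). All package tests use
#' the synthetic fixture generator instead.
#'
#' @return data.frame with `system_id` (PDB code) and empty path columns.
#' @export
demo_manifest <- function() {
  codes <- c("5F2E", "5V9U", "6OIM", "6P8X", "6UT0", "6T5B", "6TAN",
             "8DNI", "8DNJ", "8DNK")
  data.frame(system_id = codes, receptor = "", ligand = "", reference = "",
             cognate = TRUE, stringsAsFactors = FALSE)
}

#' @rdname demo_manifest
#' @param dir Download directory.
#' @export
fetch_demo_structures <- function(dir = "demo_structures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  codes <- demo_manifest()$system_id
  bio3d::get.pdb(codes, path = dir)
  invisible(file.path(dir, paste0(tolower(codes), ".pdb")))
}
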