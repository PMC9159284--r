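# End-to-end orchestration of the two workflows: rigid docking
# (dock -> cluster -> refine -> ranked models) and whole-surface mapping
# (probes -> clusters -> hotspots -> druggability -> sites), with
# manifests for reproducibility.

md5_of_text <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

structure_checksum <- function(s) md5_of_text(write_pdb(s))

pkg_version <- function() {
  as.character(utils::packageVersion("dockmapr"))
}

new_manifest <- function(kind, inputs, params, seed, outputs = character(),
                         timings = NULL) {
  list(tool = "dockmapr", version = pkg_version(), kind = kind,
       inputs = inputs, params = params, seed = seed,
       outputs = outputs, timings = timings)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

stage <- function(name, expr, timings_env) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  timings_env$timings[[name]] <- proc.time()[["elapsed"]] - t0
  out
}

#' Full rigid-body docking pipeline
#'
#' Exhaustive FFT docking (with optional restraint filtering during
#' retention), greedy RMSD clustering of the retained low-energy poses,
#' refinement of the cluster representatives by rigid-body minimization,
#' and up to `cluster_p$max_clusters` (default 10) output models ranked
#' by cluster population.
#'
#' @param rec,lig `ParamStructure`s
#' @param params [dock_params()]
#' @param restraints optional `RestraintSet`
#' @param cluster_p [cluster_params()]
#' @param outdir optional output directory (model PDBs, TSV report,
#'   manifest JSON)
#' @return list: `models` (refined representative `Pose`s, ranked),
#'   `clusters`, `poses` (retained `PoseList`), `manifest`
#' @export
run_docking_pipeline <- function(rec, lig, params = dock_params(),
                                 restraints = NULL,
                                 cluster_p = cluster_params(),
                                 outdir = NULL) {
  tenv <- new.env(); tenv$timings <- list()
  poses <- stage("dock", dock_rigid(rec, lig, params, restraints), tenv)
  clusters <- stage("cluster", greedy_cluster(poses, lig, cluster_p), tenv)
  models <- stage("refine", lapply(clusters, function(cl) {
    m <- refine_pose(rec, lig, poses[[cl$representative]])
    m$cluster_rank <- cl$rank
    m$cluster_population <- cl$population
    m
  }), tenv)
  manifest <- new_manifest(
    "docking",
    inputs = list(receptor = structure_checksum(rec),
                  ligand = structure_checksum(lig)),
    params = list(n_rotations = params$n_rotations,
                  retained = params$retained,
                  per_rotation_keep = params$per_rotation_keep,
                  coeffs = params$weights$name, h = params$h,
                  margin = params$margin,
                  cluster_radius = cluster_p$radius,
                  max_clusters = cluster_p$max_clusters,
                  restrained = !is.null(restraints)),
    seed = params$seed, timings = tenv$timings)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (i in seq_along(models)) {
      f <- file.path(outdir, sprintf("model.%02d.pdb", i))
      write_pdb(pose_ligand(models[[i]], lig), f)
      files <- c(files, f)
    }
    rep_df <- data.frame(
      rank = vapply(models, `[[`, numeric(1), "cluster_rank"),
      population = vapply(models, `[[`, numeric(1), "cluster_population"),
      center_energy = vapply(clusters, `[[`, numeric(1), "center_energy"),
      representative = vapply(clusters, `[[`, numeric(1), "representative"),
      refined_energy = vapply(models, `[[`, numeric(1), "energy_cont"))
    f <- file.path(outdir, "clusters.tsv")
    write.table(rep_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <- c(files, f)
    write_manifest(manifest, file.path(outdir, "manifest.json"))
  }
  list(models = models, clusters = clusters, poses = poses,
       manifest = manifest)
}

#' Full whole-surface mapping pipeline
#'
#' Sweeps all 16 probes, clusters each probe's minimized poses, merges
#' probe clusters into consensus sites, classifies druggability and
#' assembles predicted binding sites.
#'
#' @param prot a `ParamStructure`
#' @param params [map_params()]
#' @param probes probe set (default the 16-probe library)
#' @param outdir optional output directory (TSV reports + manifest)
#' @return list: `per_probe`, `clusters`, `sites`, `druggability`,
#'   `binding_sites`, `manifest`
#' @export
run_mapping_pipeline <- function(prot, params = map_params(),
                                 probes = probe_library(), outdir = NULL) {
  tenv <- new.env(); tenv$timings <- list()
  res <- stage("map", map_structure(prot, params, probes), tenv)
  drug <- stage("druggability",
                druggability_report(res$sites,
                                    strong_threshold = params$strong_threshold),
                tenv)
  bsites <- stage("sites", predict_sites(res$sites, prot, params), tenv)
  manifest <- new_manifest(
    "mapping",
    inputs = list(protein = structure_checksum(prot)),
    params = list(K = params$K, n_rotations = params$n_rotations,
                  h = params$h,
                  probe_cluster_radius = params$probe_cluster_radius,
                  clusters_kept = params$clusters_kept,
                  consensus_radius = params$consensus_radius,
                  strong_threshold = params$strong_threshold,
                  site_merge_cutoff = params$site_merge_cutoff,
                  n_probes = length(probes)),
    seed = params$seed, timings = tenv$timings)
  out <- list(per_probe = res$per_probe, clusters = res$clusters,
              sites = res$sites, druggability = drug,
              binding_sites = bsites, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ht <- hotspot_table(res$sites)
    f1 <- file.path(outdir, "hotspots.tsv")
    write.table(format(ht, digits = 6), f1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    pp <- do.call(rbind, lapply(names(res$per_probe), function(nm) {
      cls <- res$per_probe[[nm]]$clusters
      if (!length(cls)) return(NULL)
      data.frame(probe = nm,
                 rank = vapply(cls, `[[`, numeric(1), "rank"),
                 size = vapply(cls, `[[`, numeric(1), "size"),
                 avg_energy = vapply(cls, `[[`, numeric(1), "avg_energy"))
    }))
    f2 <- file.path(outdir, "probe_clusters.tsv")
    write.table(format(pp, digits = 6), f2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    bs <- do.call(rbind, lapply(bsites, function(b)
      data.frame(rank = b$rank, total_population = b$total_population,
                 n_hotspots = length(b$hotspots),
                 n_residues = if (is.null(b$residues)) 0 else
                   nrow(b$residues))))
    f3 <- file.path(outdir, "binding_sites.tsv")
    write.table(bs, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    # per-probe cluster poses: best member of each kept cluster
    pfiles <- character()
    for (nm in names(res$per_probe)) {
      cls <- res$per_probe[[nm]]$clusters
      if (!length(cls)) next
      tmpl <- probes[[nm]]
      lines <- character()
      for (cl in cls) {
        best <- cl$members[[which.min(vapply(cl$members, `[[`, numeric(1),
                                             "energy_min"))]]
        posed <- tmpl
        coords(posed) <- best$xyz
        posed$atoms$res_seq <- cl$rank
        lines <- c(lines, sprintf("MODEL     %4d", cl$rank),
                   head(write_pdb(posed), -1), "ENDMDL")
      }
      f <- file.path(outdir, sprintf("probe_%s.pdb", gsub("[^A-Za-z0-9]", "_", nm)))
      writeLines(c(lines, "END"), f)
      pfiles <- c(pfiles, f)
    }
    manifest$outputs <- c(f1, f2, f3, pfiles)
    out$manifest <- manifest
    write_manifest(manifest, file.path(outdir, "manifest.json"))
  }
  out
}
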