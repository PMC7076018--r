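#' Run the full synthetic-cohort pipeline
#'
#' Executes the whole analysis end to end on a seeded synthetic cohort:
#' simulate rest and task scans, estimate the group ICN partition by
#' consensus clustering, summarize ICN-level task activation, estimate the
#' gPPI difference matrix, run the network-density permutation statistics,
#' classify hubs, and (when a reference set is given) compute overlap
#' statistics. All stage outputs are written as TSV/JSON under `out_dir`
#' and listed, with md5 hashes, in a run manifest.
#'
#' @param cfg A [synth_config()]; its `seed` fans out into per-stage
#'   substreams.
#' @param out_dir Output directory (created if missing).
#' @param subject_cost,group_threshold Proportional thresholds for the
#'   consensus-clustering stage.
#' @param subject_runs,group_runs Map-equation runs per subject / at group
#'   level.
#' @param n_perm Permutations for density and hub tests.
#' @param reference_set Optional integer node indices of a reference region
#'   set for overlap statistics.
#' @param association_scores Optional per-node association scores (length
#'   `n_nodes`).
#' @return The run manifest (list), invisibly; all results are in
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir,
                         subject_cost = 0.15, group_threshold = 0.15,
                         subject_runs = 30, group_runs = 60,
                         n_perm = 999, reference_set = NULL,
                         association_scores = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  note <- function(path) { files <<- c(files, path); path }

  # simulate
  cohort <- simulate_cohort(cfg)
  truth <- cohort$truth
  jsonlite::write_json(list(true_partition = truth$true_partition,
                            true_ppi_edges = truth$true_ppi_edges,
                            true_active_modules = truth$true_active_modules,
                            generator_seed = truth$generator_seed),
                       note(file.path(out_dir, "ground_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(cohort$design),
                     note(file.path(out_dir, "task_design.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # intrinsic networks
  conn <- lapply(cohort$rest, function(ts)
    partial_correlation_lw(bandpass(ts)))
  part <- consensus_cluster(conn, subject_cost = subject_cost,
                            subject_runs = subject_runs,
                            group_threshold = group_threshold,
                            group_runs = group_runs,
                            seed = child_seed(cfg$seed, 21))
  write_partition(part, note(file.path(out_dir, "icn_partition.tsv")))

  # task GLM + ICN activation
  glm_betas <- t(vapply(cohort$task, function(scan) {
    x <- build_design(scan$designs, nuisance = scan$nuisance, hrf = cfg$hrf,
                      n_sessions = cfg$n_sessions)
    pw <- prewhiten_ar1(scan$ts, x, pool = TRUE)
    cw <- numeric(ncol(x))
    cw[grep("^emotion", colnames(x))] <- 1 / cfg$n_sessions
    cw[grep("^shape", colnames(x))] <- -1 / cfg$n_sessions
    fit_first_level(pw$ts, pw$design, cw)$beta
  }, numeric(cfg$n_nodes)))
  act <- group_icn_activation(glm_betas, part)
  utils::write.table(act, note(file.path(out_dir, "icn_activation.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # gPPI difference matrix (unassigned nodes dropped)
  d <- gppi_difference(cohort$task, partition = part, hrf = cfg$hrf)
  write_matrix(d, note(file.path(out_dir, "difference_matrix.tsv")))
  kept <- attr(d, "kept_nodes")
  part_kept <- icn_partition(part$labels[kept], node_ids = part$node_ids[kept])

  # network densities + degree
  dens <- density_permutation_test(d, part_kept, n_perm = n_perm,
                                   seed = child_seed(cfg$seed, 22))
  write_matrix(dens$positive,
               note(file.path(out_dir, "density_positive.tsv")))
  write_matrix(dens$negative,
               note(file.path(out_dir, "density_negative.tsv")))
  nd <- network_degree_and_chi2(dens)

  # hubs
  ct <- centralities(absolute_graph(d), part_kept)
  hubs <- hub_score_classify(ct)
  hubs_km <- kmeans_classify(ct, seed = child_seed(cfg$seed, 23))
  utils::write.table(cbind(ct, hub_score = hubs$is_hub,
                           hub_kmeans = hubs_km$is_hub),
                     note(file.path(out_dir, "centralities.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hub_dens <- hub_icn_test(hubs, part_kept, n_perm = n_perm,
                           seed = child_seed(cfg$seed, 24))
  utils::write.table(hub_dens, note(file.path(out_dir, "hub_density.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- edge_class_counts(d, hubs)

  # overlap with a reference set
  overlap <- NULL
  if (!is.null(reference_set)) {
    kept_ref <- intersect(reference_set, kept)
    hub_set_nodes <- node_set(which(hubs$is_hub), length(kept))
    ref_nodes <- node_set(match(kept_ref, kept), length(kept))
    jp <- jaccard_permutation_p(hub_set_nodes, ref_nodes, n_perm = n_perm,
                                seed = child_seed(cfg$seed, 25))
    or <- odds_ratio(contingency_table(hub_set_nodes, ref_nodes))
    overlap <- list(jaccard = attr(jp, "observed"), jaccard_p = as.numeric(jp),
                    max_jaccard = max_jaccard(sum(hubs$is_hub),
                                              length(kept_ref)),
                    odds_ratio = or$or, ci95 = or$ci95)
    if (!is.null(association_scores)) {
      overlap$association <- association_comparison(
        association_scores[kept], hubs, part_kept, n_perm = n_perm,
        seed = child_seed(cfg$seed, 26))
    }
  }

  results <- list(n_modules = part$n_modules,
                  n_unassigned = sum(is.na(part$labels)),
                  ari_vs_truth = ari(part$labels, truth$true_partition),
                  icn_activation = act,
                  n_positive_edges = sum(unclass(d) == 1),
                  n_negative_edges = sum(unclass(d) == -1),
                  network_degree = nd, n_hubs = sum(hubs$is_hub),
                  edge_classes = as.list(edges), overlap = overlap)
  jsonlite::write_json(results, note(file.path(out_dir, "results.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  manifest <- list(package_version = as.character(utils::packageVersion("gppinet")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   master_seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "hrf")],
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(c(results, list(manifest = manifest, partition = part,
                            difference = d, hubs = hubs, hubs_km = hubs_km,
                            densities = dens)))
}
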