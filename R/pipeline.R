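#' Default algorithm ensemble
#'
#' Five deterministic presence-only configurations spanning the three
#' algorithm families: a strict and a permissive ("light") climate envelope,
#' the envelope fraction score, and two environmental-distance models. The
#' weighted elitist consensus retains the best-evaluated half of them.
#'
#' @return List of [algorithm_config()]s.
#' @export
default_ensemble <- function() {
  list(
    algorithm_config("bioclim", sd_cutoff = 0.674, model_id = "bioclim"),
    algorithm_config("bioclim", sd_cutoff = 1.282, model_id = "bioclim_light"),
    algorithm_config("envelope_score", model_id = "envelope_score"),
    algorithm_config("env_distance", metric = "gower",
                     model_id = "env_distance_gower"),
    algorithm_config("env_distance", metric = "euclidean",
                     model_id = "env_distance_euclidean"))
}

#' Fit a consensus eco-linguistic niche for one group
#'
#' The full single-group modelling chain: extract environmental vectors at
#' the occurrences, split them into train/test halves, fit every ensemble
#' member on the training half, evaluate each prediction (ACC, AUC,
#' partial-ROC) against the held-out presences and a random background
#' sample, build the weighted elitist consensus, and apply the
#' fixed-sensitivity omission threshold using all occurrences.
#'
#' @param occurrences An `occurrence_set` (from [sample_occurrences()]) or a
#'   data frame with `lon`, `lat`.
#' @param stack The [eln_stack()] of the study area.
#' @param configs Ensemble of [algorithm_config()]s (default
#'   [default_ensemble()]).
#' @param split_fraction Fraction of occurrences used for training (default
#'   0.5).
#' @param top_k Consensus size (default: half the models, rounded up).
#' @param weighting Consensus weighting rule.
#' @param sensitivity Omission sensitivity `s` (default 0.10).
#' @param background_factor,background_cap Background sample size: `factor`
#'   times the number of presences, capped (defaults 10 and 10000).
#' @param seed Integer seed controlling the split, the background sample and
#'   the partial-ROC bootstrap.
#' @return List: `eln` (thresholded consensus `suitability_map`),
#'   `consensus_raw` (pre-threshold), `predictions`, `evaluations`,
#'   `consensus_auc` (held-out AUC of the consensus itself),
#'   `low_confidence`.
#' @export
fit_consensus_eln <- function(occurrences, stack,
                              configs = default_ensemble(),
                              split_fraction = 0.5, top_k = NULL,
                              weighting = "score_proportional",
                              sensitivity = 0.10,
                              background_factor = 10,
                              background_cap = 10000, seed = 1L) {
  if (!inherits(occurrences, "occurrence_set")) {
    occurrences <- structure(
      list(group_id = NA_character_,
           points = occurrences[, c("lon", "lat")],
           env_vectors = NULL, low_confidence = FALSE,
           seed = as.integer(seed)),
      class = "occurrence_set")
  }
  occ <- extract_env(occurrences, stack)
  n <- nrow(occ$points)
  if (n < 4) stop("need at least 4 usable occurrences")
  old <- .Random.seed_save(); set.seed(seed)
  train_idx <- sort(sample.int(n, max(2, round(split_fraction * n))))
  .Random.seed_restore(old)
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) < 2) {
    test_idx <- train_idx     # degenerate split: evaluate on training points
  }
  train_env <- occ$env_vectors[train_idx, , drop = FALSE]
  test_pts <- occ$points[test_idx, , drop = FALSE]

  nb <- min(background_factor * n, background_cap)
  background <- sample_background(stack, nb, seed = seed + 1L,
                                  exclude = occ$points)

  predictions <- list(); evaluations <- list()
  for (cfg in configs) {
    model <- fit_niche_model(cfg, train_env)
    map <- predict(model, stack)
    map$group_id <- occ$group_id
    predictions[[cfg$model_id]] <- map
    evaluations[[cfg$model_id]] <-
      evaluate_model(map, test_pts, background, seed = seed + 2L)
  }
  consensus <- weighted_elitist_consensus(predictions, evaluations,
                                          top_k = top_k,
                                          weighting = weighting)
  consensus_auc <- compute_auc(
    suitability_at_points(consensus, test_pts),
    consensus$values[cbind(background$row, background$col)])
  # threshold on the held-out occurrences: the fitted algorithms score their
  # own training cells perfectly, which would bias tau upwards and omit far
  # more than the nominal fraction s of generalisable presences
  eln <- fixed_sensitivity_threshold(consensus, test_pts, s = sensitivity)
  list(eln = eln, consensus_raw = consensus, predictions = predictions,
       evaluations = evaluations, consensus_auc = consensus_auc,
       low_confidence = occ$low_confidence)
}

#' Run the full eco-linguistic niche pipeline on a synthetic world
#'
#' End-to-end orchestration: per-group occurrence sampling (cap 50), ensemble
#' fitting, evaluation, weighted elitist consensus, omission thresholding,
#' accessibility filtering, pairwise overlap (Schoener's D / Hellinger's I)
#' with complete-linkage clustering, eco-linguistic pattern identification
#' and diversity counting, family potentials with their suitability
#' differential, and the growing-season / ecological-risk grids. Per-stage
#' seeds are derived deterministically from the single global seed, so a
#' rerun with the same config reproduces every artifact exactly.
#'
#' @param world A synthetic world from [generate_synthetic_world()].
#' @param configs Algorithm ensemble (default [default_ensemble()]).
#' @param cap,minimum Occurrence cap and minimum per group (50 / 10).
#' @param sensitivity Omission sensitivity (0.10).
#' @param projection_threshold Suitability cutoff for PCA clouds (0.9).
#' @param ellipse_coverage Inertia-ellipse coverage (0.61).
#' @param g_min,d_min ELP thresholds on geographic (Jaccard) and
#'   environmental (Schoener's D) overlap (0.4 / 0.6).
#' @param seed Global integer seed.
#' @param output_dir Optional directory; when given, rasters (`.asc`),
#'   overlap matrices (CSV), the dendrogram (Newick), the ELP table (CSV)
#'   and a JSON report with provenance are written there.
#' @param with_pca Also fit the environment PCA and project per-group clouds
#'   and ellipses (default TRUE).
#' @return A list with elements `elns`, `ranges`, `evaluations`,
#'   `consensus_auc`, `overlap`, `dendrogram`, `elps`, `diversity`, `pca`,
#'   `clouds`, `ellipses`, `potentials`, `delta`, `gs`, `risk`, `seed`.
#' @export
run_elnm_pipeline <- function(world, configs = default_ensemble(),
                              cap = 50, minimum = 10, sensitivity = 0.10,
                              projection_threshold = 0.9,
                              ellipse_coverage = 0.61,
                              g_min = 0.4, d_min = 0.6,
                              seed = 1L, output_dir = NULL,
                              with_pca = TRUE) {
  stack <- world$stack
  missing_layers <- setdiff(STACK_CODES, names(stack$layers))
  if (length(missing_layers) > 0)
    stop("stack is missing required layers: ",
         paste(missing_layers, collapse = ", "))
  groups <- world$groups
  ids <- vapply(groups, function(g) g$group_id, character(1))

  elns <- list(); ranges <- list(); evals <- list(); cons_auc <- numeric(0)
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    cand <- world$villages[world$villages$group_id == g$group_id,
                           c("lon", "lat")]
    occ <- sample_occurrences(g, cand, cap = cap, minimum = minimum,
                              seed = seed + 10L * k)
    fit <- fit_consensus_eln(occ, stack, configs = configs,
                             sensitivity = sensitivity,
                             seed = seed + 10L * k + 1L)
    fit$eln$group_id <- g$group_id
    elns[[g$group_id]] <- fit$eln
    evals[[g$group_id]] <- fit$evaluations
    cons_auc[g$group_id] <- fit$consensus_auc
    ranges[[g$group_id]] <- accessibility_filter(
      fit$eln, g$polygon, maritime = isTRUE(g$maritime), sea = world$sea)
  }

  ov <- overlap_matrix(elns)
  hc <- cluster_niches(ov$d_dissim)

  n <- length(ids)
  geo <- matrix(1, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) for (b in seq_len(n)) if (b > a)
    geo[a, b] <- geo[b, a] <- geographic_overlap(ranges[[a]], ranges[[b]])

  elps <- identify_elps(ids, geo, ov$d, g_min = g_min, d_min = d_min)
  metadata <- data.frame(
    group_id = ids,
    family = vapply(groups, function(g) g$family, character(1)),
    n_languages = NA_integer_)
  diversity <- diversity_summary(elps, metadata)

  pca <- NULL; clouds <- NULL; ellipses <- NULL
  if (with_pca) {
    pca <- fit_env_pca(stack)
    clouds <- lapply(elns, function(e)
      project_eln(pca, e, stack, threshold = projection_threshold))
    ellipses <- lapply(clouds, function(cl)
      if (!cl$empty && nrow(cl$scores) >= 3)
        inertia_ellipse(cl, coverage = ellipse_coverage) else NULL)
  }

  fams <- split(ids, vapply(groups, function(g) g$family, character(1)))
  potentials <- lapply(fams, function(members)
    eco_linguistic_potential(elns[members], family = NA))
  for (f in names(potentials)) potentials[[f]]$family <- f
  delta <- if (length(potentials) == 2)
    delta_eln(potentials[[setdiff(names(potentials), "Austronesian")[1]]],
              potentials[["Austronesian"]]) else NULL

  gs <- growing_season(prec = stack$monthly$prec,
                       tmin = stack$monthly$tmin, tmax = stack$monthly$tmax)
  risk <- ecological_risk(gs)

  res <- list(elns = elns, ranges = ranges, evaluations = evals,
              consensus_auc = cons_auc, overlap = ov, dendrogram = hc,
              geo_overlap = geo, elps = elps, diversity = diversity,
              pca = pca, clouds = clouds, ellipses = ellipses,
              potentials = potentials, delta = delta, gs = gs, risk = risk,
              seed = seed)
  if (!is.null(output_dir)) write_pipeline_artifacts(res, world, output_dir)
  res
}

# write standard-format artifacts with provenance
write_pipeline_artifacts <- function(res, world, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- world$grid
  for (id in names(res$elns))
    write_raster(res$elns[[id]],
                 file.path(output_dir, paste0("eln_", id, ".asc")))
  utils::write.csv(res$overlap$d,
                   file.path(output_dir, "overlap_schoener_d.csv"))
  utils::write.csv(res$overlap$i,
                   file.path(output_dir, "overlap_hellinger_i.csv"))
  write_dendrogram_newick(res$dendrogram,
                          file.path(output_dir, "dendrogram.nwk"))
  utils::write.csv(res$diversity, file.path(output_dir, "elp_table.csv"),
                   row.names = FALSE)
  if (!is.null(res$delta))
    write_raster(eln_layer(res$delta$values, grid, "delta_eln"),
                 file.path(output_dir, "delta_eln.asc"))
  write_raster(eln_layer(res$gs + 0, grid, "growing_season"),
               file.path(output_dir, "growing_season.asc"))
  report <- list(
    seed = res$seed,
    n_groups = length(res$elns),
    elns = names(res$elns),
    consensus_auc = as.list(res$consensus_auc),
    elps = lapply(res$elps, function(e)
      list(label = e$elp_label, members = e$member_ids)),
    mgs = res$risk$mgs, ecological_risk = res$risk$risk,
    package_version = as.character(utils::packageVersion("elnm")))
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' Read and write pipeline configuration as YAML
#'
#' Thresholds, extents, seeds and layer paths round-trip through a flat YAML
#' file so runs are fully described by a text artifact.
#'
#' @param config Named list of pipeline settings.
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns the named list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}
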