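# End-to-end workflow: filter -> rescore -> (calibrate) -> triage ->
# cluster -> select, with a JSON run manifest recording the parameters,
# the per-stage molecule funnel and content hashes of every output.

default_run_config <- function() {
  list(
    library = NULL,            # path to SMILES table
    library_format = "smiles_table",
    scores = NULL,             # path(s) to score tables
    scores_dialect = "table",
    activity = NULL,           # optional activity panel CSV
    classes = NULL,            # optional receptor class CSV
    out_dir = "orscreen_run",
    targets = NULL,            # receptors to cluster; NULL = all
    filter = list(mw_max = 400, heavy_atoms_max = 25,
                  heteroatoms_max = 10, logp_min = -1, logp_max = 7),
    method = "LE",
    grid = list(from = 0.01, to = 1, by = 0.01),
    top_fraction = 0.06,
    promiscuity_threshold = 0.7,
    bottom_fraction = 0.45,
    cluster = list(n_neighbors = 10, min_dist = 0.0, min_cluster_size = 30,
                   metric = "euclidean"),
    fingerprint = list(radius = 2, n_bits = 2048),
    known_ligands = character(),
    available = NULL,
    top_k_known = 5,
    seed = 42L)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Load a workflow configuration
#'
#' Reads a YAML run configuration and fills unset fields with the
#' published defaults (filter 400 g/mol / 25 heavy atoms / 10
#' heteroatoms / logP \[-1, 7\]; method LE; top fraction 0.06; decoy
#' frequency 0.7; bottom fraction 0.45; clustering n_neighbors 10,
#' min_dist 0, min_cluster_size 30).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return A run-configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  merge_config(cfg, overrides)
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("workflow aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full screening workflow
#'
#' Executes filter, rescore, optional calibration, triage, clustering and
#' candidate selection in order, writing every interchange file under
#' `config$out_dir` and a JSON run manifest recording the configuration,
#' the molecule count surviving each stage and the MD5 hash of every
#' output file. Reruns with identical inputs and seed produce identical
#' hashes.
#'
#' @param config a configuration list from [load_run_config()] (or a YAML
#'   path, which is loaded first).
#' @return The manifest, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  cfg <- merge_config(default_run_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  funnel <- list()
  outputs <- character()

  # filter ------------------------------------------------------------------
  lib <- stage_error("filter", {
    if (is.null(cfg$library)) stop("config missing the library path")
    lib <- load_library(cfg$library, cfg$library_format)
    lib <- compute_descriptors(lib)
    funnel$loaded <- nrow(lib)
    flt <- physchem_filter(lib, do.call(filter_limits, cfg$filter))
    utils::write.csv(flt$passing, file.path(cfg$out_dir, "passed.csv"),
                     row.names = FALSE)
    utils::write.csv(flt$rejected[, c("id", "reasons")],
                     file.path(cfg$out_dir, "rejects.csv"), row.names = FALSE)
    outputs <- c(outputs, "passed.csv", "rejects.csv")
    flt$passing
  })
  funnel$filtered <- nrow(lib)

  # rescore -----------------------------------------------------------------
  res <- stage_error("rescore", {
    if (is.null(cfg$scores)) stop("config missing the scores path")
    raw <- parse_scores(cfg$scores, cfg$scores_dialect)
    raw <- lapply(raw, function(t) {
      keep <- names(t$scores) %in% lib$id
      if (!any(keep)) stop("no scored molecule passed the filter for ", t$receptor_id)
      score_table(t$receptor_id, t$scores[keep])
    })
    write_rescored_csv(raw, lib, file.path(cfg$out_dir, "rescored.csv"))
    outputs <- c(outputs, "rescored.csv")
    lapply(raw, rescore, library = lib, method = cfg$method)
  })
  funnel$scored <- length(res[[1]]$scores)
  ranked <- lapply(res, rank_scores)

  # calibrate (optional) ----------------------------------------------------
  top_fraction <- cfg$top_fraction
  if (!is.null(cfg$activity)) {
    stage_error("calibrate", {
      act <- read_activity_csv(cfg$activity, cfg$classes)
      raw_tabs <- read_rescored_csv(file.path(cfg$out_dir, "rescored.csv"),
                                    "vinardo_raw")
      all_tabs <- c(raw_tabs, unlist(lapply(c("LE", "LEln", "LESA"), function(m)
        read_rescored_csv(file.path(cfg$out_dir, "rescored.csv"), m)),
        recursive = FALSE))
      rep <- calibrate(all_tabs, act, grid = seq(cfg$grid$from, cfg$grid$to,
                                                 by = cfg$grid$by))
      write_calibration(rep, file.path(cfg$out_dir, "calibration.json"),
                        file.path(cfg$out_dir, "auc_matrix.csv"))
      outputs <- c(outputs, "calibration.json", "auc_matrix.csv")
    })
  }

  # triage ------------------------------------------------------------------
  tri <- stage_error("triage", {
    t <- triage(ranked, top_fraction = top_fraction,
                promiscuity_threshold = cfg$promiscuity_threshold,
                bottom_fraction = cfg$bottom_fraction)
    write_triage_csv(t, ranked, file.path(cfg$out_dir, "triage"))
    outputs <- c(outputs, file.path("triage",
      c(paste0("triage_", names(ranked), ".csv"), "suspected_decoys.csv")))
    t
  })
  funnel$top_fraction <- tri$parameters$top_k
  funnel$binders <- lapply(tri$potential_binders, length)

  # cluster + select per target receptor ------------------------------------
  targets <- cfg$targets %||% names(ranked)
  slates <- stage_error("cluster", {
    out <- list()
    for (rc in targets) {
      binders <- tri$potential_binders[[rc]]
      if (length(binders) < 2) next
      fps <- morgan_fp(lib[lib$id %in% binders, c("id", "smiles")],
                       radius = cfg$fingerprint$radius,
                       n_bits = cfg$fingerprint$n_bits)
      asg <- embed_and_cluster(fps,
                               n_neighbors = cfg$cluster$n_neighbors,
                               min_dist = cfg$cluster$min_dist,
                               min_cluster_size = cfg$cluster$min_cluster_size,
                               seed = cfg$seed, metric = cfg$cluster$metric)
      write_clusters_csv(asg, file.path(cfg$out_dir, paste0("clusters_", rc, ".csv")))
      outputs <- c(outputs, paste0("clusters_", rc, ".csv"))
      if (max(asg$labels) >= 1) {
        clustered <- names(asg$labels)[asg$labels != NOISE]
        slate <- select_candidates(clustered, asg, res[[rc]],
                                   known_ligands = cfg$known_ligands,
                                   available = cfg$available,
                                   top_k_known = cfg$top_k_known)
        utils::write.csv(slate, file.path(cfg$out_dir, paste0("slate_", rc, ".csv")),
                         row.names = FALSE)
        outputs <- c(outputs, paste0("slate_", rc, ".csv"))
        out[[rc]] <- slate
      }
    }
    outputs <- outputs
    out
  })
  funnel$clusters <- lapply(slates, function(s) length(unique(s$cluster)))
  funnel$candidates <- lapply(slates, nrow)

  manifest <- list(
    package_version = as.character(utils::packageVersion("orscreen")),
    config = cfg, funnel = funnel,
    input_hashes = as.list(tools::md5sum(
      c(cfg$library, cfg$scores, cfg$activity, cfg$classes))),
    output_hashes = as.list(tools::md5sum(file.path(cfg$out_dir, outputs))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
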