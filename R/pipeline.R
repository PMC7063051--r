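#' Run the full backbone-prediction pipeline
#'
#' Executes the prediction stages in order: read the density map,
#' normalize it (threshold, median division, percentile cap) and
#' resample to 1 A voxels if needed, obtain the five confidence maps
#' (from a trained network checkpoint, or from the ground-truth model
#' in oracle mode), trace C-alpha chains with the path walker, refine
#' the trace graph (path combination, side-chain, loop and dead-end
#' removal), refit alpha-helices, and write the final trace PDB. When
#' a ground-truth PDB is supplied the prediction is scored with the
#' one-to-one matching metrics. Every stage writes an inspectable
#' intermediate under `out_dir`, and a JSON manifest records all
#' resolved parameters; re-running with the same inputs reproduces the
#' output byte for byte.
#'
#' @param map input map: a file path (`.mrc`/`.map`) or a
#'   [density_map()].
#' @param threshold density threshold for [preprocess_map()].
#' @param mode `"network"` (requires `checkpoint`) or `"oracle"`
#'   (requires `pdb`).
#' @param pdb ground-truth PDB path or [atomic_model()]; mandatory in
#'   oracle mode, optional (for evaluation) in network mode.
#' @param checkpoint path to a [save_ccnn()] checkpoint (network mode).
#' @param out_dir output directory, created if missing.
#' @param params a [walk_params()].
#' @param helix_refine logical; run the helix refinement stage.
#' @param min_helix_len minimum helix run length for refitting.
#' @param seed integer recorded in the manifest (all pipeline stages
#'   are deterministic; the seed matters only for network training
#'   upstream).
#' @return Object of class `backbone_prediction`: list with `pdb_path`,
#'   `traces`, `graph`, `metrics` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(map, threshold, mode = c("oracle", "network"),
                         pdb = NULL, checkpoint = NULL,
                         out_dir = tempfile("cryotrace_run_"),
                         params = walk_params(), helix_refine = TRUE,
                         min_helix_len = 6L, seed = 1) {
  mode <- match.arg(mode)
  if (is.character(map) && !file.exists(map)) {
    stop("input map not found: ", map)
  }
  if (mode == "oracle" && is.null(pdb)) {
    stop("oracle mode requires a ground-truth PDB")
  }
  if (mode == "network" && is.null(checkpoint)) {
    stop("network mode requires a model checkpoint")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dmap <- if (is.character(map)) read_mrc(map) else map
  stopifnot(inherits(dmap, "density_map"))
  resampled <- any(abs(dmap$voxel - 1) > 1e-6)
  if (resampled) dmap <- resample_to_unit_voxel(dmap)
  pre <- preprocess_map(dmap, threshold)
  write_mrc(pre, file.path(out_dir, "preprocessed.mrc"))

  model_gt <- NULL
  if (!is.null(pdb)) {
    model_gt <- if (is.character(pdb)) read_pdb(pdb) else pdb
    stopifnot(inherits(model_gt, "atomic_model"))
  }

  maps <- if (mode == "oracle") {
    oracle_confidence(model_gt, pre)
  } else {
    predict_confidence(load_ccnn(checkpoint), pre)
  }

  traces <- trace_all(maps, params)
  if (length(traces) > 0) {
    write_trace_pdb(traces, file.path(out_dir, "traces_raw.pdb"))
  }
  graph <- traces_to_graph(traces)
  graph <- refine_graph(graph, pre)
  if (helix_refine) graph <- refine_helices(graph, maps, min_helix_len)
  out_traces <- graph_to_traces(graph)

  pdb_path <- file.path(out_dir, "prediction.pdb")
  if (length(out_traces) > 0) {
    write_trace_pdb(out_traces, pdb_path)
  } else {
    pdb_path <- NULL
  }

  metrics <- NULL
  if (!is.null(model_gt) && length(out_traces) > 0) {
    pred_xyz <- do.call(rbind, lapply(out_traces, function(tr) tr$xyz))
    metrics <- compute_metrics(pred_xyz, ca_coords(model_gt))
    write_metrics(metrics, csv = file.path(out_dir, "metrics.csv"),
                  json = file.path(out_dir, "metrics.json"))
  }

  manifest <- list(
    mode = mode, threshold = threshold, resampled_to_unit_voxel = resampled,
    helix_refine = helix_refine, min_helix_len = min_helix_len,
    seed = seed, walk_params = unclass(params),
    map_dims = dim(pre$grid), voxel = pre$voxel, origin = pre$origin,
    n_traces = length(out_traces),
    n_ca = sum(vapply(out_traces, function(tr) nrow(tr$xyz), 0L)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(pdb_path = pdb_path, traces = out_traces, graph = graph,
                 confidence = maps, metrics = metrics, manifest = manifest,
                 out_dir = out_dir),
            class = "backbone_prediction")
}

#' @export
print.backbone_prediction <- function(x, ...) {
  cat("<backbone_prediction>\n")
  cat(sprintf("  traces : %d (%d CA)\n", x$manifest$n_traces, x$manifest$n_ca))
  cat(sprintf("  output : %s\n", x$pdb_path %||% "(none)"))
  if (!is.null(x$metrics)) {
    cat(sprintf("  %% CA in 3 A %.1f, RMSD %.3f A, error rate %.4f\n",
                x$metrics$pct3, x$metrics$rmsd, x$metrics$error_rate))
  }
  invisible(x)
}

#' Run the pipeline over several maps
#'
#' Processes maps independently (optionally in parallel worker
#' processes) with shared settings; each map gets its own output
#' subdirectory.
#'
#' @param maps character vector of map paths.
#' @param pdbs optional parallel vector of ground-truth PDB paths.
#' @param out_root root output directory.
#' @param cores number of worker processes.
#' @param ... passed to [run_pipeline()].
#' @return List of `backbone_prediction` objects.
#' @export
run_pipeline_batch <- function(maps, pdbs = NULL, out_root = tempdir(),
                               cores = 1L, ...) {
  runs <- seq_along(maps)
  worker <- function(i) {
    run_pipeline(maps[i], pdb = if (!is.null(pdbs)) pdbs[i],
                 out_dir = file.path(out_root, sprintf("map_%03d", i)), ...)
  }
  if (cores > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(runs, worker, mc.cores = cores)
  } else {
    lapply(runs, worker)
  }
}
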