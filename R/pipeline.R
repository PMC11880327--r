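#' Write a JSON artifact with provenance metadata
#' @noRd
write_json_artifact <- function(payload, path, config) {
  payload$provenance <- list(
    package = "tcrshape",
    version = as.character(utils::packageVersion("tcrshape")),
    seed = config$seed %||% NA,
    thresholds = config$thresholds %||% NULL,
    inputs = config$inputs %||% NULL)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run an analysis pipeline over configured stages
#'
#' Thin orchestration over the package's analysis functions. Stages run in
#' dependency order; every numeric artifact (CSV/JSON) carries provenance
#' metadata (seed, thresholds, package version) and re-running an identical
#' config byte-reproduces every artifact. On a stage failure the completed
#' stages' artifacts are kept and a failure manifest is written.
#'
#' Supported stages:
#' * `"synth"`: generate a synthetic repertoire
#'   ([generate_repertoire()]) and write it under `out_dir/synthetic/`.
#' * `"cluster"`: pairwise structural distances and greedy clustering per
#'   requested region; writes assignments CSV per region.
#' * `"census"`: cluster census JSON per region (requires `"cluster"`).
#' * `"vj"`: VJ coherence report ([vj_coherence()]) as JSON.
#' * `"seq_scan"`: sequence-identity threshold scan CSV.
#' * `"benchmark"`: per-region RMSD table for predictions vs references read
#'   from `pred_dir` / `ref_dir`.
#'
#' @param config list with fields: `stages` (character vector), `out_dir`,
#'   `seed`, `tau` (Angstrom, default 1), `min_group` (default 5),
#'   `identity_thresholds`, `regions` (e.g. `list(c("alpha", "CDR3"))`),
#'   `generator` (arguments for [generator_config()]), `pred_dir`,
#'   `ref_dir`, `chain_map`
#' @return invisibly, list with `status` (0 ok, 1 stage failure, 2 bad
#'   config), `artifacts` (paths written), `error` (message, if any)
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir) || is.null(config$stages)) {
    return(invisible(list(status = 2L, artifacts = character(),
                          error = "config must name out_dir and stages")))
  }
  if ("benchmark" %in% config$stages &&
      (is.null(config$pred_dir) || !dir.exists(config$pred_dir) ||
       is.null(config$ref_dir) || !dir.exists(config$ref_dir))) {
    return(invisible(list(status = 2L, artifacts = character(),
                          error = "benchmark stage needs existing pred_dir and ref_dir")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- config$seed %||% 1L
  config$tau <- config$tau %||% 1
  config$min_group <- config$min_group %||% 5L
  artifacts <- character()
  state <- new.env(parent = emptyenv())
  meta <- list(seed = config$seed,
               thresholds = list(tau = config$tau,
                                 min_group = config$min_group))
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      manifest <- file.path(config$out_dir, "failure_manifest.json")
      jsonlite::write_json(
        list(failed_stage = name, message = conditionMessage(e),
             completed_artifacts = artifacts),
        manifest, auto_unbox = TRUE, pretty = TRUE)
      stop_with("stage_error", sprintf("stage '%s' failed: %s", name,
                                       conditionMessage(e)))
    })
  }
  status <- 0L
  err <- NULL
  for (stage in config$stages) {
    res <- tryCatch({
      switch(stage,
        synth = run_stage("synth", function() {
          gc_args <- config$generator %||% list()
          gc_args$seed <- gc_args$seed %||% config$seed
          rep <- generate_repertoire(do.call(generator_config, gc_args))
          state$repertoire <- rep
          d <- file.path(config$out_dir, "synthetic")
          write_repertoire(rep, d)
          artifacts <<- c(artifacts, d)
        }),
        cluster = run_stage("cluster", function() {
          rep <- state$repertoire
          if (is.null(rep)) stop("cluster stage needs a synth stage first")
          regions <- config$regions %||%
            list(c(rep$config$chain_kinds[1], "CDR3"))
          state$assignments <- list()
          for (rg in regions) {
            loops <- collect_loops(rep$records, rg[1], rg[2])
            D <- pairwise_distance_matrix(loops)
            ca <- greedy_cluster(D, config$tau)
            key <- paste(rg[1], rg[2], sep = "_")
            state$assignments[[key]] <- ca
            p <- file.path(config$out_dir,
                           paste0("clusters_", key, ".csv"))
            utils::write.csv(cluster_table(ca), p, row.names = FALSE)
            artifacts <<- c(artifacts, p)
          }
        }),
        census = run_stage("census", function() {
          if (is.null(state$assignments)) stop("census stage needs cluster stage")
          payload <- lapply(state$assignments, function(ca) {
            cc <- cluster_census(ca)
            list(n_clusters = cc$n_clusters, n_items = cc$n_items,
                 singleton_fraction = cc$singleton_fraction,
                 sizes = cc$sizes)
          })
          p <- file.path(config$out_dir, "census.json")
          write_json_artifact(list(census = payload), p, meta)
          artifacts <<- c(artifacts, p)
        }),
        vj = run_stage("vj", function() {
          rep <- state$repertoire
          if (is.null(rep)) stop("vj stage needs a synth stage first")
          payload <- list()
          for (kind in rep$config$chain_kinds) {
            loops <- collect_loops(rep$records, kind, "CDR3")
            rpt <- vj_coherence(loops, tau = 2, min_group = config$min_group)
            payload[[kind]] <- list(
              fraction_single_cluster = rpt$fraction_single_cluster,
              n_pairs = nrow(rpt$per_pair), per_pair = rpt$per_pair)
          }
          p <- file.path(config$out_dir, "vj_coherence.json")
          write_json_artifact(payload, p, meta)
          artifacts <<- c(artifacts, p)
        }),
        seq_scan = run_stage("seq_scan", function() {
          rep <- state$repertoire
          if (is.null(rep)) stop("seq_scan stage needs a synth stage first")
          th <- config$identity_thresholds %||% seq(0.5, 0.9, by = 0.1)
          out <- NULL
          for (kind in rep$config$chain_kinds) {
            seqs <- vapply(collect_loops(rep$records, kind, "CDR3"),
                           `[[`, "", "sequence")
            sc <- identity_threshold_scan(seqs, th)
            sc$chain <- kind
            out <- rbind(out, sc)
          }
          p <- file.path(config$out_dir, "seq_scan.csv")
          utils::write.csv(out, p, row.names = FALSE)
          artifacts <<- c(artifacts, p)
        }),
        benchmark = run_stage("benchmark", function() {
          cm <- config$chain_map %||% c(A = "alpha", B = "beta")
          read_dir <- function(d) {
            fs <- sort(list.files(d, pattern = "\\.pdb$", full.names = TRUE))
            lapply(fs, read_structure, chain_map = cm)
          }
          preds <- read_dir(config$pred_dir)
          refs <- read_dir(config$ref_dir)
          rpt <- region_report(preds, refs,
                               model_name = config$model_name %||% "model")
          p1 <- file.path(config$out_dir, "benchmark_per_record.csv")
          p2 <- file.path(config$out_dir, "benchmark_summary.csv")
          utils::write.csv(rpt$per_record, p1, row.names = FALSE)
          utils::write.csv(report_summary(rpt), p2, row.names = FALSE)
          artifacts <<- c(artifacts, p1, p2)
          state$benchmark <- rpt
        }),
        stop_with("stage_error", paste("unknown stage:", stage)))
      NULL
    }, tcrshape_error = function(e) e)
    if (!is.null(res)) {
      status <- 1L
      err <- conditionMessage(res)
      break
    }
  }
  invisible(list(status = status, artifacts = artifacts, error = err,
                 state = as.list(state)))
}
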