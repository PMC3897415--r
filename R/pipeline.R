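# End-to-end orchestration: read clouds -> distance matrices -> NMMDS ->
# centrality -> treeishness -> per-gene incongruence screens, with
# reproducible seeding and a run log.

#' Assemble a pipeline run configuration
#'
#' @param manifest data frame with columns `cloud_id`, `path`, and
#'   optionally `kind` (`gene`/`reference`/`randomized`); exactly one
#'   reference row. Alternatively `clouds`/`reference` may be passed to
#'   [run_pipeline()] directly.
#' @param reference_id `cloud_id` of the reference cloud (required when the
#'   manifest has no `kind` column).
#' @param metrics metrics to analyse (subset of [treecloud_metrics()]).
#' @param burnin_fraction burn-in removed when reading each file.
#' @param n_trees,n_pairs subsampling sizes (matrix building / statistics).
#' @param n_restarts NMMDS random restarts per run.
#' @param n_nmds_runs independent NMMDS runs per metric (different seeds).
#' @param include_randomized add a tip-randomized copy of every cloud.
#' @param reference_member_ids gene cloud ids that are members of the
#'   concatenated reference set; centrality is also rerun excluding them.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(manifest = NULL, reference_id = NULL,
                       metrics = c("symmetric", "rf_rescaled"),
                       burnin_fraction = 0, n_trees = 100, n_pairs = 1000,
                       n_restarts = 20, n_nmds_runs = 3,
                       include_randomized = TRUE,
                       reference_member_ids = character(), seed = 1,
                       out_dir = "treecloud_out") {
  metrics <- match.arg(metrics, treecloud_metrics(), several.ok = TRUE)
  structure(list(manifest = manifest, reference_id = reference_id,
                 metrics = metrics, burnin_fraction = burnin_fraction,
                 n_trees = n_trees, n_pairs = n_pairs,
                 n_restarts = n_restarts, n_nmds_runs = n_nmds_runs,
                 include_randomized = include_randomized,
                 reference_member_ids = reference_member_ids,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a key-value text file
#'
#' Lines of the form `key = value` (`#` comments allowed). `manifest`
#' names a TSV with columns `cloud_id`, `path` and optionally `kind`;
#' list-valued keys (`metrics`, `reference_member_ids`) are
#' comma-separated.
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), function(p)
    c(trimws(p[1]), trimws(paste(p[-1], collapse = "="))))
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d) if (k %in% names(vals)) vals[[k]] else d
  lst <- function(k, d) if (k %in% names(vals))
    trimws(strsplit(vals[[k]], ",")[[1]]) else d
  manifest <- NULL
  if ("manifest" %in% names(vals)) {
    mp <- vals[["manifest"]]
    if (!file.exists(mp)) stopf("manifest not found: %s", mp)
    manifest <- read.table(mp, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  run_config(manifest = manifest,
             reference_id = chr("reference_id", NULL),
             metrics = lst("metrics", c("symmetric", "rf_rescaled")),
             burnin_fraction = num("burnin_fraction", 0),
             n_trees = num("n_trees", 100), n_pairs = num("n_pairs", 1000),
             n_restarts = num("n_restarts", 20),
             n_nmds_runs = num("n_nmds_runs", 3),
             include_randomized =
               tolower(chr("include_randomized", "true")) == "true",
             reference_member_ids = lst("reference_member_ids", character()),
             seed = num("seed", 1), out_dir = chr("out_dir", "treecloud_out"))
}

load_manifest_clouds <- function(config) {
  m <- config$manifest
  if (is.null(m)) stopf("config has no manifest")
  if (!all(c("cloud_id", "path") %in% names(m)))
    stopf("manifest needs cloud_id and path columns")
  if (!"kind" %in% names(m)) {
    if (is.null(config$reference_id))
      stopf("manifest has no kind column and no reference_id given")
    m$kind <- ifelse(m$cloud_id == config$reference_id, "reference", "gene")
  }
  if (sum(m$kind == "reference") != 1L)
    stopf("exactly one reference cloud required (found %d)",
          sum(m$kind == "reference"))
  clouds <- lapply(seq_len(nrow(m)), function(i)
    read_tree_samples(m$path[i], burnin_fraction = config$burnin_fraction,
                      cloud_id = m$cloud_id[i],
                      source_kind = m$kind[i]))
  list(genes = clouds[m$kind == "gene"],
       reference = clouds[[which(m$kind == "reference")]])
}

#' Run the full treecloud congruence pipeline
#'
#' Stages: (randomize) -> all-pairs distance matrices for every requested
#' metric -> independent NMMDS embeddings per metric -> centrality tests
#' with and without reference-member gene clouds -> treeishness -> per-gene
#' incongruence and gamma reports. All artifacts are written under
#' `config$out_dir`; a run log records seeds, the config hash and stage
#' timings. Any stage failure aborts with a stage-named error; artifacts
#' already written are retained.
#'
#' @param config a [run_config()].
#' @param clouds optional list of gene `tree_cloud`s (bypasses the
#'   manifest).
#' @param reference optional reference `tree_cloud`.
#' @return invisibly, a list of the in-memory results
#'   (`matrices`, `embeddings`, `centrality`, `treeishness`, `report`).
#' @export
run_pipeline <- function(config, clouds = NULL, reference = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    logf("stage %-12s done in %.1fs", name,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  # echo config + hash
  # hash covers the analysis-relevant settings, not output location
  cfg_path <- file.path(config$out_dir, "config_echo.json")
  jsonlite::write_json(
    unclass(config[setdiff(names(config), c("manifest", "out_dir"))]),
    cfg_path, auto_unbox = TRUE, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_path))
  logf("run seed %d, config hash %s", config$seed, cfg_hash)

  if (is.null(clouds) || is.null(reference)) {
    loaded <- stage("read", load_manifest_clouds(config))
    clouds <- loaded$genes
    reference <- loaded$reference
  }
  seeds <- derive_seeds(config$seed, 6L)
  all_clouds <- c(clouds, list(reference))
  randomized <- list()
  if (config$include_randomized) {
    rs <- derive_seeds(seeds[1], length(all_clouds))
    randomized <- stage("randomize", lapply(seq_along(all_clouds), function(i)
      shuffle_cloud(all_clouds[[i]], rs[i])))
  }
  analysis_set <- c(all_clouds, randomized)

  matrices <- list(); embeddings <- list(); summary_rows <- list()
  nmds_seeds <- derive_seeds(seeds[2], config$n_nmds_runs)
  for (metric in config$metrics) {
    mat <- stage(paste0("dist_", metric),
                 all_pairs_matrix(analysis_set, metric = metric,
                                  n_trees = config$n_trees,
                                  seed = seeds[3]))
    matrices[[metric]] <- mat
    write_dist_matrix(mat, file.path(config$out_dir,
                                     paste0("distmatrix_", metric, ".csv")))
    runs <- stage(paste0("nmds_", metric),
                  lapply(nmds_seeds, function(s)
                    nmds_embed(mat, n_restarts = config$n_restarts,
                               seed = s)))
    embeddings[[metric]] <- runs
    for (r in seq_along(runs)) {
      em <- runs[[r]]
      coords <- data.frame(cloud_id = rownames(em$points),
                           x = em$points[, 1], y = em$points[, 2],
                           source_kind = em$source_kinds)
      utils::write.csv(coords,
                       file.path(config$out_dir,
                                 sprintf("nmds_%s_run%d.csv", metric, r)),
                       row.names = FALSE)
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(metric = metric,
                   randomized_included = config$include_randomized,
                   iteration = r, stress = em$stress,
                   r_squared = em$r_squared, seed = em$seed)
    }
  }
  write.table(do.call(rbind, summary_rows),
              file.path(config$out_dir, "nmds_summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  # centrality with and without reference-member gene clouds
  centrality <- stage("centrality", {
    res <- list(all = centrality_test(matrices[[config$metrics[1]]],
                                      focal = reference$cloud_id))
    if (length(config$reference_member_ids) > 0) {
      keep <- !(vapply(clouds, function(cl) cl$cloud_id, "") %in%
                  config$reference_member_ids)
      res$without_members <- centrality_test(
        c(clouds[keep], list(reference), randomized),
        focal = reference$cloud_id, metric = config$metrics[1],
        n_pairs = config$n_pairs, seed = seeds[4])
    }
    res
  })

  tau <- NULL
  if (length(randomized) > 0) {
    tau <- stage("treeishness", lapply(config$metrics, function(metric)
      treeishness(clouds, reference, randomized, metric = metric,
                  n_triplets = config$n_pairs, seed = seeds[5])))
    names(tau) <- config$metrics
    jsonlite::write_json(
      list(seed = config$seed, config_hash = cfg_hash,
           tau = lapply(tau, function(t)
             t[c("tau_from_means", "tau_mean", "tau_sd", "p_ge_1", "p_le_0",
                 "metric")]),
           centrality = lapply(centrality, function(ct)
             ct[c("focal_cloud", "focal_rank", "n_clouds_in_null",
                  "p_value")])),
      file.path(config$out_dir, "summary.json"), auto_unbox = TRUE,
      digits = NA)
  }

  report <- stage("screen", incongruence_report(
    clouds, reference, metric = config$metrics[1], n_pairs = config$n_pairs,
    gamma_n_null = config$n_pairs, gamma_n_between = config$n_pairs,
    seed = seeds[6]))
  report$seed <- config$seed
  report$config_hash <- cfg_hash
  write.table(report, file.path(config$out_dir, "incongruence_report.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  logf("pipeline complete")
  invisible(list(matrices = matrices, embeddings = embeddings,
                 centrality = centrality, treeishness = tau,
                 report = report))
}
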