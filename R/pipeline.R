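## End-to-end pipeline: simulate/read -> snapshots -> cube -> triclusters
## -> patterns -> distance matrix -> progression groups -> evaluation,
## with a validated config, serialized intermediates and a run manifest.

.configDefaults <- function() {
  list(
    input = NULL,            # long-format records CSV (NULL = simulate)
    schema = NULL,           # column mapping list or YAML path
    simulate = list(nPatients = 200L, seed = 1L),
    windowDays = 100,
    nContexts = 3L,
    epsilon = 0.05,
    shift = NULL,
    minSubjects = NULL,
    minFeatures = 2L,
    minTimes = NULL,
    delta = 1,
    patternFamily = "scaling",
    standardize = FALSE,
    includeStatic = FALSE,
    kCandidates = 3:5,
    k = NULL,
    horizonMonths = 96,
    nAppointments = 5L,
    anchor = FALSE,
    seed = 1L,
    outDir = NULL
  )
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected; every parameter is checked against its
#' domain before any stage runs.
#'
#' @param config named list of overrides (or a YAML file path).
#' @return the completed config list.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!is.null(config$k)) cfg$k <- config$k
  stopifnot(cfg$windowDays > 0, cfg$nContexts >= 1)
  if (cfg$epsilon < 0) stop("epsilon must be nonnegative")
  if (cfg$delta < 0 || cfg$delta > 1) stop("delta must lie in [0, 1]")
  if (!cfg$patternFamily %in% c("scaling", "shifting"))
    stop("patternFamily must be 'scaling' or 'shifting'")
  if (!is.null(cfg$k) && cfg$k < 1) stop("k must be positive")
  if (cfg$minFeatures < 1) stop("minFeatures must be >= 1")
  cfg
}

#' Run the full stratification pipeline
#'
#' Executes preprocess, tricluster, transform, cluster and evaluate in
#' order. With no input file a synthetic cohort is generated (all
#' randomness flows from the config seed), so the pipeline is runnable
#' end-to-end without clinical data. When \code{outDir} is set every
#' stage's artifact is written (CSV/JSON) together with a run manifest
#' that pins parameters, seed, package version and input checksum.
#'
#' @param config list of config overrides or YAML path
#'   (see \code{\link{pipelineConfig}}).
#' @return (invisibly) list with \code{cohort} (when simulated),
#'   \code{dataset}, \code{solution}, \code{patterns}, \code{matrix},
#'   \code{clustering}, \code{trajectories}, \code{survival},
#'   \code{manifest}.
#' @export
runPipeline <- function(config = list()) {
  cfg <- pipelineConfig(config)
  out <- list()
  ## stage: input
  if (!is.null(cfg$input)) {
    schema <- cfg$schema %||% defaultSchema()
    if (is.character(schema)) schema <- yaml::read_yaml(schema)
    records <- readLongRecords(cfg$input, schema)
    static <- NULL
    checksum <- unname(tools::md5sum(cfg$input))
  } else {
    cohort <- generateCohort(cfg$simulate$nPatients %||% 200L,
                             seed = cfg$simulate$seed %||% cfg$seed)
    out$cohort <- cohort
    records <- cohortToRecords(cohort)
    static <- cohortStaticData(cohort)
    checksum <- sprintf("simulated(seed=%d)", cohort$seed)
  }
  ## stage: preprocess
  snaps <- buildSnapshots(records, windowDays = cfg$windowDays)
  feats <- featureTable(snaps)
  dataset <- assembleThreeWay(feats, nContexts = cfg$nContexts,
                              staticData = static)
  out$features <- feats
  out$dataset <- dataset
  if (length(subjects(dataset)) < 2L)
    stop("fewer than two patients survive preprocessing")
  ## stage: tricluster
  solution <- mineTriclusters(dataset, epsilon = cfg$epsilon,
                              minSubjects = cfg$minSubjects,
                              minFeatures = cfg$minFeatures,
                              minTimes = cfg$minTimes, delta = cfg$delta,
                              patternFamily = cfg$patternFamily,
                              shift = cfg$shift)
  out$solution <- solution
  if (length(solution) == 0L) stop("no triclusters found; relax epsilon")
  ## stage: transform
  patterns <- virtualPatterns(solution, dataset)
  pdm <- transformDataset(dataset, patterns, standardize = cfg$standardize)
  if (isTRUE(cfg$includeStatic) && nrow(staticData(dataset)))
    pdm <- appendStaticColumns(pdm, staticData(dataset))
  out$patterns <- patterns
  out$matrix <- pdm
  ## stage: cluster
  clustering <- progressionClusters(pdm, k = cfg$k,
                                    candidates = cfg$kCandidates)
  out$clustering <- clustering
  ## stage: evaluate
  labels <- clusterLabels(clustering)
  out$trajectories <- trajectorySummary(feats, labels,
                                        nAppointments = cfg$nAppointments,
                                        anchor = cfg$anchor)
  sdat <- staticData(dataset)
  if (all(c("survival_months", "event") %in% names(sdat)) && nrow(sdat))
    out$survival <- survivalByGroup(sdat, labels,
                                    horizonMonths = cfg$horizonMonths)
  out$manifest <- list(
    package = "clustric",
    version = as.character(utils::packageVersion("clustric")),
    parameters = cfg[setdiff(names(cfg), "outDir")],
    input_checksum = checksum,
    generated = length(out$cohort) > 0
  )
  if (!is.null(cfg$outDir)) .writeArtifacts(out, cfg$outDir)
  invisible(out)
}

.writeArtifacts <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$cohort))
    writeCohort(out$cohort, file.path(dir, "records.csv"),
                file.path(dir, "truth.csv"))
  writeThreeWay(out$dataset, file.path(dir, "cube.csv"))
  writeTriclusters(out$solution, file.path(dir, "triclusters.json"))
  writeDistanceMatrix(out$matrix, file.path(dir, "matrix.csv"))
  writeClusterLabels(out$clustering, file.path(dir, "groups.csv"))
  writeLinkageTree(out$clustering@tree, file.path(dir, "linkage.json"))
  utils::write.csv(validityTable(out$clustering),
                   file.path(dir, "validity.csv"), row.names = FALSE)
  utils::write.csv(out$trajectories$points,
                   file.path(dir, "trajectory_points.csv"), row.names = FALSE)
  utils::write.csv(out$trajectories$slopes,
                   file.path(dir, "trajectory_slopes.csv"), row.names = FALSE)
  if (!is.null(out$survival)) {
    utils::write.csv(out$survival$table, file.path(dir, "survival.csv"),
                     row.names = FALSE)
    utils::write.csv(out$survival$logrank$pairwise,
                     file.path(dir, "logrank_pairwise.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
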