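# End-to-end orchestration: simulate -> features -> cluster -> peaks ->
# classify -> stats, under one seeded, serializable configuration. A single
# global seed fans out deterministically to per-stage seeds (stageSeed), so
# stages are independently reproducible from persisted intermediates.

#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param nEvents number of synthetic events when simulating.
#' @param outDir optional output directory for the report bundle.
#' @return a config list of class `"RunConfig"` (YAML-serializable via
#'   [writeRunConfig()]).
#' @export
defaultConfig <- function(seed = 1L, nEvents = 400L, outDir = NULL) {
  structure(list(
    seed = as.integer(seed),
    nEvents = as.integer(nEvents),
    params = eventParams(),
    varianceTarget = 0.9,
    kRange = 2:8,
    heightGrid = c(2, 3, 4),
    widthGrid = c(1, 2, 3),
    distanceGrid = c(3, 5, 8),
    linkRadius = 300,
    minOverlap = 3L,
    earlyLead = 20,
    cohortEdges = c(10, 20, 40, 60, 120),
    motilityWindow = 10L,
    outDir = outDir,
    version = as.character(utils::packageVersion("cmetracks"))),
    class = "RunConfig")
}

validateConfig <- function(config) {
  need <- c("seed", "nEvents", "params", "varianceTarget", "kRange",
            "heightGrid", "widthGrid", "distanceGrid", "linkRadius",
            "minOverlap", "cohortEdges", "motilityWindow")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "))
  if (!length(config$heightGrid) || !length(config$widthGrid) ||
      !length(config$distanceGrid))
    stop("peak-parameter grids must be non-empty")
  if (!length(config$kRange)) stop("kRange must be non-empty")
  if (!inherits(config$params, "EventParams"))
    config$params <- do.call(eventParams, config$params)
  config
}

#' Read / write a run configuration as YAML
#'
#' @param config a config list ([defaultConfig()]).
#' @param path YAML file path.
#' @return `writeRunConfig` invisibly returns `path`; `readRunConfig`
#'   returns a validated config list.
#' @export
writeRunConfig <- function(config, path) {
  out <- config
  out$params <- unclass(out$params)
  out$outDir <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$params <- do.call(eventParams, raw$params)
  raw$kRange <- as.integer(raw$kRange)
  structure(validateConfig(raw), class = "RunConfig")
}

.writeTable <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> feature extraction -> scaling -> PCA -> Gaussian
#' mixture clustering -> DNM2-positive cluster selection -> peak-parameter
#' survey and single-peak filtering -> third-channel linking and timing
#' classification -> kinetic statistics, under the seeds derived from
#' `config$seed`. When `config$outDir` is set, all intermediate tables plus
#' the exact configuration used are written there as delimited text.
#'
#' @param config a config list from [defaultConfig()] / [readRunConfig()].
#' @param dataset optionally, a precomputed dataset (list with `events`,
#'   `third`, `truth`) instead of simulating.
#' @return a report bundle: list with the dataset, feature matrix, cluster
#'   model and labels, selected peak parameters and survey, annotations,
#'   positive fraction, cohort summary, separation table, group comparisons,
#'   and the configuration.
#' @export
runPipeline <- function(config = defaultConfig(), dataset = NULL) {
  config <- validateConfig(config)
  seed <- config$seed
  if (is.null(dataset))
    dataset <- simulateDataset(config$params, config$nEvents, seed = seed)

  feats <- extractFeatures(dataset$events)
  sc <- scaleFeatures(feats)
  red <- reduceDimensions(sc$scaled, config$varianceTarget)
  model <- fitMixture(red$scores, kRange = config$kRange,
                      seed = stageSeed(seed, 2L), basis = red$basis)
  asg <- assignClusters(model, red$scores)
  sel <- identifyDnm2PositiveCluster(asg$labels, feats)
  if (is.na(sel$cluster))
    stop("no DNM2-positive cluster passed the selection floor; ",
         "per-cluster summaries:\n",
         paste(utils::capture.output(print(sel$summaries)), collapse = "\n"))
  cmeIds <- feats$event_id[asg$labels %in% sel$dnm2Positive]
  cme <- subsetEvents(dataset$events, cmeIds)

  peaks <- selectPeakParameters(cme, config$heightGrid, config$widthGrid,
                                config$distanceGrid)
  fsp <- filterSinglePeak(cme, peaks$params)

  links <- linkThirdChannel(fsp$events, dataset$third,
                            linkRadius = config$linkRadius,
                            minOverlap = config$minOverlap)
  ann <- classifyTiming(fsp$annotations, fsp$events, dataset$third, links,
                        earlyLead = config$earlyLead)
  posFrac <- positiveFraction(ann, seed = stageSeed(seed, 3L))

  cohorts <- cohortAverage(fsp$events, ann, edges = config$cohortEdges,
                           third = dataset$third)
  sepMot <- separationExceedsMotility(fsp$events, ann, dataset$third,
                                      windowFrames = config$motilityWindow)
  pos <- ann$arpc3_class != "negative"
  comparisons <- NULL
  if (sum(pos) >= 2L && sum(!pos) >= 2L) {
    lt <- eventLifetime(ann)
    motB <- lateralMotility(fsp$events, ann, "before",
                            config$motilityWindow)
    comparisons <- data.frame(
      comparison = c("lifetime_pos_vs_neg_welch",
                     "motility_before_pos_vs_neg_ks"),
      statistic = NA_real_, p_value = NA_real_)
    w <- compareGroups(lt[pos], lt[!pos], "welch")
    k <- tryCatch(compareGroups(motB[pos & !is.na(motB)],
                                motB[!pos & !is.na(motB)], "ks"),
                  error = function(e) list(statistic = NA_real_,
                                           p.value = NA_real_))
    comparisons$statistic <- c(w$statistic, k$statistic)
    comparisons$p_value <- c(w$p.value, k$p.value)
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeRunConfig(config, file.path(config$outDir, "config.yaml"))
    writeTracks(dataset$events, file.path(config$outDir, "events.tracks.tsv"),
                pixelSize = config$params$pixelSize)
    writeTracks(dataset$third, file.path(config$outDir, "third.tracks.tsv"),
                pixelSize = config$params$pixelSize)
    .writeTable(dataset$truth, config$outDir, "ground_truth")
    .writeTable(feats, config$outDir, "features")
    .writeTable(data.frame(event_id = feats$event_id,
                           cluster = asg$labels), config$outDir, "clusters")
    .writeTable(sel$summaries, config$outDir, "cluster_summaries")
    .writeTable(peaks$survey, config$outDir, "peak_survey")
    .writeTable(ann, config$outDir, "annotations")
    .writeTable(cohorts$summary, config$outDir, "cohort_traces")
    .writeTable(cohorts$cohorts, config$outDir, "cohort_sizes")
    if (!is.null(comparisons))
      .writeTable(comparisons, config$outDir, "group_comparisons")
  }

  list(dataset = dataset, features = feats, scaler = sc$scaler,
       model = model, labels = asg$labels, posterior = asg$posterior,
       dnm2Cluster = sel$cluster, clusterSummaries = sel$summaries,
       peakParams = peaks$params, peakSurvey = peaks$survey,
       annotations = ann, links = links, positiveFraction = posFrac,
       cohorts = cohorts, separationVsMotility = sepMot,
       comparisons = comparisons, config = config)
}
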