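#' Run configuration for the end-to-end pipeline
#'
#' @param outDir output directory for all artifacts.
#' @param seed master seed; every stage and subject derives its own
#'   sub-seed from it.
#' @param cohort a \code{\link{cohortConfig}} (its seed is overridden by
#'   the master seed).
#' @param preprocessing a \code{\link{preprocessParams}} list.
#' @param sweep list with lo, hi, step for the proportional-threshold
#'   grid.
#' @param nRandom random-reference ensemble size per network.
#' @param classifier a \code{\link{classifierConfig}}.
#' @param inDir optional directory of existing signal CSVs (with
#'   meta.csv) to ingest instead of simulating.
#' @param skip character vector of stage names to skip, among
#'   \code{"stats"} and \code{"classify"}.
#' @return Named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(outDir = "motornet-run", seed = 1L,
                      cohort = cohortConfig(),
                      preprocessing = preprocessParams(),
                      sweep = list(lo = 0.3, hi = 0.7, step = 0.01),
                      nRandom = 100,
                      classifier = classifierConfig(),
                      inDir = NULL, skip = character(0)) {
  structure(list(outDir = outDir, seed = as.integer(seed), cohort = cohort,
                 preprocessing = preprocessing, sweep = sweep,
                 nRandom = nRandom, classifier = classifier,
                 inDir = inDir, skip = skip),
            class = "RunConfig")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Top-level keys mirror the arguments of \code{\link{runConfig}};
#' unspecified values keep their defaults.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return A \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("outDir", "seed", "nRandom", "inDir", "skip"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$cohort)) {
    cc <- raw$cohort
    if (!is.null(cc$group_rewiring)) cc$group_rewiring <-
      unlist(cc$group_rewiring)
    args$cohort <- do.call(cohortConfig, cc)
  }
  if (!is.null(raw$preprocessing))
    args$preprocessing <- do.call(preprocessParams, raw$preprocessing)
  if (!is.null(raw$sweep)) args$sweep <- raw$sweep
  if (!is.null(raw$classifier))
    args$classifier <- do.call(classifierConfig, raw$classifier)
  do.call(runConfig, args)
}

#' Run the full pipeline: simulate, preprocess, connect, metrics, stats,
#' classify
#'
#' Executes every stage in order under the master seed, writes all
#' tabular artifacts (signals, features.csv, per-threshold long table,
#' group report, classification result) under \code{outDir}, and returns
#' a manifest recording seeds and md5 hashes of the written files.
#' Reruns with the same config reproduce identical artifacts. When
#' \code{inDir} is set, existing signal CSVs are ingested instead of
#' simulating.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose print stage progress.
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(seed = config$seed, stages = character(0))
  tryCatch({
    if (is.null(config$inDir)) {
      say("simulate: generating cohort")
      cfg <- config$cohort
      cfg$seed <- deriveSeed(config$seed, 1)
      cohort <- generateCohort(cfg)
      writeCohort(cohort, file.path(out, "signals"))
    } else {
      say("simulate: skipped, ingesting ", config$inDir)
      cohort <- readCohort(config$inDir, fs = config$cohort$fs)
    }
    manifest$stages <- c(manifest$stages, "simulate")
    meta <- cohortMeta(cohort)
    n <- length(cohort)

    stage <- "preprocess"
    say("preprocess: ", n, " subjects")
    clean <- vector("list", n)
    logs <- vector("list", n)
    for (k in seq_len(n)) {
      clean[[k]] <- preprocess(cohort[[k]], config$preprocessing)
      logs[[k]] <- attr(clean[[k]], "preprocessLog")
    }
    names(logs) <- meta$subject_id
    jsonlite::write_json(
      lapply(logs, function(l) l[c("nSegments", "residualFraction",
                                   "fallback", "window")]),
      file.path(out, "preprocess_log.json"), auto_unbox = TRUE,
      digits = NA)
    manifest$stages <- c(manifest$stages, "preprocess")

    stage <- "connect+metrics"
    say("connectivity and metrics: sweep ", config$sweep$lo, "-",
        config$sweep$hi, ", ", config$nRandom, " references")
    profiles <- vector("list", n)
    for (k in seq_len(n)) {
      zm <- connectivityMatrix(clean[[k]])
      nets <- thresholdSweep(zm, config$sweep$lo, config$sweep$hi,
                             config$sweep$step)
      profiles[[k]] <- subjectProfile(nets, nRandom = config$nRandom,
                                      seed = deriveSeed(config$seed, 2, k),
                                      subjectId = meta$subject_id[k])
    }
    se <- featureTable(profiles, meta)
    fx <- t(SummarizedExperiment::assay(se, "auc"))
    write.csv(cbind(subject_id = rownames(fx), as.data.frame(fx)),
              file.path(out, "features.csv"), row.names = FALSE)
    write.csv(S4Vectors::metadata(se)$perThreshold,
              file.path(out, "per_threshold.csv"), row.names = FALSE)
    manifest$stages <- c(manifest$stages, "metrics")

    if (!"stats" %in% config$skip) {
      stage <- "stats"
      say("group statistics")
      report <- runGroupAnalysis(se)
      writeGroupReport(report, file.path(out, "group_report.json"))
      manifest$stages <- c(manifest$stages, "stats")
    }

    result <- NULL
    if (!"classify" %in% config$skip) {
      stage <- "classify"
      say("nested-CV classification")
      ccfg <- config$classifier
      ccfg$seed <- deriveSeed(config$seed, 3)
      result <- nestedCV(fx, meta$group, ccfg)
      jsonlite::write_json(
        list(confusion = result@confusion, accuracy = result@accuracy,
             perClass = result@perClass, ranking = result@ranking),
        file.path(out, "classification.json"), auto_unbox = TRUE,
        digits = NA)
      manifest$stages <- c(manifest$stages, "classify")
    }

    files <- list.files(out, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest$hashes <- as.list(tools::md5sum(files))
    names(manifest$hashes) <- substring(files, nchar(out) + 2)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$features <- se
    manifest$classification <- result
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
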