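#' Run the full gradient pipeline
#'
#' Executes the analysis stages in order: subject connectomes (loaded from
#' a cohort directory or passed in memory), Fisher-z group average,
#' group-level PCA gradients, Procrustes-aligned individual gradients,
#' per-subject segregation metrics, and -- when trait columns are present
#' -- the Spearman association grid with Bonferroni flags. Fails fast with
#' stage-tagged errors; given a fixed config and inputs the outputs are
#' bit-stable.
#'
#' @param config a [RunConfig-class] (validated before any compute).
#' @param inputDir directory in the [writeCohort()] layout; ignored when
#'   \code{cohort} is given.
#' @param cohort in-memory cohort list as from [simulateCohort()], or a
#'   list with elements \code{matrices}, \code{partition} and optionally
#'   \code{participants}.
#' @param outputDir optional directory for TSV/JSON result files.
#' @param peaks include the KDE peak-distance metric.
#' @return list with \code{groupGradients}, \code{gradients} (per subject),
#'   \code{report} ([SegregationReport-class]), \code{grid} (association
#'   table or NULL), and \code{manifest} (seed, config hash, stage
#'   timings, inputs, outputs).
#' @export
runPipeline <- function(config = runConfig(), inputDir = NULL, cohort = NULL,
                        outputDir = NULL, peaks = TRUE) {
  validObject(config)
  timings <- c()
  manifest <- list(seed = config@seed, config_hash = configHash(config),
                   inputs = list(), outputs = character())
  tick <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tick()
    out <- tryCatch(force(expr), error = function(e)
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(tick() - t0, 3)
    out
  }

  loaded <- stage("load", {
    if (is.null(cohort)) {
      if (is.null(inputDir)) stop("supply either inputDir or cohort")
      partition <- readNetworkPartition(file.path(inputDir, "partition.tsv"))
      files <- sort(list.files(file.path(inputDir, "matrices"),
                               pattern = "\\.tsv$", full.names = TRUE))
      if (!length(files)) stop("no matrix files under ", inputDir)
      matrices <- lapply(files, readConnectivityMatrix,
                         expectedParcels = nParcels(partition),
                         parcelIds = parcelIds(partition))
      names(matrices) <- sub("\\.tsv$", "", basename(files))
      ppath <- file.path(inputDir, "participants.csv")
      participants <- if (file.exists(ppath)) readParticipantTable(ppath)
                      else NULL
      list(matrices = matrices, partition = partition,
           participants = participants,
           inputs = as.list(tools::md5sum(c(files, ppath[file.exists(ppath)]))))
    } else {
      cohort
    }
  })
  if (!is.null(loaded$inputs)) manifest$inputs <- loaded$inputs
  matrices <- loaded$matrices
  partition <- loaded$partition
  if (config@nGradients > nParcels(partition))
    stop("[stage: load] nGradients exceeds parcel count")

  groupMatrix <- stage("group_average", groupAverage(matrices))
  groupGradients <- stage("group_gradients",
                          computeGradients(groupMatrix, config))
  gradients <- stage("individual_gradients",
    lapply(matrices, computeGradients, config = config,
           reference = groupGradients))
  report <- stage("segregation_metrics",
    segregationReport(gradients, partition, config, peaks = peaks))

  grid <- NULL
  traits <- loaded$participants
  if (!is.null(traits) &&
      all(c("aq_total", "gsq_total") %in% names(traits))) {
    grid <- stage("association", {
      if (!setequal(traits$subject_id, names(matrices)))
        stop("participant ids do not match matrix files")
      runAssociationGrid(report, traits, alpha = config@alpha)
    })
  }

  manifest$timings <- as.list(timings)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    outs <- character()
    gp <- file.path(outputDir, "group_gradients.tsv")
    writeGradientSet(groupGradients, gp)
    outs <- c(outs, gp, paste0(gp, ".json"))
    rp <- file.path(outputDir, "segregation_report.tsv")
    writeSegregationReport(report, rp)
    outs <- c(outs, rp)
    if (!is.null(grid)) {
      ap <- file.path(outputDir, "association_grid.tsv")
      utils::write.table(grid, ap, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(outs, ap)
    }
    manifest$outputs <- as.list(tools::md5sum(outs))
    jsonlite::write_json(manifest, file.path(outputDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(groupGradients = groupGradients, gradients = gradients,
       report = report, grid = grid, manifest = manifest)
}

# md5 of the serialized config: identifies a parameter set in manifests
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeRunConfig(config, tmp)
  unname(tools::md5sum(tmp))
}
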