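## End-to-end orchestration: simulate/load -> quantify -> compare -> report.

#' Default pipeline configuration
#'
#' @param simulate a [makeCohort()] object, or `NULL` to read masks from
#'   `maskTable`.
#' @param maskTable data.frame with columns `path`, `animal_id`, `group`
#'   (and optionally `image_id`) pointing at palette PNG masks; used when
#'   `simulate` is `NULL`.
#' @param outDir output directory for the report, or `NULL` to skip
#'   writing.
#' @param pixelSize micrometers per pixel.
#' @param minSpurLength spur-pruning threshold (px).
#' @param tTestVariant `"student"` or `"welch"`.
#' @param alpha significance level.
#' @param withChannels quantify fluorescence channels too (simulated
#'   cohorts only).
#' @param seed master seed recorded in the manifest.
#' @return A config list of class `duravascConfig`.
#' @export
pipelineConfig <- function(simulate = NULL, maskTable = NULL, outDir = NULL,
                           pixelSize = 1, minSpurLength = 5,
                           tTestVariant = "student", alpha = 0.05,
                           withChannels = FALSE, seed = 1) {
  if (is.null(simulate) == is.null(maskTable))
    stop("exactly one input source required: simulate or maskTable")
  stopifnot(alpha > 0, alpha < 1)
  structure(list(simulate = simulate, maskTable = maskTable,
                 outDir = outDir, pixelSize = pixelSize,
                 minSpurLength = minSpurLength,
                 tTestVariant = tTestVariant, alpha = alpha,
                 withChannels = withChannels, seed = seed),
            class = "duravascConfig")
}

quantifyScene <- function(scene, config) {
  graph <- maskToGraph(scene$bloodMask,
                       minSpurLength = config$minSpurLength)
  rec <- summarizeImage(graph, scene$bloodMask)
  if (!is.null(scene$lymphMask)) {
    lm <- lymphaticMorphometry(scene$lymphMask,
                               minSpurLength = config$minSpurLength)
    rec$pdpl_vessel_fraction <- unname(lm["area_fraction"])
    rec$lymph_mean_segment_length <- unname(lm["mean_segment_length"])
    rec$lymph_total_length <- unname(lm["total_length"])
  }
  if (!is.null(scene$channels)) {
    lymphFg <- maskGrid(scene$lymphMask) == maskLabels()[["LYMPHATIC"]]
    fq <- quantifyFluorescence(scene$channels, lymphMask = lymphFg)
    for (nm in setdiff(names(fq), c("image_id", "animal_id", "group",
                                    "pdpl_vessel_fraction"))) {
      rec[[nm]] <- fq[[nm]]
    }
  }
  rec
}

#' Run the analysis pipeline
#'
#' For each image: mask (simulated or read from disk) -> skeleton graph
#' -> morphometry record (plus fluorescence record when channels are
#' present) -> per-animal summaries -> two-group comparisons -> report.
#' Per-image failures are quarantined (the row is flagged and the run
#' continues); any quarantine is reported in the result and the manifest
#' so batch runs fail loudly at the end rather than silently dropping
#' images.
#'
#' @param config a [pipelineConfig()].
#' @return List: `perImage`, `perAnimal`, `comparisons`, `manifest`,
#'   `quarantined` (data.frame of failed images), `reportPaths`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "duravascConfig"))
  records <- list()
  quarantined <- data.frame(image_id = character(), error = character(),
                            stringsAsFactors = FALSE)
  if (!is.null(config$simulate)) {
    cohort <- config$simulate
    n <- nrow(cohort$plan)
    for (i in seq_len(n)) {
      rec <- tryCatch({
        scene <- cohortScene(cohort, i,
                             withChannels = isTRUE(config$withChannels))
        quantifyScene(scene, config)
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        quarantined <- rbind(quarantined, data.frame(
          image_id = cohort$plan$image_id[i],
          error = conditionMessage(rec), stringsAsFactors = FALSE))
      } else {
        records[[length(records) + 1L]] <- rec
      }
    }
  } else {
    mt <- config$maskTable
    if (is.null(mt$image_id)) mt$image_id <- basename(mt$path)
    for (i in seq_len(nrow(mt))) {
      rec <- tryCatch({
        mask <- readLabelMask(mt$path[i], pixelSize = config$pixelSize,
                              imageId = mt$image_id[i],
                              animalId = mt$animal_id[i],
                              group = mt$group[i])
        quantifyScene(list(bloodMask = mask, lymphMask = NULL,
                           channels = NULL), config)
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        quarantined <- rbind(quarantined, data.frame(
          image_id = mt$image_id[i], error = conditionMessage(rec),
          stringsAsFactors = FALSE))
      } else {
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  perImage <- if (length(records)) do.call(rbind, records) else NULL
  perAnimal <- NULL
  comparisons <- NULL
  if (!is.null(perImage)) {
    perAnimal <- averagePerAnimal(perImage)
    if (length(unique(perAnimal$group)) == 2L &&
        all(table(perAnimal$group) >= 2L)) {
      comparisons <- compareGroups(perAnimal,
                                   variant = config$tTestVariant,
                                   alpha = config$alpha)
    }
  }
  manifest <- list(
    pixel_size = config$pixelSize,
    unit = if (config$pixelSize == 1) "px" else "um",
    min_spur_length = config$minSpurLength,
    t_test_variant = config$tTestVariant,
    alpha = config$alpha,
    seed = config$seed,
    simulated = !is.null(config$simulate),
    with_channels = isTRUE(config$withChannels),
    n_images = if (is.null(perImage)) 0L else nrow(perImage),
    n_quarantined = nrow(quarantined),
    quarantined = if (nrow(quarantined)) quarantined$image_id else list()
  )
  reportPaths <- NULL
  if (!is.null(config$outDir)) {
    reportPaths <- buildReport(perImage, perAnimal, comparisons, manifest,
                               config$outDir)
  }
  list(perImage = perImage, perAnimal = perAnimal,
       comparisons = comparisons, manifest = manifest,
       quarantined = quarantined, reportPaths = reportPaths)
}

#' Quantify every image of a simulated cohort
#'
#' Streaming wrapper used by tests and the acceptance script: returns the
#' per-image morphometry table for a cohort without writing anything.
#'
#' @param cohort a [makeCohort()] object.
#' @param minSpurLength spur threshold (px), default 5.
#' @param withChannels also quantify fluorescence.
#' @param withLymph include lymphatic morphometry columns (default FALSE;
#'   skipping them saves a second skeletonization per image).
#' @return data.frame of per-image records.
#' @export
quantifyCohort <- function(cohort, minSpurLength = 5, withChannels = FALSE,
                           withLymph = FALSE) {
  stopifnot(inherits(cohort, "duravascCohort"))
  cfg <- list(minSpurLength = minSpurLength)
  rows <- lapply(seq_len(nrow(cohort$plan)), function(i) {
    scene <- cohortScene(cohort, i, withChannels = withChannels)
    if (!withLymph && !withChannels) scene$lymphMask <- NULL
    quantifyScene(scene, cfg)
  })
  do.call(rbind, rows)
}
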