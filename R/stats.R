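## Per-animal aggregation, two-group comparison, densitometry, reporting.
##
## The experimental unit is the animal: per-image records are averaged per
## animal first, and animal-level means enter the unpaired t-test, so the
## degrees of freedom reflect animal counts, not image counts.

#' Average per-image records per animal
#'
#' One summary row per animal: the arithmetic mean over that animal's
#' images for every numeric metric column. Missing per-image values (for
#' example zero complete venular segments) are dropped from that animal's
#' mean, with the exclusion counts recorded in the `exclusions` attribute.
#' An animal assigned to two groups is an error.
#'
#' @param records data.frame of per-image records with `animal_id` and
#'   `group` columns plus numeric metric columns.
#' @param metrics character vector of metric columns; default all numeric
#'   columns except identifiers.
#' @return data.frame with `animal_id`, `group`, `n_images` and one mean
#'   column per metric; attribute `exclusions` counts dropped NAs.
#' @export
#' @examples
#' df <- data.frame(animal_id = c("a", "a"), group = "CONTROL",
#'                  image_id = c("i1", "i2"), total_length = c(2, 4))
#' averagePerAnimal(df)$total_length   # 3
averagePerAnimal <- function(records, metrics = NULL) {
  stopifnot(all(c("animal_id", "group") %in% names(records)))
  gmap <- unique(records[, c("animal_id", "group")])
  if (anyDuplicated(gmap$animal_id))
    stop(sprintf("animal(s) assigned to more than one group: %s",
                 paste(unique(gmap$animal_id[duplicated(gmap$animal_id)]),
                       collapse = ", ")))
  if (is.null(metrics)) {
    metrics <- names(records)[vapply(records, is.numeric, TRUE)]
    metrics <- setdiff(metrics, c("pixel_size"))
  }
  animals <- gmap$animal_id
  out <- data.frame(animal_id = animals,
                    group = gmap$group,
                    n_images = vapply(animals, function(a)
                      sum(records$animal_id == a), 0L),
                    stringsAsFactors = FALSE)
  excl <- setNames(integer(length(metrics)), metrics)
  for (m in metrics) {
    v <- vapply(animals, function(a) {
      x <- records[[m]][records$animal_id == a]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, 0)
    excl[m] <- sum(is.na(records[[m]]))
    out[[m]] <- unname(v)
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Unpaired two-sample t-test
#'
#' Two-sided unpaired t-test between two groups of (animal-level) values.
#' The default is the classical Student test with pooled variance (the
#' usual meaning of "unpaired t-test" in common analysis software);
#' Welch's unequal-variance variant is available. Degenerate zero-variance
#' inputs are handled by convention: equal means give `t = 0, p = 1`;
#' unequal means with zero pooled variance are flagged degenerate with
#' `p = NA`.
#'
#' @param valuesA,valuesB numeric vectors, each with at least 2 finite
#'   values.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @param groupNames length-2 character, labels for A and B.
#' @param metric optional metric name carried into the output.
#' @return One-row data.frame: `metric`, means, SEMs and n per group,
#'   `t_statistic`, `df`, `p_value`, `significant`, `degenerate`.
#' @export
#' @examples
#' unpairedTTest(c(1, 2, 3), c(2, 3, 4))   # t = -1.2247, p ~ 0.2879
unpairedTTest <- function(valuesA, valuesB, variant = c("student", "welch"),
                          alpha = 0.05, groupNames = c("A", "B"),
                          metric = NA_character_) {
  variant <- match.arg(variant)
  a <- valuesA[is.finite(valuesA)]
  b <- valuesB[is.finite(valuesB)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite values")
  sem <- function(x) sd(x) / sqrt(length(x))
  base <- data.frame(
    metric = metric,
    group_a = groupNames[1L], mean_a = mean(a), sem_a = sem(a),
    n_a = length(a),
    group_b = groupNames[2L], mean_b = mean(b), sem_b = sem(b),
    n_b = length(b), stringsAsFactors = FALSE)
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    base$t_statistic <- if (eq) 0 else NA_real_
    base$df <- length(a) + length(b) - 2L
    base$p_value <- if (eq) 1 else NA_real_
    base$significant <- if (eq) FALSE else NA
    base$degenerate <- !eq
    return(base)
  }
  tt <- t.test(a, b, var.equal = (variant == "student"),
               alternative = "two.sided")
  base$t_statistic <- unname(tt$statistic)
  base$df <- unname(tt$parameter)
  base$p_value <- tt$p.value
  base$significant <- tt$p.value < alpha
  base$degenerate <- FALSE
  base
}

#' Compare two groups metric by metric
#'
#' Runs [unpairedTTest()] on animal-level means for each metric; no
#' multiple-testing correction is applied (the number of tests run is
#' recorded so users can apply their own).
#'
#' @param perAnimal data.frame from [averagePerAnimal()].
#' @param metrics metric columns to test; default all numeric columns
#'   except `n_images`.
#' @param groups length-2 character: the two group labels, order A then B.
#' @inheritParams unpairedTTest
#' @return data.frame with one row per metric; attribute `n_tests`.
#' @export
compareGroups <- function(perAnimal, metrics = NULL, groups = NULL,
                          variant = c("student", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  if (is.null(groups)) groups <- unique(perAnimal$group)
  if (length(groups) != 2L)
    stop(sprintf("need exactly 2 groups, have: %s",
                 paste(groups, collapse = ", ")))
  if (is.null(metrics)) {
    metrics <- names(perAnimal)[vapply(perAnimal, is.numeric, TRUE)]
    metrics <- setdiff(metrics, "n_images")
  }
  rows <- lapply(metrics, function(m) {
    a <- perAnimal[[m]][perAnimal$group == groups[1L]]
    b <- perAnimal[[m]][perAnimal$group == groups[2L]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(metric = m, group_a = groups[1L],
                        mean_a = if (length(a)) mean(a) else NA_real_,
                        sem_a = NA_real_, n_a = length(a),
                        group_b = groups[2L],
                        mean_b = if (length(b)) mean(b) else NA_real_,
                        sem_b = NA_real_, n_b = length(b),
                        t_statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, significant = NA,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    unpairedTTest(a, b, variant = variant, alpha = alpha,
                  groupNames = groups, metric = m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  out
}

#' Densitometry normalization ratio
#'
#' Normalized expression of a Western-blot target band relative to its
#' loading-control band (for example TGF-beta1 over beta-actin): the
#' plain intensity ratio, invariant to any common gain.
#'
#' @param target,loading positive band intensities (vectorized).
#' @return `target / loading`.
#' @export
#' @examples
#' densitometryRatio(2000, 1000)   # 2
densitometryRatio <- function(target, loading) {
  if (any(!is.finite(target)) || any(!is.finite(loading)) ||
      any(target <= 0) || any(loading <= 0))
    stop("band intensities must be positive and finite")
  target / loading
}

#' Densitometry table
#'
#' @param sampleId,group identifiers (vectorized).
#' @param targetIntensity,loadingIntensity positive band intensities.
#' @return data.frame with `normalized_expression = target / loading`.
#' @export
densitometryTable <- function(sampleId, group, targetIntensity,
                              loadingIntensity) {
  data.frame(sample_id = sampleId, group = group,
             target_band_intensity = targetIntensity,
             loading_band_intensity = loadingIntensity,
             normalized_expression = densitometryRatio(targetIntensity,
                                                       loadingIntensity),
             stringsAsFactors = FALSE)
}

#' Write the run report
#'
#' Writes the per-image, per-animal and per-comparison CSV tables and a
#' JSON run manifest holding every tunable parameter that affects output
#' numbers (pixel size, spur threshold, segmentation settings, t-test
#' variant, alpha, seed, software version, units, number of tests).
#' Deterministic: regeneration from the same inputs is byte-identical
#' (no timestamps unless supplied in the manifest).
#'
#' @param perImage,perAnimal,comparisons data.frames (any may be `NULL`).
#' @param manifest named list of run parameters.
#' @param outDir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
buildReport <- function(perImage, perAnimal, comparisons, manifest, outDir) {
  if (is.null(manifest$package_version))
    manifest$package_version <- as.character(packageVersion("duravasc"))
  if (!is.null(comparisons))
    manifest$n_tests <- sum(!is.na(comparisons$p_value))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(outDir, name)
    write.csv(df, p, row.names = FALSE)
    p
  }
  if (!is.null(perImage)) paths["per_image"] <- wr(perImage, "per_image.csv")
  if (!is.null(perAnimal)) paths["per_animal"] <- wr(perAnimal, "per_animal.csv")
  if (!is.null(comparisons))
    paths["comparisons"] <- wr(comparisons, "comparisons.csv")
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths["manifest"] <- mp
  invisible(paths)
}
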