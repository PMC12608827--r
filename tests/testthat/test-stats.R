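# Per-animal aggregation, unpaired t-test, densitometry, reporting.

test_that("per-animal averaging takes arithmetic means over images", {
  df <- data.frame(animal_id = c("a", "a", "b"),
                   group = c("CONTROL", "CONTROL", "OVX"),
                   total_length = c(2, 4, 10))
  pa <- averagePerAnimal(df)
  expect_equal(pa$total_length[pa$animal_id == "a"], 3)
  expect_equal(pa$total_length[pa$animal_id == "b"], 10)  # single image
  expect_equal(pa$n_images, c(2L, 1L))

  # an animal in two groups is an error
  bad <- data.frame(animal_id = c("a", "a"), group = c("CONTROL", "OVX"),
                    x = 1:2)
  expect_error(averagePerAnimal(bad), "more than one group")

  # missing values are dropped with a recorded count
  dfna <- data.frame(animal_id = c("a", "a", "a"), group = "CONTROL",
                     tort = c(1.2, NA, 1.4))
  pa2 <- averagePerAnimal(dfna)
  expect_equal(pa2$tort, 1.3)
  expect_equal(unname(attr(pa2, "exclusions")["tort"]), 1L)

  # brute-force group-by oracle on a random cohort
  set.seed(8)
  rc <- data.frame(animal_id = sample(letters[1:6], 60, replace = TRUE),
                   metric = rnorm(60))
  rc$group <- ifelse(rc$animal_id %in% letters[1:3], "CONTROL", "OVX")
  pa3 <- averagePerAnimal(rc)
  for (a in unique(rc$animal_id)) {
    expect_equal(pa3$metric[pa3$animal_id == a],
                 mean(rc$metric[rc$animal_id == a]))
  }
})

test_that("the unpaired Student t-test matches the pooled-variance formula", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- unpairedTTest(a, b)
  # hand oracle: pooled variance formula
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pHand <- 2 * pt(-abs(tHand), length(a) + length(b) - 2)
  expect_equal(res$t_statistic, tHand)
  expect_equal(res$t_statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, pHand)
  expect_equal(res$p_value, 0.2878641, tolerance = 1e-6)
  expect_false(res$significant)

  # identical groups: t = 0, p = 1
  res0 <- unpairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)

  # degenerate zero variance
  eq <- unpairedTTest(c(2, 2), c(2, 2))
  expect_equal(eq$p_value, 1); expect_false(eq$degenerate)
  ne <- unpairedTTest(c(2, 2), c(3, 3))
  expect_true(ne$degenerate); expect_true(is.na(ne$p_value))

  expect_error(unpairedTTest(1, c(1, 2)), "at least 2")
})

test_that("the test is symmetric and affine invariant", {
  set.seed(9)
  for (rep in 1:10) {
    a <- rnorm(5); b <- rnorm(6, 0.5)
    r1 <- unpairedTTest(a, b)
    r2 <- unpairedTTest(b, a)
    expect_equal(r2$t_statistic, -r1$t_statistic)
    expect_equal(r2$p_value, r1$p_value)
    g <- runif(1, 0.5, 3); o <- runif(1, -5, 5)
    r3 <- unpairedTTest(g * a + o, g * b + o)
    expect_equal(r3$p_value, r1$p_value)
    expect_equal(r3$t_statistic, r1$t_statistic)
    # Welch differs from Student in df when variances differ
    rw <- unpairedTTest(a, 3 * b, variant = "welch")
    expect_lt(rw$df, length(a) + length(b) - 2)
  }
})

test_that("null calibration: rejection rate near alpha under the null", {
  set.seed(1234)
  nrep <- 10000
  rej <- 0L
  for (i in seq_len(nrep)) {
    a <- rnorm(5); b <- rnorm(5)
    rej <- rej + (unpairedTTest(a, b)$p_value < 0.05)
  }
  expect_gte(rej / nrep, 0.040)
  expect_lte(rej / nrep, 0.060)
})

test_that("group comparison uses animal-level degrees of freedom", {
  set.seed(10)
  df <- data.frame(
    animal_id = rep(sprintf("a%d", 1:9), each = 10),
    group = rep(c("CONTROL", "OVX"), c(40, 50)),
    total_length = rnorm(90, 1000, 100))
  pa <- averagePerAnimal(df)
  cm <- compareGroups(pa, metrics = "total_length")
  expect_equal(cm$df, 4 + 5 - 2)     # animals, not the 90 images
  expect_equal(cm$n_a, 4); expect_equal(cm$n_b, 5)
  expect_equal(attr(cm, "n_tests"), 1L)
})

test_that("densitometry normalization is the target over loading ratio", {
  expect_equal(densitometryRatio(2000, 1000), 2)
  expect_equal(densitometryRatio(750, 750), 1)
  t0 <- 1234; l0 <- 567; g <- 3.3
  expect_equal(densitometryRatio(g * t0, g * l0), t0 / l0)
  expect_error(densitometryRatio(-1, 5), "positive")
  expect_error(densitometryRatio(5, 0), "positive")
  tab <- densitometryTable(c("s1", "s2"), c("SHAM", "OVX"),
                           c(1500, 2400), c(1000, 1200))
  expect_equal(tab$normalized_expression, c(1.5, 2))
})

test_that("reports regenerate byte-identically and recompute consistently", {
  set.seed(11)
  df <- data.frame(
    image_id = sprintf("i%02d", 1:40),
    animal_id = rep(sprintf("a%d", 1:8), each = 5),
    group = rep(c("CONTROL", "OVX"), each = 20),
    total_length = rnorm(40, 900, 80),
    mean_tortuosity = rnorm(40, 1.06, 0.01))
  pa <- averagePerAnimal(df)
  cm <- compareGroups(pa)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  manifest <- list(seed = 1, min_spur_length = 5, unit = "px")
  buildReport(df, pa, cm, manifest, d1)
  buildReport(df, pa, cm, manifest, d2)
  for (f in c("per_image.csv", "per_animal.csv", "comparisons.csv",
              "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # every comparison number recomputes from the per-animal table
  paBack <- read.csv(file.path(d1, "per_animal.csv"))
  cmBack <- read.csv(file.path(d1, "comparisons.csv"))
  for (i in seq_len(nrow(cmBack))) {
    m <- cmBack$metric[i]
    a <- paBack[[m]][paBack$group == cmBack$group_a[i]]
    b <- paBack[[m]][paBack$group == cmBack$group_b[i]]
    re <- unpairedTTest(a, b)
    expect_equal(cmBack$t_statistic[i], re$t_statistic, tolerance = 1e-6)
    expect_equal(cmBack$p_value[i], re$p_value, tolerance = 1e-6)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
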