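smallConfig <- function(seed, ...)
  cohortConfig(seed = seed, nNodes = 40, ...)

test_that("the default parcellation has 225 uniquely labelled nodes", {
  labels <- defaultNodeLabels()
  expect_length(labels, 225)
  expect_false(anyDuplicated(labels) > 0)
  expect_true(all(defaultRoiTable()$atlas_label %in% labels))
  expect_length(nodeModules(225, 8), 225)
  expect_equal(sort(unique(nodeModules(225, 8))), 1:8)
})

test_that("base connectome generation is seed-deterministic", {
  cfg <- smallConfig(99)
  b1 <- generateBaseConnectome(cfg)
  b2 <- generateBaseConnectome(cfg)
  expect_identical(b1@weights, b2@weights)
  b3 <- generateBaseConnectome(smallConfig(100))
  expect_false(identical(b1@weights, b3@weights))
  expect_s4_class(b1, "WeightedConnectome")  # validity: symmetric, >= 0
})

test_that("default thresholding of a generated connectome hits 20% density", {
  cfg <- cohortConfig(seed = 5, nNodes = 120)
  g <- binarize(thresholdProportional(generateBaseConnectome(cfg), 0.2))
  n <- nNodes(g)
  expect_lt(abs(edgeDensity(g) - 0.2), 1 / (n * (n - 1) / 2) + 1e-12)
})

test_that("subject tables mirror the study design", {
  cfg <- cohortConfig(seed = 7)
  s <- generateSubjects(cfg)
  expect_equal(nrow(s), 34)
  expect_equal(sum(s$group == "control"), 15)
  expect_equal(sum(s$group == "PD"), 19)
  ctrl <- s[s$group == "control", ]
  pd <- s[s$group == "PD", ]
  expect_true(all(ctrl$braak_asyn <= 2))
  expect_true(all(pd$braak_asyn >= 3))
  expect_equal(unname(table(factor(ctrl$braak_asyn, 0:2))), c(13L, 1L, 1L),
               ignore_attr = TRUE)
  expect_true(all(s$age_at_death >= 50 & s$age_at_death <= 100))
  expect_true(all(s$postmortem_delay >= 3.5 & s$postmortem_delay <= 11))
  expect_true(all(is.na(ctrl$disease_duration)))
  expect_true(all(pd$disease_duration >= 8 & pd$disease_duration <= 23))
  expect_equal(sum(!is.na(pd$cdr)), 11)
  expect_true(all(is.na(pd$cdr) | pd$cdr %in% c(0.5, 1, 2, 3)))
})

test_that("reliance scaling conserves total edge weight and is braak-monotone", {
  cfg <- smallConfig(13)
  base <- generateBaseConnectome(cfg)
  s <- generateSubjects(cfg)
  pdRow <- s[s$group == "PD", ][1, ]
  sc <- generateSubjectConnectome(base, pdRow, cfg, 777)
  # conservation: total weight equals total of base x noise (reconstructed
  # by replaying the same noise draws with the reliance effect off)
  cfg0 <- smallConfig(13, relianceKappa = 0, relianceNoiseSd = 0)
  sc0 <- generateSubjectConnectome(base, pdRow, cfg0, 777)
  expect_equal(sum(sc@weights), sum(sc0@weights),
               tolerance = 1e-6 / sum(sc0@weights))
  # same seed, higher braak -> relatively heavier insula edges
  insula <- match("R_dAI", base@labels)
  low <- pdRow; low$braak_asyn <- 3
  high <- pdRow; high$braak_asyn <- 6
  scLow <- generateSubjectConnectome(base, low, cfg, 777)
  scHigh <- generateSubjectConnectome(base, high, cfg, 777)
  expect_gt(sum(scHigh@weights[insula, ]) / sum(scHigh@weights),
            sum(scLow@weights[insula, ]) / sum(scLow@weights))
})

test_that("with the reliance effect off, case and control connectomes are exchangeable", {
  cfg <- smallConfig(17, relianceKappa = 0)
  base <- generateBaseConnectome(cfg)
  s <- generateSubjects(cfg)
  ctrlRow <- s[s$group == "control", ][1, ]
  pdRow <- s[s$group == "PD", ][1, ]
  # identical seeds give identical matrices regardless of group/stage
  expect_identical(generateSubjectConnectome(base, ctrlRow, cfg, 5)@weights,
                   generateSubjectConnectome(base, pdRow, cfg, 5)@weights)
})

test_that("with the default effect, case insula dGE is lower than control", {
  set.seed(71)
  cfg <- smallConfig(19)
  base <- generateBaseConnectome(cfg)
  rois <- resolveRois(base@labels)
  dge <- function(row, seed) {
    g <- binarize(thresholdProportional(
      generateSubjectConnectome(base, row, cfg, seed), 0.2))
    deltaGlobalEfficiency(g, unname(nodeIndices(rois)["dorsal_anterior_insula"]))
  }
  tpl <- generateSubjects(cfg)[1, ]
  ctrl <- pd <- tpl
  ctrl$braak_asyn <- 0; pd$braak_asyn <- 6
  ctrl$group <- "control"; pd$group <- "PD"
  dCtrl <- vapply(1:100, function(i) dge(ctrl, i), numeric(1))
  dPd <- vapply(101:200, function(i) dge(pd, i), numeric(1))
  expect_lt(mean(dPd), mean(dCtrl))
})

test_that("pathology tables respect the stage rules and bounds", {
  cfg <- cohortConfig(seed = 23)
  s <- generateSubjects(cfg)
  ctrlRow <- s[s$group == "control" & s$braak_asyn == 0, ][1, ]
  pdRow <- s[s$braak_asyn == 6, ][1, ]
  pc <- generatePathology(ctrlRow, cfg, 1)
  expect_equal(nrow(pc), 8)
  expect_true(all(pc$lb_density == 0))
  draws <- do.call(rbind, lapply(1:125, function(i)
    generatePathology(pdRow, cfg, i)))
  expect_true(all(draws$lb_density >= 0 & draws$lb_density <= 80))
  expect_true(all(draws$abeta_load >= 0 & draws$abeta_load <= 100))
  expect_true(all(draws$nfl_load >= 0 & draws$nfl_load <= 100))
  expect_true(all(draws$syn_density >= 0))
})

test_that("the parahippocampal NfL case/control ratio matches the configured +48%", {
  cfg <- cohortConfig(seed = 29)
  s <- generateSubjects(cfg)
  ctrlRow <- s[s$group == "control", ][1, ]
  pdRow <- s[s$group == "PD", ][1, ]
  nflPhg <- function(row, seeds) vapply(seeds, function(i) {
    p <- generatePathology(row, cfg, i)
    p$nfl_load[p$roi == "parahippocampal_gyrus"]
  }, numeric(1))
  ratio <- mean(nflPhg(pdRow, 1:250)) / mean(nflPhg(ctrlRow, 251:500))
  expect_gte(ratio, 1.38)
  expect_lte(ratio, 1.58)
})

test_that("cohort writing is byte-identical on replay and validates sizes", {
  cfg <- smallConfig(31, nControl = 4, nPd = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateCohort(cfg, d1)
  generateCohort(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_length(list.files(file.path(d1, "connectomes")), 9)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  back <- readCohort(d1)
  expect_equal(nrow(back$subjects), 9)
  expect_equal(back$config$seed, 31L)
  expect_identical(back$connectomes[[1]]@weights,
                   simulateCohort(cfg)$connectomes[[1]]@weights)
  expect_error(cohortConfig(seed = 1, nPd = 0), "non-empty")
  expect_error(cohortConfig(nControl = 3), "seed")
})

test_that("adding subjects never perturbs existing subjects' draws", {
  cfg1 <- smallConfig(37, nControl = 4, nPd = 4)
  cfg2 <- smallConfig(37, nControl = 4, nPd = 6)
  c1 <- simulateCohort(cfg1)
  c2 <- simulateCohort(cfg2)
  for (id in names(c1$connectomes)[1:4])   # shared control subjects
    expect_identical(c1$connectomes[[id]]@weights,
                     c2$connectomes[[id]]@weights)
})
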