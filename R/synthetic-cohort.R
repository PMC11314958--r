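# Seeded generator of a synthetic postmortem case-control study:
# connectomes, demographics, staging, regional pathology. The generator
# targets the statistical structure the downstream analysis assumes
# (symmetric positive weights, modular geometric topology, a stage-coupled
# insula-reliance effect, stage-coupled pathology), not tractography
# physics.

# deterministic child seeds: adding a subject never perturbs the draws of
# other subjects because every unit consumes its own stream
.childSeed <- function(seed, k) {
  as.integer(((as.double(seed) %% 46340) * 46327 + k + 13) %% 2147483629)
}

.rtrunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

# short ROI keys used in metric column names, in default-table order
.roiKeys <- c(sfg = "superior_frontal_gyrus",
              acg = "anterior_cingulate_gyrus",
              pcg = "posterior_cingulate_gyrus",
              dai = "dorsal_anterior_insula",
              mtg = "middle_temporal_gyrus",
              ent = "entorhinal_cortex",
              phg = "parahippocampal_gyrus",
              fug = "fusiform_gyrus")

# regional Lewy-body vulnerability weights (limbic/insular cortex first)
.lbVulnerability <- c(superior_frontal_gyrus = 0.5,
                      anterior_cingulate_gyrus = 0.8,
                      posterior_cingulate_gyrus = 0.4,
                      dorsal_anterior_insula = 0.9,
                      middle_temporal_gyrus = 0.6,
                      entorhinal_cortex = 1.0,
                      parahippocampal_gyrus = 0.9,
                      fusiform_gyrus = 0.7)

#' Module assignment of the synthetic parcellation
#'
#' Contiguous, near-equal blocks of node indices, one block per module.
#'
#' @param nNodes number of nodes
#' @param moduleCount number of modules
#' @return integer vector of module ids, length nNodes
#' @export
nodeModules <- function(nNodes = 225, moduleCount = 8) {
  bounds <- round(seq(0, nNodes, length.out = moduleCount + 1))
  rep(seq_len(moduleCount), times = diff(bounds))
}

#' Default node-label table of the synthetic parcellation
#'
#' 225 region labels emulating a whole-brain grey-matter parcellation. The
#' atlas labels of the 8 analysis ROIs (see [defaultRoiTable()]) are placed
#' at the first node of each of the 8 modules; the remaining nodes get
#' generic per-module labels.
#'
#' @param nNodes number of nodes (default 225)
#' @param moduleCount number of modules (default 8)
#' @return character vector of nNodes unique labels
#' @export
defaultNodeLabels <- function(nNodes = 225, moduleCount = 8) {
  mod <- nodeModules(nNodes, moduleCount)
  labels <- sprintf("R_M%d_N%03d", mod, seq_len(nNodes))
  roi <- defaultRoiTable()
  nRoi <- min(nrow(roi), moduleCount)
  for (j in seq_len(nRoi)) labels[match(j, mod)] <- roi$atlas_label[j]
  labels
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles and validates all generator parameters. The defaults mirror the
#' study design the analysis targets: 15 control and 19 case donors,
#' 225-node connectomes, a Braak-stage-scaled reliance of the network on the
#' dorsal anterior insula node, and stage-coupled regional pathology with a
#' +48\% neurofilament contrast in the parahippocampal gyrus of cases.
#'
#' @param seed mandatory integer seed; all randomness derives from it
#'   through deterministic per-unit child seeds.
#' @param nControl,nPd group sizes (defaults 15 and 19).
#' @param nNodes,moduleCount connectome size and module count (225, 8).
#' @param lambda exponential distance-decay length of expected edge weight
#'   (unit-cube coordinates).
#' @param withinModuleBonus multiplicative within-module weight bonus.
#' @param edgeNoiseSd log-normal sd of the base connectome edge noise.
#' @param subjectNoiseSd log-normal sd of the per-subject edge noise.
#' @param relianceKappa strength of the insula-reliance effect at Braak
#'   stage 6 (edges incident to the insula node are scaled by
#'   1 + relianceKappa * braak/6 before mass-conserving renormalization).
#' @param relianceNoiseSd sd of the per-subject additive noise on the
#'   reliance factor.
#' @param insulaRoi roi_name of the reliance target region.
#' @param pathologyEffects logical; FALSE turns off every group/stage
#'   dependence of the pathology tables (null configuration).
#' @param lbScale mean LB density (count/mm^2) at vulnerability 1 and Braak
#'   stage 6.
#' @param nflEffect fractional neurofilament increase in cases in the
#'   parahippocampal gyrus (default 0.48).
#' @param nflBase,abetaBase,ptauBase,synBase baseline marker means
#'   (\% area for NfL/Abeta/p-tau, puncta/um^3 for synaptophysin).
#' @return a validated list of class "CohortConfig"
#' @export
cohortConfig <- function(seed,
                         nControl = 15, nPd = 19,
                         nNodes = 225, moduleCount = 8,
                         lambda = 0.30, withinModuleBonus = 1.5,
                         edgeNoiseSd = 0.40, subjectNoiseSd = 0.30,
                         relianceKappa = 0.55, relianceNoiseSd = 0.05,
                         insulaRoi = "dorsal_anterior_insula",
                         pathologyEffects = TRUE,
                         lbScale = 40, nflEffect = 0.48,
                         nflBase = 5, abetaBase = 4, ptauBase = 2,
                         synBase = 0.5) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("an integer seed is mandatory")
  cfg <- list(seed = as.integer(seed), nControl = as.integer(nControl),
              nPd = as.integer(nPd), nNodes = as.integer(nNodes),
              moduleCount = as.integer(moduleCount), lambda = lambda,
              withinModuleBonus = withinModuleBonus,
              edgeNoiseSd = edgeNoiseSd, subjectNoiseSd = subjectNoiseSd,
              relianceKappa = relianceKappa,
              relianceNoiseSd = relianceNoiseSd, insulaRoi = insulaRoi,
              pathologyEffects = isTRUE(pathologyEffects),
              lbScale = lbScale, nflEffect = nflEffect, nflBase = nflBase,
              abetaBase = abetaBase, ptauBase = ptauBase, synBase = synBase)
  if (cfg$nControl < 1 || cfg$nPd < 1)
    stop("both groups must be non-empty (group sizes must allow comparison)")
  if (cfg$nNodes < 3) stop("nNodes must be >= 3")
  if (cfg$moduleCount < 1 || cfg$moduleCount > cfg$nNodes)
    stop("invalid moduleCount")
  if (cfg$lambda <= 0 || cfg$edgeNoiseSd < 0 || cfg$subjectNoiseSd < 0 ||
      cfg$relianceNoiseSd < 0)
    stop("scale parameters must be positive")
  if (!cfg$insulaRoi %in% defaultRoiTable()$roi_name)
    stop("unknown reliance target ROI: ", cfg$insulaRoi)
  class(cfg) <- "CohortConfig"
  cfg
}

#' Generate the group-level base connectome
#'
#' Modular geometric model: nodes are placed in the unit cube around
#' module centres, and the expected weight of edge (i, j) is
#' exp(-dist_ij / lambda) * (1 + withinModuleBonus * same-module), with
#' log-normal multiplicative edge noise. Deterministic given the seed.
#'
#' @param config a [cohortConfig()]
#' @return a [WeightedConnectome-class] with the default node labels
#' @export
generateBaseConnectome <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(.childSeed(config$seed, 0))
  n <- config$nNodes
  mod <- nodeModules(n, config$moduleCount)
  centers <- matrix(stats::runif(config$moduleCount * 3), ncol = 3)
  pos <- centers[mod, , drop = FALSE] +
    matrix(stats::rnorm(n * 3, sd = 0.12), ncol = 3)
  d <- as.matrix(stats::dist(pos))
  same <- outer(mod, mod, "==")
  w <- exp(-d / config$lambda) * (1 + config$withinModuleBonus * same)
  noise <- matrix(0, n, n)
  up <- upper.tri(noise)
  noise[up] <- stats::rnorm(sum(up), sd = config$edgeNoiseSd)
  noise <- noise + t(noise)
  w <- w * exp(noise) * 1000   # streamline-count-like magnitude
  diag(w) <- 0
  WeightedConnectome((w + t(w)) / 2,
                     defaultNodeLabels(n, config$moduleCount))
}

#' Generate one subject's connectome from the base connectome
#'
#' Applies per-subject log-normal edge noise, then scales every edge
#' incident to the insula node by the reliance factor
#' rho = 1 + relianceKappa * braak_asyn/6 + noise and renormalizes the whole
#' matrix so total edge weight is conserved. Higher Braak stage therefore
#' concentrates connection mass on the insula node without changing total
#' mass: after proportional thresholding the network relies more on that
#' node and its removal costs more global efficiency (a more negative dGE),
#' monotonically in stage.
#'
#' @param base the [generateBaseConnectome()] output
#' @param subject one row of the [generateSubjects()] table
#' @param config a [cohortConfig()]
#' @param seed integer seed for this subject's draws
#' @return a [WeightedConnectome-class]
#' @export
generateSubjectConnectome <- function(base, subject, config, seed) {
  stopifnot(is(base, "WeightedConnectome"), inherits(config, "CohortConfig"))
  set.seed(seed)
  w <- base@weights
  n <- nrow(w)
  noise <- matrix(0, n, n)
  up <- upper.tri(noise)
  noise[up] <- stats::rnorm(sum(up), sd = config$subjectNoiseSd)
  noise <- noise + t(noise)
  w <- w * exp(noise)
  target <- defaultRoiTable()
  hit <- target$atlas_label[target$roi_name == config$insulaRoi]
  if (length(hit) != 1) stop("unknown reliance target ROI: ", config$insulaRoi)
  node <- match(hit, base@labels)
  if (is.na(node)) stop("reliance target label absent from base connectome")
  total <- sum(w)
  rho <- 1 + config$relianceKappa * subject$braak_asyn / 6 +
    stats::rnorm(1, sd = config$relianceNoiseSd)
  rho <- max(rho, 0.05)
  w[node, ] <- w[node, ] * rho
  w[, node] <- w[, node] * rho
  w[node, node] <- 0
  w <- w * (total / sum(w))
  WeightedConnectome(w, base@labels)
}

#' Generate the subject metadata table
#'
#' Demographics, covariates and staging for nControl + nPd donors, drawn to
#' mirror the target study design: control Braak alpha-synuclein stages
#' 13/1/1 over 0/1/2 and case stages 1/2/8/8 over 3/4/5/6 (at the default
#' group sizes; sampled with the same proportions otherwise), ages
#' N(73, 9) / N(81, 7) truncated to [50, 100], postmortem delay in
#' [5, 11] / [3.5, 10.5] hours, disease duration in [8, 23] years, and CDR
#' observed for 11 of 19 cases.
#'
#' @param config a [cohortConfig()]
#' @return data.frame with columns subject_id, group, age_at_death, sex,
#'   postmortem_delay, disease_duration, cdr, braak_asyn, braak_nft, thal
#' @export
generateSubjects <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(.childSeed(config$seed, 1))
  nc <- config$nControl
  np <- config$nPd
  drawCounts <- function(n, values, counts) {
    if (n == sum(counts)) sample(rep(values, counts))
    else sample(values, n, replace = TRUE, prob = counts / sum(counts))
  }
  braakC <- drawCounts(nc, 0:2, c(13, 1, 1))
  braakP <- drawCounts(np, 3:6, c(1, 2, 8, 8))
  nftC <- drawCounts(nc, 0:3, c(3, 7, 4, 1))
  nftP <- drawCounts(np, 1:4, c(2, 10, 4, 3))
  thalC <- drawCounts(nc, 0:4, c(2, 8, 3, 1, 1))
  thalP <- drawCounts(np, 0:4, c(1, 6, 4, 6, 2))
  sexC <- drawCounts(nc, c("M", "F"), c(7, 8))
  sexP <- drawCounts(np, c("M", "F"), c(12, 7))
  cdr <- rep(NA_real_, np)
  nObs <- round(np * 11 / 19)
  obs <- sample(seq_len(np), nObs)
  cdr[obs] <- drawCounts(nObs, c(0.5, 1, 2, 3), c(5, 2, 2, 2))
  data.frame(
    subject_id = sprintf("sub%03d", seq_len(nc + np)),
    group = rep(c("control", "PD"), c(nc, np)),
    age_at_death = c(.rtrunc(nc, 73, 9, 50, 100),
                     .rtrunc(np, 81, 7, 50, 100)),
    sex = c(sexC, sexP),
    postmortem_delay = c(stats::runif(nc, 5, 11),
                         stats::runif(np, 3.5, 10.5)),
    disease_duration = c(rep(NA_real_, nc), .rtrunc(np, 16, 4, 8, 23)),
    cdr = c(rep(NA_real_, nc), cdr),
    braak_asyn = c(braakC, braakP),
    braak_nft = c(nftC, nftP),
    thal = c(thalC, thalP),
    stringsAsFactors = FALSE)
}

#' Generate one subject's regional pathology rows
#'
#' Five markers for each of the 8 analysis ROIs. LB density is
#' Gamma-distributed with mean proportional to regional vulnerability and
#' Braak alpha-synuclein stage, zero at stages <= 2, and clipped to
#' [0, 80] count/mm^2. NfL area load carries the configured +48\% case
#' effect in the parahippocampal gyrus only; Abeta and p-tau loads increase
#' weakly with Thal phase and Braak NFT stage; synaptophysin density has no
#' group effect. With \code{pathologyEffects = FALSE} every dependence on
#' group and stage is removed.
#'
#' @param subject one row of the [generateSubjects()] table
#' @param config a [cohortConfig()]
#' @param seed integer seed for this subject's draws
#' @return data.frame with one row per ROI: subject_id, roi, lb_density,
#'   abeta_load, ptau_load, nfl_load, syn_density
#' @export
generatePathology <- function(subject, config, seed) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(seed)
  rois <- unname(.roiKeys)
  eff <- config$pathologyEffects
  rgammaMean <- function(n, mean, shape)
    stats::rgamma(n, shape = shape, scale = mean / shape)
  lbMean <- if (eff && subject$braak_asyn > 2)
    .lbVulnerability[rois] * config$lbScale * (subject$braak_asyn - 2) / 4
  else rep(0, length(rois))
  lb <- ifelse(lbMean > 0, pmin(80, rgammaMean(length(rois), lbMean, 2)), 0)
  isPd <- subject$group == "PD"
  nflMean <- config$nflBase *
    (1 + config$nflEffect * eff * isPd *
       (rois == "parahippocampal_gyrus"))
  nfl <- pmin(100, rgammaMean(length(rois), nflMean, 4))
  abMean <- config$abetaBase * (if (eff) 0.4 + 0.3 * subject$thal else 1)
  ab <- pmin(100, rgammaMean(length(rois), rep(abMean, length(rois)), 2))
  ptMean <- config$ptauBase * (if (eff) 0.4 + 0.3 * subject$braak_nft else 1)
  pt <- pmin(100, rgammaMean(length(rois), rep(ptMean, length(rois)), 2))
  syn <- rgammaMean(length(rois), rep(config$synBase, length(rois)), 10)
  data.frame(subject_id = subject$subject_id, roi = rois,
             lb_density = unname(lb), abeta_load = ab, ptau_load = pt,
             nfl_load = nfl, syn_density = syn, stringsAsFactors = FALSE)
}

#' Simulate a complete cohort in memory
#'
#' Subjects, regional pathology, and one connectome per subject, all
#' reproducible from the single config seed through per-unit child seeds.
#'
#' @param config a [cohortConfig()]
#' @return list with elements subjects (data.frame), pathology
#'   (data.frame), connectomes (named list of
#'   [WeightedConnectome-class]), config
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  subjects <- generateSubjects(config)
  base <- generateBaseConnectome(config)
  conns <- vector("list", nrow(subjects))
  paths <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    conns[[i]] <- generateSubjectConnectome(base, subjects[i, ], config,
                                            .childSeed(config$seed, 100 + i))
    paths[[i]] <- generatePathology(subjects[i, ], config,
                                    .childSeed(config$seed, 100000 + i))
  }
  names(conns) <- subjects$subject_id
  list(subjects = subjects, pathology = do.call(rbind, paths),
       connectomes = conns, config = config)
}

#' Write a simulated cohort to a directory tree
#'
#' Writes subjects.csv, pathology.csv, connectomes/<subject_id>.tsv and a
#' manifest.json holding the full config (including the seed). Re-running
#' with the same config reproduces every file byte-identically.
#'
#' @param config a [cohortConfig()]
#' @param outDir output directory (created if needed)
#' @return invisibly, the in-memory cohort list
#' @export
generateCohort <- function(config, outDir) {
  cohort <- simulateCohort(config)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  cdir <- file.path(outDir, "connectomes")
  if (!dir.exists(cdir) && !dir.create(cdir, showWarnings = FALSE))
    stop("cannot create output directory: ", cdir)
  utils::write.csv(cohort$subjects, file.path(outDir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$pathology, file.path(outDir, "pathology.csv"),
                   row.names = FALSE)
  for (id in names(cohort$connectomes))
    writeConnectome(cohort$connectomes[[id]],
                    file.path(cdir, paste0(id, ".tsv")))
  manifest <- unclass(config)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Read a cohort directory written by generateCohort
#'
#' @param dir directory containing subjects.csv, pathology.csv and
#'   connectomes/
#' @return list with subjects, pathology, connectomes (and config if a
#'   manifest is present)
#' @export
readCohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  pathology <- utils::read.csv(file.path(dir, "pathology.csv"),
                               stringsAsFactors = FALSE)
  files <- file.path(dir, "connectomes", paste0(subjects$subject_id, ".tsv"))
  missing <- !file.exists(files)
  if (any(missing))
    stop("missing connectome file(s): ",
         paste(subjects$subject_id[missing], collapse = ", "))
  conns <- lapply(files, readConnectome)
  names(conns) <- subjects$subject_id
  config <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    raw <- jsonlite::read_json(mf, simplifyVector = TRUE)
    config <- do.call(cohortConfig, raw[setdiff(names(raw), character(0))])
  }
  list(subjects = subjects, pathology = pathology, connectomes = conns,
       config = config)
}
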