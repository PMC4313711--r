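#' @include AllClasses.R cohort.R segmentation.R fusion.R morphometry.R volumetry.R stats.R
NULL

#' Build a pipeline run configuration
#'
#' @param outputDir directory for all run artefacts.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param stages subset of c("cohort", "phantom", "segment", "fuse",
#'   "measure", "volumes", "stats") to execute (dependency order is
#'   enforced).
#' @param nTable cohort age table (see [simulateCohort()]).
#' @param model a [GrowthModel].
#' @param template [PhantomSpec] for imaging parameters.
#' @param ageScheme "two_year" or "one_year" grouping for the statistics.
#' @param responses response measures for the MANOVA stage.
#' @param design one-sided formula for the statistics stage.
#' @param nAtlases number of perturbed template atlases fused per subject.
#' @param cohortFile optional existing cohort TSV (enables stats-only
#'   runs without the imaging stages).
#' @param writeVolumes write per-subject NIfTI volumes (default FALSE;
#'   tables and the manifest are always written).
#' @return a list of class "RunConfig".
#' @export
runConfig <- function(outputDir, seed = 1L,
                      stages = c("cohort", "phantom", "segment", "fuse",
                                 "measure", "volumes", "stats"),
                      nTable = referenceAgeTable(),
                      model = defaultGrowthModel(),
                      template = phantomSpec(),
                      ageScheme = "two_year",
                      responses = c("brain_length", "brain_width",
                                    "brain_height", "ac_pc_distance"),
                      design = ~ age_group * group,
                      nAtlases = 3L, cohortFile = NULL,
                      writeVolumes = FALSE) {
  allStages <- c("cohort", "phantom", "segment", "fuse", "measure",
                 "volumes", "stats")
  stages <- allStages[allStages %in% stages]
  structure(list(outputDir = outputDir, seed = as.integer(seed),
                 stages = stages, nTable = nTable, model = model,
                 template = template, ageScheme = ageScheme,
                 responses = responses, design = design,
                 nAtlases = as.integer(nAtlases), cohortFile = cohortFile,
                 writeVolumes = writeVolumes),
            class = "RunConfig")
}

#' Read a RunConfig from YAML
#'
#' Recognised keys: output_dir, seed, stages, age_scheme, responses,
#' design (formula string), n_atlases, cohort_file, write_volumes, and a
#' `phantom` block of [phantomSpec()] arguments. The growth model and age
#' table currently come from the package defaults.
#' @param path YAML file path.
#' @return a "RunConfig" list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  tmpl <- if (is.null(y$phantom)) phantomSpec()
          else do.call(phantomSpec, y$phantom)
  args <- list(outputDir = y$output_dir, template = tmpl)
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$stages)) args$stages <- y$stages
  if (!is.null(y$age_scheme)) args$ageScheme <- y$age_scheme
  if (!is.null(y$responses)) args$responses <- y$responses
  if (!is.null(y$design)) args$design <- stats::as.formula(y$design)
  if (!is.null(y$n_atlases)) args$nAtlases <- y$n_atlases
  if (!is.null(y$cohort_file)) args$cohortFile <- y$cohort_file
  if (!is.null(y$write_volumes)) args$writeVolumes <- y$write_volumes
  do.call(runConfig, args)
}

stageSeed <- function(seed, stage) {
  allStages <- c("cohort", "phantom", "segment", "fuse", "measure",
                 "volumes", "stats")
  (seed %% 1000000L) * 1000L + match(stage, allStages)
}

# perturbed copies of the template phantom used as synthetic "atlas heads"
makeTemplateAtlases <- function(template, n, seed) {
  withSeed(seed, lapply(seq_len(n), function(i) {
    f <- 1 + stats::runif(3, -0.06, 0.06)
    sp <- phantomSpec(
      scalpSemiAxes = template@scalpSemiAxes * f,
      skullThickness = template@skullThickness,
      csfGap = template@csfGap,
      brainSemiAxes = template@brainSemiAxes * f,
      wmFraction = template@wmFraction,
      ventricleSemiAxes = if (length(template@ventricleSemiAxes))
        template@ventricleSemiAxes * f else NULL,
      acOffset = template@acOffset * f[2],
      pcOffset = template@pcOffset * f[2],
      landmarkElevation = template@landmarkElevation,
      intensityMeans = template@intensityMeans, noiseSd = 0,
      voxelSpacing = template@voxelSpacing, seed = seed + i)
    makePhantom(sp)
  }))
}

#' Run the measurement pipeline
#'
#' Executes the enabled stages in dependency order — cohort simulation,
#' phantom rendering, tissue segmentation, atlas fusion, morphometry,
#' volumetry, statistics — writing per-subject records, the cohort table,
#' statistics tables and a JSON run manifest (per-file MD5 hashes, stage
#' seeds, wall-clock) under the configured output directory. A stage whose
#' upstream artefact is missing fails naming the stage and file.
#'
#' @param config a "RunConfig" from [runConfig()] or [readRunConfig()].
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `measured`, `stats`, `fusionQc`) and the `manifest`.
#' @export
runPipeline <- function(config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = config$stages,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   files = list(), stageSeconds = list())
  res <- list()
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    manifest$stageSeconds[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  record <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }

  needSpecs <- any(c("phantom", "segment", "fuse", "measure", "volumes")
                   %in% config$stages)
  cohort <- NULL; specs <- NULL
  if ("cohort" %in% config$stages) {
    sim <- simulateCohort(config$model, config$nTable,
                          seed = stageSeed(config$seed, "cohort"),
                          makeSpecs = needSpecs, template = config$template)
    cohort <- regroupAges(sim$cohort, config$ageScheme)
    specs <- sim$specs
    p <- file.path(config$outputDir, "cohort.tsv")
    writeCohort(cohort, p); record(p)
    tick("cohort")
  } else if (!is.null(config$cohortFile)) {
    if (!file.exists(config$cohortFile))
      stop("stage 'stats': missing cohort file ", config$cohortFile)
    cohort <- regroupAges(readCohort(config$cohortFile), config$ageScheme)
  }
  res$cohort <- cohort

  imagingStages <- intersect(config$stages,
                             c("phantom", "segment", "fuse", "measure",
                               "volumes"))
  phantoms <- NULL
  if (length(imagingStages)) {
    if (is.null(specs))
      stop("stage '", imagingStages[1],
           "': missing upstream cohort stage (no phantom specs)")
    phantoms <- lapply(specs, makePhantom)
    if (config$writeVolumes)
      for (id in names(phantoms)) {
        p <- file.path(config$outputDir, paste0(id, "_T1.nii.gz"))
        writeVolume(phantoms[[id]]@intensity, p); record(p)
      }
    tick("phantom")
  }

  pves <- NULL
  if ("segment" %in% config$stages) {
    pves <- lapply(phantoms, function(ph) {
      bm <- binarize(ph@masks@brain)
      fit <- fitTissueMixture(ph@intensity, bm,
                              seed = stageSeed(config$seed, "segment"))
      pveFromFit(ph@intensity, bm, fit)
    })
    tick("segment")
  }

  fused <- NULL
  if ("fuse" %in% config$stages) {
    atlasPh <- makeTemplateAtlases(config$template, config$nAtlases,
                                   stageSeed(config$seed, "fuse"))
    fused <- lapply(phantoms, function(ph) {
      dstPts <- registrationPoints(ph@landmarks, ph@masks@scalp)
      regs <- lapply(atlasPh, function(at) {
        srcPts <- registrationPoints(at@landmarks, at@masks@scalp)
        tr <- registerLandmarks(srcPts, dstPts)
        resampleLabels(at@labels, tr, ph@intensity)
      })
      majorityVote(regs)
    })
    qc <- vapply(names(fused), function(id) {
      bm <- binarize(phantoms[[id]]@masks@brain)@values >= 0.5
      mean(fused[[id]]@values[bm] == 0)
    }, numeric(1))
    res$fusionQc <- data.frame(subject_id = names(fused),
                               background_frac_in_brain = unname(qc))
    p <- file.path(config$outputDir, "fusion_qc.tsv")
    utils::write.table(res$fusionQc, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record(p)
    tick("fuse")
  }

  measured <- NULL
  if (any(c("measure", "volumes") %in% config$stages)) {
    rows <- lapply(names(phantoms), function(id) {
      ph <- phantoms[[id]]
      out <- data.frame(subject_id = id)
      if ("measure" %in% config$stages)
        out <- cbind(out, as.data.frame(as.list(
          morphometryRecord(ph@masks@brain, ph@masks@scalp, ph@landmarks))))
      if ("volumes" %in% config$stages) {
        bm <- binarize(ph@masks@brain)
        maps <- if (!is.null(pves)) pves[[id]] else ph@truePve
        labs <- if (!is.null(fused)) fused[[id]] else ph@labels
        prof <- regionalProfile(maps, labs, ph@lobes, bm)
        out$head_volume <- headVolume(ph@masks@scalp, ph@landmarks)
        out$intracranial_volume <- maskVolume(binarize(ph@masks@innerSkull))
        out <- cbind(out, as.data.frame(as.list(prof$totals)))
      }
      out
    })
    measured <- do.call(rbind, rows)
    p <- file.path(config$outputDir, "measured.tsv")
    writeCohort(measured, p); record(p)
    tick("measure")
  }
  res$measured <- measured

  if ("stats" %in% config$stages) {
    if (is.null(cohort))
      stop("stage 'stats': missing upstream cohort table ",
           "(run the cohort stage or set cohortFile)")
    man <- cohortManova(cohort, config$responses, config$design)
    p <- file.path(config$outputDir, "effects.tsv")
    utils::write.table(man, p, sep = "\t", quote = FALSE, row.names = FALSE)
    record(p)
    anovas <- lapply(config$responses, function(rsp)
      factorialAnova(cohort, rsp, config$design))
    names(anovas) <- config$responses
    cm <- do.call(rbind, lapply(config$responses, function(rsp)
      cbind(measure = rsp, anovas[[rsp]]$cellMeans)))
    p2 <- file.path(config$outputDir, "cell_means.tsv")
    utils::write.table(cm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    record(p2)
    peaks <- NULL
    if ("gm_total" %in% names(cohort)) {
      groups <- sort(unique(as.character(cohort$group)))
      peaks <- do.call(rbind, lapply(groups, function(g) {
        f <- fitPeakTrajectory(cohort, "gm_total", g, nBoot = 200L,
                               seed = stageSeed(config$seed, "stats"))
        data.frame(measure = "gm_total", group = g, peak_age = f$peakAge,
                   ci_lo = f$ci[1], ci_hi = f$ci[2], shape = f$shape)
      }))
      p3 <- file.path(config$outputDir, "peaks.tsv")
      utils::write.table(peaks, p3, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record(p3)
    }
    res$stats <- list(manova = man, anovas = anovas, peaks = peaks)
    tick("stats")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  mPath <- file.path(config$outputDir, "manifest.json")
  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
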