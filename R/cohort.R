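#' @include AllClasses.R phantom.R
NULL

#' Construct a GrowthModel
#'
#' @param measures named list of per-measure trajectory definitions; each a
#'   list with `kind` ("quadratic" or "linear"), for quadratic `peakValue`,
#'   `peakAge`, `curvature` (>= 0, so value = peakValue - curvature *
#'   (age - peakAge)^2), for linear `intercept` and `slope` (value =
#'   intercept + slope * age); optional `groupValue` and `groupPeakAge`
#'   (named per-group additive offsets), `sexOffset` (added for males) and
#'   `residualSd` (default 0).
#' @param groups character length-2 group labels.
#' @param ageRange numeric length-2, years.
#' @return a [GrowthModel].
#' @export
growthModel <- function(measures, groups = c("A", "B"), ageRange = c(8, 16)) {
  measures <- lapply(measures, function(m) {
    m$residualSd <- if (is.null(m$residualSd)) 0 else m$residualSd
    m$sexOffset <- if (is.null(m$sexOffset)) 0 else m$sexOffset
    if (is.null(m$groupValue)) m$groupValue <- stats::setNames(c(0, 0), groups)
    if (is.null(m$groupPeakAge)) m$groupPeakAge <- stats::setNames(c(0, 0), groups)
    if (m$kind == "quadratic" && is.null(m$curvature)) m$curvature <- 0
    m
  })
  new("GrowthModel", measures = measures, groups = groups,
      ageRange = as.numeric(ageRange))
}

#' Measure names carried by a growth model
#' @param model a [GrowthModel].
#' @export
measureNames <- function(model) names(model@measures)

#' Default two-group growth model
#'
#' Trajectories for the seven distance measures plus total GM and WM
#' volume, ages 8-16, with group effect directions chosen to mirror the
#' published qualitative contrasts between a Chinese (CN) and a U.S. (US)
#' cohort: US heads/brains longer, CN wider and taller; total GM follows an
#' inverted U peaking earlier for US; total WM increases linearly for both.
#' Magnitudes are synthetic (order-of-magnitude plausible), not estimates
#' of any real cohort.
#'
#' @param groups group labels, default c("CN", "US"); offsets are applied
#'   to the second group.
#' @param residualScale multiplier on all residual sds (0 gives noise-free
#'   cohorts).
#' @return a [GrowthModel].
#' @export
defaultGrowthModel <- function(groups = c("CN", "US"), residualScale = 1) {
  g2 <- groups[2]
  off <- function(x) stats::setNames(c(0, x), groups)
  lin <- function(intercept, slope, g2off, sexOff, sd)
    list(kind = "linear", intercept = intercept, slope = slope,
         groupValue = off(g2off), sexOffset = sexOff,
         residualSd = sd * residualScale)
  m <- list(
    head_length    = lin(175, 0.9, +5, 2.0, 2.5),
    head_width     = lin(148, 0.4, -5, 2.0, 2.0),
    head_height    = lin(103, 0.5, -4, 1.5, 2.0),
    brain_length   = lin(138, 0.7, +4, 1.5, 2.0),
    brain_width    = lin(116, 0.0, -4, 1.5, 2.0),
    brain_height   = lin( 78, 0.35, -2, 1.0, 1.5),
    ac_pc_distance = lin( 24, 0.2,  0, 0.3, 0.8),
    gm_total = list(kind = "quadratic", peakValue = 8.4e5, peakAge = 12,
                    curvature = 2600, groupValue = off(-2e4),
                    groupPeakAge = off(-2), sexOffset = 1.0e4,
                    residualSd = 2.0e4 * residualScale),
    wm_total = lin(2.8e5, 1.2e4, 0, 0.5e4, 1.5e4))
  growthModel(m, groups = groups)
}

#' Evaluate a growth-model trajectory
#'
#' @param model a [GrowthModel].
#' @param measure measure name; unknown names are an error listing the
#'   known measures.
#' @param age numeric vector of ages (years).
#' @param group group label vector (recycled).
#' @param sex "M"/"F" vector (recycled); the sex offset is added for "M".
#' @return expected measure values (no residual noise).
#' @export
evaluateGrowthModel <- function(model, measure, age, group = model@groups[1],
                                sex = "F") {
  if (!measure %in% names(model@measures))
    stop("unknown measure '", measure, "'; known measures: ",
         paste(names(model@measures), collapse = ", "))
  m <- model@measures[[measure]]
  n <- length(age)
  group <- rep_len(as.character(group), n)
  sex <- rep_len(as.character(sex), n)
  gv <- m$groupValue[group]
  base <- if (m$kind == "quadratic") {
    pa <- m$peakAge + m$groupPeakAge[group]
    m$peakValue + gv - m$curvature * (age - pa)^2
  } else {
    m$intercept + gv + m$slope * age
  }
  as.numeric(base + m$sexOffset * (sex == "M"))
}

#' Reference demographic age table
#'
#' One-year age-bin subject counts (and male counts) for a two-nationality
#' pediatric cohort aged 8-16, as published for a Chinese (CN, total 133)
#' and a U.S. (US, total 149) sample. Used as the default `nTable` for
#' [simulateCohort()] and for age-regrouping bookkeeping checks.
#'
#' @return data.frame with columns group, age, n, n_male.
#' @export
referenceAgeTable <- function() {
  data.frame(
    group = rep(c("CN", "US"), each = 9),
    age = rep(8:16, 2),
    n = c(16, 14, 8, 13, 23, 18, 21, 8, 12,
          19, 8, 16, 12, 15, 29, 30, 8, 12),
    n_male = c(12, 12, 8, 10, 13, 12, 7, 3, 6,
               11, 4, 9, 6, 11, 15, 17, 4, 6))
}

#' Derive a PhantomSpec whose analytic measures equal given values
#'
#' Inverts the nested-ellipsoid geometry: the seven distance measures fix
#' the scalp and brain semi-axes and the AC/PC offsets (AC and PC placed
#' symmetrically about the origin); `gm_total`, when present, fixes the WM
#' fraction, and `wm_total` then fixes the ventricle volume. Imaging
#' parameters (spacing, noise, intensity means, skull thickness, CSF gap)
#' come from `template`.
#'
#' @param measures named numeric vector with at least the seven distance
#'   measures (mm), optionally gm_total and wm_total (mm^3).
#' @param template a [PhantomSpec] supplying non-geometric parameters.
#' @param seed per-subject noise seed.
#' @return a validated [PhantomSpec].
#' @export
phantomSpecFromMeasures <- function(measures, template = phantomSpec(),
                                    seed = template@seed) {
  need <- c("brain_length", "brain_width", "brain_height", "ac_pc_distance",
            "head_length", "head_width", "head_height")
  missing <- setdiff(need, names(measures))
  if (length(missing))
    stop("measures missing: ", paste(missing, collapse = ", "))
  d <- measures[["ac_pc_distance"]]
  ac <- d / 2; pc <- -d / 2
  bS <- measures[["head_length"]] / 2
  aS <- measures[["head_width"]] / 2
  cS <- measures[["head_height"]] / sqrt(1 - (pc / bS)^2)
  bB <- measures[["brain_length"]] / 2
  aB <- measures[["brain_width"]] / 2
  cB <- measures[["brain_height"]] / sqrt(1 - (pc / bB)^2)
  vBrain <- ellipsoidVolume(c(aB, bB, cB))
  wmFrac <- template@wmFraction
  vent <- template@ventricleSemiAxes
  if ("gm_total" %in% names(measures)) {
    gm <- measures[["gm_total"]]
    if (gm <= 0 || gm >= vBrain)
      stop("gm_total must lie strictly between 0 and the brain volume")
    wmFrac <- (1 - gm / vBrain)^(1 / 3)
    vWmEll <- vBrain - gm
    if ("wm_total" %in% names(measures)) {
      vVent <- vWmEll - measures[["wm_total"]]
      if (vVent <= 0)
        stop("wm_total exceeds the WM ellipsoid volume implied by gm_total")
      vent <- wmFrac * c(aB, bB, cB) * (vVent / vWmEll)^(1 / 3)
    }
  }
  phantomSpec(scalpSemiAxes = c(aS, bS, cS), brainSemiAxes = c(aB, bB, cB),
              skullThickness = template@skullThickness,
              csfGap = template@csfGap, wmFraction = wmFrac,
              ventricleSemiAxes = vent, acOffset = ac, pcOffset = pc,
              landmarkElevation = template@landmarkElevation,
              intensityMeans = template@intensityMeans,
              noiseSd = template@noiseSd,
              voxelSpacing = template@voxelSpacing, seed = seed)
}

#' Simulate a cohort from a growth model
#'
#' Draws one subject per count in `nTable`: age uniform within the
#' subject's 1-year bin, sex per the table's male counts (or Bernoulli 0.5
#' when absent), then evaluates each measure's trajectory plus group/sex
#' offsets plus Gaussian residual. Optionally derives, per subject, a
#' [PhantomSpec] whose analytic measures equal the drawn values (see
#' [phantomSpecFromMeasures()]).
#'
#' @param model a [GrowthModel].
#' @param nTable data.frame with columns group, age (integer bin start),
#'   n, and optionally n_male; defaults to [referenceAgeTable()].
#' @param seed master RNG seed; the simulation is fully reproducible.
#' @param makeSpecs logical; also return per-subject PhantomSpecs.
#' @param template [PhantomSpec] for non-geometric parameters of the specs.
#' @return list with `cohort` (data.frame: subject_id, age, group, sex,
#'   one column per measure) and `specs` (list of [PhantomSpec] or NULL).
#' @export
simulateCohort <- function(model, nTable = referenceAgeTable(), seed = 1L,
                           makeSpecs = FALSE, template = phantomSpec()) {
  stopifnot(all(c("group", "age", "n") %in% names(nTable)))
  if (any(nTable$n < 0)) stop("nTable counts must be non-negative")
  withSeed(seed, {
    rows <- list()
    k <- 0L
    for (i in seq_len(nrow(nTable))) {
      ni <- nTable$n[i]
      if (ni == 0) next
      nm <- if ("n_male" %in% names(nTable)) nTable$n_male[i]
            else stats::rbinom(1, ni, 0.5)
      sex <- sample(rep(c("M", "F"), c(nm, ni - nm)))
      age <- stats::runif(ni, nTable$age[i], nTable$age[i] + 1)
      rows[[i]] <- data.frame(
        subject_id = sprintf("S%04d", k + seq_len(ni)),
        age = age, group = as.character(nTable$group[i]), sex = sex)
      k <- k + ni
    }
    cohort <- do.call(rbind, rows)
    if (is.null(cohort))
      cohort <- data.frame(subject_id = character(), age = numeric(),
                           group = character(), sex = character())
    for (ms in names(model@measures)) {
      m <- model@measures[[ms]]
      mu <- evaluateGrowthModel(model, ms, cohort$age, cohort$group,
                                cohort$sex)
      cohort[[ms]] <- mu + stats::rnorm(nrow(cohort), 0, m$residualSd)
    }
    rownames(cohort) <- NULL
    specs <- NULL
    if (makeSpecs && nrow(cohort)) {
      specs <- lapply(seq_len(nrow(cohort)), function(j) {
        mv <- unlist(cohort[j, names(model@measures), drop = TRUE])
        phantomSpecFromMeasures(mv, template = template,
                                seed = (seed %% 1000000L) * 1000L + j)
      })
      names(specs) <- cohort$subject_id
    }
    list(cohort = cohort, specs = specs)
  })
}

#' Regroup cohort ages into one- or two-year bins
#'
#' The two-year scheme uses the bins 8, 9-10, 11-12, 13-14, 15-16; the
#' one-year scheme floors age to whole years. Adds (or replaces) a factor
#' column `age_group`; the row count is unchanged.
#'
#' @param cohort cohort data.frame with an `age` column in years.
#' @param scheme "one_year" or "two_year".
#' @return the cohort with an `age_group` factor column.
#' @export
regroupAges <- function(cohort, scheme = c("two_year", "one_year")) {
  scheme <- match.arg(scheme)
  lv1 <- as.character(8:16)
  lv2 <- c("8", "9-10", "11-12", "13-14", "15-16")
  if (nrow(cohort) == 0) {
    cohort$age_group <- factor(character(),
                               levels = if (scheme == "two_year") lv2 else lv1)
    return(cohort)
  }
  bad <- which(cohort$age < 8 | cohort$age >= 17)
  if (length(bad))
    stop("age outside [8, 17) for subject(s): ",
         paste(utils::head(cohort$subject_id[bad], 5), collapse = ", "))
  yr <- floor(cohort$age)
  if (scheme == "one_year") {
    cohort$age_group <- factor(as.character(yr), levels = lv1)
  } else {
    lab <- ifelse(yr == 8, "8",
           ifelse(yr <= 10, "9-10",
           ifelse(yr <= 12, "11-12",
           ifelse(yr <= 14, "13-14", "15-16"))))
    cohort$age_group <- factor(lab, levels = lv2)
  }
  cohort
}

#' Read / write cohort tables as TSV
#' @param path TSV file path.
#' @export
readCohort <- function(path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)

#' @rdname readCohort
#' @param cohort cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
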