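#' @include AllClasses.R
NULL

# coerce the design variables to factors, dropping unused levels
designData <- function(data, rhs) {
  for (v in all.vars(rhs))
    if (!is.numeric(data[[v]]))
      data[[v]] <- droplevels(factor(data[[v]]))
  data
}

# model matrix under sum-to-zero coding with per-term column assignment
sumToZeroModel <- function(data, rhs) {
  tf <- stats::terms(rhs)
  vars <- all.vars(rhs)
  contr <- lapply(Filter(function(v) is.factor(data[[v]]), stats::setNames(
    as.list(vars), vars)), function(v) "contr.sum")
  X <- stats::model.matrix(tf, data, contrasts.arg = contr)
  list(X = X, assign = attr(X, "assign"),
       termLabels = attr(tf, "term.labels"))
}

checkCells <- function(data, rhs) {
  tf <- stats::terms(rhs)
  labs <- attr(tf, "term.labels")
  for (lab in labs[grepl(":", labs)]) {
    fs <- strsplit(lab, ":", fixed = TRUE)[[1]]
    if (all(vapply(fs, function(f) !is.numeric(data[[f]]), TRUE))) {
      tb <- table(data[fs])
      if (any(tb == 0)) {
        idx <- which(tb == 0, arr.ind = TRUE)[1, , drop = TRUE]
        cell <- paste(mapply(function(f, i) paste0(f, "=", dimnames(tb)[[f]][i]),
                             fs, idx), collapse = ", ")
        stop("empty design cell: ", cell)
      }
    }
  }
  invisible(TRUE)
}

#' Type III hypothesis and error SSCP matrices
#'
#' Multivariate general linear model under sum-to-zero factor coding.
#' For each model term the Type III hypothesis SSCP matrix is the general
#' linear hypothesis on that term's coefficient block,
#' H = (L B)' [L (X'X)^-1 L']^-1 (L B); the error SSCP E comes from the
#' full-model residuals, with error df ve = N - rank(X).
#'
#' @param cohort data.frame holding responses and factors.
#' @param responses character vector of response column names (>= 1).
#' @param rhs one-sided model formula, e.g. `~ age_group * group`.
#' @return list with `H` (named list of p x p matrices), `E`, `dfh`
#'   (named), `ve`, `p`, and the coefficient matrix `B`.
#' @export
sscpDecompose <- function(cohort, responses, rhs) {
  missingCols <- setdiff(c(responses, all.vars(rhs)), names(cohort))
  if (length(missingCols))
    stop("columns not in cohort: ", paste(missingCols, collapse = ", "))
  cohort <- designData(cohort, rhs)
  checkCells(cohort, rhs)
  Y <- as.matrix(cohort[, responses, drop = FALSE])
  if (any(!is.finite(Y))) stop("non-finite response values")
  mm <- sumToZeroModel(cohort, rhs)
  X <- mm$X
  qrX <- qr(X)
  r <- qrX$rank
  if (r < ncol(X))
    stop("design matrix is rank deficient; check for collinear factors")
  n <- nrow(X)
  ve <- n - r
  if (ve < 1) stop("no residual degrees of freedom")
  B <- qr.coef(qrX, Y)
  resid <- Y - X %*% B
  E <- crossprod(resid)
  if (length(responses) > 1 && rcond(E) < 1e-12)
    stop("error SSCP matrix is singular; responses may be collinear")
  XtXinv <- chol2inv(qr.R(qrX))
  H <- list(); dfh <- integer()
  for (i in seq_along(mm$termLabels)) {
    cols <- which(mm$assign == i)
    Lb <- B[cols, , drop = FALSE]
    M <- XtXinv[cols, cols, drop = FALSE]
    H[[mm$termLabels[i]]] <- t(Lb) %*% solve(M, Lb)
    dfh[mm$termLabels[i]] <- length(cols)
  }
  list(H = H, E = E, dfh = dfh, ve = ve, p = length(responses), B = B)
}

#' Numerator and denominator df of Rao's approximate F
#'
#' For a Wilks' lambda test with p responses, hypothesis df `dfh` and
#' error df `ve`:
#' t = sqrt((p^2 dfh^2 - 4) / (p^2 + dfh^2 - 5)) (t = 1 when p dfh <= 2),
#' w = ve - (p - dfh + 1)/2, df1 = p dfh,
#' df2 = w t - (p dfh - 2)/2. The reported df2 is rounded to the nearest
#' integer; the exact value is kept for p-values.
#'
#' @param p number of response variables.
#' @param dfh hypothesis degrees of freedom.
#' @param ve error degrees of freedom.
#' @return list(df1, df2, df2Exact, t).
#' @examples
#' raoDf(4, 4, 270)$df2   # 816
#' raoDf(3, 1, 262)$df2   # 260
#' @export
raoDf <- function(p, dfh, ve) {
  stopifnot(p >= 1, dfh >= 1, ve >= 1)
  t <- if (p * dfh <= 2 || p^2 + dfh^2 - 5 <= 0) 1
       else sqrt((p^2 * dfh^2 - 4) / (p^2 + dfh^2 - 5))
  w <- ve - (p - dfh + 1) / 2
  df1 <- p * dfh
  df2Exact <- w * t - (p * dfh - 2) / 2
  list(df1 = df1, df2 = as.integer(round(df2Exact)), df2Exact = df2Exact,
       t = t)
}

#' Wilks' lambda and Rao's approximate F for one effect
#'
#' Lambda = det(E) / det(H + E); Rao's transformation maps it to an
#' approximately F-distributed statistic
#' F = ((1 - Lambda^(1/t)) / Lambda^(1/t)) * (df2 / df1) with the df of
#' [raoDf()]. For p = 1 this reduces exactly to the univariate F.
#'
#' @param H hypothesis SSCP matrix (p x p).
#' @param E error SSCP matrix (p x p, positive definite).
#' @param dfh hypothesis df.
#' @param ve error df.
#' @return data.frame row: lambda, F, df1, df2 (rounded), df2_exact,
#'   p_value.
#' @export
wilksRao <- function(H, E, dfh, ve) {
  H <- as.matrix(H); E <- as.matrix(E)
  p <- nrow(E)
  ch <- tryCatch(chol(E), error = function(e) NULL)
  if (is.null(ch)) stop("error SSCP matrix is not positive definite")
  lambda <- det(E) / det(H + E)
  rd <- raoDf(p, dfh, ve)
  ls <- lambda^(1 / rd$t)
  Fstat <- (1 - ls) / ls * (rd$df2Exact / rd$df1)
  data.frame(lambda = lambda, F = Fstat, df1 = rd$df1, df2 = rd$df2,
             df2_exact = rd$df2Exact,
             p_value = stats::pf(Fstat, rd$df1, rd$df2Exact,
                                 lower.tail = FALSE))
}

#' MANOVA over a cohort table
#'
#' Type III Wilks'-lambda MANOVA of several response measures on a factor
#' design, reporting Rao's approximate F per effect.
#'
#' @inheritParams sscpDecompose
#' @return data.frame: effect, lambda, F, df1, df2, df2_exact, p_value,
#'   dfh, ve.
#' @examples
#' sim <- simulateCohort(defaultGrowthModel(), seed = 7)
#' coh <- regroupAges(sim$cohort, "two_year")
#' cohortManova(coh, c("brain_length", "brain_width", "brain_height",
#'                     "ac_pc_distance"), ~ age_group * group)
#' @export
cohortManova <- function(cohort, responses, rhs) {
  dec <- sscpDecompose(cohort, responses, rhs)
  rows <- lapply(names(dec$H), function(eff) {
    wr <- wilksRao(dec$H[[eff]], dec$E, dec$dfh[[eff]], dec$ve)
    cbind(effect = eff, wr, dfh = dec$dfh[[eff]], ve = dec$ve)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type III factorial ANOVA of a single measure
#'
#' Univariate general linear model under sum-to-zero coding with Type III
#' F tests per effect, plus per-cell means and standard errors over the
#' factor combinations.
#'
#' @inheritParams sscpDecompose
#' @param response single response column name.
#' @return list with `effects` (data.frame: effect, F, df1, df2, p_value)
#'   and `cellMeans` (data.frame).
#' @export
factorialAnova <- function(cohort, response, rhs) {
  dec <- sscpDecompose(cohort, response, rhs)
  sse <- as.numeric(dec$E)
  tiny <- 1e-12 * max(1, sum(cohort[[response]]^2))
  effects <- do.call(rbind, lapply(names(dec$H), function(eff) {
    ssh <- as.numeric(dec$H[[eff]])
    dfh <- dec$dfh[[eff]]
    # zero residual variance with zero effect variance: F defined as 0
    Fv <- if (ssh < tiny && sse < tiny) 0 else (ssh / dfh) / (sse / dec$ve)
    data.frame(effect = eff, ss = ssh, F = Fv, df1 = dfh, df2 = dec$ve,
               p_value = stats::pf(Fv, dfh, dec$ve, lower.tail = FALSE))
  }))
  facs <- Filter(function(v) !is.numeric(cohort[[v]]), all.vars(rhs))
  cellMeans <- NULL
  if (length(facs)) {
    splitBy <- lapply(facs, function(f) cohort[[f]])
    names(splitBy) <- facs
    agg <- stats::aggregate(cohort[[response]], splitBy, function(v)
      c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
    cellMeans <- cbind(agg[facs], as.data.frame(agg$x))
  }
  list(effects = effects, cellMeans = cellMeans)
}

#' Quadratic growth-peak estimation for one measure and group
#'
#' Fits an ordinary least-squares quadratic in age (centred at 12 years
#' for conditioning). When the curve is concave (b2 < 0) and the vertex
#' falls inside the observed age range the peak age -b1/(2 b2) is
#' reported, with a subject-resampling bootstrap confidence interval.
#' Shape is classified as "inverted-U" (b2 < 0), "U" (b2 > 0) or
#' "linear-ish" (|b2| negligible against the fitted scale).
#'
#' @param cohort cohort data.frame with `age` and the measure column.
#' @param measure measure column name.
#' @param group optional group level to subset on (`groupCol`).
#' @param nBoot bootstrap replicates (default 500).
#' @param seed RNG seed for the bootstrap.
#' @param groupCol grouping column name (default "group").
#' @param level CI level (default 0.95).
#' @return list: coefficients b0, b1, b2 (centred parameterisation),
#'   shape, peakAge (NA unless concave with interior vertex), ci, nBoot.
#' @export
fitPeakTrajectory <- function(cohort, measure, group = NULL, nBoot = 500L,
                              seed = 1L, groupCol = "group", level = 0.95) {
  dat <- if (is.null(group)) cohort else cohort[cohort[[groupCol]] == group, ]
  if (length(unique(round(dat$age, 6))) < 3)
    stop("need at least 3 distinct ages to fit a quadratic")
  fitOne <- function(d) {
    a <- d$age - 12
    stats::lm.fit(cbind(1, a, a^2), d[[measure]])$coefficients
  }
  b <- fitOne(dat)
  scale <- max(abs(b[1]), 1)
  shape <- if (abs(b[3]) < 1e-8 * scale) "linear-ish"
           else if (b[3] < 0) "inverted-U" else "U"
  peakOf <- function(b) {
    if (anyNA(b) || b[3] >= 0) return(NA_real_)   # rank-deficient resample
    pk <- 12 - b[2] / (2 * b[3])
    if (pk < min(dat$age) || pk > max(dat$age)) NA_real_ else pk
  }
  peak <- if (shape == "inverted-U") peakOf(b) else NA_real_
  ci <- c(NA_real_, NA_real_)
  boots <- numeric(0)
  if (!is.na(peak) && nBoot > 0) {
    boots <- withSeed(seed, vapply(seq_len(nBoot), function(i) {
      idx <- sample.int(nrow(dat), replace = TRUE)
      peakOf(fitOne(dat[idx, ]))
    }, numeric(1)))
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 10)
      ci <- unname(stats::quantile(boots, c((1 - level) / 2,
                                            1 - (1 - level) / 2)))
  }
  list(measure = measure, group = group, b0 = unname(b[1]), b1 = unname(b[2]),
       b2 = unname(b[3]), shape = shape, peakAge = unname(peak), ci = ci,
       nBoot = length(boots))
}

#' Compare peak ages between two groups
#'
#' Fits [fitPeakTrajectory()] per group and bootstraps the peak-age
#' difference (group 1 minus group 2) by resampling subjects within each
#' group jointly.
#'
#' @inheritParams fitPeakTrajectory
#' @param groups length-2 character; defaults to the two levels present.
#' @return list with the two fits, `difference`, and `diffCi`.
#' @export
comparePeakAges <- function(cohort, measure, groups = NULL, nBoot = 500L,
                            seed = 1L, groupCol = "group", level = 0.95) {
  if (is.null(groups)) groups <- sort(unique(as.character(cohort[[groupCol]])))
  stopifnot(length(groups) == 2)
  f1 <- fitPeakTrajectory(cohort, measure, groups[1], nBoot = 0,
                          groupCol = groupCol)
  f2 <- fitPeakTrajectory(cohort, measure, groups[2], nBoot = 0,
                          groupCol = groupCol)
  d1 <- cohort[cohort[[groupCol]] == groups[1], ]
  d2 <- cohort[cohort[[groupCol]] == groups[2], ]
  peakOf <- function(d) {
    a <- d$age - 12
    b <- stats::lm.fit(cbind(1, a, a^2), d[[measure]])$coefficients
    if (anyNA(b) || b[3] >= 0) return(NA_real_)
    12 - b[2] / (2 * b[3])
  }
  diffs <- withSeed(seed, vapply(seq_len(nBoot), function(i) {
    peakOf(d1[sample.int(nrow(d1), replace = TRUE), ]) -
      peakOf(d2[sample.int(nrow(d2), replace = TRUE), ])
  }, numeric(1)))
  diffs <- diffs[!is.na(diffs)]
  ci <- if (length(diffs) >= 10)
    unname(stats::quantile(diffs, c((1 - level) / 2, 1 - (1 - level) / 2)))
  else c(NA_real_, NA_real_)
  list(fit1 = f1, fit2 = f2,
       difference = f1$peakAge - f2$peakAge, diffCi = ci,
       nBoot = length(diffs))
}

#' Benjamini-Hochberg adjusted p-values alongside raw ones
#'
#' Convenience wrapper used for the 50-region univariate scans: returns
#' the input effects table with a `p_adj` column (BH across rows).
#' @param effects data.frame with a `p_value` column.
#' @export
adjustRegionPvalues <- function(effects) {
  effects$p_adj <- stats::p.adjust(effects$p_value, method = "BH")
  effects
}
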