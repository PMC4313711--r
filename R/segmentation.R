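#' @include AllClasses.R VolumeGrid.R
NULL

#' Fit a Gaussian intensity mixture within a brain mask by EM
#'
#' Classifies masked voxel intensities with a k-component Gaussian mixture
#' fitted by expectation-maximisation. Initialisation is a deterministic
#' quantile split of the masked intensity histogram; `jitter > 0` adds a
#' seeded random perturbation to the initial means. Iteration stops when
#' the log-likelihood gain drops below `tol` or after `maxIter` iterations
#' (with `maxIter = 0` the initialisation is returned unconverged).
#' Component standard deviations are floored at a small fraction of the
#' intensity range; a component that hits the floor is flagged via the
#' `clamped` slot.
#'
#' @param intensity a [VolumeGrid] of intensities.
#' @param brainMask a [VolumeGrid]; voxels with value >= 0.5 are used.
#' @param k number of components (default 3: CSF, GM, WM).
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param seed RNG seed, used only when `jitter > 0`.
#' @param jitter sd of the initial-mean perturbation, as a fraction of the
#'   intensity range (default 0 = fully deterministic).
#' @return a [MixtureFit] with components sorted by ascending mean.
#' @export
fitTissueMixture <- function(intensity, brainMask, k = 3L, tol = 1e-6,
                             maxIter = 200L, seed = 1L, jitter = 0) {
  x <- intensity@values[brainMask@values >= 0.5]
  if (length(x) < k)
    stop("fewer masked voxels (", length(x), ") than mixture components")
  if (any(!is.finite(x))) stop("non-finite intensities inside the mask")
  rng <- diff(range(x))
  sdFloor <- max(rng, 1e-8) * 1e-4

  qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  if (jitter > 0)
    qs <- withSeed(seed, qs + stats::rnorm(k, 0, jitter * max(rng, 1e-8)))
  mu <- as.numeric(qs)
  # a heavily skewed histogram can make quantile centres coincide; spread
  # them evenly over the intensity range instead
  if (k > 1 && min(diff(sort(mu))) <= 0)
    mu <- min(x) + (seq_len(k) - 0.5) / k * rng
  # deterministic Lloyd refinement of the initial split: keeps small,
  # well-separated classes (e.g. CSF at low noise) from being swallowed
  # by the dominant one
  if (k > 1 && min(diff(sort(mu))) > 0 && maxIter > 0) {
    km <- suppressWarnings(tryCatch(
      stats::kmeans(x, centers = sort(mu), iter.max = 10L,
                    algorithm = "Lloyd"),
      error = function(e) NULL))
    if (!is.null(km) && nrow(km$centers) == k) mu <- as.numeric(km$centers)
  }
  sigma <- rep(max(stats::sd(x) / k, sdFloor), k)
  w <- rep(1 / k, k)

  loglikOf <- function(mu, sigma, w) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(length(x)))
    sum(log(pmax(rowSums(dens), .Machine$double.xmin)))
  }
  trace <- loglikOf(mu, sigma, w)
  converged <- FALSE
  clamped <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(length(x)))
    tot <- pmax(rowSums(dens), .Machine$double.xmin)
    r <- dens / tot
    nj <- colSums(r)
    w <- nj / length(x)
    mu <- colSums(r * x) / nj
    sigma <- sqrt(colSums(r * (outer(x, mu, "-"))^2) / nj)
    if (any(sigma < sdFloor)) {
      clamped <- TRUE
      sigma <- pmax(sigma, sdFloor)
    }
    ll <- loglikOf(mu, sigma, w)
    trace <- c(trace, ll)
    if (ll - trace[length(trace) - 1L] < tol) {
      converged <- TRUE
      break
    }
  }
  ord <- order(mu)
  new("MixtureFit", means = mu[ord], sds = sigma[ord], weights = w[ord],
      loglik = trace, nIter = it, converged = converged, clamped = clamped)
}

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: %d components, %d iterations, %s\n",
              length(object@means), object@nIter,
              if (object@converged) "converged" else "not converged"))
  print(data.frame(mean = round(object@means, 3),
                   sd = round(object@sds, 3),
                   weight = round(object@weights, 4)))
  invisible(object)
})

#' Posterior partial-volume maps from a fitted mixture
#'
#' Computes per-voxel posterior responsibilities of the three mixture
#' components and assigns them to tissues by ascending mean — CSF, GM, WM
#' under T1 contrast. Maps are zero outside the brain mask.
#'
#' @param intensity a [VolumeGrid].
#' @param brainMask a [VolumeGrid] (binary; values >= 0.5 are inside).
#' @param fit a 3-component [MixtureFit]; non-distinct component means are
#'   an error (the tissue assignment would be undefined).
#' @return a [TissueMaps].
#' @export
pveFromFit <- function(intensity, brainMask, fit) {
  if (length(fit@means) != 3L)
    stop("pveFromFit requires a 3-component fit")
  if (min(diff(sort(fit@means))) < 1e-9)
    stop("component means are not distinct; tissue assignment undefined")
  m <- brainMask@values >= 0.5
  x <- intensity@values[m]
  dens <- vapply(1:3,
                 function(j) fit@weights[j] * stats::dnorm(x, fit@means[j],
                                                           fit@sds[j]),
                 numeric(length(x)))
  tot <- rowSums(dens)
  # all densities underflown (possible with near-point-mass components):
  # fall back to hard assignment by nearest mean
  dead <- tot <= 0
  if (any(dead)) {
    nearest <- apply(abs(outer(x[dead], fit@means, "-")), 1, which.min)
    dens[dead, ] <- 0
    dens[cbind(which(dead), nearest)] <- 1
    tot[dead] <- 1
  }
  ord <- order(fit@means)   # ascending: CSF, GM, WM
  mk <- function(j) {
    a <- array(0, dim(intensity@values))
    a[m] <- dens[, ord[j]] / tot
    new("VolumeGrid", values = a, spacing = intensity@spacing,
        affine = intensity@affine)
  }
  new("TissueMaps", gm = mk(2), wm = mk(3), csf = mk(1),
      brainMask = new("VolumeGrid", values = m * 1,
                      spacing = brainMask@spacing,
                      affine = brainMask@affine))
}

#' Write tissue maps as three NIfTI files with a JSON sidecar
#'
#' @param maps a [TissueMaps].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param fit optional [MixtureFit] recorded in the sidecar.
#' @return the sidecar path, invisibly.
#' @export
writeTissueMaps <- function(maps, dir, prefix = "subject", fit = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in c("gm", "wm", "csf"))
    writeVolume(slot(maps, t), file.path(dir, paste0(prefix, "_", t,
                                                     "_pve.nii.gz")))
  writeVolume(maps@brainMask, file.path(dir, paste0(prefix,
                                                    "_brain_mask.nii.gz")))
  side <- list(tissues = c("gm", "wm", "csf"))
  if (!is.null(fit))
    side$mixture <- list(means = fit@means, sds = fit@sds,
                         weights = fit@weights, nIter = fit@nIter,
                         converged = fit@converged)
  p <- file.path(dir, paste0(prefix, "_pve.json"))
  jsonlite::write_json(side, p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Read tissue maps written by [writeTissueMaps()]
#' @inheritParams writeTissueMaps
#' @return a [TissueMaps].
#' @export
readTissueMaps <- function(dir, prefix = "subject") {
  rd <- function(t) readVolume(file.path(dir, paste0(prefix, "_", t,
                                                     ifelse(t == "brain_mask",
                                                            ".nii.gz",
                                                            "_pve.nii.gz"))))
  new("TissueMaps", gm = rd("gm"), wm = rd("wm"), csf = rd("csf"),
      brainMask = rd("brain_mask"))
}
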