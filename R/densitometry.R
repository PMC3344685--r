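#' Render a synthetic stained-nuclei image
#'
#' Single-channel transmitted-light image of immunostained nuclei on a
#' bright background: nuclei are ellipses with a Gaussian absorbance
#' profile, so the transmitted intensity at distance d from a nucleus
#' center is `I0 * 10^(-A_max * exp(-d^2 / (2 sigma^2)))` with
#' `A_max = -log10(transmittance)`. Lower `transmittance` means darker
#' (more strongly stained) nuclei and hence higher integrated optical
#' density. Images are 8-bit by default; color deconvolution of real
#' chromogens is out of scope — staining lives on one channel.
#'
#' @param width,height image size in pixels.
#' @param n_nuclei number of nuclei; centers keep `margin` pixels from
#'   the border so fixed rectangles can be cut around every nucleus.
#' @param transmittance fraction of incident light transmitted at the
#'   nucleus center, in `(0, 1]`.
#' @param nucleus_radius nominal nucleus radius in pixels (Gaussian sigma
#'   is half of it); per-nucleus radii jitter by +/-20%.
#' @param incident incident (background) intensity `I0`.
#' @param noise_sd multiplicative log10-absorbance jitter between nuclei.
#' @param margin border margin in pixels.
#' @param rng_seed integer seed.
#' @return An object of class `nuclei_image`: `pixels` (matrix),
#'   `centers` (data frame), `incident`.
#' @export
render_nuclei_image <- function(width = 512, height = 512, n_nuclei = 40,
                                transmittance = 0.35, nucleus_radius = 8,
                                incident = 255, noise_sd = 0.1,
                                margin = 16, rng_seed = 1L) {
  stopifnot(transmittance > 0, transmittance <= 1, incident > 0,
            n_nuclei >= 0)
  img <- matrix(incident, width, height)
  centers <- with_seed(rng_seed, {
    cx <- runif(n_nuclei, margin, width - margin)
    cy <- runif(n_nuclei, margin, height - margin)
    rr <- nucleus_radius * runif(n_nuclei, 0.8, 1.2)
    amax <- -log10(transmittance) * pmax(0.2, 1 + rnorm(n_nuclei, 0, noise_sd))
    ecc <- runif(n_nuclei, 0.7, 1)       # ellipse axis ratio
    ang <- runif(n_nuclei, 0, pi)
    data.frame(x = cx, y = cy, radius = rr, amax = amax, ecc = ecc,
               angle = ang)
  })
  if (n_nuclei > 0) {
    A <- matrix(0, width, height)
    for (k in seq_len(n_nuclei)) {
      r <- centers$radius[k]
      win <- ceiling(3 * r)
      xs <- max(1, floor(centers$x[k] - win)):min(width, ceiling(centers$x[k] + win))
      ys <- max(1, floor(centers$y[k] - win)):min(height, ceiling(centers$y[k] + win))
      dx <- outer(xs - centers$x[k], rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - centers$y[k])
      ca <- cos(centers$angle[k]); sa <- sin(centers$angle[k])
      u <- dx * ca + dy * sa
      v <- (-dx * sa + dy * ca) / centers$ecc[k]
      sig <- r / 2
      A[xs, ys] <- A[xs, ys] +
        centers$amax[k] * exp(-(u^2 + v^2) / (2 * sig^2))
    }
    img <- incident * 10^(-A)
  }
  structure(list(pixels = round(img), centers = centers,
                 incident = incident), class = "nuclei_image")
}

#' Optical density map of a transmitted-intensity image
#'
#' Standard Beer-Lambert densitometry with a white (fully transmitting)
#' reference: per pixel `OD = log10(incident_reference / max(I, 1))`,
#' capped at `ceiling` (default 3) to bound the logarithm on near-opaque
#' pixels. OD is 0 for pixels at the reference intensity and increases as
#' transmittance drops; multiplying all intensities and the reference by
#' a common factor leaves the map unchanged.
#'
#' @param intensities numeric matrix (or vector) of pixel intensities.
#' @param incident_reference incident intensity; must be positive.
#' @param ceiling OD cap.
#' @return OD values, same shape as the input.
#' @export
od_map <- function(intensities, incident_reference, ceiling = 3) {
  if (incident_reference <= 0)
    stop("incident reference intensity must be positive (bad calibration)")
  pmin(log10(incident_reference / pmax(intensities, 1)), ceiling)
}

#' Integrated optical density over a nucleus rectangle
#'
#' `IOD = sum of per-pixel OD` over the ROI, the semi-quantitative
#' immunostaining readout: dimensionless OD times pixel count.
#'
#' @param roi a `nucleus_roi` (see [sample_nuclei()]) or a plain
#'   intensity matrix.
#' @param incident_reference incident intensity; defaults to the ROI's
#'   recorded reference.
#' @param ceiling OD cap, as in [od_map()].
#' @return The IOD (nonnegative scalar).
#' @export
integrated_od <- function(roi, incident_reference = NULL, ceiling = 3) {
  px <- if (inherits(roi, "nucleus_roi")) roi$pixels else roi
  if (is.null(incident_reference)) {
    if (!inherits(roi, "nucleus_roi"))
      stop("incident_reference required for a plain matrix")
    incident_reference <- roi$incident
  }
  sum(od_map(px, incident_reference, ceiling))
}

#' Randomly select nucleus ROIs from rendered images
#'
#' Cuts a rectangle of fixed size (constant across the study) centered on
#' each selected nucleus. Selection is uniform without replacement within
#' each group, `n_per_group` nuclei per group (default 100), and errors
#' when fewer nuclei are available than requested.
#'
#' @param images named list (one element per group) of `nuclei_image`
#'   objects or lists of them.
#' @param n_per_group nuclei to select per group.
#' @param roi_width,roi_height rectangle size in pixels.
#' @param rng_seed integer seed.
#' @return List of `nucleus_roi` objects: `pixels`, `group`, `incident`.
#' @export
sample_nuclei <- function(images, n_per_group = 100L, roi_width = 16L,
                          roi_height = 16L, rng_seed = 1L) {
  stopifnot(n_per_group >= 1)
  if (is.null(names(images))) stop("images must be a named list of groups")
  rois <- list()
  with_seed(rng_seed, {
    for (g in names(images)) {
      imgs <- images[[g]]
      if (inherits(imgs, "nuclei_image")) imgs <- list(imgs)
      pool <- do.call(rbind, lapply(seq_along(imgs), function(k) {
        cbind(img = k, imgs[[k]]$centers[, c("x", "y")])
      }))
      if (is.null(pool) || nrow(pool) < n_per_group)
        stop("group '", g, "' has ", if (is.null(pool)) 0 else nrow(pool),
             " nuclei, fewer than the ", n_per_group, " requested")
      pick <- sample.int(nrow(pool), n_per_group)
      for (p in pick) {
        im <- imgs[[pool$img[p]]]
        cx <- round(pool$x[p]); cy <- round(pool$y[p])
        xs <- (cx - floor(roi_width / 2)):(cx + ceiling(roi_width / 2) - 1)
        ys <- (cy - floor(roi_height / 2)):(cy + ceiling(roi_height / 2) - 1)
        xs <- pmin(pmax(xs, 1), nrow(im$pixels))
        ys <- pmin(pmax(ys, 1), ncol(im$pixels))
        rois[[length(rois) + 1L]] <-
          structure(list(pixels = im$pixels[xs, ys], group = g,
                         incident = im$incident), class = "nucleus_roi")
      }
    }
  })
  rois
}

#' Per-group IOD summary
#'
#' @param rois list of `nucleus_roi` objects from [sample_nuclei()].
#' @param ceiling OD cap, as in [od_map()].
#' @return Data frame with group, mean IOD, SD and n.
#' @export
iod_group_summary <- function(rois, ceiling = 3) {
  iod <- vapply(rois, integrated_od, numeric(1), ceiling = ceiling)
  grp <- vapply(rois, function(r) r$group, character(1))
  out <- data.frame(group = unique(grp))
  out$mean_iod <- vapply(out$group, function(g) mean(iod[grp == g]), numeric(1))
  out$sd_iod <- vapply(out$group, function(g) sd(iod[grp == g]), numeric(1))
  out$n <- vapply(out$group, function(g) sum(grp == g), numeric(1))
  out
}
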