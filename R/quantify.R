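#' Segment the nucleus from the DAPI channel
#'
#' Global Otsu thresholding, 3D morphological closing (ellipsoidal element,
#' 2 voxels radius laterally, scaled for axial anisotropy) and selection of
#' the largest 6-connected foreground component. The nuclear volume is the
#' voxel count times the physical voxel volume.
#'
#' @param dapi A DAPI [image_stack()].
#' @return A `nucleus_mask` object: logical `mask` array, `centroid_nm`
#'   (z, y, x), `volume_um3`, `spacing`.
#' @export
segment_nucleus <- function(dapi) {
  stopifnot(inherits(dapi, "image_stack"))
  v <- dapi$voxels
  if (length(v) == 0) abort("empty stack")
  thr <- otsu_threshold(as.numeric(v))
  fg <- v > thr
  if (mean(fg) < 0.001 || all(fg) ) {
    abort("no nucleus found: foreground fraction below 0.1% of voxels")
  }
  sp <- dapi$spacing
  rad <- c(max(1L, as.integer(round(2 * sp$dx / sp$dz))), 2L, 2L)
  dim(fg) <- dim(v)
  fg <- .cpp_binary_closing3d(fg, rad)
  lab <- .cpp_label_components3d(fg)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) == 0) abort("no nucleus found: no foreground component")
  keep <- which.max(tab)
  mask <- lab == keep
  dim(mask) <- dim(v)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(z = mean(idx[, 1] - 0.5) * sp$dz,
                y = mean(idx[, 2] - 0.5) * sp$dy,
                x = mean(idx[, 3] - 0.5) * sp$dx)
  vol <- sum(mask) * sp$dx * sp$dy * sp$dz / 1e9
  structure(list(mask = mask, centroid_nm = centroid, volume_um3 = vol,
                 spacing = sp), class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %.1f um^3, centroid (z,y,x) = %.0f/%.0f/%.0f nm\n",
              x$volume_um3, x$centroid_nm[1], x$centroid_nm[2], x$centroid_nm[3]))
  invisible(x)
}

# Otsu's threshold on a 256-bin histogram
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Classify CD34 status from the FITC channel
#'
#' A nucleus is CD34 positive iff the mean FITC intensity inside its mask
#' reaches `threshold` (boundary inclusive).
#'
#' @param fitc A FITC [image_stack()].
#' @param mask A [segment_nucleus()] result from the same nucleus.
#' @param threshold Mean-intensity threshold (a.u.).
#' @return Logical flag.
#' @export
classify_cd34 <- function(fitc, mask, threshold = 0.2) {
  stopifnot(inherits(fitc, "image_stack"), inherits(mask, "nucleus_mask"))
  if (!identical(dim(fitc$voxels), dim(mask$mask))) {
    abort("FITC stack and nucleus mask have different shapes")
  }
  mean(fitc$voxels[mask$mask]) >= threshold
}

#' Detect 3D telomere spots in the Cy3 channel
#'
#' Spots are local maxima of an anisotropy-corrected
#' Laplacian-of-Gaussian response (Gaussian smoothing at the PSF scale,
#' then a spacing-weighted negated Laplacian) inside the nuclear mask,
#' thresholded against a robust noise estimate. Each detection gets an
#' intensity-weighted sub-voxel centroid and a background-corrected
#' integrated intensity measured in an ellipsoidal aperture of
#' `aperture_sigmas` PSF sigmas, with an aperture correction calibrated on
#' a unit spot rendered on the same grid so that integrated intensity is an
#' unbiased estimate of total spot flux.
#'
#' @param cy3 A Cy3 [image_stack()].
#' @param mask A [segment_nucleus()] result.
#' @param log_sigma_nm Smoothing scale `c(x, y, z)` nm (default = PSF sigma).
#' @param snr_threshold Detection threshold in robust noise sigmas of the
#'   response inside the mask.
#' @param min_rel_response Floor on the threshold as a fraction of the
#'   maximum response (guards the noise-free limit).
#' @param aperture_sigmas Photometry aperture radius in PSF sigmas.
#' @return A tibble of detections: `x_nm`, `y_nm`, `z_nm`, `intensity`,
#'   `response`; attribute `background` holds the background estimate.
#' @export
detect_spots <- function(cy3, mask, log_sigma_nm = c(150, 150, 300),
                         snr_threshold = 6, min_rel_response = 0.08,
                         aperture_sigmas = 2.5) {
  stopifnot(inherits(cy3, "image_stack"), inherits(mask, "nucleus_mask"))
  sp <- cy3$spacing
  v <- cy3$voxels
  sigma_vox <- c(log_sigma_nm[3] / sp$dz, log_sigma_nm[2] / sp$dy,
                 log_sigma_nm[1] / sp$dx)
  sm <- .cpp_gaussian_blur3d(v, sigma_vox)
  resp <- .cpp_neg_laplacian3d(sm, spacing_zyx(sp))
  inside <- resp[mask$mask]
  noise <- stats::mad(inside)
  thr <- max(snr_threshold * noise, min_rel_response * max(resp[mask$mask], 0))
  hits <- .cpp_local_maxima3d(resp, mask$mask, thr)
  empty <- tibble(x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
                  intensity = numeric(0), response = numeric(0))
  if (length(hits) == 0) {
    attr(empty, "background") <- stats::median(v[mask$mask])
    return(empty)
  }
  d <- dim(v)
  ai <- arrayInd(hits, d)

  # aperture geometry (voxel offsets within aperture_sigmas PSF sigmas)
  rz <- ceiling(aperture_sigmas * log_sigma_nm[3] / sp$dz)
  ry <- ceiling(aperture_sigmas * log_sigma_nm[2] / sp$dy)
  rx <- ceiling(aperture_sigmas * log_sigma_nm[1] / sp$dx)
  off <- expand.grid(dz = -rz:rz, dy = -ry:ry, dx = -rx:rx)
  q <- (off$dz * sp$dz / log_sigma_nm[3])^2 +
       (off$dy * sp$dy / log_sigma_nm[2])^2 +
       (off$dx * sp$dx / log_sigma_nm[1])^2
  off <- off[q <= aperture_sigmas^2, ]

  # background: median Cy3 inside the mask, excluding detection apertures
  excl <- array(FALSE, d)
  for (i in seq_len(nrow(ai))) {
    z <- ai[i, 1] + off$dz; y <- ai[i, 2] + off$dy; x <- ai[i, 3] + off$dx
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    excl[cbind(z[ok], y[ok], x[ok])] <- TRUE
  }
  bg_vox <- mask$mask & !excl
  background <- if (any(bg_vox)) stats::median(v[bg_vox]) else
    stats::median(v[mask$mask])

  # aperture correction: fraction of a unit spot's flux falling in the
  # aperture when rendered on this grid
  apcor <- aperture_correction(log_sigma_nm, sp, off)

  res <- vector("list", nrow(ai))
  for (i in seq_len(nrow(ai))) {
    z <- ai[i, 1] + off$dz; y <- ai[i, 2] + off$dy; x <- ai[i, 3] + off$dx
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    vals <- v[cbind(z[ok], y[ok], x[ok])] - background
    w <- pmax(vals, 0)
    cz <- (sum(w * (z[ok] - 0.5)) / sum(w)) * sp$dz
    cy <- (sum(w * (y[ok] - 0.5)) / sum(w)) * sp$dy
    cx <- (sum(w * (x[ok] - 0.5)) / sum(w)) * sp$dx
    res[[i]] <- tibble(x_nm = cx, y_nm = cy, z_nm = cz,
                       intensity = sum(vals) / apcor,
                       response = resp[hits[i]])
  }
  out <- bind_rows(res)
  out <- out[out$intensity > 0, ]
  attr(out, "background") <- background
  out
}

# fraction of a unit-flux PSF spot captured by the aperture when rendered
# on this voxel grid (midpoint mass per voxel)
aperture_correction <- function(sigma_nm, sp, off) {
  gz <- stats::dnorm(off$dz * sp$dz, 0, sigma_nm[3]) * sp$dz
  gy <- stats::dnorm(off$dy * sp$dy, 0, sigma_nm[2]) * sp$dy
  gx <- stats::dnorm(off$dx * sp$dx, 0, sigma_nm[1]) * sp$dx
  sum(gz * gy * gx)
}

#' Flag telomere aggregates among detected signals
#'
#' A detection is called an aggregate when its integrated intensity exceeds
#' `intensity_factor` times the nucleus' median detection intensity (an
#' unresolvable cluster carries the summed flux of its members), or when a
#' group of detections sits within the optical resolution limit of each
#' other (anisotropy-scaled pairwise distance below
#' `resolution_limit_nm`); such a group is one aggregate.
#'
#' @param signals A [detect_spots()] tibble.
#' @param resolution_limit_nm `c(lateral, axial)` nm.
#' @param intensity_factor Multiplier of the median integrated intensity
#'   above which a single detection is called an aggregate.
#' @return `signals` with `is_aggregate` (logical) and `aggregate_id`
#'   (integer, `NA` for non-aggregates) columns; the number of distinct
#'   aggregates is `n_distinct(aggregate_id)` over flagged rows.
#' @export
call_aggregates <- function(signals,
                            resolution_limit_nm = c(lateral = 200, axial = 500),
                            intensity_factor = 1.8) {
  n <- nrow(signals)
  if (n == 0) {
    signals$is_aggregate <- logical(0)
    signals$aggregate_id <- integer(0)
    return(signals)
  }
  med <- stats::median(signals$intensity)
  bright <- signals$intensity > intensity_factor * med

  # proximity clusters: union-find over pairs below the resolution limit
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    sc <- cbind(signals$x_nm / resolution_limit_nm[1],
                signals$y_nm / resolution_limit_nm[1],
                signals$z_nm / resolution_limit_nm[2])
    dd <- as.matrix(stats::dist(sc))
    close_pairs <- which(dd < 1 & upper.tri(dd), arr.ind = TRUE)
    for (k in seq_len(nrow(close_pairs))) {
      a <- find(close_pairs[k, 1]); b <- find(close_pairs[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  csize <- table(root)
  in_cluster <- csize[as.character(root)] > 1

  flagged <- bright | as.vector(in_cluster)
  # aggregate identity: proximity clusters keep one id; bright singletons
  # get their own
  agg_id <- rep(NA_integer_, n)
  agg_id[flagged] <- match(root[flagged], unique(root[flagged]))
  signals$is_aggregate <- flagged
  signals$aggregate_id <- agg_id
  signals
}

#' Count distinct aggregates among called signals
#' @param signals Output of [call_aggregates()].
#' @return Integer aggregate count.
#' @export
count_aggregates <- function(signals) {
  if (!"aggregate_id" %in% names(signals)) abort("run call_aggregates() first")
  length(unique(signals$aggregate_id[signals$is_aggregate]))
}

#' Radial nuclear position of telomere signals
#'
#' For each signal, the distance from the nuclear centroid to the signal
#' divided by the distance from the centroid to the nuclear boundary along
#' the same ray, in physical nm (0 = centre, 1 = periphery), clamped to
#' `[0, 1]`.
#'
#' @param signals A detections tibble with `x_nm`, `y_nm`, `z_nm`.
#' @param mask A [segment_nucleus()] result.
#' @return Numeric vector of radial positions.
#' @export
radial_position <- function(signals, mask) {
  stopifnot(inherits(mask, "nucleus_mask"))
  n <- nrow(signals)
  if (n == 0) return(numeric(0))
  sp <- mask$spacing
  d <- dim(mask$mask)
  cen <- mask$centroid_nm
  inside <- function(p_nm) {
    iz <- ceiling(p_nm[1] / sp$dz); iy <- ceiling(p_nm[2] / sp$dy)
    ix <- ceiling(p_nm[3] / sp$dx)
    if (iz < 1 || iz > d[1] || iy < 1 || iy > d[2] || ix < 1 || ix > d[3]) {
      return(FALSE)
    }
    mask$mask[iz, iy, ix]
  }
  vapply(seq_len(n), function(i) {
    p <- c(signals$z_nm[i], signals$y_nm[i], signals$x_nm[i])
    if (!inside(p)) {
      abort("signal centroid lies outside the nuclear mask; radial position undefined")
    }
    u <- p - cen
    r_sig <- sqrt(sum(u^2))
    if (r_sig < 1e-9) return(0)
    u <- u / r_sig
    step <- min(sp$dx, sp$dy, sp$dz) / 2
    t <- r_sig
    while (inside(cen + u * (t + step))) t <- t + step
    min(r_sig / t, 1)
  }, numeric(1))
}

#' Quantify one nucleus from its rendered channels
#'
#' Convenience wrapper: segments the DAPI channel, optionally gates CD34 on
#' FITC, detects Cy3 spots, calls aggregates and computes radial positions.
#'
#' @param channels Named list of [image_stack()]s (needs `DAPI` and `Cy3`).
#' @param cd34_threshold FITC gating threshold, used when a FITC channel is
#'   present.
#' @param ... Passed to [detect_spots()].
#' @return List with `mask`, `signals` (with aggregate and radial columns)
#'   and `cd34_positive` (NA without a FITC channel).
#' @export
quantify_nucleus <- function(channels, cd34_threshold = 0.2, ...) {
  if (!all(c("DAPI", "Cy3") %in% names(channels))) {
    abort("quantify_nucleus() needs DAPI and Cy3 channels")
  }
  mask <- segment_nucleus(channels$DAPI)
  cd34 <- if ("FITC" %in% names(channels)) {
    classify_cd34(channels$FITC, mask, cd34_threshold)
  } else NA
  signals <- detect_spots(channels$Cy3, mask, ...)
  signals <- call_aggregates(signals)
  signals$radial_position <- radial_position(signals, mask)
  list(mask = mask, signals = signals, cd34_positive = cd34)
}
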