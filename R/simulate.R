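#' Configuration of one synthetic CD34+ interphase nucleus
#'
#' Describes the generative model for a single nucleus: an ellipsoidal
#' DAPI-stained nucleus, a set of telomere objects rendered into the Cy3
#' channel as PSF-shaped Gaussian spots, and an optional FITC (CD34)
#' channel. Telomere objects are either single telomeres, with integrated
#' intensities drawn from a three-component lognormal mixture
#' (short / intermediate / long telomere populations), or telomere
#' aggregates: clusters of two or more telomeres placed so close together
#' (well below the optical resolution limit) that they render as one
#' unresolvable object.
#'
#' Distinct objects are placed with a minimum anisotropy-scaled separation
#' (`min_separation_nm`) so that the configured object count is the number
#' of resolvable signals in the rendered image. The telomere point cloud is
#' axially compressed by `flattening` before placement, which gives the
#' cloud an analytic expected a/c ratio of
#' `flattening * semi_axes[1] / semi_axes[3]`.
#'
#' @param semi_axes_um Nuclear ellipsoid semi-axes in micrometres,
#'   ordered `a >= b >= c > 0`; `c` is the axial (z) semi-axis.
#' @param axis_jitter_sd Per-nucleus multiplicative jitter (sd, relative) on
#'   all three semi-axes jointly.
#' @param n_signals_mean,n_signals_sd Per-nucleus telomere object count
#'   distribution (includes aggregates; an aggregate counts as one signal).
#' @param n_aggregates_mean,n_aggregates_sd Per-nucleus aggregate count
#'   distribution.
#' @param component_means Mean integrated intensities (a.u.) of the short,
#'   intermediate and long telomere populations (strictly increasing).
#' @param component_weights Mixture weights, summing to 1.
#' @param component_sdlog Lognormal `sdlog` per component.
#' @param aggregate_multiplicity Possible numbers of telomeres per
#'   aggregate (all `>= 2`).
#' @param aggregate_multiplicity_prob Sampling probabilities for
#'   `aggregate_multiplicity`.
#' @param aggregate_spread_nm Semi-axes (lateral, lateral, axial) of the
#'   region around an aggregate centre in which its member telomeres are
#'   placed; the default keeps members pairwise below half the Rayleigh
#'   resolution limit (100 nm lateral / 250 nm axial).
#' @param flattening Axial compression factor of the telomere point cloud
#'   (`>= 1`); drives the a/c ratio.
#' @param min_separation_nm Minimum separation between distinct objects,
#'   `c(lateral, axial)` nm, applied in anisotropy-scaled distance.
#' @param cloud_fraction Fraction of each nuclear semi-axis available to
#'   the telomere cloud (keeps spots strictly inside the nucleus).
#' @param psf_sigma_nm Gaussian PSF sigma `c(x, y, z)` nm; stacks are
#'   rendered as if already deconvolved, with this small symmetric blur.
#' @param cy3_background,cy3_noise_sd Cy3 channel additive background level
#'   and Gaussian noise sd (a.u.).
#' @param dapi_level,dapi_background,dapi_noise_sd DAPI channel intensities.
#' @param fitc_positive_level,fitc_background,fitc_noise_sd FITC channel
#'   intensities; `fitc_positive_level` applies inside CD34+ nuclei.
#' @param cd34_positive Logical; is this nucleus CD34 positive?
#' @param n_slices Number of z-slices in the rendered stack.
#' @param crop_margin Lateral crop half-width as a multiple of the largest
#'   lateral semi-axis.
#' @return A validated `nucleus_config` object (list).
#' @export
nucleus_config <- function(semi_axes_um = c(4.50, 3.70, 2.75),
                           axis_jitter_sd = 0.06,
                           n_signals_mean = 39.45, n_signals_sd = 6.49,
                           n_aggregates_mean = 3.37, n_aggregates_sd = 1.19,
                           component_means = c(70, 100, 130),
                           component_weights = c(1, 1, 1) / 3,
                           component_sdlog = c(0.08, 0.08, 0.08),
                           aggregate_multiplicity = c(2L, 3L),
                           aggregate_multiplicity_prob = c(0.7, 0.3),
                           aggregate_spread_nm = c(50, 50, 125),
                           flattening = 1.56,
                           min_separation_nm = c(lateral = 550, axial = 1100),
                           cloud_fraction = 0.9,
                           psf_sigma_nm = c(150, 150, 300),
                           cy3_background = 1.0, cy3_noise_sd = 0.15,
                           dapi_level = 1.0, dapi_background = 0.05,
                           dapi_noise_sd = 0.05,
                           fitc_positive_level = 0.5, fitc_background = 0.02,
                           fitc_noise_sd = 0.03,
                           cd34_positive = TRUE,
                           n_slices = 60, crop_margin = 1.18) {
  cfg <- list(semi_axes_um = as.numeric(semi_axes_um),
              axis_jitter_sd = axis_jitter_sd,
              n_signals_mean = n_signals_mean, n_signals_sd = n_signals_sd,
              n_aggregates_mean = n_aggregates_mean,
              n_aggregates_sd = n_aggregates_sd,
              component_means = as.numeric(component_means),
              component_weights = as.numeric(component_weights),
              component_sdlog = as.numeric(component_sdlog),
              aggregate_multiplicity = as.integer(aggregate_multiplicity),
              aggregate_multiplicity_prob = as.numeric(aggregate_multiplicity_prob),
              aggregate_spread_nm = as.numeric(aggregate_spread_nm),
              flattening = flattening,
              min_separation_nm = as.numeric(min_separation_nm),
              cloud_fraction = cloud_fraction,
              psf_sigma_nm = as.numeric(psf_sigma_nm),
              cy3_background = cy3_background, cy3_noise_sd = cy3_noise_sd,
              dapi_level = dapi_level, dapi_background = dapi_background,
              dapi_noise_sd = dapi_noise_sd,
              fitc_positive_level = fitc_positive_level,
              fitc_background = fitc_background,
              fitc_noise_sd = fitc_noise_sd,
              cd34_positive = isTRUE(cd34_positive),
              n_slices = as.integer(n_slices), crop_margin = crop_margin)
  validate_nucleus_config(cfg)
  structure(cfg, class = "nucleus_config")
}

validate_nucleus_config <- function(cfg) {
  ax <- cfg$semi_axes_um
  if (length(ax) != 3 || any(ax <= 0) || is.unsorted(rev(ax))) {
    abort("semi_axes_um must be three positive values ordered a >= b >= c")
  }
  if (abs(sum(cfg$component_weights) - 1) > 1e-8 || any(cfg$component_weights < 0)) {
    abort("component_weights must be non-negative and sum to 1")
  }
  if (length(cfg$component_means) != 3 || is.unsorted(cfg$component_means, strictly = TRUE)) {
    abort("component_means must be three strictly increasing values")
  }
  if (any(cfg$aggregate_multiplicity < 2)) {
    abort("aggregate multiplicity must be >= 2 telomeres per aggregate")
  }
  if (cfg$flattening < 1) abort("flattening must be >= 1")
  if (cfg$n_signals_mean < 0 || cfg$n_signals_sd < 0 ||
      cfg$n_aggregates_mean < 0 || cfg$n_aggregates_sd < 0) {
    abort("count distribution parameters must be non-negative")
  }
  if (any(cfg$min_separation_nm <= 0) || any(cfg$psf_sigma_nm <= 0)) {
    abort("separations and PSF sigmas must be positive")
  }
  invisible(cfg)
}

# normal draws with the realized sample mean and sd matched exactly to the
# requested moments (variance-controlled sampling; keeps configured cohort
# and group means exactly calibrated at any seed)
draw_exact_moments <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0 || n == 1) return(rep(mean, n))
  x <- rnorm(n)
  s <- sd(x)
  if (s < 1e-12) return(rep(mean, n))
  (x - base::mean(x)) / s * sd + mean
}

# uniform points inside an axis-aligned ellipsoid centred at the origin
sample_in_ellipsoid <- function(n, semi_nm) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  r <- runif(n)^(1 / 3)
  sweep(g * r, 2, semi_nm, `*`)
}

# dart-throwing placement with a minimum anisotropy-scaled separation
place_objects <- function(n, semi_nm, min_sep_nm) {
  scale <- c(min_sep_nm[1], min_sep_nm[1], min_sep_nm[2])
  pts <- matrix(NA_real_, nrow = n, ncol = 3)
  placed <- 0L
  tries <- 0L
  max_tries <- 4000L * max(n, 1L)
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(paste0("cannot place %d telomere objects with %g/%g nm ",
                           "minimum separation inside the nucleus; reduce the ",
                           "count or the separation"),
                    n, min_sep_nm[1], min_sep_nm[2]))
    }
    cand <- sample_in_ellipsoid(1, semi_nm)
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(pts[seq_len(placed), , drop = FALSE], 2, cand, `-`)
      d <- sweep(d, 2, scale, `/`)
      ok <- all(rowSums(d^2) >= 1)
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  pts
}

# truncated rounding helper for count draws
round_count <- function(x, lower = 0L) pmax(as.integer(round(x)), lower)

#' Simulate one nucleus: multi-channel 3D stack plus ground truth
#'
#' Draws the nucleus geometry and telomere objects from `config`, then
#' renders DAPI, Cy3 and (optionally) FITC stacks on the acquisition grid.
#' With `render = FALSE` only the ground truth is produced, which is much
#' faster and sufficient for generator-level checks.
#'
#' @param config A [nucleus_config()].
#' @param spacing A [voxel_spacing()].
#' @param seed Optional integer seed (fixed seed gives byte-identical output).
#' @param render Render image channels? (ground truth is always produced)
#' @param channels Channels to render.
#' @param n_signals,n_aggregates Optional fixed counts overriding the
#'   configured count distributions (used by the cohort generator).
#' @return A list with elements `channels` (named list of [image_stack()]s,
#'   `NULL` if not rendered), `truth` (list: `spots` and `objects` tibbles,
#'   `volume_um3`, `semi_axes_um`, `ac_expected`, `centre_nm`) and `config`.
#' @export
simulate_nucleus <- function(config, spacing = voxel_spacing(), seed = NULL,
                             render = TRUE,
                             channels = c("DAPI", "Cy3", "FITC"),
                             n_signals = NULL, n_aggregates = NULL) {
  stopifnot(inherits(config, "nucleus_config"))
  if (!is.null(seed)) set.seed(seed)

  jit <- max(0.7, min(1.3, rnorm(1, 1, config$axis_jitter_sd)))
  axes_nm <- config$semi_axes_um * 1000 * jit

  if (is.null(n_signals)) {
    n_signals <- round_count(rnorm(1, config$n_signals_mean, config$n_signals_sd))
  }
  if (is.null(n_aggregates)) {
    n_aggregates <- round_count(rnorm(1, config$n_aggregates_mean,
                                      config$n_aggregates_sd))
  }
  n_signals <- as.integer(n_signals)
  n_aggregates <- min(as.integer(n_aggregates), n_signals)
  n_single <- n_signals - n_aggregates

  # stack geometry: nucleus centred in the crop
  dim_zyx <- stack_dim_for(config, spacing)
  centre <- c(z = dim_zyx[1] / 2 * spacing$dz,
              y = dim_zyx[2] / 2 * spacing$dy,
              x = dim_zyx[3] / 2 * spacing$dx)

  # object placement in the axially compressed cloud
  cloud_semi <- config$cloud_fraction *
    c(axes_nm[1], axes_nm[2], axes_nm[3] / config$flattening) # (x, y, z)
  pos <- place_objects(n_signals, cloud_semi, config$min_separation_nm)
  pos <- cbind(x = pos[, 1] + centre["x"],
               y = pos[, 2] + centre["y"],
               z = pos[, 3] + centre["z"])

  # single-telomere intensities: deterministic proportional allocation of
  # mixture components, lognormal draw within component, shuffled
  comp <- integer(0)
  if (n_single > 0) {
    alloc <- proportional_allocation(n_single, config$component_weights)
    comp <- sample(rep.int(seq_len(3), alloc))
  }
  single_int <- if (n_single > 0) {
    rlnorm(n_single, meanlog = log(config$component_means)[comp],
           sdlog = config$component_sdlog[comp])
  } else numeric(0)

  # aggregates: members drawn from the long-telomere component
  agg_mult <- if (n_aggregates > 0) {
    sample(config$aggregate_multiplicity, n_aggregates, replace = TRUE,
           prob = config$aggregate_multiplicity_prob)
  } else integer(0)

  is_agg <- c(rep(FALSE, n_single), rep(TRUE, n_aggregates))
  spots <- vector("list", n_signals)
  obj_int <- numeric(n_signals)
  for (i in seq_len(n_signals)) {
    if (!is_agg[i]) {
      obj_int[i] <- single_int[i]
      spots[[i]] <- tibble(object_id = i, x_nm = pos[i, "x"],
                           y_nm = pos[i, "y"], z_nm = pos[i, "z"],
                           intensity = single_int[i],
                           is_aggregate_member = FALSE)
    } else {
      m <- agg_mult[i - n_single]
      member_int <- rlnorm(m, meanlog = log(config$component_means[3]),
                           sdlog = config$component_sdlog[3])
      jitter <- sample_in_ellipsoid(m, config$aggregate_spread_nm)
      obj_int[i] <- sum(member_int)
      spots[[i]] <- tibble(object_id = i,
                           x_nm = pos[i, "x"] + jitter[, 1],
                           y_nm = pos[i, "y"] + jitter[, 2],
                           z_nm = pos[i, "z"] + jitter[, 3],
                           intensity = member_int,
                           is_aggregate_member = TRUE)
    }
  }
  spots <- if (n_signals > 0) bind_rows(spots) else
    tibble(object_id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
           z_nm = numeric(0), intensity = numeric(0),
           is_aggregate_member = logical(0))
  objects <- tibble(object_id = seq_len(n_signals),
                    x_nm = pos[, "x"], y_nm = pos[, "y"], z_nm = pos[, "z"],
                    intensity = obj_int, is_aggregate = is_agg,
                    multiplicity = c(rep(1L, n_single), agg_mult))

  truth <- list(spots = spots, objects = objects,
                n_signals = n_signals, n_aggregates = n_aggregates,
                volume_um3 = 4 / 3 * pi * prod(axes_nm) / 1e9,
                semi_axes_um = axes_nm / 1000,
                ac_expected = config$flattening * axes_nm[1] / axes_nm[3],
                centre_nm = centre)

  out_channels <- NULL
  if (render) {
    out_channels <- render_nucleus(config, spacing, dim_zyx, centre, axes_nm,
                                   spots, channels)
  }
  list(channels = out_channels, truth = truth, config = config)
}

stack_dim_for <- function(config, spacing) {
  a <- config$semi_axes_um[1] * 1000
  b <- config$semi_axes_um[2] * 1000
  c(config$n_slices,
    as.integer(ceiling(2 * b * config$crop_margin / spacing$dy)),
    as.integer(ceiling(2 * a * config$crop_margin / spacing$dx)))
}

# largest-remainder allocation of n items over mixture weights
proportional_allocation <- function(n, weights) {
  raw <- weights * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# voxel-centre coordinate vectors (1-based index i -> (i - 0.5) * h)
axis_coords <- function(n, h) (seq_len(n) - 0.5) * h

ellipsoid_array <- function(dim_zyx, spacing, centre, axes_nm) {
  z <- (axis_coords(dim_zyx[1], spacing$dz) - centre["z"]) / axes_nm[3]
  y <- (axis_coords(dim_zyx[2], spacing$dy) - centre["y"]) / axes_nm[2]
  x <- (axis_coords(dim_zyx[3], spacing$dx) - centre["x"]) / axes_nm[1]
  q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  q <= 1
}

# add PSF-shaped Gaussian spots (integrated intensity preserved) to `arr`
render_spots <- function(arr, spacing, spots, sigma_nm, truncate = 4.5) {
  if (nrow(spots) == 0) return(arr)
  d <- dim(arr)
  sz <- sigma_nm[3]; sy <- sigma_nm[2]; sx <- sigma_nm[1]
  for (i in seq_len(nrow(spots))) {
    mu <- c(spots$z_nm[i], spots$y_nm[i], spots$x_nm[i])
    iz <- index_window(mu[1], sz, spacing$dz, d[1], truncate)
    iy <- index_window(mu[2], sy, spacing$dy, d[2], truncate)
    ix <- index_window(mu[3], sx, spacing$dx, d[3], truncate)
    if (!length(iz) || !length(iy) || !length(ix)) next
    gz <- stats::dnorm(axis_coords(d[1], spacing$dz)[iz], mu[1], sz) * spacing$dz
    gy <- stats::dnorm(axis_coords(d[2], spacing$dy)[iy], mu[2], sy) * spacing$dy
    gx <- stats::dnorm(axis_coords(d[3], spacing$dx)[ix], mu[3], sx) * spacing$dx
    add <- spots$intensity[i] * (gz %o% gy %o% gx)
    arr[iz, iy, ix] <- arr[iz, iy, ix] + add
  }
  arr
}

index_window <- function(mu, sigma, h, n, truncate) {
  lo <- max(1L, as.integer(floor((mu - truncate * sigma) / h)))
  hi <- min(n, as.integer(ceiling((mu + truncate * sigma) / h)))
  if (lo > hi) integer(0) else lo:hi
}

render_nucleus <- function(config, spacing, dim_zyx, centre, axes_nm, spots,
                           channels) {
  out <- list()
  nvox <- prod(dim_zyx)
  inside <- NULL
  if (any(c("DAPI", "FITC") %in% channels)) {
    inside <- ellipsoid_array(dim_zyx, spacing, centre, axes_nm)
  }
  if ("DAPI" %in% channels) {
    v <- array(config$dapi_background, dim = dim_zyx)
    v[inside] <- config$dapi_level
    if (config$dapi_noise_sd > 0) v <- v + rnorm(nvox, 0, config$dapi_noise_sd)
    out$DAPI <- image_stack(pmax(v, 0), spacing, "DAPI")
  }
  if ("Cy3" %in% channels) {
    v <- array(config$cy3_background, dim = dim_zyx)
    v <- render_spots(v, spacing, spots, config$psf_sigma_nm)
    if (config$cy3_noise_sd > 0) v <- v + rnorm(nvox, 0, config$cy3_noise_sd)
    out$Cy3 <- image_stack(pmax(v, 0), spacing, "Cy3")
  }
  if ("FITC" %in% channels) {
    lev <- if (config$cd34_positive) config$fitc_positive_level else
      config$fitc_background
    v <- array(config$fitc_background, dim = dim_zyx)
    v[inside] <- lev
    if (config$fitc_noise_sd > 0) v <- v + rnorm(nvox, 0, config$fitc_noise_sd)
    out$FITC <- image_stack(pmax(v, 0), spacing, "FITC")
  }
  out
}

#' Cohort-level generator configuration
#'
#' Wraps a per-nucleus [nucleus_config()] with the cohort design: number of
#' patients, nuclei analysed per sample (30 CD34+ interphase nuclei by
#' default) and between-patient variation. Patient effects shift the
#' per-nucleus count means and scale intensities, nuclear size and
#' flattening multiplicatively; both patient effects and within-patient
#' count draws use variance-controlled sampling so the realized cohort
#' means match the configured values.
#'
#' @param phase Cohort label, `"chronic"` or `"accelerated_blast"`.
#' @param n_patients Number of patients.
#' @param n_nuclei_per_sample Nuclei analysed per sample (>= 1).
#' @param nucleus A [nucleus_config()].
#' @param patient_effects Named list of between-patient sds:
#'   `n_signals_sd`, `n_aggregates_sd` (additive, count units) and
#'   `intensity_scale_sd`, `axis_scale_sd`, `flattening_scale_sd`
#'   (multiplicative, relative).
#' @param seed Integer RNG seed; a fixed seed gives byte-identical cohorts.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(phase = c("chronic", "accelerated_blast"),
                          n_patients = 18, n_nuclei_per_sample = 30,
                          nucleus = nucleus_config(),
                          patient_effects = list(n_signals_sd = 0.35,
                                                 n_aggregates_sd = 0.2,
                                                 intensity_scale_sd = 0.03,
                                                 axis_scale_sd = 0.03,
                                                 flattening_scale_sd = 0.05),
                          seed = 1L) {
  phase <- match.arg(phase)
  if (n_nuclei_per_sample < 1) abort("n_nuclei_per_sample must be >= 1")
  if (n_patients < 0) abort("n_patients must be >= 0")
  stopifnot(inherits(nucleus, "nucleus_config"))
  structure(list(phase = phase, n_patients = as.integer(n_patients),
                 n_nuclei_per_sample = as.integer(n_nuclei_per_sample),
                 nucleus = nucleus, patient_effects = patient_effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Packaged phase-calibrated cohort configurations
#'
#' Cohort generators calibrated to the chronic-phase and
#' accelerated/blast-phase telomere parameter summaries of the CML study
#' conditions: per-nucleus telomere counts 39.45 +/- 6.49 vs 41.51 +/- 5.25,
#' aggregate counts 3.37 +/- 1.19 vs 4.73 +/- 0.92, larger and more
#' intensely labelled blast nuclei, and a flatter (higher a/c) blast
#' telomere cloud. Values are read from the YAML files shipped in
#' `inst/extdata`.
#'
#' @param n_patients,n_nuclei_per_sample,seed Overrides of the packaged
#'   design (18 patients x 30 nuclei).
#' @return A [cohort_config()].
#' @export
chronic_cohort_config <- function(n_patients = NULL, n_nuclei_per_sample = NULL,
                                  seed = NULL) {
  read_cohort_yaml(system.file("extdata", "chronic_cohort.yaml",
                               package = "telarch"),
                   n_patients, n_nuclei_per_sample, seed)
}

#' @rdname chronic_cohort_config
#' @export
blast_cohort_config <- function(n_patients = NULL, n_nuclei_per_sample = NULL,
                                seed = NULL) {
  read_cohort_yaml(system.file("extdata", "blast_cohort.yaml",
                               package = "telarch"),
                   n_patients, n_nuclei_per_sample, seed)
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file describing a cohort (see the packaged
#'   `chronic_cohort.yaml` for the schema).
#' @param n_patients,n_nuclei_per_sample,seed Optional overrides.
#' @return A [cohort_config()].
#' @export
read_cohort_yaml <- function(path, n_patients = NULL,
                             n_nuclei_per_sample = NULL, seed = NULL) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  nuc <- y$nucleus
  ncfg <- nucleus_config(
    semi_axes_um = nuc$semi_axes_um,
    axis_jitter_sd = nuc$axis_jitter_sd,
    n_signals_mean = nuc$n_signals$mean, n_signals_sd = nuc$n_signals$sd,
    n_aggregates_mean = nuc$n_aggregates$mean,
    n_aggregates_sd = nuc$n_aggregates$sd,
    component_means = nuc$intensity_mixture$component_means,
    component_weights = nuc$intensity_mixture$weights,
    component_sdlog = nuc$intensity_mixture$sdlog,
    aggregate_multiplicity = nuc$aggregate$multiplicity,
    aggregate_multiplicity_prob = nuc$aggregate$multiplicity_prob,
    aggregate_spread_nm = nuc$aggregate$spread_nm,
    flattening = nuc$flattening,
    min_separation_nm = unlist(nuc$min_separation_nm),
    psf_sigma_nm = nuc$psf_sigma_nm,
    cy3_background = nuc$cy3$background, cy3_noise_sd = nuc$cy3$noise_sd,
    dapi_level = nuc$dapi$level, dapi_background = nuc$dapi$background,
    dapi_noise_sd = nuc$dapi$noise_sd,
    fitc_positive_level = nuc$fitc$positive_level,
    fitc_background = nuc$fitc$background, fitc_noise_sd = nuc$fitc$noise_sd,
    cd34_positive = nuc$cd34_positive,
    n_slices = nuc$n_slices)
  cohort_config(phase = y$phase,
                n_patients = n_patients %||% y$n_patients,
                n_nuclei_per_sample = n_nuclei_per_sample %||%
                  y$n_nuclei_per_sample,
                nucleus = ncfg,
                patient_effects = y$patient_effects,
                seed = seed %||% y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Precompute the per-nucleus design of a cohort: patient effects and
# variance-controlled count draws. One RNG pass under the cohort seed.
cohort_plan <- function(config) {
  set.seed(config$seed)
  np <- config$n_patients
  nn <- config$n_nuclei_per_sample
  pe <- config$patient_effects
  nuc <- config$nucleus
  if (np == 0) {
    return(tibble(patient_id = character(0), sample_id = character(0),
                  nucleus_id = integer(0), n_signals = integer(0),
                  n_aggregates = integer(0), intensity_scale = numeric(0),
                  axis_scale = numeric(0), flattening_scale = numeric(0),
                  nucleus_seed = integer(0)))
  }
  sig_shift <- draw_exact_moments(np, 0, pe$n_signals_sd %||% 0)
  agg_shift <- draw_exact_moments(np, 0, pe$n_aggregates_sd %||% 0)
  int_scale <- pmax(0.5, draw_exact_moments(np, 1, pe$intensity_scale_sd %||% 0))
  axis_scale <- pmax(0.7, draw_exact_moments(np, 1, pe$axis_scale_sd %||% 0))
  flat_scale <- pmax(1 / nuc$flattening,
                     draw_exact_moments(np, 1, pe$flattening_scale_sd %||% 0))
  within_sig <- sqrt(max(nuc$n_signals_sd^2 - (pe$n_signals_sd %||% 0)^2, 0))
  within_agg <- sqrt(max(nuc$n_aggregates_sd^2 - (pe$n_aggregates_sd %||% 0)^2, 0))
  plans <- lapply(seq_len(np), function(p) {
    nsig <- round_count(draw_exact_moments(nn, nuc$n_signals_mean + sig_shift[p],
                                           within_sig), lower = 1L)
    nagg <- round_count(draw_exact_moments(nn, nuc$n_aggregates_mean + agg_shift[p],
                                           within_agg), lower = 0L)
    tibble(patient_id = sprintf("P%02d", p),
           sample_id = sprintf("P%02d_%s", p, config$phase),
           nucleus_id = seq_len(nn),
           n_signals = nsig, n_aggregates = pmin(nagg, nsig),
           intensity_scale = int_scale[p], axis_scale = axis_scale[p],
           flattening_scale = flat_scale[p])
  })
  plan <- bind_rows(plans)
  plan$nucleus_seed <- vapply(seq_len(nrow(plan)), function(i) {
    derive_seed(config$seed, paste0("nucleus", i))
  }, integer(1))
  plan
}

# nucleus config adjusted for one row of a cohort plan
plan_nucleus_config <- function(nuc, row) {
  nuc$semi_axes_um <- nuc$semi_axes_um * row$axis_scale
  nuc$component_means <- nuc$component_means * row$intensity_scale
  nuc$flattening <- max(1, nuc$flattening * row$flattening_scale)
  nuc
}

#' Generate a cohort of synthetic nuclei
#'
#' Iterates the cohort design drawn by the generator (patients x nuclei),
#' simulating each nucleus under its own derived seed. With `out_dir` set,
#' writes per-nucleus multi-page TIFFs (pattern
#' `<sample>_<nucleus>_<channel>.tif`) with JSON sidecars, a ground-truth
#' CSV per nucleus, and a cohort `manifest.csv`; otherwise keeps results in
#' memory (use small designs for in-memory rendering).
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory, or `NULL` for in-memory results.
#' @param spacing A [voxel_spacing()].
#' @param render Render image channels? `FALSE` gives ground truth only.
#' @param channels Channels to render.
#' @return A manifest tibble (one row per nucleus) with ground truth in the
#'   `truth` list-column; with `render = TRUE` and no `out_dir`, rendered
#'   channels are in the `channels` list-column. With `out_dir`, file path
#'   columns instead.
#' @export
simulate_cohort <- function(config, out_dir = NULL,
                            spacing = voxel_spacing(),
                            render = !is.null(out_dir),
                            channels = c("DAPI", "Cy3", "FITC")) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- cohort_plan(config)
  write_files <- !is.null(out_dir)
  if (write_files) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  res <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    ncfg <- plan_nucleus_config(config$nucleus, row)
    sim <- simulate_nucleus(ncfg, spacing, seed = row$nucleus_seed,
                            render = render, channels = channels,
                            n_signals = row$n_signals,
                            n_aggregates = row$n_aggregates)
    entry <- tibble(patient_id = row$patient_id, sample_id = row$sample_id,
                    nucleus_id = row$nucleus_id, phase = config$phase,
                    truth = list(sim$truth))
    if (render && !write_files) entry$channels <- list(sim$channels)
    if (write_files) {
      base <- sprintf("%s_%03d", row$sample_id, row$nucleus_id)
      for (ch in names(sim$channels)) {
        p <- file.path(out_dir, sprintf("%s_%s.tif", base, ch))
        write_stack(sim$channels[[ch]], p)
        entry[[paste0(tolower(ch), "_path")]] <- p
      }
      tp <- file.path(out_dir, sprintf("%s_truth.csv", base))
      write.csv(sim$truth$spots, tp, row.names = FALSE)
      entry$truth_path <- tp
    }
    res[[i]] <- entry
  }
  manifest <- if (length(res)) bind_rows(res) else
    tibble(patient_id = character(0), sample_id = character(0),
           nucleus_id = integer(0), phase = character(0), truth = list())
  if (write_files) {
    flat <- manifest %>% select(-"truth")
    write.csv(flat, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  manifest
}
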