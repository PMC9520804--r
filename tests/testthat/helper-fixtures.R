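# small, fast nucleus for unit tests (not the study-calibrated conditions)
tiny_nucleus_config <- function(...) {
  args <- utils::modifyList(
    list(semi_axes_um = c(2.5, 2.2, 1.8),
         n_signals_mean = 12, n_signals_sd = 2,
         n_aggregates_mean = 1, n_aggregates_sd = 0.5,
         flattening = 1.2, n_slices = 30),
    list(...))
  do.call(nucleus_config, args)
}

# independent spot rendering oracle: plain dnorm sums on the voxel grid,
# written without the package's renderer
oracle_spot_stack <- function(positions_nm, intensities, dim_zyx,
                              spacing = voxel_spacing(),
                              sigma_nm = c(150, 150, 300),
                              background = 0, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  zc <- (seq_len(dim_zyx[1]) - 0.5) * spacing$dz
  yc <- (seq_len(dim_zyx[2]) - 0.5) * spacing$dy
  xc <- (seq_len(dim_zyx[3]) - 0.5) * spacing$dx
  v <- array(background, dim_zyx)
  for (i in seq_len(nrow(positions_nm))) {
    gz <- dnorm(zc, positions_nm[i, 3], sigma_nm[3]) * spacing$dz
    gy <- dnorm(yc, positions_nm[i, 2], sigma_nm[2]) * spacing$dy
    gx <- dnorm(xc, positions_nm[i, 1], sigma_nm[1]) * spacing$dx
    v <- v + intensities[i] * (gz %o% gy %o% gx)
  }
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  image_stack(pmax(v, 0), spacing, "Cy3")
}

# a permissive all-inclusive mask for detector tests on synthetic stacks
full_mask <- function(stack) {
  m <- array(TRUE, dim(stack$voxels))
  sp <- stack$spacing
  d <- dim(m)
  structure(list(mask = m,
                 centroid_nm = c(z = d[1] / 2 * sp$dz, y = d[2] / 2 * sp$dy,
                                 x = d[3] / 2 * sp$dx),
                 volume_um3 = prod(d) * sp$dx * sp$dy * sp$dz / 1e9,
                 spacing = sp),
            class = "nucleus_mask")
}

# brute-force nested ANOVA oracle: explicit loops over the sums of squares,
# independent of the package implementation
oracle_nested_anova <- function(values, patient, phase) {
  df <- data.frame(y = values, pat = paste(phase, patient), ph = phase,
                   stringsAsFactors = FALSE)
  grand <- mean(df$y)
  ss_phase <- 0
  for (g in unique(df$ph)) {
    sub <- df$y[df$ph == g]
    ss_phase <- ss_phase + length(sub) * (mean(sub) - grand)^2
  }
  ss_pat <- 0
  ss_within <- 0
  for (p in unique(df$pat)) {
    sub <- df[df$pat == p, ]
    ph_mean <- mean(df$y[df$ph == sub$ph[1]])
    ss_pat <- ss_pat + nrow(sub) * (mean(sub$y) - ph_mean)^2
    ss_within <- ss_within + sum((sub$y - mean(sub$y))^2)
  }
  g <- length(unique(df$ph))
  npat <- length(unique(df$pat))
  F_phase <- (ss_phase / (g - 1)) / (ss_pat / (npat - g))
  list(ss_phase = ss_phase, ss_patient = ss_pat, ss_within = ss_within,
       F_phase = F_phase,
       p = pf(F_phase, g - 1, npat - g, lower.tail = FALSE))
}

# nuclei with well-separated spots for detector recall/precision checks
detector_test_config <- function(noise_sd) {
  nucleus_config(semi_axes_um = c(3.5, 3.2, 2.5),
                 n_signals_mean = 15, n_signals_sd = 0,
                 n_aggregates_mean = 0, n_aggregates_sd = 0,
                 min_separation_nm = c(lateral = 1000, axial = 2000),
                 flattening = 1, cy3_noise_sd = noise_sd, n_slices = 36)
}

# match detections to ground-truth objects within a tolerance (nm)
match_detections <- function(signals, objects, tol_nm = 300) {
  used <- rep(FALSE, nrow(objects))
  hits <- 0L
  for (i in seq_len(nrow(signals))) {
    d <- sqrt((objects$x_nm - signals$x_nm[i])^2 +
              (objects$y_nm - signals$y_nm[i])^2 +
              (objects$z_nm - signals$z_nm[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_nm) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = hits / nrow(objects), precision = hits / nrow(signals))
}
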