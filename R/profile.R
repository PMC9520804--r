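#' a/c ratio of a telomere signal cloud
#'
#' Shape statistic of the 3D telomere distribution: the square root of the
#' ratio of the largest to the smallest eigenvalue of the covariance matrix
#' of signal centroids (physical nm). A spherical cloud gives 1; a
#' flattened telomere disk, as seen later in the cell cycle, gives larger
#' values. Rotation- and translation-invariant by construction.
#'
#' @param signals Detections tibble with `x_nm`, `y_nm`, `z_nm` (already in
#'   physical nm, so no further anisotropy correction is needed).
#' @return The a/c ratio (`>= 1`), or `NA` for fewer than 4 signals or a
#'   degenerate (rank < 3) cloud.
#' @export
ac_ratio <- function(signals) {
  if (nrow(signals) < 4) return(NA_real_)
  m <- cbind(signals$x_nm, signals$y_nm, signals$z_nm)
  cv <- stats::cov(m)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) return(NA_real_)
  sqrt(max(ev) / min(ev))
}

#' Build the six-parameter profile of one nucleus
#'
#' The per-nucleus TeloView-style record: (1) number of telomere signals,
#' (2) total integrated intensity, (3) number of telomere aggregates,
#' (4) a/c ratio of the signal cloud, (5) nuclear volume, (6) radial
#' positions of the signals (summarised as their mean; the full vector and
#' the per-signal intensities are kept as list-columns).
#'
#' @param mask A [segment_nucleus()] result.
#' @param signals A [call_aggregates()]-annotated detections tibble (with
#'   `radial_position` if available).
#' @param patient_id,sample_id,nucleus_id,phase Identifiers.
#' @return One-row tibble.
#' @export
build_profile <- function(mask, signals, patient_id = NA_character_,
                          sample_id = NA_character_, nucleus_id = NA_integer_,
                          phase = NA_character_) {
  n <- nrow(signals)
  total <- sum(signals$intensity)
  nagg <- if (n > 0 && "is_aggregate" %in% names(signals)) {
    count_aggregates(signals)
  } else 0L
  radial <- if ("radial_position" %in% names(signals)) {
    signals$radial_position
  } else numeric(0)
  tibble(patient_id = patient_id, sample_id = sample_id,
         nucleus_id = nucleus_id, phase = phase,
         n_telomeres = n,
         total_intensity = total,
         n_aggregates = as.integer(nagg),
         mean_signal_intensity = if (n > 0) total / n else NA_real_,
         ac_ratio = ac_ratio(signals),
         nuclear_volume = mask$volume_um3,
         mean_radial_position = if (length(radial)) mean(radial) else NA_real_,
         signal_intensities = list(signals$intensity),
         radial_positions = list(radial))
}

#' Partition signal intensities into short / intermediate / long populations
#'
#' Splits a pooled intensity distribution into the three cell populations
#' visible in per-sample intensity histograms. The default method places
#' cut points at the 33.3% and 66.7% percentiles; `method = "fixed"` uses
#' caller-supplied thresholds instead.
#'
#' @param intensities Numeric vector (>= 3 values).
#' @param method `"tertile"` or `"fixed"`.
#' @param thresholds Two increasing cut points, required for
#'   `method = "fixed"`.
#' @return An `intensity_partition`: list with `thresholds` and `counts`
#'   (named short/intermediate/long). Degenerate (tied) thresholds produce
#'   a warning and put all mass in the lowest class.
#' @export
partition_intensities <- function(intensities, method = c("tertile", "fixed"),
                                  thresholds = NULL) {
  method <- match.arg(method)
  x <- intensities[!is.na(intensities)]
  if (length(x) < 3) abort("at least 3 intensities are needed to partition")
  if (method == "tertile") {
    thresholds <- unname(quantile(x, c(1 / 3, 2 / 3), type = 7))
  } else {
    if (is.null(thresholds) || length(thresholds) != 2) {
      abort("method = 'fixed' needs two thresholds")
    }
    thresholds <- sort(as.numeric(thresholds))
  }
  if (diff(thresholds) <= 0) {
    warn("degenerate intensity thresholds (tied values); all signals in one class")
    counts <- c(short = length(x), intermediate = 0L, long = 0L)
  } else {
    counts <- c(short = sum(x <= thresholds[1]),
                intermediate = sum(x > thresholds[1] & x <= thresholds[2]),
                long = sum(x > thresholds[2]))
  }
  structure(list(thresholds = thresholds, counts = counts, n = length(x)),
            class = "intensity_partition")
}

#' @export
print.intensity_partition <- function(x, ...) {
  cat(sprintf("<intensity_partition> cuts at %.3g / %.3g; short %d, intermediate %d, long %d\n",
              x$thresholds[1], x$thresholds[2],
              x$counts[1], x$counts[2], x$counts[3]))
  invisible(x)
}

#' @method tidy intensity_partition
#' @export
tidy.intensity_partition <- function(x, ...) {
  tibble(population = names(x$counts), count = as.integer(x$counts),
         lower = c(-Inf, x$thresholds), upper = c(x$thresholds, Inf))
}

#' @method autoplot intensity_partition
#' @export
autoplot.intensity_partition <- function(object, intensities = NULL, ...) {
  if (is.null(intensities)) {
    td <- tidy(object)
    return(ggplot(td, aes(x = .data$population, y = .data$count)) +
             geom_col(fill = "firebrick") +
             labs(x = NULL, y = "telomere signals",
                  title = "Telomere populations by signal intensity") +
             theme_minimal())
  }
  ggplot(tibble(intensity = intensities), aes(x = .data$intensity)) +
    geom_histogram(bins = 40, fill = "firebrick") +
    geom_vline(xintercept = object$thresholds, linewidth = 1) +
    labs(x = "integrated signal intensity (a.u.)", y = "telomere signals",
         title = "Short / intermediate / long telomere populations") +
    theme_minimal()
}
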