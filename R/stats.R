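#' Per-phase summary of a telomere parameter
#'
#' Mean and SD of a per-nucleus parameter for each phase, both across all
#' nuclei and across patient means (the latter is the right scale for
#' cohort-level sampling error, since nuclei within a patient are
#' correlated).
#'
#' @param profiles A profiles tibble (one row per nucleus, as produced by
#'   [build_profile()] / [profile_cohort()]).
#' @param parameter Column name of the parameter to summarise.
#' @return Tibble with one row per phase: `n_nuclei`, `n_patients`,
#'   `mean`, `sd`, `patient_mean`, `patient_sd`, `patient_sem`.
#' @export
summarize_phase <- function(profiles, parameter) {
  if (!parameter %in% names(profiles)) {
    abort(sprintf("unknown parameter '%s'", parameter))
  }
  per_patient <- profiles %>%
    group_by(.data$phase, .data$patient_id) %>%
    summarise(pm = mean(.data[[parameter]], na.rm = TRUE), .groups = "drop")
  nuc <- profiles %>%
    group_by(.data$phase) %>%
    summarise(n_nuclei = dplyr::n(),
              mean = mean(.data[[parameter]], na.rm = TRUE),
              sd = if (dplyr::n() > 1) sd(.data[[parameter]], na.rm = TRUE)
                   else NA_real_,
              .groups = "drop")
  pat <- per_patient %>%
    group_by(.data$phase) %>%
    summarise(n_patients = dplyr::n(),
              patient_mean = mean(.data$pm),
              patient_sd = if (dplyr::n() > 1) sd(.data$pm) else NA_real_,
              .groups = "drop") %>%
    mutate(patient_sem = .data$patient_sd / sqrt(.data$n_patients))
  left_join(nuc, pat, by = "phase") %>%
    mutate(parameter = parameter, .before = 1)
}

#' Nested factorial analysis of variance
#'
#' Tests a phase (group) effect on per-nucleus measurements while taking
#' both patient and cellular variation into account: phase is a fixed
#' effect, patient is a random effect nested within phase, and nuclei are
#' replicates within patient. In the balanced case the phase mean square is
#' tested against the patient-within-phase mean square with
#' `(g - 1, n_patients - g)` degrees of freedom. Unbalanced data are
#' collapsed to patient means and analysed by one-way ANOVA (conservative),
#' with a warning.
#'
#' @param values Numeric per-nucleus measurements.
#' @param patient Patient identifier per value.
#' @param phase Phase/group identifier per value.
#' @return A `nested_anova` object: statistic, df, p-value and the sums of
#'   squares decomposition. Use [tidy()] / [glance()] for tibble views.
#' @export
nested_anova <- function(values, patient, phase) {
  keep <- is.finite(values)
  values <- values[keep]
  patient <- as.character(patient)[keep]
  phase <- as.character(phase)[keep]
  groups <- unique(phase)
  g <- length(groups)
  if (g < 2) abort("nested_anova() needs at least 2 phases")
  pat_by_phase <- tapply(patient, phase, function(p) unique(p))
  if (any(lengths(pat_by_phase) < 2)) {
    abort("nested_anova() needs at least 2 patients per phase")
  }
  cells <- table(paste(phase, patient, sep = "\x1f"))
  if (any(cells < 2)) {
    abort("nested_anova() needs at least 2 cells (nuclei) per patient")
  }
  balanced <- length(unique(cells)) == 1 &&
    length(unique(lengths(pat_by_phase))) == 1

  if (!balanced) {
    warn("unbalanced design: collapsing to patient means (one-way ANOVA on patients)")
    pm <- tapply(values, paste(phase, patient, sep = "\x1f"), mean)
    pg <- vapply(strsplit(names(pm), "\x1f", fixed = TRUE), `[`, character(1), 1)
    fit <- stats::oneway.test(pm ~ factor(pg), var.equal = TRUE)
    out <- list(F_phase = unname(fit$statistic),
                df = unname(fit$parameter),
                p_value = fit$p.value,
                ss = c(phase = NA_real_, patient = NA_real_, within = NA_real_),
                method = "patient-mean one-way ANOVA (unbalanced fallback)",
                degenerate = !is.finite(fit$statistic))
    return(structure(out, class = "nested_anova"))
  }

  n_cell <- unname(cells[1])                  # nuclei per patient
  npat <- sum(lengths(pat_by_phase))          # total patients
  grand <- mean(values)
  phase_means <- tapply(values, phase, mean)
  pat_means <- tapply(values, paste(phase, patient, sep = "\x1f"), mean)
  pat_phase <- vapply(strsplit(names(pat_means), "\x1f", fixed = TRUE), `[`, character(1), 1)

  n_per_phase <- table(phase)
  ss_phase <- sum(n_per_phase[names(phase_means)] * (phase_means - grand)^2)
  ss_patient <- sum(n_cell * (pat_means - phase_means[pat_phase])^2)
  ss_within <- sum((values - pat_means[paste(phase, patient, sep = "\x1f")])^2)

  df_phase <- g - 1
  df_patient <- npat - g
  df_within <- length(values) - npat
  ms_phase <- ss_phase / df_phase
  ms_patient <- ss_patient / df_patient
  degenerate <- ms_patient <= 0
  F_phase <- if (degenerate) NA_real_ else ms_phase / ms_patient
  p <- if (degenerate) NA_real_ else pf(F_phase, df_phase, df_patient,
                                        lower.tail = FALSE)
  structure(list(F_phase = F_phase, df = c(df_phase, df_patient),
                 p_value = p,
                 ss = c(phase = ss_phase, patient = ss_patient,
                        within = ss_within),
                 ms = c(phase = ms_phase, patient = ms_patient,
                        within = ss_within / max(df_within, 1)),
                 df_within = df_within,
                 n = length(values), n_patients = npat, n_phases = g,
                 method = "balanced nested factorial ANOVA",
                 degenerate = degenerate),
            class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat("Nested factorial ANOVA (phase fixed, patient within phase random)\n")
  if (x$degenerate) {
    cat("  degenerate: no patient-level variance; F undefined\n")
  } else {
    cat(sprintf("  F(%g, %g) = %.4g, p = %.3g\n", x$df[1], x$df[2],
                x$F_phase, x$p_value))
  }
  invisible(x)
}

#' @method tidy nested_anova
#' @export
tidy.nested_anova <- function(x, ...) {
  if (is.na(x$ss[1])) {
    return(tibble(term = "phase", statistic = x$F_phase, df = x$df[1],
                  df_residual = x$df[2], p.value = x$p_value))
  }
  tibble(term = c("phase", "patient:phase", "residual"),
         sumsq = unname(x$ss),
         df = c(x$df, x$df_within),
         meansq = unname(x$ms),
         statistic = c(x$F_phase, NA, NA),
         p.value = c(x$p_value, NA, NA))
}

#' @method glance nested_anova
#' @export
glance.nested_anova <- function(x, ...) {
  tibble(statistic = x$F_phase, df = x$df[1], df_residual = x$df[2],
         p.value = x$p_value, method = x$method)
}

#' Chi-square comparison of two binned distributions
#'
#' Pearson chi-square on the 2 x B contingency table of two histograms over
#' the same bins, with automatic pooling of adjacent bins until every
#' expected count is at least 5. Degrees of freedom are `B - 1` for the B
#' bins that remain.
#'
#' @param hist_a,hist_b Integer counts per bin (same binning).
#' @param min_expected Minimum expected count per cell before testing.
#' @return List: `statistic`, `df`, `p_value`, `bins_used`.
#' @export
chi_square_distributions <- function(hist_a, hist_b, min_expected = 5) {
  if (length(hist_a) != length(hist_b)) abort("histograms must share binning")
  if (sum(hist_a) == 0 || sum(hist_b) == 0) {
    abort("cannot compare an all-zero histogram")
  }
  tab <- rbind(hist_a, hist_b)
  # pool adjacent bins until all expected counts reach the minimum
  repeat {
    if (ncol(tab) <= 1) abort("bin pooling collapsed the histogram to one bin")
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- which(apply(exp_counts, 2, min) < min_expected)
    if (length(bad) == 0) break
    j <- bad[1]
    k <- if (j == ncol(tab)) j - 1 else j + 1
    tab[, k] <- tab[, k] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, bins_used = ncol(tab))
}

# equal-probability bin edges on a pooled sample
pooled_bins <- function(x, n_bins = 10) {
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7))
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  edges
}

#' Compare two cohorts across all six telomere parameters
#'
#' Produces the phase-comparison report: per-phase mean +/- SD and the
#' nested-ANOVA phase p-value for each telomere parameter, plus a
#' chi-square comparison of the pooled signal-intensity distributions
#' (10 equal-probability bins on the pooled data, adjacent bins merged
#' until expected counts reach 5). No multiple-testing correction is
#' applied across parameters.
#'
#' @param profiles Profiles tibble containing both phases.
#' @param parameters Parameter columns to compare.
#' @return A `cohort_comparison` object; [tidy()] gives the report tibble.
#' @export
compare_cohorts <- function(profiles,
                            parameters = c("n_telomeres", "n_aggregates",
                                           "total_intensity",
                                           "mean_signal_intensity",
                                           "ac_ratio", "nuclear_volume")) {
  phases <- unique(profiles$phase)
  if (length(phases) != 2) abort("compare_cohorts() needs exactly two phases")
  rows <- lapply(parameters, function(p) {
    s <- summarize_phase(profiles, p)
    an <- tryCatch(nested_anova(profiles[[p]], profiles$patient_id,
                                profiles$phase),
                   warning = function(w) {
                     suppressWarnings(nested_anova(profiles[[p]],
                                                   profiles$patient_id,
                                                   profiles$phase))
                   })
    tibble(parameter = p,
           mean_a = s$mean[s$phase == phases[1]],
           sd_a = s$sd[s$phase == phases[1]],
           mean_b = s$mean[s$phase == phases[2]],
           sd_b = s$sd[s$phase == phases[2]],
           F_phase = an$F_phase, p_value = an$p_value)
  })
  report <- bind_rows(rows)

  chisq <- NULL
  if ("signal_intensities" %in% names(profiles)) {
    ia <- unlist(profiles$signal_intensities[profiles$phase == phases[1]])
    ib <- unlist(profiles$signal_intensities[profiles$phase == phases[2]])
    if (length(ia) && length(ib)) {
      edges <- pooled_bins(c(ia, ib))
      ha <- as.integer(table(cut(ia, edges)))
      hb <- as.integer(table(cut(ib, edges)))
      chisq <- chi_square_distributions(ha, hb)
    }
  }
  structure(list(report = report, phases = phases,
                 intensity_chisq = chisq),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison: %s vs %s\n", x$phases[1], x$phases[2]))
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-22s %8.3f +/- %7.3f  vs %8.3f +/- %7.3f   p = %.3g\n",
                r$parameter[i], r$mean_a[i], r$sd_a[i], r$mean_b[i],
                r$sd_b[i], r$p_value[i]))
  }
  if (!is.null(x$intensity_chisq)) {
    cat(sprintf("  signal intensity distribution: chi-square = %.4g (df %d), p = %.3g\n",
                x$intensity_chisq$statistic, x$intensity_chisq$df,
                x$intensity_chisq$p_value))
  }
  cat("  (no multiple-testing correction across parameters)\n")
  invisible(x)
}

#' @method tidy cohort_comparison
#' @export
tidy.cohort_comparison <- function(x, ...) {
  r <- x$report
  names(r)[names(r) == "mean_a"] <- paste0("mean_", x$phases[1])
  names(r)[names(r) == "sd_a"] <- paste0("sd_", x$phases[1])
  names(r)[names(r) == "mean_b"] <- paste0("mean_", x$phases[2])
  names(r)[names(r) == "sd_b"] <- paste0("sd_", x$phases[2])
  r
}

#' @method autoplot cohort_comparison
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  r <- object$report
  long <- bind_rows(
    tibble(parameter = r$parameter, phase = object$phases[1],
           mean = r$mean_a, sd = r$sd_a),
    tibble(parameter = r$parameter, phase = object$phases[2],
           mean = r$mean_b, sd = r$sd_b))
  ggplot(long, aes(x = .data$phase, y = .data$mean, fill = .data$phase)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.25) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = NULL, y = "mean +/- SD",
         title = "Telomere parameters by CML phase") +
    theme_minimal()
}
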