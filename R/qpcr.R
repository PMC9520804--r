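#' Configuration of a synthetic qPCR Ct table
#'
#' Generates comparative-Ct data for one aurora kinase gene against a GAPDH
#' reference across three donor groups. Per-sample fold changes (on the
#' 2^-ddCt scale) are drawn with variance-controlled sampling, so the
#' realized group mean and sd match the configured values exactly; Ct
#' values are then back-computed, and technical duplicates add optional
#' replicate noise on the Ct scale.
#'
#' @param gene `"AURKA"` or `"AURKB"`.
#' @param fold_means,fold_sds Named numeric vectors over the groups
#'   `healthy`, `chronic`, `accelerated_blast`: target per-sample fold
#'   change mean and sd (2^-ddCt scale, healthy donors as calibrator).
#' @param n_per_group Samples per group (single value or named vector).
#' @param replicates Technical replicates per sample (duplicates by default).
#' @param technical_sd Replicate noise sd on the Ct scale.
#' @param reference_ct Baseline GAPDH Ct level.
#' @param sample_ct_sd Between-sample sd of the reference Ct (cancels in
#'   the delta-Ct, present for realism).
#' @param baseline_dct Calibrator-group delta-Ct level (target - reference).
#' @return A `ct_config` object.
#' @export
ct_config <- function(gene = c("AURKA", "AURKB"),
                      fold_means = c(healthy = 1, chronic = 2.85,
                                     accelerated_blast = 4.12),
                      fold_sds = c(healthy = 0.11, chronic = 0.20,
                                   accelerated_blast = 0.22),
                      n_per_group = 8, replicates = 2, technical_sd = 0,
                      reference_ct = 18, sample_ct_sd = 0.5,
                      baseline_dct = 5) {
  gene <- match.arg(gene)
  groups <- c("healthy", "chronic", "accelerated_blast")
  if (!all(groups %in% names(fold_means)) ||
      !all(names(fold_means) %in% groups)) {
    abort("fold_means must be named over healthy/chronic/accelerated_blast")
  }
  if (!all(names(fold_sds) %in% groups)) {
    abort(sprintf("unknown group in fold_sds: %s",
                  paste(setdiff(names(fold_sds), groups), collapse = ", ")))
  }
  if (any(fold_means <= 0)) abort("fold-change means must be > 0")
  if (any(fold_sds < 0)) abort("fold-change sds must be >= 0")
  if (length(n_per_group) == 1) {
    n_per_group <- setNames(rep(n_per_group, 3), groups)
  }
  structure(list(gene = gene, reference_gene = "GAPDH",
                 fold_means = fold_means[groups], fold_sds = fold_sds[groups],
                 n_per_group = n_per_group[groups],
                 replicates = as.integer(replicates),
                 technical_sd = technical_sd, reference_ct = reference_ct,
                 sample_ct_sd = sample_ct_sd, baseline_dct = baseline_dct),
            class = "ct_config")
}

#' Packaged qPCR fixture configurations
#'
#' Ct generators calibrated to the reported group mean 2^-ddCt values:
#' AURKA 2.85 +/- 0.20 (chronic) and 4.12 +/- 0.22 (accelerated/blast),
#' AURKB 2.62 +/- 0.12 and 3.02 +/- 0.21, with the healthy-donor
#' calibrator group at fold 1 and sd set to the average of the two printed
#' healthy-donor sds per gene. Eight samples per group, analysed in
#' duplicate.
#'
#' @return A [ct_config()].
#' @export
aurka_ct_config <- function() {
  ct_config("AURKA",
            fold_means = c(healthy = 1, chronic = 2.85,
                           accelerated_blast = 4.12),
            fold_sds = c(healthy = 0.11, chronic = 0.20,
                         accelerated_blast = 0.22),
            n_per_group = 8, replicates = 2, technical_sd = 0.05)
}

#' @rdname aurka_ct_config
#' @export
aurkb_ct_config <- function() {
  ct_config("AURKB",
            fold_means = c(healthy = 1, chronic = 2.62,
                           accelerated_blast = 3.02),
            fold_sds = c(healthy = 0.08, chronic = 0.12,
                         accelerated_blast = 0.21),
            n_per_group = 8, replicates = 2, technical_sd = 0.05)
}

#' Simulate a qPCR Ct table
#'
#' @param config A [ct_config()].
#' @param seed Optional integer seed.
#' @return Tibble of Ct records: `sample_id`, `group`, `gene`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @export
simulate_ct_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ct_config"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (grp in names(config$fold_means)) {
    n <- config$n_per_group[[grp]]
    if (n == 0) next
    folds <- draw_exact_moments(n, config$fold_means[[grp]],
                                config$fold_sds[[grp]])
    folds <- pmax(folds, 1e-3)
    ddct <- -log2(folds)
    ct_ref <- config$reference_ct + rnorm(n, 0, config$sample_ct_sd)
    ct_tar <- ct_ref + config$baseline_dct + ddct
    for (i in seq_len(n)) {
      for (r in seq_len(config$replicates)) {
        noise_t <- if (config$technical_sd > 0) rnorm(1, 0, config$technical_sd) else 0
        noise_r <- if (config$technical_sd > 0) rnorm(1, 0, config$technical_sd) else 0
        rows[[length(rows) + 1]] <- tibble(
          sample_id = sprintf("%s_%s_%02d", config$gene, grp, i),
          group = grp, gene = config$gene, replicate = r,
          ct_target = ct_tar[i] + noise_t,
          ct_reference = ct_ref[i] + noise_r)
      }
    }
  }
  bind_rows(rows)
}

#' Comparative-Ct (2^-ddCt) relative quantification
#'
#' Technical replicates are averaged on the Ct scale; per sample,
#' `dCt = mean(ct_target) - mean(ct_reference)`; `ddCt` subtracts the mean
#' dCt of the calibrator group (healthy donors), and expression is
#' reported as `2^-ddCt` relative to the GAPDH reference.
#'
#' @param records Ct tibble (columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct_target`, `ct_reference`).
#' @param gene Optional gene filter when `records` holds several genes.
#' @param calibrator_group Calibrator group name.
#' @return A `ddct_result`: `samples` tibble (dct, ddct, fold_change) and
#'   `groups` tibble (mean +/- SD of fold change, n). [tidy()] returns the
#'   per-sample table, [glance()] the group summary.
#' @export
delta_delta_ct <- function(records, gene = NULL,
                           calibrator_group = "healthy") {
  if (!is.null(gene)) records <- records %>% filter(.data$gene == !!gene)
  if (nrow(records) == 0) abort("no Ct records for the requested gene")
  if (any(!is.finite(records$ct_target)) || any(!is.finite(records$ct_reference))) {
    abort("Ct values must be finite; a sample is missing its reference gene")
  }
  if (any(records$ct_target <= 0) || any(records$ct_reference <= 0)) {
    abort("Ct values must be positive")
  }
  samples <- records %>%
    group_by(.data$sample_id, .data$group, .data$gene) %>%
    summarise(ct_target = mean(.data$ct_target),
              ct_reference = mean(.data$ct_reference), .groups = "drop") %>%
    mutate(dct = .data$ct_target - .data$ct_reference)
  if (!calibrator_group %in% samples$group) {
    abort(sprintf("calibrator group '%s' has no samples", calibrator_group))
  }
  cal <- mean(samples$dct[samples$group == calibrator_group])
  samples <- samples %>%
    mutate(ddct = .data$dct - cal, fold_change = 2^(-.data$ddct))
  groups <- samples %>%
    group_by(.data$group, .data$gene) %>%
    summarise(n = dplyr::n(), mean_fold = mean(.data$fold_change),
              sd_fold = if (dplyr::n() > 1) sd(.data$fold_change) else NA_real_,
              .groups = "drop")
  structure(list(samples = samples, groups = groups,
                 calibrator_group = calibrator_group),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("2^-ddCt relative quantification (calibrator: %s)\n",
              x$calibrator_group))
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s %-18s n=%d  fold = %.3f +/- %.3f\n", g$gene[i],
                g$group[i], g$n[i], g$mean_fold[i], g$sd_fold[i]))
  }
  invisible(x)
}

#' @method tidy ddct_result
#' @export
tidy.ddct_result <- function(x, ...) x$samples

#' @method glance ddct_result
#' @export
glance.ddct_result <- function(x, ...) x$groups

#' Group comparison of fold changes: ANOVA with Bonferroni post-test
#'
#' One-way ANOVA of per-sample 2^-ddCt fold changes across donor groups,
#' followed by pairwise two-sample t-tests with Bonferroni multiplication
#' (adjusted p capped at 1).
#'
#' @param result A [delta_delta_ct()] result.
#' @return List: `anova_p`, `anova_F`, and `pairwise` tibble
#'   (`group_a`, `group_b`, `p_raw`, `p_bonferroni`).
#' @export
qpcr_group_comparison <- function(result) {
  stopifnot(inherits(result, "ddct_result"))
  s <- result$samples
  groups <- unique(s$group)
  if (length(groups) < 2) abort("need at least two groups to compare")
  sizes <- table(s$group)
  if (any(sizes < 2)) abort("each group needs at least 2 samples")
  degenerate <- vapply(groups, function(g) {
    var(s$fold_change[s$group == g]) < 1e-14
  }, logical(1))
  fit <- stats::oneway.test(fold_change ~ factor(group), data = s,
                            var.equal = TRUE)
  pairs <- utils::combn(sort(groups), 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(k) {
    a <- s$fold_change[s$group == pairs[1, k]]
    b <- s$fold_change[s$group == pairs[2, k]]
    p <- if (var(a) + var(b) < 1e-14) 1 else
      t.test(a, b, var.equal = TRUE)$p.value
    tibble(group_a = pairs[1, k], group_b = pairs[2, k], p_raw = p,
           p_bonferroni = min(p * m, 1))
  })
  list(anova_F = unname(fit$statistic),
       anova_p = if (all(degenerate)) 1 else fit$p.value,
       pairwise = bind_rows(pw),
       degenerate_groups = groups[degenerate])
}

#' @method autoplot ddct_result
#' @export
autoplot.ddct_result <- function(object, ...) {
  g <- object$groups %>%
    mutate(group = factor(.data$group,
                          levels = c("healthy", "chronic",
                                     "accelerated_blast")))
  ggplot(g, aes(x = .data$group, y = .data$mean_fold, fill = .data$group)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$mean_fold - .data$sd_fold,
                      ymax = .data$mean_fold + .data$sd_fold), width = 0.25) +
    facet_wrap(~gene) +
    labs(x = NULL, y = expression(2^{-Delta*Delta*Ct}),
         title = "Relative aurora kinase expression vs healthy donors") +
    theme_minimal()
}
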