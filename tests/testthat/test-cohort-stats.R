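test_that("phase summaries report hand-checkable means and missing SDs", {
  profiles <- tibble::tibble(phase = c("chronic", "chronic", "chronic"),
                             patient_id = c("P1", "P1", "P2"),
                             n_telomeres = c(1, 2, 3))
  s <- summarize_phase(profiles, "n_telomeres")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)

  single <- summarize_phase(profiles[1, ], "n_telomeres")
  expect_true(is.na(single$sd))
  expect_error(summarize_phase(profiles, "bogus"), "unknown parameter")
})

test_that("nested ANOVA matches the brute-force sums-of-squares oracle", {
  # 2 phases x 2 patients x 3 cells, integer values
  values <- c(3, 5, 4,  6, 8, 7,   10, 12, 11,  9, 13, 14)
  patient <- rep(c("p1", "p2", "p3", "p4"), each = 3)
  phase <- rep(c("A", "B"), each = 6)
  fit <- nested_anova(values, patient, phase)
  oracle <- oracle_nested_anova(values, patient, phase)
  expect_equal(fit$ss[["phase"]], oracle$ss_phase, tolerance = 1e-10)
  expect_equal(fit$ss[["patient"]], oracle$ss_patient, tolerance = 1e-10)
  expect_equal(fit$ss[["within"]], oracle$ss_within, tolerance = 1e-10)
  expect_equal(fit$F_phase, oracle$F_phase, tolerance = 1e-10)
  expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(fit$df, c(1, 2))

  # sums of squares are additive in the balanced case
  ss_total <- sum((values - mean(values))^2)
  expect_equal(sum(fit$ss), ss_total, tolerance = 1e-8)
})

test_that("nested ANOVA agrees with the aov() error-stratum oracle", {
  set.seed(10)
  values <- rnorm(2 * 4 * 5, mean = rep(c(0, 1), each = 20) +
                    rep(rnorm(8, 0, 0.5), each = 5))
  patient <- rep(sprintf("p%d", 1:8), each = 5)
  phase <- rep(c("A", "B"), each = 20)
  fit <- nested_anova(values, patient, phase)
  av <- summary(aov(values ~ phase + Error(factor(patient))))
  tab <- av[["Error: factor(patient)"]][[1]]
  expect_equal(fit$F_phase, tab["phase", "F value"], tolerance = 1e-8)
  expect_equal(fit$p_value, tab["phase", "Pr(>F)"], tolerance = 1e-8)
})

test_that("degenerate and under-replicated designs are flagged or rejected", {
  vals <- rep(5, 12)
  patient <- rep(c("p1", "p2", "p3", "p4"), each = 3)
  phase <- rep(c("A", "B"), each = 6)
  fit <- nested_anova(vals, patient, phase)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$F_phase))
  expect_equal(unname(fit$ss), c(0, 0, 0))

  expect_error(nested_anova(1:6, rep(c("p1", "p2"), each = 3),
                            rep("A", 6)), "2 phases")
  expect_error(nested_anova(1:6, rep(c("p1", "p2"), each = 3),
                            rep(c("A", "B"), each = 3)), "2 patients")
  expect_error(nested_anova(1:4, c("p1", "p2", "p3", "p4"),
                            rep(c("A", "B"), each = 2)), "2 cells")
})

test_that("unbalanced designs fall back to a patient-mean one-way ANOVA", {
  set.seed(11)
  values <- rnorm(22)
  patient <- c(rep("p1", 5), rep("p2", 6), rep("p3", 5), rep("p4", 6))
  phase <- c(rep("A", 11), rep("B", 11))
  expect_warning(fit <- nested_anova(values, patient, phase), "unbalanced")
  pm <- tapply(values, patient, mean)
  ref <- stats::oneway.test(pm ~ factor(c("A", "A", "B", "B")),
                            var.equal = TRUE)
  expect_equal(fit$F_phase, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(fit$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("null simulations give a uniform type-I error near 5%", {
  set.seed(99)
  reps <- 1000
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    values <- rnorm(30)
    patient <- rep(sprintf("p%d", 1:6), each = 5)
    phase <- rep(c("A", "B"), each = 15)
    p[r] <- nested_anova(values, patient, phase)$p_value
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("study-scale aggregate effects are detected at p < 0.001 with near-certain power", {
  set.seed(7)
  hits <- 0L
  reps <- 100
  for (r in seq_len(reps)) {
    pat_means <- c(rnorm(18, 3.37, 0.2), rnorm(18, 4.73, 0.2))
    values <- rnorm(36 * 30, mean = rep(pat_means, each = 30),
                    sd = rep(c(1.17, 0.9), each = 540))
    patient <- rep(sprintf("p%d", 1:36), each = 30)
    phase <- rep(c("chronic", "blast"), each = 540)
    if (nested_anova(values, patient, phase)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.99)
})

test_that("chi-square distribution comparison matches hand computations", {
  same <- chi_square_distributions(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  flip <- chi_square_distributions(c(10, 20), c(20, 10))
  expect_equal(flip$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(flip$df, 1)

  expect_error(chi_square_distributions(c(0, 0), c(1, 2)), "all-zero")
})

test_that("chi-square equals the brute-force Pearson formula on random tables", {
  set.seed(12)
  for (rep in 1:30) {
    B <- sample(2:6, 1)
    a <- sample(5:30, B, replace = TRUE)
    b <- sample(5:30, B, replace = TRUE)
    tab <- rbind(a, b)
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (min(expct) < 5) next  # merging path tested separately
    stat <- sum((tab - expct)^2 / expct)
    got <- chi_square_distributions(a, b)
    expect_equal(got$statistic, stat, tolerance = 1e-10)
    expect_equal(got$df, B - 1)
  }
})

test_that("bins with small expected counts are pooled before testing", {
  got <- chi_square_distributions(c(40, 2, 40), c(38, 1, 43))
  expect_equal(got$bins_used, 2)
  merged <- rbind(c(40, 42), c(38, 44))  # small middle bin pools rightward
  expct <- outer(rowSums(merged), colSums(merged)) / sum(merged)
  expect_equal(got$statistic, sum((merged - expct)^2 / expct),
               tolerance = 1e-10)
})

test_that("identical cohorts show no phase differences beyond type-I noise", {
  set.seed(20)
  make_phase <- function(phase, shift = 0) {
    tibble::tibble(
      phase = phase, patient_id = rep(sprintf("%s_p%d", phase, 1:5), each = 6),
      nucleus_id = rep(1:6, 5),
      n_telomeres = rnorm(30, 40 + shift, 5),
      n_aggregates = rnorm(30, 3, 1),
      total_intensity = rnorm(30, 4000, 300),
      mean_signal_intensity = rnorm(30, 100, 8),
      ac_ratio = rnorm(30, 2.5, 0.4),
      nuclear_volume = rnorm(30, 200, 30),
      signal_intensities = replicate(30, rlnorm(40, log(100), 0.3),
                                     simplify = FALSE))
  }
  profiles <- dplyr::bind_rows(make_phase("chronic"),
                               make_phase("accelerated_blast"))
  cmp <- compare_cohorts(profiles)
  expect_lte(sum(cmp$report$p_value < 0.05), 1)

  sub <- compare_cohorts(profiles, parameters = "n_telomeres")
  expect_equal(nrow(sub$report), 1)
  expect_equal(sub$report$parameter, "n_telomeres")
})
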