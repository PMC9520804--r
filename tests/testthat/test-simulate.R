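test_that("identical config and seed give byte-identical nuclei", {
  cfg <- tiny_nucleus_config()
  a <- simulate_nucleus(cfg, seed = 5)
  b <- simulate_nucleus(cfg, seed = 5)
  expect_identical(a$channels$Cy3$voxels, b$channels$Cy3$voxels)
  expect_identical(a$channels$DAPI$voxels, b$channels$DAPI$voxels)
  expect_identical(a$truth$spots, b$truth$spots)
  c <- simulate_nucleus(cfg, seed = 6)
  expect_false(identical(a$channels$Cy3$voxels, c$channels$Cy3$voxels))
})

test_that("a nucleus with zero telomeres renders background-only Cy3", {
  cfg <- tiny_nucleus_config(cy3_noise_sd = 0)
  sim <- simulate_nucleus(cfg, seed = 1, n_signals = 0, n_aggregates = 0)
  expect_equal(nrow(sim$truth$spots), 0)
  expect_true(all(sim$channels$Cy3$voxels == cfg$cy3_background))
})

test_that("rendering conserves spot flux (PSF preserves integrated intensity)", {
  # one deterministic spot at the nucleus centre, no background, no noise
  cfg <- tiny_nucleus_config(cy3_background = 0, cy3_noise_sd = 0,
                             component_sdlog = c(0, 0, 0),
                             n_aggregates_mean = 0, n_aggregates_sd = 0)
  sim <- simulate_nucleus(cfg, seed = 3, n_signals = 1, n_aggregates = 0)
  total <- sum(sim$channels$Cy3$voxels)
  expect_lt(abs(total - sum(sim$truth$spots$intensity)) /
              sum(sim$truth$spots$intensity), 0.01)

  # many spots, still within 2%
  sim2 <- simulate_nucleus(tiny_nucleus_config(cy3_background = 0,
                                               cy3_noise_sd = 0),
                           seed = 4)
  total2 <- sum(sim2$channels$Cy3$voxels)
  expect_lt(abs(total2 - sum(sim2$truth$spots$intensity)) /
              sum(sim2$truth$spots$intensity), 0.02)
})

test_that("ground-truth spots lie inside the nuclear ellipsoid and aggregate members are unresolvable", {
  for (seed in 1:5) {
    sim <- simulate_nucleus(tiny_nucleus_config(), seed = seed,
                            render = FALSE)
    ax <- sim$truth$semi_axes_um * 1000
    cen <- sim$truth$centre_nm
    sp <- sim$truth$spots
    q <- ((sp$x_nm - cen["x"]) / ax[1])^2 + ((sp$y_nm - cen["y"]) / ax[2])^2 +
      ((sp$z_nm - cen["z"]) / ax[3])^2
    expect_true(all(q <= 1))
    # members of one aggregate are pairwise below the resolution limit
    for (id in unique(sp$object_id[sp$is_aggregate_member])) {
      m <- sp[sp$object_id == id, ]
      expect_gte(nrow(m), 2)
      d <- as.matrix(dist(cbind(m$x_nm / 200, m$y_nm / 200, m$z_nm / 500)))
      expect_true(all(d[upper.tri(d)] < 1))
    }
  }
})

test_that("zero-spread mixture yields exactly three intensity levels at configured weights", {
  cfg <- tiny_nucleus_config(component_sdlog = c(0, 0, 0),
                             n_signals_mean = 30, n_signals_sd = 0,
                             n_aggregates_mean = 0, n_aggregates_sd = 0)
  sim <- simulate_nucleus(cfg, seed = 9, render = FALSE)
  ints <- sim$truth$objects$intensity
  expect_equal(length(unique(ints)), 3)
  expect_equal(sort(unique(ints)), sort(cfg$component_means),
               tolerance = 1e-12)
  counts <- table(factor(ints, levels = cfg$component_means))
  expect_true(all(abs(as.integer(counts) - 10) <= 1))
})

test_that("cohort manifests have one row per nucleus and empty cohorts are fine", {
  cfg <- cohort_config(phase = "chronic", n_patients = 18,
                       n_nuclei_per_sample = 30,
                       nucleus = tiny_nucleus_config(), seed = 2)
  man <- simulate_cohort(cfg, render = FALSE)
  expect_equal(nrow(man), 540)
  expect_equal(length(unique(man$patient_id)), 18)

  empty <- simulate_cohort(cohort_config(n_patients = 0,
                                         nucleus = tiny_nucleus_config()),
                           render = FALSE)
  expect_equal(nrow(empty), 0)
})

test_that("packaged cohort configs order ground-truth means as chronic < blast", {
  cc <- chronic_cohort_config()
  bc <- blast_cohort_config()
  mc <- simulate_cohort(cc, render = FALSE)
  mb <- simulate_cohort(bc, render = FALSE)
  mean_sig <- function(m) mean(vapply(m$truth, function(t) t$n_signals, numeric(1)))
  mean_agg <- function(m) mean(vapply(m$truth, function(t) t$n_aggregates, numeric(1)))
  expect_lt(mean_sig(mc), mean_sig(mb))
  expect_lt(mean_agg(mc), mean_agg(mb))
  # and the realized means sit at the configured values
  expect_lt(abs(mean_sig(mc) - 39.45), 0.15)
  expect_lt(abs(mean_sig(mb) - 41.51), 0.15)
  expect_lt(abs(mean_agg(mc) - 3.37), 0.1)
  expect_lt(abs(mean_agg(mb) - 4.73), 0.1)
})

test_that("cohorts written to disk round-trip through TIFF + manifest", {
  out <- withr::local_tempdir()
  cfg <- cohort_config(phase = "chronic", n_patients = 1,
                       n_nuclei_per_sample = 2,
                       nucleus = tiny_nucleus_config(), seed = 7)
  man <- simulate_cohort(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_equal(nrow(man), 2)
  st <- read_stack(man$cy3_path[1])
  direct <- simulate_cohort(cfg, render = TRUE)
  expect_equal(st$voxels, direct$channels[[1]]$Cy3$voxels, tolerance = 1e-6)
  expect_equal(st$spacing, direct$channels[[1]]$Cy3$spacing)
})

test_that("infeasible spot packing is rejected with a clear error", {
  cfg <- tiny_nucleus_config(n_signals_mean = 500, n_signals_sd = 0,
                             min_separation_nm = c(lateral = 900, axial = 1800))
  expect_error(simulate_nucleus(cfg, seed = 1, render = FALSE),
               "cannot place")
})

test_that("the Ct generator honours exact null and twofold cases", {
  cfg <- ct_config("AURKA",
                   fold_means = c(healthy = 1, chronic = 1,
                                  accelerated_blast = 2),
                   fold_sds = c(healthy = 0, chronic = 0,
                                accelerated_blast = 0),
                   n_per_group = 4, technical_sd = 0)
  ct <- simulate_ct_table(cfg, seed = 11)
  res <- delta_delta_ct(ct)
  expect_equal(res$samples$fold_change[res$samples$group == "chronic"],
               rep(1, 4))
  expect_equal(res$samples$ddct[res$samples$group == "accelerated_blast"],
               rep(-1, 4))
  expect_equal(res$samples$fold_change[res$samples$group == "accelerated_blast"],
               rep(2, 4))
})

test_that("the packaged fixtures recover configured group means within 2 SEM", {
  for (build in list(aurka_ct_config, aurkb_ct_config)) {
    cfg <- build()
    res <- delta_delta_ct(simulate_ct_table(cfg, seed = 42))
    g <- res$groups
    for (grp in c("chronic", "accelerated_blast")) {
      row <- g[g$group == grp, ]
      sem <- row$sd_fold / sqrt(row$n)
      expect_lt(abs(row$mean_fold - cfg$fold_means[[grp]]), 2 * sem)
    }
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(nucleus_config(component_weights = c(0.5, 0.6, 0.2)), "sum to 1")
  expect_error(nucleus_config(aggregate_multiplicity = 1), ">= 2")
  expect_error(nucleus_config(semi_axes_um = c(2, 3, 1)), "ordered")
  expect_error(voxel_spacing(dx = -1), "positive")
  expect_error(ct_config(fold_sds = c(bogus = 1)), "unknown group|named over")
  expect_error(ct_config(fold_means = c(healthy = -1, chronic = 1,
                                        accelerated_blast = 1)), "> 0")
})
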