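# Synthetic cohort generator: coherence calibration, artifact process,
# clinical model, determinism.

test_that("planted coherence hits its calibrated target", {
  cfg <- test_config(coupling_base = 0.2, coupling_effect = 0.3)
  planted_nodes <- unique(as.vector(cfg$dmn_edges))
  gap <- vapply(1:8, function(s) {
    rec <- simulate_recording(cfg, "sp_before", seed = s)
    cm <- segments_coherence(segment_recording(rec, 3))
    pm <- outer(cm$labels %in% planted_nodes, cm$labels %in% planted_nodes, "&")
    ut <- upper.tri(cm$values)
    mean(cm$values[ut & pm]) - mean(cm$values[ut & !pm])
  }, numeric(1))
  expect_equal(mean(gap), 0.3, tolerance = 0.05 / 0.3)  # +-0.05 absolute

  # a single planted pair at target 0.6
  cfg2 <- test_config(coupling_base = 0.2, coupling_effect = 0.4,
                      dmn_edges = matrix(c("Fz", "Pz"), 1))
  vals <- vapply(1:6, function(s) {
    rec <- simulate_recording(cfg2, "sp_before", seed = s)
    segments_coherence(segment_recording(rec, 3))$values["Fz", "Pz"]
  }, numeric(1))
  expect_equal(mean(vals), 0.6, tolerance = 0.05 / 0.6)
})

test_that("no planted effect means no planted-background gap", {
  cfg <- test_config(coupling_base = 0.2, coupling_effect = 0)
  planted_nodes <- unique(as.vector(cfg$dmn_edges))
  gaps <- vapply(1:4, function(s) {
    rec <- simulate_recording(cfg, "sp_before", seed = s)
    cm <- segments_coherence(segment_recording(rec, 3))
    pm <- outer(cm$labels %in% planted_nodes, cm$labels %in% planted_nodes, "&")
    ut <- upper.tri(cm$values)
    mean(cm$values[ut & pm]) - mean(cm$values[ut & !pm])
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.03)

  # hc and fully attenuated sp_after carry no planted effect either
  for (cond in c("hc", "sp_after")) {
    cfg2 <- test_config(coupling_base = 0.2, coupling_effect = 0.3)
    rec <- simulate_recording(cfg2, cond, seed = 1)
    cm <- segments_coherence(segment_recording(rec, 3))
    pm <- outer(cm$labels %in% planted_nodes, cm$labels %in% planted_nodes, "&")
    ut <- upper.tri(cm$values)
    expect_lt(abs(mean(cm$values[ut & pm]) - mean(cm$values[ut & !pm])), 0.05)
  }
})

test_that("independent channels sit at the Welch bias floor", {
  cfg <- test_config(coupling_base = 0, coupling_effect = 0,
                     duration = 48)
  rec <- simulate_recording(cfg, "hc", seed = 1)
  cm <- segments_coherence(segment_recording(rec, 3))
  M <- cm$welch$n_windows
  expect_equal(mean(cm$values[upper.tri(cm$values)]), 1 / M,
               tolerance = 0.03 / (1 / M))
})

test_that("measured gap grows monotonically with the coupling effect", {
  effects <- c(0.05, 0.15, 0.25, 0.35, 0.45)
  mean_gap <- vapply(effects, function(eff) {
    cfg <- test_config(coupling_base = 0.2, coupling_effect = eff,
                       duration = 12)
    planted_nodes <- unique(as.vector(cfg$dmn_edges))
    mean(vapply(1:4, function(s) {
      rec <- simulate_recording(cfg, "sp_before", seed = s)
      cm <- segments_coherence(segment_recording(rec, 3))
      pm <- outer(cm$labels %in% planted_nodes,
                  cm$labels %in% planted_nodes, "&")
      ut <- upper.tri(cm$values)
      mean(cm$values[ut & pm]) - mean(cm$values[ut & !pm])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(effects, mean_gap, method = "spearman"), 0.9)
})

test_that("blink injection is a seeded Poisson process with frontal topography", {
  base <- recording(matrix(0, 3, 60 * 128), 128, c("FP1", "Cz", "O1"))
  out <- inject_ocular_artifacts(base, rate = 0, amplitude = 150, seed = 1)
  expect_equal(out$data, base$data)
  expect_length(attr(out, "artifact_onsets"), 0)

  counts <- vapply(1:100, function(s)
    length(attr(inject_ocular_artifacts(base, 12, 150, seed = s),
                "artifact_onsets")), numeric(1))
  expect_equal(mean(counts), 12, tolerance = 1.2 / 12)
  expect_gt(var(counts) / mean(counts), 0.5)  # Poisson-like dispersion

  one <- inject_ocular_artifacts(base, 12, 150, seed = 7)
  expect_equal(max(one$data["FP1", ]), 150, tolerance = 1e-6)
  expect_lt(max(abs(one$data["O1", ])), 10)

  # a 150 uV blink trips the downstream +-120 uV rejection
  segs <- reject_segments(segment_recording(one, 3), 120)
  expect_lt(length(segs$segments), 20)
})

test_that("clinical model links change ratio to the latent path-length change", {
  cfg <- sim_config(n_sp = 5, n_hc = 4, panss_intercept = 0.2,
                    panss_slope = -2, panss_noise_sd = 0)
  clin <- simulate_clinical(cfg, delta_l = rep(0, 5), seed = 1)
  sp <- clin[clin$group == "sp" & clin$phase == "before", ]
  # latent ratio exactly 0.2; integer rounding of the scores moves the
  # realized ratio by at most 0.5/30
  expect_true(all(abs(sp$change_ratio - 0.2) < 0.017))
  expect_true(all(sp$panss_pre >= 30 & sp$panss_pre <= 210))
  expect_true(all(sp$panss_post >= 30))
  expect_true(all(sp$tht_steps >= 7))

  expect_error(simulate_clinical(cfg, delta_l = rep(0, 3)), "one entry per")

  # group means of the printed scale: (74.62 - 57.24) / 74.62
  expect_equal(panss_change_ratio(74.62, 57.24), 0.2329, tolerance = 1e-3)
})

test_that("behavioral effects point the expected directions", {
  cfg <- sim_config(n_sp = 21, n_hc = 24)
  clin <- simulate_clinical(cfg, delta_l = rnorm(21, -0.017, 0.02), seed = 5)
  before <- clin[clin$phase == "before", ]
  after <- clin[clin$phase == "after", ]
  hc <- clin[clin$phase == "hc", ]
  expect_gt(mean(before$tmta_rt), mean(hc$tmta_rt))
  expect_gt(mean(before$tmtb_rt), mean(hc$tmtb_rt))
  expect_gt(mean(before$tmtb_err), mean(hc$tmtb_err))
  expect_gt(mean(before$tmtb_rt), mean(after$tmtb_rt))
  expect_true(all(clin$tht_steps >= 7))
  expect_true(all(clin[c("tht_rt", "tmta_rt", "tmtb_rt")] > 0))
})

test_that("the regression machinery recovers the generating slope", {
  b_hat <- vapply(1:100, function(s) {
    cfg <- sim_config(n_sp = 21, n_hc = 2, panss_noise_sd = 0.03)
    set.seed(s)
    dl <- rnorm(21, -0.017, 0.02)
    clin <- simulate_clinical(cfg, dl, seed = s + 1000)
    sp <- clin[clin$phase == "before", ]
    unname(coef(lm(sp$change_ratio ~ sp$delta_l))[2])
  }, numeric(1))
  expect_lt(abs(median(b_hat) - (-2.081)), 0.5)
})

test_that("a cohort is byte-identical under a fixed seed", {
  cfg <- test_config(n_sp = 2, n_hc = 2, duration = 9, seed = 42)
  b1 <- simulate_cohort(cfg, tasks = 1)
  b2 <- simulate_cohort(cfg, tasks = 1)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$truth$delta_l, b2$truth$delta_l)
  for (k in names(b1$recordings))
    expect_identical(b1$recordings[[k]]$data, b2$recordings[[k]]$data)
  expect_identical(b1$truth$artifact_onsets, b2$truth$artifact_onsets)

  # patients appear in both phases, controls in one
  expect_setequal(unique(b1$index$phase[grepl("^SP", b1$index$subject)]),
                  c("before", "after"))
  expect_setequal(unique(b1$index$phase[grepl("^HC", b1$index$subject)]),
                  "hc")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(coupling_base = 0.8, coupling_effect = 0.4),
               "base \\+ effect")
  expect_error(sim_config(n_sp = 1), "n_sp")
  expect_error(sim_config(dmn_edges = matrix(c("Fz", "Fz"), 1)), "distinct")
  expect_error(sim_config(dmn_edges = matrix(c("Fz", "XX"), 1)), "montage")
  expect_error(simulate_recording(test_config(), "bogus"))
})
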