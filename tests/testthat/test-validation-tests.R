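# the five test procedures: protocols, scoring rules, classification

## ---- somatic features -----------------------------------------------------

test_that("a model hitting every observation mean scores exactly zero", {
  m <- mock_model()
  proto <- list(delay = 500, duration = 1000, tstop = 1700)
  # build the observation from the model's own measured features
  feats <- c("voltage_base", "spikecount", "AP_amplitude_from_voltagebase",
             "sag_ratio2")
  obs <- list()
  for (f in feats) {
    obs[[f]] <- list()
    for (a in c("-0.1", "0.3")) {
      tr <- step_current_response(m, as.numeric(a), proto$delay,
                                  proto$duration, proto$tstop)$soma
      fv <- extract_feature(tr, f)
      if (fv$evaluable)
        obs[[f]][[a]] <- list(mean = fv$scalar, std = 1)
    }
    if (!length(obs[[f]])) obs[[f]] <- NULL
  }
  r <- run_somatic_features_test(m, obs, proto)
  expect_equal(r$final_score, 0)
})

test_that("spiking features of a silent model count as attempted but not evaluated", {
  m <- mock_model(mock_params(fi_slope = 0))   # never spikes
  obs <- list(
    voltage_base = list("0.2" = list(mean = -70, std = 1)),
    AP_amplitude = list("0.2" = list(mean = 100, std = 5)),
    mean_frequency = list("0.2" = list(mean = 10, std = 2)))
  r <- run_somatic_features_test(m, obs)
  expect_equal(r$n_attempted, 3)
  expect_equal(r$n_evaluated, 1)
  unev <- r$feature_scores$feature_key[!r$feature_scores$evaluated]
  expect_setequal(unev, c("AP_amplitude@0.2", "mean_frequency@0.2"))
})

test_that("perturbing one of k feature means by 2 SD shifts the final score by 2/k", {
  m <- mock_model()
  proto <- list(delay = 500, duration = 1000, tstop = 1700)
  tr <- step_current_response(m, 0.3, proto$delay, proto$duration,
                              proto$tstop)$soma
  feats <- c("voltage_base", "spikecount", "mean_frequency",
             "AP_amplitude_from_voltagebase")
  obs <- list()
  for (f in feats)
    obs[[f]] <- list("0.3" = list(mean = extract_feature(tr, f)$scalar,
                                  std = 2))
  base <- run_somatic_features_test(m, obs, proto)
  expect_equal(base$final_score, 0)
  obs$voltage_base$`0.3`$mean <- obs$voltage_base$`0.3`$mean + 2 * 2  # +2 SD
  pert <- run_somatic_features_test(m, obs, proto)
  expect_equal(pert$final_score - base$final_score, 2 / length(feats),
               tolerance = 1e-9)
})

test_that("the Table 1 patch-clamp fixture runs end to end", {
  r <- run_somatic_features_test(mock_model(),
                                 hv_ext("obs_somatic_patch_table1.json"))
  expect_s3_class(r, "hippo_test_result")
  expect_gt(r$n_evaluated, 0)
  expect_lte(r$n_evaluated, r$n_attempted)
  expect_true(is.finite(r$final_score))
})

## ---- depolarization block -------------------------------------------------

obs_db <- function() hv_ext("obs_depol_block_synthetic.json")

test_that("a model that never blocks scores exactly 100", {
  r <- run_depol_block_test(mock_model(), obs_db())
  expect_identical(r$final_score, 100)
  expect_equal(r$penalty, 0)
  expect_equal(sum(!r$feature_scores$evaluated), 2)  # I_below and V_eq absent
})

test_that("a genuinely blocking model yields matching current features and V_eq", {
  m <- mock_model(mock_params(block = list(enabled = TRUE, I_block = 0.45,
                                           t_block = 400, v_eq = -42)))
  r <- run_depol_block_test(m, obs_db())
  fs <- r$feature_scores
  expect_equal(fs$model_value[fs$feature_key == "I_maxNumAP"], 0.4)
  expect_equal(fs$model_value[fs$feature_key == "I_below_depol_block"], 0.4)
  expect_equal(r$penalty, 0)
  expect_equal(fs$model_value[fs$feature_key == "V_eq"], -42, tolerance = 0.1)
  expect_match(fs$note[fs$feature_key == "V_eq"], "0.45")
  expect_equal(r$final_score,
               mean(fs$z), tolerance = 1e-9)
})

test_that("one step between the current features adds a penalty of exactly 10", {
  r <- run_depol_block_test(mock_one_step_penalty(), obs_db())
  expect_equal(r$penalty, 10)
  fs <- r$feature_scores
  expect_equal(fs$model_value[fs$feature_key == "I_maxNumAP"], 0.40)
  expect_equal(fs$model_value[fs$feature_key == "I_below_depol_block"], 0.45)
  expect_equal(r$final_score, mean(fs$z) + 10, tolerance = 1e-9)
})

test_that("the block detector is specific to late silence above I_maxNumAP", {
  # monotone f-I: never flagged
  for (rheo in c(0, 0.1, 0.3)) {
    r <- run_depol_block_test(mock_model(mock_params(rheobase = rheo)),
                              obs_db())
    expect_identical(r$final_score, 100, info = sprintf("rheobase %g", rheo))
  }
  # any mock that falls silent late above some amplitude is flagged,
  # including the "cheating" one whose membrane never settles
  for (Ib in c(0.3, 0.6, 1.0)) {
    m <- mock_model(mock_params(block = list(enabled = TRUE, I_block = Ib)))
    r <- run_depol_block_test(m, obs_db())
    expect_false(identical(r$final_score, 100), info = sprintf("I_block %g", Ib))
  }
  mc <- mock_model(mock_params(
    fi_rollover = list(I_start = 0.5, slope_down = 10, floor = 12),
    block = list(enabled = TRUE, I_block = 0.6, cheat = TRUE)))
  rc <- run_depol_block_test(mc, obs_db())
  expect_false(identical(rc$final_score, 100))
})

test_that("an empty depol-block observation is rejected", {
  expect_error(run_depol_block_test(mock_model(), list(mean_Ith = 0.45)),
               class = "hippoval_invalid_observation")
})

## ---- back-propagating AP --------------------------------------------------

test_that("the bAP amplitude search follows the 10-20 Hz band rules", {
  s <- find_bap_amplitude(mock_fi30())
  expect_equal(s$amplitude, 0.5)
  expect_equal(s$rate, 15)

  # spontaneous spiking: rheobase below zero fires at I = 0
  expect_error(find_bap_amplitude(mock_model(mock_params(rheobase = -0.2))),
               class = "hippoval_protocol_error")
  # never reaches 10 Hz
  expect_error(find_bap_amplitude(mock_model(mock_params(fi_slope = 5))),
               class = "hippoval_protocol_error")
  # rate jumps over the band: binary search lands inside it
  m_jump <- mock_model(mock_params(rheobase = 0.27, fi_slope = 200,
                                   latency_base = 2))
  s2 <- find_bap_amplitude(m_jump)
  expect_gte(s2$rate, 10)
  expect_lte(s2$rate, 20)
  expect_gt(s2$amplitude, 0.3)
  expect_lt(s2$amplitude, 0.4)
})

test_that("bAP amplitude extraction uses the somatic windows and no dendritic threshold", {
  m <- mock_fi30()
  tr <- step_current_response(m, 0.5, 500, 1000, 1700)$soma
  # identity recording: amplitude equals the somatic amplitude by the same rule
  a_ident <- extract_bap_amplitude(tr, tr, "first")
  sp <- detect_spikes(tr)
  expect_equal(a_ident,
               max(tr$v[tr$t >= sp$begin_time[1] & tr$t < sp$begin_time[2]]) -
                 v_at_oracle(tr, sp$begin_time[1] - 1),
               tolerance = 1e-9)
  # flat dendritic trace: amplitude 0
  flat <- voltage_trace(tr$t, rep(-70, length(tr$t)))
  expect_equal(extract_bap_amplitude(tr, flat, "first"), 0)
  expect_equal(extract_bap_amplitude(tr, flat, "last"), 0)
  # fewer than two somatic spikes: unevaluable
  one <- step_current_response(mock_fi30(), 0.05, 500, 1000, 1700)$soma
  expect_true(is.na(extract_bap_amplitude(one, flat, "first")))
})

test_that("dendritic bAP amplitudes recover the mock attenuation profile", {
  m <- mock_fi30()
  p <- mock_params()
  soma <- step_current_response(m, 0.5, 500, 1000, 1700)$soma
  for (d in c(60, 200, 340)) {
    dtr <- step_current_response(m, 0.5, 500, 1000, 1700,
                                 sites = list(list(path_distance = d,
                                                   label = "x")))$x
    expected <- p$bap_profile$plateau +
      (p$ap_peak - p$v_rest - p$bap_profile$plateau) *
        exp(-d / p$bap_profile$lambda)
    expect_equal(extract_bap_amplitude(soma, dtr, "first"), expected,
                 tolerance = 0.02 * expected, info = sprintf("d = %g", d))
  }
})

test_that("the bAP test classifies strong and weak propagation profiles", {
  obs <- hv_ext("obs_bap_synthetic.json")
  strong <- run_bap_test(mock_fi30(), obs)
  expect_match(strong$classification_notes, "strongly propagating")
  weak <- run_bap_test(
    mock_fi30(bap_profile = list(plateau = 8, lambda = 80)), obs)
  expect_match(weak$classification_notes, "weakly propagating")
  expect_true("AP1_amp_350_weak" %in% weak$feature_scores$feature_key)
  expect_false("AP1_amp_350_strong" %in% weak$feature_scores$feature_key)
})

test_that("distance ranges without trunk locations are skipped with a note", {
  obs <- jsonlite::read_json(hv_ext("obs_bap_synthetic.json"),
                             simplifyVector = TRUE)
  obs$AP1_amp_450 <- list(mean = 20, std = 10)
  r <- run_bap_test(mock_fi30(), obs,
                    config = list(distances = c(50, 150, 250, 450)))
  fs <- r$feature_scores
  expect_false(fs$evaluated[fs$feature_key == "AP1_amp_450"])
  expect_match(fs$note[fs$feature_key == "AP1_amp_450"], "no suitable trunk")
  expect_lt(r$n_evaluated, r$n_attempted)
})

## ---- PSP attenuation ------------------------------------------------------

test_that("PSP attenuation recovers the closed-form exp(-d/lambda) profile", {
  m <- mock_model()
  p <- mock_params()
  cfg <- list(num_of_dend_locations = 12, seed = 42)
  r <- run_psp_attenuation_test(m, hv_ext("obs_psp_synthetic.json"), cfg)
  # re-derive the sampled locations deterministically and compare
  morph <- model_morphology(m)
  locs <- sample_random_trunk_locations(morph$tree,
                                        morph$classification$trunk,
                                        12, seed = 42, bounds = c(50, 350))
  att <- p$somatic_coupling * exp(-locs$path_distance / p$psp_lambda)
  for (d in c(100, 200, 300)) {
    sel <- locs$path_distance >= d - 50 & locs$path_distance <= d + 50
    key <- sprintf("attenuation_soma/dend_%d_um", d)
    expect_equal(r$feature_scores$model_value[
                   r$feature_scores$feature_key == key],
                 mean(att[sel]), tolerance = 1e-9, info = key)
  }
})

test_that("an unattenuating model reports attenuation 1 everywhere", {
  m <- mock_model(mock_params(psp_lambda = 1e9, somatic_coupling = 1))
  r <- run_psp_attenuation_test(m, hv_ext("obs_psp_synthetic.json"),
                                list(num_of_dend_locations = 6, seed = 3))
  expect_equal(r$feature_scores$model_value, rep(1, 3), tolerance = 1e-6)
})

test_that("PSP attenuation results are reproducible under a fixed seed", {
  m <- mock_model()
  cfg <- list(num_of_dend_locations = 8, seed = 9)
  r1 <- run_psp_attenuation_test(m, hv_ext("obs_psp_synthetic.json"), cfg)
  r2 <- run_psp_attenuation_test(m, hv_ext("obs_psp_synthetic.json"), cfg)
  expect_identical(r1$feature_scores, r2$feature_scores)
  expect_identical(r1$final_score, r2$final_score)
  expect_equal(r1$seed, 9)
})

## ---- oblique integration --------------------------------------------------

test_that("a linear dendrite excludes every location and errors out", {
  m <- mock_model(mock_params(dendrite = list(spike_threshold_weight = NULL)))
  expect_error(run_oblique_integration_test(
    m, hv_ext("obs_oblique_synthetic.json")),
    class = "hippoval_test_error")
})

test_that("a threshold dendrite is supralinear at threshold and linear asynchronously", {
  r <- run_oblique_integration_test(mock_model(),
                                    hv_ext("obs_oblique_synthetic.json"))
  fs <- r$feature_scores
  val <- function(k) fs$model_value[fs$feature_key == k]
  expect_gt(val("nonlin_at_th"), 100)
  expect_equal(val("async_nonlin"), 100, tolerance = 1)
  expect_true(all(fs$evaluated))
  expect_equal(r$n_attempted, 9)
  # thresholds are positive somatic depolarizations of plausible size
  expect_gt(val("threshold"), 0)
  expect_gt(val("peak_amp"), val("threshold"))
})

test_that("oblique selection extends in 15 um steps and not beyond 190 um", {
  # obliques only at 150 um: selection succeeds after two extensions
  m150 <- generate_morphology(morphology_spec(oblique_distances = c(150, 160)))
  cls <- classify_apical(m150, find_apical_points(m150, 100))
  sel <- select_oblique_dendrites(m150, cls)
  expect_equal(sel$limit_used, 150)
  expect_gt(length(sel$sections), 0)
  # no oblique at all: hard failure after extending to 190 um
  m_none <- generate_morphology(morphology_spec(oblique_distances = numeric(0)))
  cls0 <- classify_apical(m_none, find_apical_points(m_none, 100))
  err <- expect_error(select_oblique_dendrites(m_none, cls0),
                      class = "hippoval_selection_error")
  expect_match(conditionMessage(err), "190")
  # oblique beyond the 190 um cap is never reached
  m200 <- generate_morphology(morphology_spec(oblique_distances = c(200, 220)))
  cls2 <- classify_apical(m200, find_apical_points(m200, 100))
  expect_error(select_oblique_dendrites(m200, cls2),
               class = "hippoval_selection_error")
})

## ---- cross-cutting invariants ---------------------------------------------

test_that("per-amplitude simulations are order independent", {
  m <- mock_model()
  amps <- seq(0, 1.6, by = 0.05)
  fwd <- lapply(amps, function(a)
    step_current_response(m, a, 500, 1000, 1700)$soma)
  shuffled_idx <- withr::with_seed(5, sample(seq_along(amps)))
  bwd <- vector("list", length(amps))
  for (i in shuffled_idx)
    bwd[[i]] <- step_current_response(m, amps[i], 500, 1000, 1700)$soma
  expect_identical(fwd, bwd)
  r1 <- run_depol_block_test(m, obs_db())
  r2 <- run_depol_block_test(m, obs_db())
  expect_identical(r1$feature_scores, r2$feature_scores)
})

test_that("every dendritic test scores zero against its own measured features", {
  m <- mock_fi30()
  # bAP
  rb <- run_bap_test(m, hv_ext("obs_bap_synthetic.json"))
  obs_b <- list()
  for (k in seq_len(nrow(rb$feature_scores))) {
    key <- sub("_(strong|weak)$", "", rb$feature_scores$feature_key[k])
    obs_b[[key]] <- list(mean = rb$feature_scores$model_value[k], std = 1)
  }
  rb0 <- run_bap_test(m, obs_b)
  expect_equal(rb0$final_score, 0, tolerance = 1e-12)
  # PSP
  cfgp <- list(num_of_dend_locations = 6, seed = 2)
  rp <- run_psp_attenuation_test(m, hv_ext("obs_psp_synthetic.json"), cfgp)
  obs_p <- list()
  for (k in seq_len(nrow(rp$feature_scores))) {
    d <- sub("attenuation_soma/dend_", "", rp$feature_scores$feature_key[k])
    obs_p[[sprintf("mean_attenuation_soma/dend_%s", d)]] <-
      rp$feature_scores$model_value[k]
    obs_p[[sprintf("std_attenuation_soma/dend_%s", d)]] <- 1
  }
  rp0 <- run_psp_attenuation_test(m, obs_p, cfgp)
  expect_equal(rp0$final_score, 0, tolerance = 1e-12)
  # oblique
  ro <- run_oblique_integration_test(m, hv_ext("obs_oblique_synthetic.json"))
  obs_o <- list()
  for (k in seq_len(nrow(ro$feature_scores))) {
    obs_o[[paste0("mean_", ro$feature_scores$feature_key[k])]] <-
      ro$feature_scores$model_value[k]
    obs_o[[paste0("std_", ro$feature_scores$feature_key[k])]] <- 1
  }
  ro0 <- run_oblique_integration_test(m, obs_o)
  expect_equal(ro0$final_score, 0, tolerance = 1e-12)
})

test_that("halving the trace resolution moves scores by less than 1%", {
  obs <- obs_db()
  coarse <- run_depol_block_test(
    mock_model(mock_params(block = list(enabled = TRUE, I_block = 0.45))), obs)
  fine <- run_depol_block_test(
    mock_model(mock_params(block = list(enabled = TRUE, I_block = 0.45),
                           dt = 0.0125)), obs)
  expect_equal(fine$final_score, coarse$final_score,
               tolerance = 0.01 * max(1, abs(coarse$final_score)))
})
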