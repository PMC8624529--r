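test_that("packaged scenarios carry the reference subject parameters", {
  control <- build_scenario("control_obese")
  expect_equal(control$compound$dose_mg, 1000)
  expect_equal(control$pk$body_weight_kg, 114.6)
  expect_equal(control$pk$clearance_L_h_kg, 0.18)
  expect_equal(control$pk$vd_L_kg, 1.0)
  expect_false(any(control$physiology$bypassed))

  adjusted <- build_scenario("rygb_adjusted")
  expect_true(adjusted$physiology$bypassed[adjusted$physiology$name == "duodenum"])
  expect_equal(adjusted$pk$vd_L_kg, 1.4)
  expect_equal(adjusted$pk$clearance_L_h_kg, 0.258)
  expect_equal(adjusted$pk$body_weight_kg, 104.0)
  expect_equal(adjusted$perm_kind, "segmental")

  healthy <- build_scenario("healthy")
  expect_equal(healthy$compound$dose_mg, 500)
  expect_equal(healthy$compound$water_mL, 200)
  expect_equal(healthy$pk$body_weight_kg, 63.4)
  expect_equal(healthy$pk$clearance_L_h_kg, 0.5177)
  expect_equal(healthy$pk$vd_L_kg, 1.784)

  naive <- build_scenario("rygb_naive")
  expect_equal(naive$perm_kind, "uniform")
  expect_true(any(naive$physiology$bypassed))

  expect_error(build_scenario("sleeve_gastrectomy"))
})

test_that("scenario permeability maps uniform and segmental sources as declared", {
  naive <- build_scenario("rygb_naive", multiplier = 0.5)
  perm_u <- scenario_permeability(naive)
  anchor <- 0.5 * naive$base_peff_cm_s
  expect_equal(unname(perm_u[["jejunum2"]]), anchor)
  expect_equal(unname(perm_u[["ileum3"]]), anchor)   # single value everywhere
  expect_equal(unname(perm_u[["asc_colon"]]), 0.1 * anchor)

  adj <- build_scenario("rygb_adjusted", multiplier = 0.5)
  perm_s <- scenario_permeability(adj)
  expect_equal(unname(perm_s[["jejunum2"]]), anchor)
  expect_equal(unname(perm_s[["ileum1"]]), 0.75 * anchor)
  expect_equal(unname(perm_s[["ileum3"]]), 0.50 * anchor)
  expect_equal(unname(perm_s[["duodenum"]]), 1.2 * anchor)
  expect_equal(attr(perm_s, "provenance"), "segmental_measured")
})

test_that("the calibration metric increases monotonically with the multiplier", {
  sc <- build_scenario("control_obese")
  spec <- calibration_spec("auc_0_24", target_value = 12810)
  settings <- simulation_settings(t_end_h = 24, output_step_h = 0.05)
  aucs <- vapply(c(0.05, 0.1, 0.2, 0.5), function(m) {
    compute_metrics(simulate_scenario(
      build_scenario("control_obese", multiplier = m), settings))$auc_0_24_ng_h_mL
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("calibration converges to the anchor and is idempotent", {
  p <- get_pipeline()
  m_control <- p$multipliers[["control"]]
  expect_equal(p$metrics$control_obese$auc_0_24_ng_h_mL, 12810, tolerance = 1e-3)
  expect_equal(p$metrics$rygb_adjusted$auc_0_24_ng_h_mL, 14830, tolerance = 1e-3)

  # recalibrating the already-calibrated scenario returns the same multiplier
  again <- calibrate_multiplier(p$scenarios$control_obese,
                                calibration_spec("auc_0_24", 12810, tolerance = 1))
  expect_equal(again$multiplier, m_control, tolerance = 1e-2)
})

test_that("calibration boundary behavior: lower bound already sufficient, unbracketed target", {
  sc <- build_scenario("control_obese")
  hit_low <- calibrate_multiplier(
    sc, calibration_spec("auc_0_24", target_value = 1, bounds = c(0.05, 1)))
  expect_equal(hit_low$multiplier, 0.05)
  expect_equal(hit_low$iterations, 0L)

  expect_error(
    calibrate_multiplier(
      sc, calibration_spec("auc_0_24", target_value = 1e9, bounds = c(0.05, 1))),
    "not bracketed")
})

test_that("the comparison table has four scenarios by five metrics and is deterministic", {
  p <- get_pipeline()
  expect_equal(nrow(p$comparison), 20L)
  expect_equal(length(unique(p$comparison$scenario)), 4L)
  expect_equal(length(unique(p$comparison$metric)), 5L)

  p2 <- run_rygb_pipeline()
  expect_identical(p$comparison, p2$comparison) # seed-free, bit-stable
})

test_that("reference PK table holds the literature values used as anchors", {
  ref <- reference_pk_table()
  expect_equal(nrow(ref), 10L)
  anchor_control <- ref$predicted_reference[ref$condition == "control" &
                                              ref$metric == "auc_0_24_ng_h_mL"]
  anchor_rygb <- ref$predicted_reference[ref$condition == "post_rygb" &
                                           ref$metric == "auc_0_24_ng_h_mL"]
  expect_equal(anchor_control, 12810)
  expect_equal(anchor_rygb, 14830)
})
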