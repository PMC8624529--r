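uniform_perm <- function(peff) {
  segmental_permeability(
    stats::setNames(rep(peff, 8),
                    c("duodenum", "jejunum1", "jejunum2", "ileum1",
                      "ileum2", "ileum3", "caecum", "asc_colon")),
    "single_value")
}

test_that("transit rates are the reciprocal transit times; bypassed have none", {
  phys <- default_fasted_physiology()
  expect_equal(transit_rate(phys[phys$name == "jejunum2", ]), 1 / 0.73)
  expect_equal(round(transit_rate(phys[phys$name == "jejunum2", ]), 3), 1.370)

  post <- apply_rygb(phys)
  expect_equal(transit_rate(post[post$name == "stomach", ]), 1 / 0.12)
  expect_equal(round(transit_rate(post[post$name == "stomach", ]), 3), 8.333)
  expect_error(transit_rate(post[post$name == "duodenum", ]), "bypassed")
})

test_that("absorption rate constant is 2 Peff ASF / R in per-hour units", {
  expect_equal(absorption_rate_constant(1.0e-4, 0.949, 1),
               2 * 1e-4 / 0.949 * 3600, tolerance = 1e-12)
  expect_equal(round(absorption_rate_constant(1.0e-4, 0.949, 1), 3), 0.759)
  expect_equal(absorption_rate_constant(0, 0.5, 1), 0)
  expect_equal(absorption_rate_constant(1e-4, 0.949, 0.1),
               0.1 * absorption_rate_constant(1e-4, 0.949, 1))
  expect_error(absorption_rate_constant(1e-4, 0), "> 0")
})

test_that("zero permeability gives a flat plasma profile and full unabsorbed exit", {
  phys <- default_fasted_physiology()
  met <- metformin_profile(1000)
  pk <- pk_parameters(114.6, 0.18, 1.0)
  res <- simulate_absorption(phys, uniform_perm(0), met, pk,
                             simulation_settings(t_end_h = 400, output_step_h = 0.5))
  expect_true(all(res$plasma_conc_ng_mL == 0))
  expect_true(all(regional_absorption(res) == 0))
  n <- length(res$time_h)
  expect_gt(res$unabsorbed_exit_mg[n], 0.999 * 1000) # everything exits as t -> inf
  expect_lt(res$mass_balance_residual_mg, 1e-6 * 1000)
})

test_that("intravenous limit reproduces AUC(0-inf) = dose / (CL x BW) analytically", {
  phys <- default_fasted_physiology()
  met <- metformin_profile(1000)
  pk <- pk_parameters(114.6, 0.18, 1.0)
  res <- simulate_absorption(phys, uniform_perm(0), met, pk, dose_to_central = TRUE)
  m <- iv_reference_metrics(res)
  analytic <- 1000 / (0.18 * 114.6) * 1000 # mg.h/L -> ng.h/mL
  expect_equal(m$auc_0_inf_ng_h_mL, analytic, tolerance = 5e-3)
  expect_true(is.na(m$bioavailability_pct))
})

test_that("mass is conserved to 1e-6 of dose at every output time in all scenarios", {
  p <- get_pipeline()
  for (nm in names(p$results)) {
    res <- p$results[[nm]]
    expect_lt(res$mass_balance_residual_mg, 1e-6 * res$dose_mg,
              label = paste("mass-balance residual,", nm))
    expect_true(all(res$plasma_conc_ng_mL >= 0))
  }
})

test_that("fraction absorbed rises with permeability and with transit time", {
  met <- metformin_profile(1000)
  pk <- pk_parameters(114.6, 0.18, 1.0)
  phys <- default_fasted_physiology()
  settings <- simulation_settings(t_end_h = 48, output_step_h = 0.1)

  f_of <- function(physiology, peff) {
    res <- simulate_absorption(physiology, uniform_perm(peff), met, pk, settings)
    sum(regional_absorption(res))
  }
  peffs <- c(5e-6, 1e-5, 3e-5, 1e-4)
  fs <- vapply(peffs, function(pe) f_of(phys, pe), numeric(1))
  expect_true(all(diff(fs) > 0))

  # longer residence in an absorbing compartment also raises F
  slow <- phys
  slow$transit_h[slow$name == "jejunum2"] <- 1.5
  expect_gt(f_of(slow, 1e-5), f_of(phys, 1e-5))
})

test_that("regional absorption fractions account for the total fraction absorbed", {
  p <- get_pipeline()
  res <- p$results$control_obese
  frac <- regional_absorption(res)
  expect_equal(sum(frac),
               p$metrics$control_obese$bioavailability_pct / 100,
               tolerance = 1e-9)

  # single absorbing compartment carries all of F
  met <- metformin_profile(1000)
  pk <- pk_parameters(114.6, 0.18, 1.0)
  only_j1 <- uniform_perm(0)
  only_j1[["jejunum1"]] <- 1e-4
  res1 <- simulate_absorption(default_fasted_physiology(), only_j1, met, pk,
                              simulation_settings(t_end_h = 48, output_step_h = 0.1))
  frac1 <- regional_absorption(res1)
  expect_gt(frac1[["jejunum1"]], 0)
  expect_equal(sum(frac1), frac1[["jejunum1"]], tolerance = 1e-12)
})

test_that("post-RYGB physiology with the naive permeability underestimates absorption", {
  p <- get_pipeline()
  f_control <- p$metrics$control_obese$bioavailability_pct
  f_naive <- p$metrics$rygb_naive$bioavailability_pct
  f_adjusted <- p$metrics$rygb_adjusted$bioavailability_pct
  expect_lt(f_naive, f_control)     # bypass alone cuts absorption
  expect_gt(f_adjusted, f_naive)    # segmental values restore it
})
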