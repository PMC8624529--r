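test_that("rat-to-human scaling is the published affine map", {
  expect_equal(rat_to_human(0), 3.0e-6)
  expect_equal(rat_to_human(2.795e-5), 3.6 * 2.795e-5 + 3e-6, tolerance = 1e-12)
  expect_equal(rat_to_human(2.795e-5), 1.036e-4, tolerance = 1e-3)
  expect_equal(rat_to_human(1.0e-4), 3.63e-4, tolerance = 1e-12)
  expect_error(rat_to_human(-1e-6), ">= 0")

  # affinity: f(a) + f(b) - f(0) = f(a + b)
  for (pair in list(c(1e-5, 3e-5), c(0, 7e-5), c(2.5e-4, 1e-6))) {
    expect_equal(rat_to_human(pair[1]) + rat_to_human(pair[2]) - rat_to_human(0),
                 rat_to_human(sum(pair)), tolerance = 1e-15)
  }
})

test_that("Renkin sieving runs from 1 (point solute) to 0 (size exclusion)", {
  expect_equal(renkin_factor(0), 1.0)
  expect_equal(renkin_factor(1), 0.0)
  expect_equal(renkin_factor(1.5), 0.0)
  expect_equal(renkin_factor(0.5),
               0.25 * (1 - 1.052 + 0.26125 - 0.0296875), tolerance = 1e-12)
  expect_equal(renkin_factor(0.5), 0.0449, tolerance = 1e-2)
  lam <- seq(0, 1.2, by = 0.01)
  f <- renkin_factor(lam)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f[lam <= 1]) <= 1e-12)) # non-increasing
})

test_that("paracellular permeability is capacity times the sieving factor", {
  m <- paracellular_model(pore_radius_A = 6, capacity_cm_s = 1e-4,
                          molecular_radius_A = 3)
  expect_equal(paracellular_peff(m), 1e-4 * renkin_factor(0.5), tolerance = 1e-12)
  expect_equal(paracellular_peff(m), 4.49e-6, tolerance = 1e-3)

  m$molecular_radius_A <- 0
  expect_equal(paracellular_peff(m), 1e-4) # unhindered
  m$molecular_radius_A <- 6
  expect_equal(paracellular_peff(m), 0)    # sieved out
  m$molecular_radius_A <- 9
  expect_equal(paracellular_peff(m), 0)
})

test_that("molecular-radius fit hits the target paracellular fraction (grid oracle)", {
  m <- paracellular_model(pore_radius_A = 6, capacity_cm_s = 1e-4)
  trans <- 1e-6 # capacity = 100 x transcellular
  r <- fit_molecular_radius(0.90, trans, m)

  # round trip: the fitted radius reproduces the fraction to 1e-6
  p <- paracellular_peff(paracellular_model(6, 1e-4, r))
  expect_equal(p / (p + trans), 0.90, tolerance = 1e-6)
  # at this capacity the 90% split corresponds to a sieving factor of 0.09
  expect_equal(renkin_factor(r / 6), 0.09, tolerance = 1e-6)

  # independent oracle: dense grid scan over the radius
  grid <- seq(1e-6, 6 - 1e-6, length.out = 200000)
  frac <- vapply(grid, function(g) {
    pg <- 1e-4 * renkin_factor(g / 6)
    pg / (pg + trans)
  }, numeric(1))
  r_grid <- grid[which.min(abs(frac - 0.90))]
  expect_equal(r, r_grid, tolerance = 1e-4)
})

test_that("molecular-radius fit handles limits and unreachable targets", {
  m <- paracellular_model(pore_radius_A = 6, capacity_cm_s = 1e-4)
  # vanishing target fraction pushes the radius toward the pore radius
  r_small <- fit_molecular_radius(1e-4, 1e-6, m)
  expect_gt(r_small, 0.9 * 6)
  # capacity equal to transcellular caps the fraction at 0.5
  expect_error(fit_molecular_radius(0.90, 1e-4, m), "unreachable")
  expect_error(fit_molecular_radius(1.2, 1e-6, m), "in \\(0, 1\\)")
})

test_that("segment assignment maps the three perfused segments onto compartments", {
  phys <- default_fasted_physiology()
  measured <- c(jejunum = 1e-4, mid_SI = 8e-5, ileum = 6e-5)
  perm <- assign_segments(measured, duodenal_peff = 1.2e-4, phys,
                          colon_factor = 0.1)
  expect_equal(unname(perm[["duodenum"]]), 1.2e-4)
  expect_equal(unname(perm[["jejunum1"]]), 1e-4)
  expect_equal(unname(perm[["jejunum2"]]), 1e-4)
  expect_equal(unname(perm[["ileum1"]]), 8e-5)
  expect_equal(unname(perm[["ileum2"]]), 6e-5)
  expect_equal(unname(perm[["ileum3"]]), 6e-5)
  expect_equal(unname(perm[["caecum"]]), 6e-6)
  expect_equal(unname(perm[["asc_colon"]]), 6e-6)
  expect_equal(attr(perm, "provenance"), "segmental_measured")

  # ordered inputs stay ordered along the intestine (no reordering)
  vals <- as.numeric(perm)[match(c("jejunum1", "ileum1", "ileum3"), names(perm))]
  expect_true(all(diff(vals) <= 0))
})

test_that("segment assignment degenerate cases: zero colon, uniform map, missing key", {
  phys <- default_fasted_physiology()
  v <- 5e-5
  uniform <- assign_segments(c(jejunum = v, mid_SI = v, ileum = v), v, phys,
                             colon_factor = 1)
  expect_true(all(abs(as.numeric(uniform) - v) < 1e-18))

  zero_colon <- assign_segments(c(jejunum = v, mid_SI = v, ileum = v), v, phys,
                                colon_factor = 0)
  expect_equal(unname(zero_colon[["caecum"]]), 0)
  expect_equal(unname(zero_colon[["asc_colon"]]), 0)

  expect_error(assign_segments(c(jejunum = v, ileum = v), v, phys), "mid_SI")
})
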