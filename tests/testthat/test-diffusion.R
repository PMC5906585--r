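# The diffusion engine: stability bounds, timescale choice, stencil and
# composed-kernel construction, truncation accounting and field convolution,
# all checked against independent brute-force / analytic oracles.

test_that("stability bound matches the analytic formula", {
  expect_equal(stability_dt(900, 15), 1 / 24)           # 2.5 s in minutes
  expect_equal(stability_dt(780, 15), 225 / 4680)       # ~2.8846 s
  expect_equal(stability_dt(6, sqrt(36)), 1)            # dx^2 = 6 D
  expect_identical(stability_dt(0, 15), Inf)            # no constraint
  # decay tightens the bound so the centre weight stays non-negative
  expect_lt(stability_dt(900, 15, gamma = 0.02), stability_dt(900, 15))
  expect_error(stability_dt(-1, 15), "non-negative")
})

test_that("timescale choice yields a shared micro step with m * dt == tick", {
  ts <- choose_timescales(30, default_chemical_specs(), 15)
  expect_equal(ts$steps_per_tick, 720)
  expect_equal(ts$micro_step * ts$steps_per_tick, 30)
  # tick equal to the bound gives m = 1
  one <- choose_timescales(1 / 24, default_chemical_specs(), 15)
  expect_equal(one$steps_per_tick, 1)
  # ceiling arithmetic: dt_max = 2.6 s -> m = ceil(1800 / 2.6) = 693
  D <- 15^2 / (6 * (2.6 / 60))
  m <- choose_timescales(30, list(chemical_spec("IL8", D)), 15)$steps_per_tick
  expect_equal(m, 693)
})

test_that("the single-step stencil matches the explicit scheme coefficients", {
  ds <- default_chemical_specs()
  # lambda = 1/6, gamma = 0: centre 0, neighbours 1/6, mass 1
  st <- build_step_stencil(ds$TNFa, 15, stability_dt(900, 15))
  expect_equal(st$lam, 1 / 6)
  expect_equal(st$weights[2, 2, 2], 0)
  expect_equal(st$weights[1, 2, 2], 1 / 6)
  expect_equal(sum(st$weights), 1)
  expect_equal(sum(st$weights != 0), 6)
  # lambda = 0.1, gamma * dt = 0.05: centre 0.35, mass 0.95
  sp <- chemical_spec("IL6", 0.1 * 15^2 / 0.5, 0.1)  # dt = 0.5 min
  st2 <- build_step_stencil(sp, 15, 0.5)
  expect_equal(st2$weights[2, 2, 2], 0.35)
  expect_equal(st2$weights[2, 1, 2], 0.1)
  expect_equal(sum(st2$weights), 0.95)
  # lambda = 0.2 violates non-negativity
  bad <- chemical_spec("IL6", 0.2 * 15^2 / 0.5)
  expect_error(build_step_stencil(bad, 15, 0.5), "stability violated")
})

test_that("kernel composition equals brute-force repeated convolution", {
  ts <- choose_timescales(30, default_chemical_specs(), 15)
  st <- build_step_stencil(default_chemical_specs()$TGFb1, 15, ts$micro_step)
  k1 <- compose_kernel(st, 1, 3)
  expect_equal(k1$weights, st$weights)        # identity composition
  expect_equal(k1$retained_mass_fraction, 1)
  k2 <- compose_kernel(st, 2, 7)
  expect_equal(k2$weights, conv3_bruteforce(st$weights, st$weights),
               tolerance = 1e-14)
  k4 <- compose_kernel(st, 4, 11)
  bf4 <- conv3_bruteforce(conv3_bruteforce(st$weights, st$weights),
                          conv3_bruteforce(st$weights, st$weights))
  expect_equal(k4$weights, bf4, tolerance = 1e-13)
  expect_error(compose_kernel(st, 2, 4), "odd")
  expect_error(compose_kernel(st, 0, 3), "m must be")
})

test_that("composed kernels carry the 48 cube symmetries exactly", {
  ts <- choose_timescales(30, default_chemical_specs(), 15)
  for (nm in c("TNFa", "IL6")) {
    st <- build_step_stencil(default_chemical_specs()[[nm]], 15,
                             ts$micro_step)
    k <- compose_kernel(st, 6, 13)
    for (sym in cube_symmetries())
      expect_identical(apply_cube_symmetry(k$weights, sym), k$weights)
  }
})

test_that("truncation tracks real mass loss and the curve is monotone", {
  ts <- choose_timescales(30, default_chemical_specs(), 15)
  st <- build_step_stencil(default_chemical_specs()$IL8, 15, ts$micro_step)
  k <- compose_kernel(st, 10, 21)
  expect_equal(k$retained_mass_fraction, 1, tolerance = 1e-12)
  same <- truncate_kernel(k, 21)
  expect_equal(same$weights, k$weights)
  kt <- truncate_kernel(k, 7)
  expect_lt(kt$retained_mass_fraction, 1)
  expect_equal(sum(kt$weights), kt$mass)
  # width 1 keeps exactly the centre weight
  k1 <- truncate_kernel(k, 1)
  expect_equal(as.numeric(k1$weights), k$weights[11, 11, 11])
  expect_error(truncate_kernel(k, 6), "odd")
  # mass curve: monotone, ends at 1, matches brute-force window sums
  curve <- kernel_mass_curve(k)
  expect_equal(curve$width, seq(1, 21, by = 2))
  expect_true(all(diff(curve$mass_fraction) >= -1e-15))
  expect_equal(curve$mass_fraction[nrow(curve)], 1)
  w7 <- sum(k$weights[8:14, 8:14, 8:14]) / sum(k$weights)
  expect_equal(curve$mass_fraction[curve$width == 7], w7)
  expect_gte(kernel_width_for_coverage(k, w7), 7)
})

test_that("FFT diffusion equals naive m-step stenciling for all chemicals", {
  ts <- choose_timescales(30, default_chemical_specs(), 15)
  f <- make_field("random", c(21, 21, 21), value = 3, seed = 11)
  for (nm in chemical_names()) {
    st <- build_step_stencil(default_chemical_specs()[[nm]], 15,
                             ts$micro_step)
    for (m in c(1, 2, 10, 20)) {
      k <- compose_kernel(st, m, 2L * m + 1L)
      got <- diffuse(f, k)
      want <- diffuse_naive(f, st, m)
      expect_lt(max(abs(got - want)) / max(want), 1e-10)
    }
  }
})

test_that("a point source reproduces the kernel weights", {
  ts <- choose_timescales(30, default_chemical_specs(), 15)
  st <- build_step_stencil(default_chemical_specs()$FGF, 15, ts$micro_step)
  k <- compose_kernel(st, 3, 7)
  f <- make_field("point", c(15, 15, 15), value = 1)
  out <- diffuse(f, k)
  expect_equal(out[5:11, 5:11, 5:11], k$weights, tolerance = 1e-12)
})

test_that("mass accounting: periodic conservation and decay scaling", {
  ts <- choose_timescales(30, default_chemical_specs(), 15)
  # gamma = 0: uniform periodic field is a fixed point
  st0 <- build_step_stencil(default_chemical_specs()$TNFa, 15, ts$micro_step)
  k0 <- compose_kernel(st0, 8, 17)
  u <- make_field("uniform", c(20, 20, 20), value = 3.7)
  du <- diffuse(u, k0, boundary = "periodic")
  expect_lt(max(abs(du - 3.7)) / 3.7, 1e-10)
  # random periodic field conserves total mass
  r <- make_field("random", c(20, 20, 20), value = 1, seed = 5)
  expect_lt(abs(sum(diffuse(r, k0, boundary = "periodic")) - sum(r)) / sum(r),
            1e-10)
  # with decay the uniform field scales by (1 - gamma dt)^m
  specs <- default_chemical_specs(decay = c(IL1b = 0.02))
  tsd <- choose_timescales(30, specs, 15)
  std <- build_step_stencil(specs$IL1b, 15, tsd$micro_step)
  kd <- compose_kernel(std, 12, 25)
  dd <- diffuse(u, kd, boundary = "periodic")
  expect_equal(dd[1, 1, 1], 3.7 * (1 - 0.02 * tsd$micro_step)^12,
               tolerance = 1e-12)
})

test_that("absorbing diffusion loses boundary mass but stays non-negative", {
  ts <- choose_timescales(30, default_chemical_specs(), 15)
  st <- build_step_stencil(default_chemical_specs()$IL10, 15, ts$micro_step)
  k <- compose_kernel(st, 10, 21)
  u <- make_field("uniform", c(12, 12, 12), value = 1)
  out <- diffuse(u, k)
  expect_lt(sum(out), sum(u))      # mass leaves the tissue
  expect_true(all(out >= 0))
})

test_that("Monte-Carlo truncation loss is tiny for the walk at the limit", {
  set.seed(99)
  mc <- kernel_truncation_loss_mc(m = 720, half_width = 73, n_walkers = 2e5)
  expect_lt(mc$loss, 0.001)
  expect_equal(mc$n_outside / mc$n_walkers, mc$loss)
  # narrower windows lose more mass
  set.seed(99)
  mc2 <- kernel_truncation_loss_mc(m = 720, half_width = 30, n_walkers = 2e5)
  expect_gt(mc2$loss, mc$loss)
})
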