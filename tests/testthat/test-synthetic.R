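test_that("block mass and stiffness follow the stated geometry and materials", {
  mats <- impact_materials()
  # mid steel cylinder: pi * 12.5^2 * 12 * 7.8e-6 kg
  expect_equal(block_mass("mid", mats$steel), pi * 12.5^2 * 12 * 7.8e-6)
  expect_equal(block_mass("mid", mats$steel), 0.0459, tolerance = 1e-2)
  # density ratio rubber/steel
  expect_equal(block_mass("mid", mats$rubber) / block_mass("mid", mats$steel),
               1.829 / 7.8, tolerance = 1e-12)
  # doubling the diameter at fixed thickness quadruples the mass
  expect_equal(block_mass("max", mats$glass) / block_mass("min", mats$glass),
               (37.5 / 12.5)^2, tolerance = 1e-12)

  # stiffness ratios: E and area scaling
  expect_equal(contact_stiffness("mid", mats$steel) /
                 contact_stiffness("mid", mats$glass), 210000 / 70000)
  expect_equal(contact_stiffness("mid", mats$rubber) /
                 contact_stiffness("mid", mats$steel), 4 / 210000)
  expect_equal(contact_stiffness("max", mats$steel) /
                 contact_stiffness("min", mats$steel), 9)
  expect_equal(contact_stiffness("mid", mats$steel, position_factor = 1.1) /
                 contact_stiffness("mid", mats$steel), 1.1)
})

test_that("full factorial matrix enumerates the design deterministically", {
  m <- generate_matrix(master_seed = 5)
  expect_length(m, 81)
  ids <- vapply(m, `[[`, "", "scenario_id")
  expect_false(anyDuplicated(ids) > 0)
  vels <- vapply(m, `[[`, 0, "velocity")
  expect_setequal(unique(vels), c(2, 6, 10))
  # per-scenario seeds derive from the master seed
  expect_equal(vapply(m, `[[`, 0L, "seed"), 5L + seq_len(81))
  # one level per factor
  one <- generate_matrix("front", "steel", 6, "mid")
  expect_length(one, 1)
  expect_error(generate_matrix(positions = character(0)), "at least one")
  # identical matrices from identical master seeds
  m2 <- generate_matrix(master_seed = 5)
  expect_identical(vapply(m2, `[[`, "", "scenario_id"), ids)
})

test_that("undamped simulation conserves mechanical energy", {
  head0 <- lumped_head_model(c_sb = 0)
  sc <- impact_scenario("front", "glass", 6, "mid", duration = 0.1)
  # the internal audit errors beyond 0.1% drift; completing is the check
  sig <- simulate_impact(sc, head0)
  expect_s3_class(sig, "accel_signal")
  expect_equal(sampling_rate(sig), 5000)
})

test_that("free skull-brain ringdown oscillates at the closed-form frequency", {
  # free head (no grounding), undamped coupling: the only oscillatory mode
  # after contact ends is the skull-brain mode at
  # (1/2pi) sqrt(k_sb (m_s + m_b) / (m_s m_b))
  head0 <- lumped_head_model(c_sb = 0, k_ground = 0)
  f_expect <- sqrt(head0$k_sb * (head0$m_skull + head0$m_brain) /
                     (head0$m_skull * head0$m_brain)) / (2 * pi)
  sc <- impact_scenario("front", "rubber", 2, "mid", duration = 0.4)
  sig <- simulate_impact(sc, head0)
  # analyze the tail, well past contact
  tail_part <- sig$values[1001:2000]
  n <- length(tail_part)
  mag <- Mod(stats::fft(tail_part))[2:(n %/% 2)]
  f_peak <- which.max(mag) * sampling_rate(sig) / n
  expect_lt(abs(f_peak - f_expect), sampling_rate(sig) / n + 1e-9)
})

test_that("zero-ish velocity and reproducibility contracts hold", {
  expect_error(impact_scenario(velocity = 0), "velocity")
  s1 <- simulate_impact(impact_scenario("top", "steel", 10, "max", seed = 3))
  s2 <- simulate_impact(impact_scenario("top", "steel", 10, "max", seed = 3))
  expect_identical(s1$values, s2$values)
  # seeded noise is reproducible and changes with the seed
  n1 <- simulate_impact(impact_scenario("top", "steel", 10, "max", seed = 3,
                                        snr_db = 20))
  n2 <- simulate_impact(impact_scenario("top", "steel", 10, "max", seed = 3,
                                        snr_db = 20))
  n3 <- simulate_impact(impact_scenario("top", "steel", 10, "max", seed = 4,
                                        snr_db = 20))
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
})

test_that("soft slow impacts concentrate energy at low frequency, stiff fast ones do not", {
  frac_low <- function(mat, v) {
    sc <- impact_scenario("front", mat, v, "mid", seed = 1)
    sp <- wp_decompose(simulate_impact(sc), levels = 9)
    df <- as.data.frame(sp)
    sum(df$energy[df$f_high_hz <= 100]) / sp$total_energy
  }
  expect_gt(frac_low("rubber", 2), 0.5)
  expect_lt(frac_low("steel", 10), 0.5)
})

test_that("head model rejects over-damped or non-physical parameters", {
  expect_error(lumped_head_model(c_sb = 1e5), "under-damped")
  expect_error(lumped_head_model(m_skull = -1), "m_skull")
})
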