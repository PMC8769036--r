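test_that("volume-control waveform delivers the set tidal volume", {
  sc <- ventilation_scenario(vt_ml = 600, bpm = 20, ie_ratio = 1,
                             peep_cmh2o = 5)
  wf <- generate_waveform(sc)
  # 600 mL over 1.5 s of inspiration = 400 mL/s = 24 L/min plateau
  expect_equal(max(wf$true_flow_lpm), 24, tolerance = 1e-12)

  # per-breath inspired integral equals VT to 0.1% (discretisation only)
  br <- segment_breaths(wf$t_s, wf$true_flow_lpm)
  done <- br[br$complete, ]
  expect_true(all(abs(done$v_insp_ml - 600) / 600 < 0.001))
  # the expired branch carries a half-sample artifact at the flow
  # discontinuity; its continuous-time integral is matched by construction
  expect_true(all(abs(done$v_exp_ml - 600) / 600 < 0.01))

  # airway pressure sits at PEEP between breaths and rises during inspiration
  expect_equal(min(wf$p_airway_pa), cmh2o_to_pa(5), tolerance = 1e-6)
  expect_gt(max(wf$p_airway_pa), cmh2o_to_pa(5))

  wf0 <- generate_waveform(ventilation_scenario(vt_ml = 0))
  expect_equal(wf0$true_flow_lpm, rep(0, nrow(wf0)))
})

test_that("virtual sensor degenerates to the inverse Venturi model", {
  ideal <- sensor_model(cd_breakpoints = function(q) 0.7, noise_sd_pa = 0,
                        offset_pa = 0, saturation_pa = Inf)
  q <- c(-40, -3, 0, 0.5, 7.5, 25, 70)
  expect_equal(virtual_sensor_read(q, ideal, 1.2), dp_from_flow(q, 1.2),
               tolerance = 1e-14)

  # flow-dependent cd: at the 0.75 plateau the reading is (0.7/0.75)^2 of
  # the fixed-cd model's value
  varcd <- sensor_model(noise_sd_pa = 0, saturation_pa = Inf)
  expect_equal(virtual_sensor_read(7.5, varcd, 1.2) / dp_from_flow(7.5, 1.2),
               (0.7 / 0.75)^2, tolerance = 1e-12)

  # offset and saturation
  off <- sensor_model(cd_breakpoints = function(q) 0.7, noise_sd_pa = 0,
                      offset_pa = 2, saturation_pa = 5)
  expect_equal(virtual_sensor_read(0, off, 1.2), 2)
  expect_equal(virtual_sensor_read(70, off, 1.2), 5)
})

test_that("calibration sessions are seed-reproducible with protocol length", {
  model <- sensor_model()
  amb <- ambient_conditions(81800, 293.15)
  a <- generate_calibration_run(model, amb, seed = 11)
  b <- generate_calibration_run(model, amb, seed = 11)
  c <- generate_calibration_run(model, amb, seed = 12)
  expect_identical(a, b)
  expect_equal(nrow(a), 48)
  expect_false(all(a$dps_pa == c$dps_pa))
  expect_equal(c$flow_lpm, a$flow_lpm)
})

test_that("noise-free closed loop with matched cd recovers volumes exactly", {
  amb <- ambient_conditions(81800, 293.15)
  ideal <- sensor_model(cd_breakpoints = function(q) 0.7, noise_sd_pa = 0,
                        offset_pa = 0, saturation_pa = Inf)
  cal <- generate_calibration_run(ideal, amb)
  tab <- build_table(cal, amb)
  # identity table: model transfer == assumed transfer
  expect_equal(tab$dp_model_pa, tab$dps_pa, tolerance = 1e-12)

  sc <- ventilation_scenario(vt_ml = 600, amb = amb, duration_s = 9)
  res <- run_virtual_bench(sc, ideal, tab, density_mode = "per_sample")
  done <- res[res$complete, ]
  expect_true(all(abs(done$err_insp_percent) <= 1e-6))
  expect_true(all(abs(done$err_exp_percent) <= 1e-6))
})

test_that("bench runs are reproducible under a fixed seed", {
  amb <- ambient_conditions(81800, 293.15)
  model <- sensor_model()
  tab <- build_table(generate_calibration_run(model, amb, seed = 5), amb)
  sc <- ventilation_scenario(vt_ml = 400, amb = amb, duration_s = 9)
  r1 <- run_virtual_bench(sc, model, tab, seed = 99)
  r2 <- run_virtual_bench(sc, model, tab, seed = 99)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("density correction keeps volume error stable under a varying FiO2 schedule", {
  amb <- ambient_conditions(81800, 293.15)
  model <- sensor_model()
  tab <- build_table(generate_calibration_run(model, amb, seed = 21), amb)

  sched <- data.frame(t_s = c(0, 6, 12), fio2_percent = c(21, 60, 100))
  sc_var <- ventilation_scenario(vt_ml = 500, amb = amb, duration_s = 18,
                                 fio2_percent = sched)
  sc_const <- ventilation_scenario(vt_ml = 500, amb = amb, duration_s = 18)
  rv <- run_virtual_bench(sc_var, model, tab, seed = 31)
  rc <- run_virtual_bench(sc_const, model, tab, seed = 31)
  mx_var <- max(abs(rv$err_insp_percent[rv$complete]))
  mx_const <- max(abs(rc$err_insp_percent[rc$complete]))
  # FiO2-aware density keeps the stepped-O2 run in the same error band as air
  expect_lt(abs(mx_var - mx_const), 2)
  expect_lt(mx_var, 10)
})
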