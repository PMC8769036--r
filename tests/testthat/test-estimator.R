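test_that("lookup is exact at stored rows and linear between them", {
  tab <- make_table(c(1, 2, 4, 8), c(10, 20, 40, 80))
  for (k in seq_len(4)) {
    r <- lookup_dp(tab, tab$dps_pa[k])
    expect_equal(r$dp, tab$dp_model_pa[k])
    expect_false(r$extrapolated)
  }
  # midway between rows -> arithmetic mean of the bracketing values
  r <- lookup_dp(tab, 3)
  expect_equal(r$dp, 30)
  expect_equal(r$idx_hi, r$idx_lo + 1L)
  # zero anchor below the first row
  expect_equal(lookup_dp(tab, 0.5)$dp, 5)
  expect_equal(lookup_dp(tab, 0)$dp, 0)
  # linear extrapolation above the last row, flagged
  top <- lookup_dp(tab, 10)
  expect_equal(top$dp, 100)
  expect_true(top$extrapolated)
  # expiration mirrors the positive branch
  expect_equal(lookup_dp(tab, -3)$dp, -30)
})

test_that("dichotomic search agrees exactly with a linear-scan oracle", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(2:60, 1)
    tab <- random_table(n)
    x <- switch(sample(3, 1),
                runif(1, 0, max(tab$dps_pa) * 1.2),          # anywhere
                tab$dps_pa[sample(n, 1)],                    # exact knot
                mean(tab$dps_pa[sample(n, 2)]))              # between knots
    if (runif(1) < 0.3) x <- -x
    expect_equal(lookup_dp(tab, x)$dp, scan_lookup(tab, x), tolerance = 1e-15)
  }
})

test_that("search step count is logarithmically bounded and interpolant continuous", {
  set.seed(7)
  for (n in c(2, 3, 5, 8, 16, 48, 100, 257, 1024)) {
    tab <- random_table(n)
    targets <- runif(50, min(tab$dps_pa), max(tab$dps_pa))
    steps <- vapply(targets, function(x) lookup_dp(tab, x)$steps, integer(1))
    expect_true(all(steps <= ceiling(log2(n))))
  }
  # continuity across every knot of a 48-row table
  tab <- identity_table()
  eps <- 1e-9
  for (k in 2:47) {
    d <- tab$dps_pa[k]
    lo <- lookup_dp(tab, d - eps)$dp
    at <- lookup_dp(tab, d)$dp
    hi <- lookup_dp(tab, d + eps)$dp
    expect_equal(lo, at, tolerance = 1e-6)
    expect_equal(hi, at, tolerance = 1e-6)
  }
})

test_that("flow estimation composes lookup, density and the Venturi equation", {
  tab <- identity_table()
  s <- list(dps_pa = 0, p_airway_pa = 0, fio2_percent = 21,
            p_atm_pa = 101325, temp_k = 293.15)
  expect_equal(estimate_flow(s, tab), 0)

  # with an identity table the pipeline reduces to the bare Venturi model
  s$dps_pa <- 100
  rho <- gas_density(fio2_to_fractions(21), ambient_conditions(101325, 293.15))
  expect_equal(estimate_flow(s, tab), flow_from_dp(100, rho), tolerance = 1e-12)
  # spec'd density 1.2 reference point
  expect_equal(flow_from_dp(lookup_dp(tab, 100)$dp, 1.2), 31.4486,
               tolerance = 1e-4)
})

test_that("trapezoidal volume matches closed forms and conserves totals", {
  t <- seq(0, 1, by = 0.005)
  v <- integrate_volume(t, rep(6, length(t)))
  expect_equal(v[1], 0)
  expect_equal(tail(v, 1), 100)          # 6 L/min = 100 mL/s for 1 s

  expect_equal(integrate_volume(t, rep(0, length(t))), rep(0, length(t)))

  # linear ramp 0 -> 24 L/min over 1.5 s: triangle area 0.5 * 400 mL/s * 1.5 s
  t2 <- seq(0, 1.5, by = 0.005)
  ramp <- 24 * t2 / 1.5
  expect_equal(tail(integrate_volume(t2, ramp), 1), 300, tolerance = 1e-9)

  # irregular timestamps: final volume equals the independent trapezoid sum
  set.seed(3)
  ti <- sort(runif(200, 0, 2))
  qi <- rnorm(200, 5, 4)
  closed <- sum(diff(ti) * (head(qi, -1) + tail(qi, -1)) / 2) * 1000 / 60
  expect_equal(tail(integrate_volume(ti, qi), 1), closed, tolerance = 1e-12)

  expect_error(integrate_volume(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
})

test_that("breath segmentation splits at sustained inspiration onsets", {
  # ideal square wave: VT 600 mL, 20 BPM, I:E 1:1 -> plateau +/-24 L/min
  dt <- 0.005
  t <- seq(0, 9 - dt, by = dt)
  q <- ifelse(t %% 3 < 1.5, 24, -24)
  br <- segment_breaths(t, q)
  expect_equal(nrow(br), 3)
  expect_equal(sum(br$complete), 2)
  done <- br[br$complete, ]
  expect_equal(done$v_insp_ml, rep(600, 2), tolerance = 0.01)
  expect_equal(done$v_exp_ml, rep(600, 2), tolerance = 0.01)
  expect_equal(done$q_peak_lpm, rep(24, 2))

  # all-positive flow: one breath, no expired volume
  br2 <- segment_breaths(t, rep(10, length(t)))
  expect_equal(nrow(br2), 1)
  expect_equal(br2$v_exp_ml, 0)
  expect_gt(br2$v_insp_ml, 0)

  # zero signal: one open breath with zero volumes
  br3 <- segment_breaths(t, rep(0, length(t)))
  expect_equal(nrow(br3), 1)
  expect_equal(br3$v_insp_ml, 0)
  expect_equal(br3$v_exp_ml, 0)
  expect_false(br3$complete)

  # sub-threshold blips do not start a breath
  q4 <- rep(-5, length(t))
  q4[100:103] <- 3   # 20 ms above threshold < 50 ms minimum
  expect_equal(nrow(segment_breaths(t, q4)), 1)
})

test_that("per-breath density mode freezes density at each cycle start", {
  tab <- identity_table()
  dt <- 0.005
  t <- seq(0, 5.995, by = dt)
  dps <- ifelse(t %% 3 < 1.5, 50, -50)
  run <- data.frame(t_s = t, dps_pa = dps, p_airway_pa = 800,
                    fio2_percent = 21, p_atm_pa = 101325, temp_k = 293.15)
  pb <- estimate_run(run, tab, density_mode = "per_breath")
  ps <- estimate_run(run, tab, density_mode = "per_sample")
  # per-breath ignores airway pressure -> lower density -> faster flow
  expect_true(all(abs(ps$q_lpm) < abs(pb$q_lpm)))
  expect_equal(unique(pb$rho_kg_m3),
               gas_density(fio2_to_fractions(21),
                           ambient_conditions(101325, 293.15)))
  expect_equal(unique(ps$rho_kg_m3),
               gas_density(fio2_to_fractions(21),
                           ambient_conditions(101325, 293.15, 800),
                           include_airway_pressure = TRUE))
})
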