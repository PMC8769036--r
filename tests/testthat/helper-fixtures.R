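# Shared fixtures, all built in code.

# calibration table straight from columns (for lookup-only tests)
make_table <- function(dps_pa, dp_model_pa,
                       flow_ref_lpm = rep(NA_real_, length(dps_pa))) {
  structure(data.frame(dps_pa = dps_pa, dp_model_pa = dp_model_pa,
                       flow_ref_lpm = flow_ref_lpm),
            class = c("calibration_table", "data.frame"))
}

# a random strictly-monotone table (keys strictly increasing, values
# non-decreasing), for property tests against the linear-scan oracle
random_table <- function(n) {
  d <- cumsum(stats::runif(n, 0.1, 2))
  p <- cumsum(stats::runif(n, 0, 2))
  make_table(d, p)
}

# linear scan + interpolation oracle, independent of the binary search;
# mirrors the zero-anchor / extrapolation conventions
scan_lookup <- function(table, x) {
  d <- table$dps_pa
  p <- table$dp_model_pa
  n <- length(d)
  ax <- abs(x)
  k <- findInterval(ax, d)
  dp <- if (k == 0L) {
    p[1] * ax / d[1]
  } else if (ax == d[k]) {
    p[k]
  } else if (k == n) {
    p[n - 1] + (ax - d[n - 1]) / (d[n] - d[n - 1]) * (p[n] - p[n - 1])
  } else {
    p[k] + (ax - d[k]) / (d[k + 1] - d[k]) * (p[k + 1] - p[k])
  }
  sign(x) * dp
}

# protocol calibration table for an ideal sensor matching the assumed model
identity_table <- function(amb = ambient_conditions(101325, 293.15),
                           geom = venturi_geometry()) {
  g <- protocol_flow_grid()
  rho <- gas_density(fio2_to_fractions(21), amb)
  build_table(data.frame(flow_lpm = g, dps_pa = dp_from_flow(g, rho, geom)),
              amb, geom)
}
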