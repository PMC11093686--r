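# Build a harmonized instrument set directly from beta/SE vectors.
make_set <- function(bx, by, sy, sx = rep(0.008, length(bx)), label = "test",
                     ids = sprintf("rs%03d", seq_along(bx)), ...) {
  instrument_set(
    data.frame(variant_id = ids,
               beta_exposure = bx, se_exposure = sx,
               beta_outcome = by, se_outcome = sy,
               stringsAsFactors = FALSE),
    label = label, ...
  )
}

# A random strong-instrument set with true causal effect theta.
random_set <- function(J, theta = 0.3, seed = 1, se_x = 0.008, se_y = 0.035) {
  cfg <- simulation_config(n_instruments = J, true_theta = theta,
                           se_x = se_x, se_y = se_y, seed = seed)
  simulate_instrument_set(cfg)
}

# Two-sided binomial 95% bounds for an empirical rate.
binom_bounds <- function(p, n) {
  p + c(-1, 1) * 1.959964 * sqrt(p * (1 - p) / n)
}

# Exposure/outcome association tables for a toy 3-variant study pair.
toy_exposure <- function() {
  variant_associations(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "T", "C"),
    beta = c(0.12, -0.08, 0.05),
    se = c(0.01, 0.009, 0.007),
    p_value = c(1e-30, 1e-18, 1e-12)
  )
}
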