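# Shared fixtures and independent oracles, built in code.

# 24-h biodistribution means of the two mass regimens (tumor/blood/kidney)
biodist_24h_low <- function() {
  biodist_table(c("tumor", "blood", "kidney"), 24,
                c(10.48, 0.68, 0.63), c(3.66, 0.11, 0.16), n = 5L)
}
biodist_24h_high <- function() {
  biodist_table(c("tumor", "blood", "kidney"), 24,
                c(0.38, 0.03, 0.47), c(0.20, 0.01, 0.04), n = 6L)
}

# Brute-force quadrature oracle for the TIA convention: fine-grid
# integration (dt) of the linear interpolant over the observed span,
# plus the same leading segment and tail definitions, computed without
# the package's trapezoid.
tia_oracle <- function(time_h, activity, lambda, tail = c("physical", "none"),
                       dt = 0.01) {
  tail <- match.arg(tail)
  lead <- time_h[1] * activity[1]
  body <- 0
  if (length(time_h) > 1) {
    grid <- seq(min(time_h), max(time_h), by = dt)
    vals <- approx(time_h, activity, xout = grid)$y
    # midpoint rule on the fine grid
    mids <- (vals[-1] + vals[-length(vals)]) / 2
    body <- sum(mids * diff(grid))
  }
  tl <- if (tail == "physical") activity[length(activity)] / lambda else 0
  lead + body + tl
}

# Closed-form dose-coefficient unit chain (hand arithmetic, kept separate
# from the implementation)
coeff_oracle <- function(tia, e_mev, rbe) {
  tia * 10 * 3600 * e_mev * 1.602176634e-13 * 1000 * rbe
}

# A one-alpha-step chain with a chosen energy, for unit-chain tests
chain_with_energy <- function(e_mev) {
  decay_chain(nuclide("X", 10, "h"),
              data.frame(nuclide = "X", position = 1,
                         branching_fraction = 1,
                         mean_alpha_energy_mev = e_mev))
}
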