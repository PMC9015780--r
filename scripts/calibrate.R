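#!/usr/bin/env Rscript
# Calibration of the generator defaults (run once; results are frozen as the
# package's default configuration, they are config, not code).
#
# Under the null, a worn-minute differential at one site is
# N(0, s^2) with s = bilateral_noise_sd * sqrt(2), so the expected window
# statistic of an uninjured patient is E|N(0,s)| = s * sqrt(2/pi).
# Solving E|N(0,s)| = 2.20 F gives bilateral_noise_sd = 1.95 F.
#
# For an injured patient the statistic over the 15-day pre-injury window is
# mean over window days d and the 6 sites of E|N(o_k(d), s)|, where o_k(d)
# is the archetype's ramp offset at affected sites (0 elsewhere). The
# folded-normal mean has the closed form below; archetype peak offsets are
# chosen so the five-archetype average is ~3.6 F.

target_control <- 2.20
sigma <- target_control / (sqrt(2) * sqrt(2 / pi))
s <- sigma * sqrt(2)
cat(sprintf("bilateral_noise_sd = %.4f (frozen default: 1.95)\n", sigma))

E_abs <- function(m) s * sqrt(2 / pi) * exp(-m^2 / (2 * s^2)) + m * (1 - 2 * pnorm(-m / s))

# offset schedule over the 15 window days (relative day -15..-1)
sched <- function(onset_rel, ramp, peak) {
  t <- (-15):(-1) - onset_rel
  frac <- if (ramp == 0) as.numeric(t >= 0) else pmin(1, pmax(0, t / ramp))
  peak * frac
}
exp_stat <- function(onset_rel, ramp, peak, k_sites) {
  mean((k_sites * E_abs(sched(onset_rel, ramp, peak)) +
        (6 - k_sites) * E_abs(0)) / 6)
}

# frozen archetype shapes (onset relative to diagnosis, ramp days, peak F,
# affected sites) -- peaks selected so the cohort mean is ~3.59 F
archetypes <- list(
  charcot       = c(onset = -6,  ramp = 3,  peak = 7.0,  k = 6),
  blister       = c(onset = -12, ramp = 5,  peak = 8.0,  k = 1),
  osteomyelitis = c(onset = -25, ramp = 10, peak = 4.8,  k = 6),
  ulcer_mts5    = c(onset = -15, ramp = 7,  peak = 10.0, k = 2),
  dvt           = c(onset = -3,  ramp = 1,  peak = 8.0,  k = 6)
)
stats <- vapply(archetypes, function(a) exp_stat(a["onset"], a["ramp"], a["peak"], a["k"]),
                numeric(1))
print(round(stats, 3))
cat(sprintf("expected study-cohort mean = %.3f F (printed target 3.59)\n", mean(stats)))
cat(sprintf("expected control mean     = %.3f F (printed target 2.20)\n", E_abs(0)))
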