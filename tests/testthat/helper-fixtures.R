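# Shared fixtures: small, fast model configurations used across tests.

# coarser solver settings for tests that check structure, not accuracy
fast_opts <- list(rtol = 1e-6, atol = 1e-8, dt_out = 0.1)

# a solubility profile high enough that dissolution never limits absorption
unlimited_solubility <- function() {
  solubility_profile(anchors = data.frame(ph = c(1, 9), solubility = c(1e4, 1e4)))
}

# exact-linear Caco-2 cumulative series reproducing a target Papp (cm/s)
linear_transport <- function(papp_target, direction = "AtoB",
                             donor_conc = 10, area = 1.12) {
  times <- c(0, 15, 30, 45, 60)
  rate <- papp_target * donor_conc * area * 60 # nmol/min
  transport_assay(direction, times, rate * times,
                  donor_conc = donor_conc, insert_area = area)
}

# mono-exponential depletion series
exp_depletion <- function(k, times = c(0, 5, 15, 30, 60), protein = 0.5) {
  depletion_assay(times, 100 * exp(-k * times), protein_conc = protein)
}
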