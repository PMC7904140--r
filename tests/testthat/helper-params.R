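# shared parameter sets
#
# default_params(): the concrete worked example (a0 = a1 = 1, lambda0 = 0.02,
# lambda1 = 0.04, u1 = 1e-6, nu = 1e-4).
default_params <- function(...) two_type_params(...)

# illustrative high-mutation parameters used for the type-1 SFS experiment
# (nu = 0.02, u1 = 2e-4, growth rates as in the worked example)
sfs_experiment_params <- function() two_type_params(u1 = 2e-4, nu = 0.02)

# down-scaled regime for comparing the exact and hybrid engines at a few
# 10^4 cells: lambda0 = 0.2, lambda1 = 0.4, u1 = 1e-2
downscaled_params <- function(nu = 0.1) {
  two_type_params(b0 = 0.8, b1 = 0.6, u1 = 1e-2, nu = nu)
}

# moderate-growth fixed-final-size parameters (g = 30% selection)
moderate_bozic <- function(M = 1e9) {
  bozic_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.127, u = 1e-5, M = M)
}
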