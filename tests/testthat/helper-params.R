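# canonical wild-type-like parameter set used across tests:
# activating-site pCa50 4.79, fixed Hill coefficients 2 and 1
wt_params <- function(Amax = 0.4, pKA = 4.79, KI = 1e-3) {
  binding_params(Amax = Amax, KA = 10^(-pKA), KI = KI, nA = 2, nI = 1)
}

# random positive parameter draw for property-style tests
random_params <- function() {
  binding_params(Amax = runif(1, 0.1, 2),
                 KA = 10^(-runif(1, 3.5, 7)),
                 KI = 10^(-runif(1, 1.5, 3.5)),
                 nA = runif(1, 0.5, 3),
                 nI = runif(1, 0.5, 2))
}
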