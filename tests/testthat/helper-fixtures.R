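# Shared fixtures: default parameters and a couple of canonical states.

default_params <- function(...) ccc_update(ccc_params(), ...)

jammed_state <- function(m0 = 100, cpool = 2) ccc_state(m0 = m0, c = cpool)

# Random full-model state with a fixed carrier pool (for conservation tests).
random_full_state <- function() {
  u <- runif(7, 0, 2)
  ccc_state(m0 = u[1], m1 = u[2], m2 = u[3], c = u[4], cstar = u[5],
            cm0 = u[6], cstarm1 = u[7])
}

# Project a full-model state onto the reduced (totals) coordinates.
full_to_reduced <- function(s) {
  ccc_state(m0 = s[["m0"]] + s[["cm0"]], m1 = s[["m1"]] + s[["cstarm1"]],
            m2 = s[["m2"]],
            c = s[["c"]] + s[["cm0"]], cstar = s[["cstar"]] + s[["cstarm1"]])
}
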