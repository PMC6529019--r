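# Shared, lazily built fixtures.  The PING/ING limit cycles and adjoint
# PRCs are used across many test files; building them once keeps the
# suite fast.  All fixtures are computed in code from the reference
# presets -- nothing is stored on disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

ping_bundle <- function() figure_preset("fig2_ping")
ing_bundle <- function() figure_preset("fig3_ing")

ping_cycle <- function() fixture("ping_cycle", function() {
  pp <- ping_bundle()
  find_limit_cycle(pp$e_params, pp$i_params, pp$couplings, c(10, 0))
})

ping_adjoint <- function() fixture("ping_adjoint", function() {
  adjoint_iprc(ping_cycle())
})

ing_cycle <- function() fixture("ing_cycle", function() {
  pp <- ing_bundle()
  find_limit_cycle(pp$e_params, pp$i_params, pp$couplings, c(25, 25))
})

ing_adjoint <- function() fixture("ing_adjoint", function() {
  adjoint_iprc(ing_cycle())
})

# interaction function for the canonical PING pair coupling
ping_coupling <- function() fixture("ping_coupling", function() {
  interaction_function(ping_adjoint(), ping_cycle(),
                       cross = cross_coupling(0.1, 0.5, 0))
})

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# synthetic rate_trace from a function of time
synthetic_trace <- function(t, re, ri = re) {
  structure(list(t = t, r_e = re, r_i = ri, bin_width = t[2] - t[1],
                 window = range(t)),
            class = "rate_trace")
}
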