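# Shared fixtures, built in code.

iso_net <- function(k1 = 10, k2 = 10, T = 200, X0 = NULL)
  isomerisation_network(k1, k2, T, X0)

schlogl_fixture <- function() {
  sc <- schlogl_default_scenario()
  schlogl_network(A = sc$A, B = sc$B, X0 = sc$X0)
}

# pure-decay S -> 0 network, rate k
decay_net <- function(k = 1, n0 = 5)
  reaction_network("S", list(-1), list(linear_propensity(k)), n0)

# two-stage tableau with alpha_21 = gamma, b = (0, 1)
two_stage_tableau <- function(gamma)
  butcher_tableau(matrix(c(0, gamma, 0, 0), 2, 2), b = c(0, 1))
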