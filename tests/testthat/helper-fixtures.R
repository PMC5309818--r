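# small networks used across tests

chain_network <- function() {
  # EX_a (uptake 10) -> T -> conversion -> T -> EX_b
  metabolic_network(data.frame(
    id = c("EX_a", "T_a", "R1", "T_b", "EX_b"),
    equation = c("a[e] <=>", "a[e] => a[c]", "a[c] => b[c]",
                 "b[c] => b[e]", "b[e] <=>"),
    gpr = c("", "", "G1", "", ""),
    lb = c(-10, 0, 0, 0, 0), ub = c(1000, 1000, 1000, 1000, 1000)))
}

# two alternative routes a -> b with separately weightable reactions
two_path_network <- function() {
  metabolic_network(data.frame(
    id = c("EX_a", "T_a", "P1a", "P1b", "P2a", "P2b", "T_b", "EX_b"),
    equation = c("a[e] <=>", "a[e] => a[c]",
                 "a[c] => x[c]", "x[c] => b[c]",
                 "a[c] => y[c]", "y[c] => b[c]",
                 "b[c] => b[e]", "b[e] <=>"),
    gpr = c("", "", "Gp1", "Gp1b", "Gp2", "Gp2b", "", ""),
    lb = c(-20, 0, 0, 0, 0, 0, 0, 0), ub = rep(1000, 8)))
}

random_fixture_table <- function(seed) {
  net <- toy_network(fixture_spec(seed = seed,
                                  n_pathways = 1 + seed %% 3,
                                  pathway_length = 1 + seed %% 4,
                                  fraction_reversible = (seed %% 5) / 5))
  net
}
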