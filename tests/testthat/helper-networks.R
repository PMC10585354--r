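# Networks built in code for the tests.

test_path_network <- function(name) shipped_network(name, load = FALSE)

two_node_net <- function() {
  differentiation_network(c("A", "B"), rbind(c("A", "B")),
                          ancestor = c(NA, "A"))
}

two_node_theta <- function(rs) {
  rate_parameters(rs, alpha = c(A = 0.2, B = 0.4),
                  delta = c(A = 0.1, B = 0.05), lambda = c("A->B" = 0.3))
}

# 4-node single-branch chain used for the recovery experiments.
chain4_net <- function() {
  differentiation_network(c("HSC", "P1", "T", "B"),
                          rbind(c("HSC", "P1"), c("P1", "T"), c("P1", "B")),
                          ancestor = c(NA, "HSC", "P1", "P1"),
                          branch = c("none", "none", "lymphoid", "lymphoid"))
}

chain4_truth <- function(rs) {
  rate_parameters(rs, alpha = 0.3, delta = 0.15,
                  lambda = c("HSC->P1" = 0.4, "P1->T" = 0.25, "P1->B" = 0.25))
}

# Over-branched alternative to chain4 (extra HSC -> B shortcut edge) over
# the same observed lineages, for model-selection experiments.
chain4_overbranched <- function() {
  differentiation_network(c("HSC", "P1", "T", "B"),
                          rbind(c("HSC", "P1"), c("P1", "T"), c("P1", "B"),
                                c("HSC", "B")),
                          ancestor = c(NA, "HSC", "P1", "P1"),
                          branch = c("none", "none", "lymphoid", "lymphoid"))
}

# Random tree-shaped topology for property tests; returns a diffnet with a
# random subset of dup/death flags.
random_tree_net <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(n_nodes))
  parent <- c(NA_integer_, vapply(2:n_nodes,
                                  function(i) sample.int(i - 1L, 1L), 0L))
  edges <- cbind(nodes[parent[-1]], nodes[-1])
  differentiation_network(nodes, edges,
                          ancestor = c(NA_character_, nodes[parent[-1]]),
                          dup = sample(c(TRUE, FALSE), n_nodes, TRUE, c(.8, .2)),
                          death = sample(c(TRUE, FALSE), n_nodes, TRUE, c(.8, .2)))
}

random_theta <- function(rs) {
  setNames(runif(rs$n_params, 0.05, 1), rs$theta_names)
}
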