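# shared builders for small networks and toy case databases

# three-level binary chain A -> B -> C (layered completeness with one node
# per level collapses to a chain)
chain_network <- function() {
  layered_network(
    data.frame(code = c("A", "B", "C"), label = c("A", "B", "C"),
               level = c(3L, 2L, 1L)),
    list(A = c("yes", "no"), B = c("yes", "no"), C = c("yes", "no")))
}

# the chain with hand-set probabilities P(A=yes)=a, P(B=yes|A)= (b1,b0),
# P(C=yes|B) = (c1,c0); rows are in row-major parent order (yes first)
chain_bn <- function(a = 0.3, b1 = 0.5, b0 = 0.5, c1 = 0.2, c0 = 0.2) {
  make_bn(chain_network(), list(
    A = cbind(yes = a, no = 1 - a),
    B = cbind(yes = c(b1, b0), no = 1 - c(b1, b0)),
    C = cbind(yes = c(c1, c0), no = 1 - c(c1, c0))))
}

# a complete all-"no"/"none" assignment over the canonical network
blank_assignment <- function(net = hfacs_network()) {
  sapply(net$nodes$code, function(code) {
    st <- node_states_of(net, code)
    if ("no" %in% st) "no" else "none"
  })
}

node_states_of <- function(net, code) net$states[[code]]

# build a record data.frame for the canonical network from a list of
# per-incident overrides, all other nodes "no"/"none"
toy_records <- function(overrides, net = hfacs_network()) {
  rows <- lapply(seq_along(overrides), function(i) {
    a <- blank_assignment(net)
    ov <- overrides[[i]]
    if (length(ov)) a[names(ov)] <- unlist(ov)
    c(incident_id = sprintf("I%03d", i), as.list(a))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# marginalize an enumerated joint table over all nodes but `code`:
# the brute-force inference oracle
oracle_marginal <- function(joint, code, states, evidence = list()) {
  keep <- rep(TRUE, nrow(joint))
  for (v in names(evidence)) keep <- keep & joint[[v]] == evidence[[v]]
  p <- vapply(states, function(s)
    sum(joint$probability[keep & joint[[code]] == s]), 1)
  p / sum(p)
}
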