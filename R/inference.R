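# ---- joint probability and the enumeration oracle --------------------------

#' Joint probability of one full assignment
#'
#' Evaluates the network factorization: the product over nodes of the
#' probability of the node's asserted state given its parents' asserted
#' states, read from the CPTs.
#'
#' @param bn an `hfacs_bn`.
#' @param assignment named list or character vector giving one legal state for
#'   every node of the network.
#' @return A single probability.
#' @export
#' @examples
#' bn <- random_bn(seed = 3)
#' a <- lapply(bn$network$states, `[`, 1)
#' joint_probability(bn, a)
joint_probability <- function(bn, assignment) {
  assignment <- unlist(assignment)
  codes <- topological_order(bn$network)
  miss <- setdiff(codes, names(assignment))
  if (length(miss))
    stop("assignment is incomplete; missing node(s): ", paste(miss, collapse = ", "))
  p <- 1
  for (code in codes) {
    cpt <- bn$cpts[[code]]
    s <- assignment[[code]]
    si <- match(s, node_states(bn$network, code))
    if (is.na(si)) stop("illegal state \"", s, "\" for node ", code)
    key <- if (length(cpt$parents))
      paste(assignment[cpt$parents], collapse = "\x1f") else ""
    ri <- match(key, config_key(cpt$configs))
    p <- p * cpt$prob[ri, si]
  }
  unname(p)
}

#' Enumerate the full joint distribution
#'
#' Brute-force tabulation of every joint configuration and its probability
#' under the factorized model. Quadratic-memory but exact; serves as the
#' independent oracle for the variable-elimination engine on small networks
#' (the canonical network has 12,288 configurations).
#'
#' @param bn an `hfacs_bn`.
#' @param cap refuse to enumerate joint spaces larger than this many
#'   configurations (default 1e6).
#' @return data.frame with one column per node plus a `probability` column;
#'   probabilities sum to 1.
#' @export
enumerate_joint <- function(bn, cap = 1e6) {
  net <- bn$network
  if (joint_size(net) > cap)
    stop("joint state space (", joint_size(net), ") exceeds cap (", cap, ")")
  grid <- parent_configs(net$states)
  p <- rep(1, nrow(grid))
  for (code in topological_order(net)) {
    cpt <- bn$cpts[[code]]
    ri <- match(config_key(grid[, cpt$parents, drop = FALSE]),
                config_key(cpt$configs))
    si <- match(grid[[code]], node_states(net, code))
    p <- p * cpt$prob[cbind(ri, si)]
  }
  grid$probability <- p
  grid
}

# ---- variable elimination ---------------------------------------------------

# a factor: list(vars, grid [data.frame of states, one column per var],
#               values [numeric, one per grid row])
cpt_as_factor <- function(bn, code) {
  cpt <- bn$cpts[[code]]
  states <- node_states(bn$network, code)
  k <- length(states)
  nc <- nrow(cpt$configs)
  grid <- cpt$configs[rep(seq_len(nc), each = k), , drop = FALSE]
  grid[[code]] <- rep(states, times = nc)
  rownames(grid) <- NULL
  list(vars = c(cpt$parents, code), grid = grid, values = as.vector(t(cpt$prob)))
}

# condition a factor on evidence: keep matching rows, drop the evidence columns
reduce_factor <- function(f, evidence) {
  ev <- intersect(f$vars, names(evidence))
  if (!length(ev)) return(f)
  keep <- rep(TRUE, nrow(f$grid))
  for (v in ev) keep <- keep & f$grid[[v]] == evidence[[v]]
  vars <- setdiff(f$vars, ev)
  list(vars = vars, grid = f$grid[keep, vars, drop = FALSE],
       values = f$values[keep])
}

factor_multiply <- function(f1, f2, states_list) {
  vars <- union(f1$vars, f2$vars)
  grid <- parent_configs(states_list[vars])
  lookup <- function(f) {
    if (!length(f$vars)) return(rep(prod(f$values), nrow(grid)))
    idx <- match(config_key(grid[, f$vars, drop = FALSE]),
                 config_key(f$grid[, f$vars, drop = FALSE]))
    f$values[idx]
  }
  list(vars = vars, grid = grid, values = lookup(f1) * lookup(f2))
}

factor_sum_out <- function(f, var, states_list) {
  vars <- setdiff(f$vars, var)
  if (!length(vars))
    return(list(vars = character(), grid = parent_configs(list()),
                values = sum(f$values)))
  grid <- parent_configs(states_list[vars])
  key <- config_key(f$grid[, vars, drop = FALSE])
  agg <- rowsum(f$values, group = key)
  list(vars = vars, grid = grid,
       values = agg[match(config_key(grid), rownames(agg)), 1])
}

#' Exact posterior of one node by variable elimination
#'
#' Computes P(target | evidence) exactly by sum-product variable elimination.
#' Elimination order follows a min-width greedy heuristic (eliminate the
#' variable whose product factor is smallest), with lexicographic code order
#' breaking ties; the result is independent of the order. With empty evidence
#' this is the prior marginal of the node.
#'
#' Conditioning is observational: asserting evidence re-weights the joint
#' distribution, mirroring evidence propagation in standard BN tools, not a
#' do-intervention.
#'
#' @param bn an `hfacs_bn`.
#' @param target node code to query; must not appear in the evidence.
#' @param evidence named list (or character vector) of asserted states, e.g.
#'   `list(RM = "yes")`; may be empty.
#' @return Named numeric vector: the posterior probability of each state of
#'   `target`, in the node's canonical state order; sums to 1.
#' @export
#' @examples
#' bn <- random_bn(seed = 5)
#' query(bn, "ERR", list(RM = "yes", CO = "no"))
query <- function(bn, target, evidence = list()) {
  net <- bn$network
  evidence <- as.list(unlist(evidence))
  codes <- topological_order(net)
  if (!target %in% codes) stop("unknown target node: ", target)
  if (target %in% names(evidence)) stop("target node appears in the evidence")
  for (v in names(evidence)) {
    if (!v %in% codes) stop("unknown evidence node: ", v)
    if (!evidence[[v]] %in% node_states(net, v))
      stop("illegal evidence state \"", evidence[[v]], "\" for node ", v)
  }
  if (anyDuplicated(names(evidence))) stop("a node appears twice in the evidence")

  states_list <- net$states
  factors <- lapply(codes, function(code)
    reduce_factor(cpt_as_factor(bn, code), evidence))
  elim <- sort(setdiff(codes, c(target, names(evidence))))
  while (length(elim)) {
    width <- vapply(elim, function(v) {
      vars <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars)))
      prod(vapply(states_list[vars], length, 1L))
    }, 1)
    v <- elim[which.min(width)]  # which.min takes the first = lexicographic tie-break
    inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prodf <- Reduce(function(a, b) factor_multiply(a, b, states_list),
                    factors[inv])
    factors <- c(factors[!inv], list(factor_sum_out(prodf, v, states_list)))
    elim <- setdiff(elim, v)
  }
  res <- Reduce(function(a, b) factor_multiply(a, b, states_list), factors)
  states <- node_states(net, target)
  vals <- res$values[match(states, res$grid[[target]])]
  z <- sum(vals)
  if (!is.finite(z) || z <= 0)
    stop("evidence has probability zero under the model: ",
         paste(names(evidence), unlist(evidence), sep = "=", collapse = ", "))
  stats::setNames(vals / z, states)
}
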