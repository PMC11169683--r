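# ---- CPT machinery ---------------------------------------------------------

# parent configurations in row-major order (last parent varies fastest);
# zero parents -> a single empty configuration
parent_configs <- function(states_list) {
  if (length(states_list) == 0)
    return(structure(data.frame(row.names = "1"), names = character()))
  g <- expand.grid(rev(states_list), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(states_list)), drop = FALSE]
  names(g) <- names(states_list)
  rownames(g) <- NULL
  g
}

config_key <- function(df) {
  if (ncol(df) == 0) return(rep("", nrow(df)))
  do.call(paste, c(df, sep = "\x1f"))
}

new_cpt <- function(node, parents, configs, prob, counts = NULL,
                    alpha = NA_real_, unobserved = NULL) {
  stopifnot(nrow(prob) == nrow(configs))
  if (any(prob < 0)) stop("CPT for ", node, " has negative probabilities")
  bad <- abs(rowSums(prob) - 1) > 1e-9
  if (any(bad))
    stop("CPT row(s) for ", node, " do not sum to 1: rows ",
         paste(which(bad), collapse = ", "))
  structure(list(node = node, parents = parents, configs = configs,
                 prob = prob, counts = counts, alpha = alpha,
                 unobserved = unobserved %||% rep(FALSE, nrow(configs))),
            class = "hfacs_cpt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_hfacs_bn <- function(network, cpts, provenance) {
  viol <- validate_network(network)
  if (length(viol)) stop("invalid network: ", paste(viol, collapse = "; "))
  stopifnot(setequal(names(cpts), network$nodes$code))
  for (code in network$nodes$code) {
    cpt <- cpts[[code]]
    if (!identical(cpt$parents, parents_of(network, code)))
      stop("CPT parent set for ", code, " does not match the network")
    if (!identical(colnames(cpt$prob), node_states(network, code)))
      stop("CPT state columns for ", code, " do not match the network")
  }
  structure(list(network = network, cpts = cpts[network$nodes$code],
                 provenance = provenance),
            class = "hfacs_bn")
}

# ---- fitting ---------------------------------------------------------------

#' Fit a layered Bayesian network to a coded-incident case database
#'
#' The model is a discrete Bayesian network on a layered factor network: the
#' joint probability of a full assignment factorizes as the product, over
#' nodes, of the probability of the node's state given its parents' states.
#' Each node's conditional probability table (CPT) is estimated from fully
#' observed records by pseudo-count-smoothed maximum likelihood: for parent
#' configuration c with observed child-state counts n(s|c),
#' P(s|c) = (n(s|c) + alpha) / (sum_s' n(s'|c) + alpha * K), where K is the
#' number of child states. `alpha = 1` (the default) is add-one Dirichlet
#' smoothing; `alpha = 0` is the pure maximum-likelihood estimate, in which
#' case parent configurations never observed in the data get a uniform row and
#' are flagged in the fit's provenance.
#'
#' @param data an `hfacs_cases` database (see [read_case_db()] /
#'   [as_case_db()]) or a data.frame coercible to one.
#' @param network the governing `hfacs_network`; defaults to the network
#'   carried by `data`, or to [hfacs_network()].
#' @param alpha non-negative Dirichlet pseudo-count added to every cell.
#' @return An object of class `hfacs_bn`: list with elements `network`, `cpts`
#'   (one `hfacs_cpt` per node, carrying the probability matrix, the raw
#'   counts and the per-configuration unobserved flags) and `provenance`
#'   (n_cases, alpha, unobserved configuration labels, fitting timestamp).
#'   Methods: [print.hfacs_bn()], [summary.hfacs_bn()], `coef()` (named list
#'   of CPT probability matrices), `logLik()`, [simulate.hfacs_bn()],
#'   [predict.hfacs_bn()].
#' @seealso [query()] for posterior inference, [sensitivity_matrix()] for the
#'   risk-change sensitivity analysis.
#' @export
#' @examples
#' db <- synthetic_cases()
#' fit <- hfacs_bn(db, alpha = 1)
#' fit
#' query(fit, "IS")                      # prior marginal
#' query(fit, "IS", list(RM = "yes"))    # posterior under evidence
hfacs_bn <- function(data, network = NULL, alpha = 1) {
  if (!inherits(data, "hfacs_cases"))
    data <- as_case_db(data, network %||% hfacs_network())
  network <- network %||% data$network
  if (nrow(data$records) == 0) stop("empty case database")
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha < 0)
    stop("alpha must be a single non-negative number")

  rec <- data$records
  cpts <- list()
  loglik <- 0
  unseen <- character()
  for (code in topological_order(network)) {
    pars <- parents_of(network, code)
    states <- node_states(network, code)
    configs <- parent_configs(network$states[pars])
    pk <- factor(config_key(rec[, pars, drop = FALSE]),
                 levels = config_key(configs))
    sk <- factor(rec[[code]], levels = states)
    counts <- unclass(table(pk, sk))
    k <- length(states)
    denom <- rowSums(counts) + alpha * k
    prob <- (counts + alpha) / denom
    unobs <- rowSums(counts) == 0
    if (alpha == 0 && any(unobs)) {
      prob[unobs, ] <- 1 / k
      unseen <- c(unseen, paste0(code, "[", config_key(configs)[unobs], "]"))
    }
    dimnames(prob) <- list(NULL, states)
    cpts[[code]] <- new_cpt(code, pars, configs, prob, counts = unclass(counts),
                            alpha = alpha, unobserved = unname(unobs))
    ridx <- as.integer(pk); sidx <- as.integer(sk)
    loglik <- loglik + sum(log(prob[cbind(ridx, sidx)]))
  }
  bn <- new_hfacs_bn(network, cpts,
                     provenance = list(method = "case-learning",
                                       n_cases = nrow(rec), alpha = alpha,
                                       unobserved_configs = unseen,
                                       fitted_at = format(Sys.time(), tz = "UTC")))
  bn$loglik <- loglik
  bn
}

#' Construct a Bayesian network from author-specified CPTs
#'
#' Used for ground-truth specifications, stubs in tests, and deserialization.
#' Each table is a probability matrix with one row per parent configuration in
#' row-major order (last parent varying fastest, parents in canonical network
#' order) and one column per node state.
#'
#' @param network an `hfacs_network`.
#' @param tables named list (one entry per node code) of probability matrices;
#'   rows must sum to 1.
#' @param provenance optional metadata list.
#' @return An `hfacs_bn` object.
#' @export
make_bn <- function(network, tables, provenance = list(method = "authored")) {
  cpts <- list()
  for (code in network$nodes$code) {
    pars <- parents_of(network, code)
    states <- node_states(network, code)
    configs <- parent_configs(network$states[pars])
    tab <- tables[[code]]
    if (is.null(tab)) stop("no table supplied for node ", code)
    tab <- as.matrix(tab)
    if (nrow(tab) != nrow(configs) || ncol(tab) != length(states))
      stop("table for ", code, " must be ", nrow(configs), " x ", length(states))
    dimnames(tab) <- list(NULL, states)
    cpts[[code]] <- new_cpt(code, pars, configs, tab)
  }
  new_hfacs_bn(network, cpts, provenance)
}

#' Random CPTs on a network, for property tests and oracle checks
#'
#' Draws every CPT row independently from a flat Dirichlet distribution.
#'
#' @param network an `hfacs_network`.
#' @param seed integer seed; the draw is fully reproducible.
#' @return An `hfacs_bn` with random valid CPTs.
#' @export
random_bn <- function(network = hfacs_network(), seed = 1) {
  with_preserved_rng({
    set.seed(as.integer(seed))
    tables <- lapply(network$nodes$code, function(code) {
      pars <- parents_of(network, code)
      k <- length(node_states(network, code))
      nc <- nrow(parent_configs(network$states[pars]))
      m <- matrix(stats::rgamma(nc * k, shape = 1), nrow = nc)
      m / rowSums(m)
    })
    names(tables) <- network$nodes$code
    make_bn(network, tables, provenance = list(method = "random", seed = seed))
  })
}

# run expr without disturbing the caller's RNG stream
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# ---- methods ---------------------------------------------------------------

#' @export
print.hfacs_bn <- function(x, ...) {
  cat("Layered Bayesian network (", nrow(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges)\n", sep = "")
  pv <- x$provenance
  cat("fitted by ", pv$method %||% "unknown",
      if (!is.null(pv$n_cases)) paste0(" from ", pv$n_cases, " cases"),
      if (!is.null(pv$alpha)) paste0(", alpha = ", pv$alpha), "\n", sep = "")
  if (length(pv$unobserved_configs))
    cat("unobserved parent configurations set uniform:",
        length(pv$unobserved_configs), "\n")
  cat("Prior marginal P(occurrence) per factor:\n")
  pm <- prior_marginals(x)
  occ <- vapply(seq_len(nrow(pm)), function(i)
    pm$state[i] %in% c("yes", setdiff(node_states(x$network, pm$node[i]),
                                      c("no", "none"))), TRUE)
  agg <- stats::aggregate(probability ~ node, pm[occ, ], sum)
  agg <- agg[match(topological_order(x$network), agg$node), ]
  cat(paste0("  ", format(agg$node, width = 4), " ",
             sprintf("%.3f", agg$probability)), sep = "\n")
  invisible(x)
}

#' Summary of a fitted layered Bayesian network
#'
#' @param object an `hfacs_bn`.
#' @param ... ignored.
#' @return A list with the prior marginal table (every node/state) and the
#'   provenance, printed compactly.
#' @export
summary.hfacs_bn <- function(object, ...) {
  out <- list(priors = prior_marginals(object), provenance = object$provenance,
              loglik = object$loglik)
  class(out) <- "summary.hfacs_bn"
  out
}

#' @export
print.summary.hfacs_bn <- function(x, ...) {
  cat("Prior marginal distributions:\n")
  pr <- x$priors
  pr$probability <- round(pr$probability, 4)
  print(pr, row.names = FALSE)
  if (!is.null(x$loglik)) cat("log-likelihood of training cases:",
                              format(x$loglik), "\n")
  invisible(x)
}

#' @export
coef.hfacs_bn <- function(object, ...) lapply(object$cpts, function(cpt) {
  m <- cpt$prob
  rownames(m) <- config_key(cpt$configs)
  m
})

#' @export
logLik.hfacs_bn <- function(object, ...) {
  if (is.null(object$loglik)) stop("no training data attached to this model")
  structure(object$loglik, df = sum(vapply(object$cpts, function(cpt)
    nrow(cpt$prob) * (ncol(cpt$prob) - 1), 1)), class = "logLik")
}

#' Posterior distributions for every non-evidence node
#'
#' Convenience wrapper around [query()]: computes the exact posterior of each
#' requested node given the evidence.
#'
#' @param object an `hfacs_bn`.
#' @param evidence named list of asserted states, e.g. `list(RM = "yes")`.
#' @param targets node codes to query (default: all non-evidence nodes).
#' @param ... ignored.
#' @return data.frame with columns `node`, `state`, `probability`.
#' @export
predict.hfacs_bn <- function(object, evidence = list(), targets = NULL, ...) {
  targets <- targets %||% setdiff(topological_order(object$network),
                                  names(evidence))
  rows <- lapply(targets, function(code) {
    d <- query(object, code, evidence)
    data.frame(node = code, state = names(d), probability = unname(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

prior_marginals <- function(bn) predict(bn, evidence = list())

# ---- serialization ---------------------------------------------------------

#' Read / write a fitted network as JSON
#'
#' Stores, per node, the parent order, the parent-configuration keys in
#' row-major order of the parent state lists, and the probability vectors (at
#' full double precision, so a write/read round trip reproduces the model
#' exactly), together with the network definition and provenance.
#'
#' @param bn an `hfacs_bn`.
#' @param path file path.
#' @return `read_bn_json()` returns an `hfacs_bn`; `write_bn_json()` returns
#'   `path` invisibly.
#' @export
write_bn_json <- function(bn, path) {
  net <- bn$network
  lvls <- sort(unique(net$nodes$level), decreasing = TRUE)
  levels_out <- lapply(lvls, function(l) {
    sel <- which(net$nodes$level == l)
    list(level = l, nodes = lapply(sel, function(i) {
      code <- net$nodes$code[i]
      list(code = code, label = net$nodes$label[i],
           states = as.list(net$states[[code]]))
    }))
  })
  cpts_out <- lapply(bn$cpts, function(cpt) {
    list(node = cpt$node, parents = as.list(cpt$parents),
         config_keys = as.list(gsub("\x1f", "|", config_key(cpt$configs))),
         prob = apply(cpt$prob, 1, as.list, simplify = FALSE),
         counts = if (!is.null(cpt$counts))
           apply(cpt$counts, 1, as.list, simplify = FALSE),
         alpha = cpt$alpha, unobserved = as.list(cpt$unobserved))
  })
  jsonlite::write_json(list(format = "bnhfacs-model-1", levels = levels_out,
                            cpts = cpts_out, provenance = bn$provenance),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "bnhfacs-model-1"))
    stop("not a bnhfacs model file: ", path)
  rows <- list(); states <- list()
  for (lv in obj$levels) for (nd in lv$nodes) {
    rows[[length(rows) + 1L]] <- data.frame(code = nd$code, label = nd$label,
                                            level = as.integer(lv$level),
                                            stringsAsFactors = FALSE)
    states[[nd$code]] <- unlist(nd$states)
  }
  net <- layered_network(do.call(rbind, rows), states)
  cpts <- list()
  for (cp in obj$cpts) {
    code <- cp$node
    prob <- do.call(rbind, lapply(cp$prob, function(r) unlist(r)))
    counts <- if (!is.null(cp$counts))
      do.call(rbind, lapply(cp$counts, function(r) unlist(r)))
    configs <- parent_configs(net$states[unlist(cp$parents)])
    dimnames(prob) <- list(NULL, node_states(net, code))
    cpts[[code]] <- new_cpt(code, unlist(cp$parents) %||% character(), configs,
                            prob, counts = counts,
                            alpha = cp$alpha %||% NA_real_,
                            unobserved = unlist(cp$unobserved))
  }
  prov <- obj$provenance
  bn <- new_hfacs_bn(net, cpts, provenance = prov)
  bn
}
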