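# ---- additive CPT construction ---------------------------------------------

# CPT for a binary child: P(yes | parents) = base + sum(delta[p] * I(p = yes)).
# Linear-in-parents form, so the child's marginal is base + sum(delta * P(parent
# = yes)) exactly, whatever the dependence among the parents.
additive_binary_cpt <- function(states_list, base, delta) {
  configs <- parent_configs(states_list)
  yes <- base + as.matrix(configs == "yes") %*% delta[names(states_list)]
  if (any(yes < 0 | yes > 1)) stop("additive CPT leaves [0, 1]")
  cbind(yes = as.vector(yes), no = 1 - as.vector(yes))
}

# CPT for a multi-state child with a residual "none" state: each named state s
# gets base[s] + sum(delta[s, p] * I(p = yes)); "none" absorbs the remainder.
additive_multistate_cpt <- function(states_list, states, base, delta) {
  configs <- parent_configs(states_list)
  ind <- as.matrix(configs == "yes")
  named <- setdiff(states, "none")
  m <- sapply(named, function(s) base[[s]] + ind %*% delta[s, names(states_list)])
  m <- cbind(m, none = 1 - rowSums(m))
  colnames(m) <- c(named, "none")
  if (any(m < 0 | m > 1)) stop("additive CPT leaves [0, 1]")
  m[, states, drop = FALSE]
}

#' Packaged ground-truth model for the synthetic incident generator
#'
#' A hand-authored, fully specified Bayesian network on the canonical HFACS
#' network, playing the role of the (unpublished) coding database that real
#' analyses would learn from. Its CPTs use an additive parent-effect form, so
#' its exact marginal occurrence rates are set by construction; they match the
#' published prior rates for radiotherapy incidents: skill-based errors 37.5%,
#' condition of operators 49.6%, personnel factors 59.8%, inadequate
#' supervision 57.6%, organizational climate 25.3% (all to within a small
#' rounding remainder), with the remaining rates chosen at plausible values
#' (resource management 9.4%, organizational process 20%, routine violations
#' 22% above exceptional 8%, environmental factors 20%). The resource-
#' management effect on inadequate supervision is calibrated so that
#' P(IS = yes | RM = yes) = 0.624 and P(IS = yes | RM = no) = 0.571, the
#' worked-example posteriors of the sensitivity statistic.
#'
#' The model carries the packaged phase/error-type distribution (see
#' [phase_error_counts()]) as its label sampler, so simulated incidents are
#' annotated like real reports.
#'
#' @return An `hfacs_bn` with authored CPTs and a `label_weights` attribute.
#' @seealso [sample_incidents()], [recovery_experiment()].
#' @export
default_truth <- function() {
  net <- hfacs_network()
  st <- net$states
  yn <- function(p) cbind(yes = p, no = 1 - p)
  l4 <- c(RM = 0.094, OC = 0.253, OP = 0.20)
  tables <- list(RM = yn(l4[["RM"]]), OC = yn(l4[["OC"]]), OP = yn(l4[["OP"]]))

  p4 <- st[c("RM", "OC", "OP")]
  # level 3: marginals IS .576, PIO .350, FCP .250, SV .150
  l3 <- list(
    IS  = list(delta = c(RM = 0.053, OC = 0.30, OP = 0.10), target = 0.576),
    PIO = list(delta = c(RM = 0.10,  OC = 0.25, OP = 0.08), target = 0.350),
    FCP = list(delta = c(RM = 0.30,  OC = 0.00, OP = 0.12), target = 0.250),
    SV  = list(delta = c(RM = 0.35,  OC = 0.00, OP = 0.15), target = 0.150))
  m3 <- numeric()
  for (code in names(l3)) {
    d <- l3[[code]]$delta
    base <- l3[[code]]$target - sum(d * l4)
    tables[[code]] <- additive_binary_cpt(p4, base, d)
    m3[code] <- l3[[code]]$target
  }

  p3 <- st[c("IS", "PIO", "FCP", "SV")]
  # level 2: marginals CO .496, PF .598, EF .200
  l2 <- list(
    CO = list(delta = c(IS = 0.05, PIO = 0.15, FCP = 0.12, SV = 0.10), target = 0.496),
    PF = list(delta = c(IS = 0.04, PIO = 0.05, FCP = 0.05, SV = 0.04), target = 0.598),
    EF = list(delta = c(IS = 0.02, PIO = 0.03, FCP = 0.25, SV = 0.28), target = 0.200))
  m2 <- numeric()
  for (code in names(l2)) {
    d <- l2[[code]]$delta
    base <- l2[[code]]$target - sum(d * m3[names(d)])
    tables[[code]] <- additive_binary_cpt(p3, base, d)
    m2[code] <- l2[[code]]$target
  }

  p2 <- st[c("CO", "PF", "EF")]
  # level 1: error marginals skill .375, decision .15, perception .08;
  # violation marginals routine .22, exceptional .08
  err_delta <- rbind(skill      = c(CO = 0.38, PF = 0.02, EF = 0.00),
                     decision   = c(CO = 0.00, PF = 0.14, EF = 0.00),
                     perception = c(CO = 0.00, PF = 0.00, EF = 0.15))
  err_target <- c(skill = 0.375, decision = 0.15, perception = 0.08)
  err_base <- err_target - as.vector(err_delta %*% m2[colnames(err_delta)])
  tables$ERR <- additive_multistate_cpt(p2, st$ERR, err_base, err_delta)

  vio_delta <- rbind(routine     = c(CO = 0.08, PF = 0.28, EF = 0.00),
                     exceptional = c(CO = 0.00, PF = 0.00, EF = 0.30))
  vio_target <- c(routine = 0.22, exceptional = 0.08)
  vio_base <- vio_target - as.vector(vio_delta %*% m2[colnames(vio_delta)])
  tables$VIO <- additive_multistate_cpt(p2, st$VIO, vio_base, vio_delta)

  bn <- make_bn(net, tables,
                provenance = list(method = "authored ground truth",
                                  calibration = "additive parent effects; marginals fixed by construction"))
  attr(bn, "label_weights") <- phase_error_counts()
  bn
}

# ---- ancestral sampling -----------------------------------------------------

# deterministic per-node seed stream derived from the master seed and the node
# code, so adding or reordering nodes never perturbs other columns
node_seed <- function(seed, code) {
  h <- 0
  for (ch in utf8ToInt(code)) h <- (h * 131 + ch) %% 1048573
  (as.numeric(as.integer(seed)) %% 2147483647 * 7919 + h) %% 2147483647
}

#' Simulate coded incidents from a Bayesian network by ancestral sampling
#'
#' Draws full incident codings from the model: nodes are sampled in
#' topological order (top level first), each conditioned on its sampled parent
#' states, which realizes the factorized joint distribution exactly. Each node
#' consumes its own seed stream derived from `seed` and the node code, so the
#' draw is fully reproducible. If the model carries a `label_weights` table
#' (see [default_truth()]), each record is annotated with a `(phase,
#' error_type)` label drawn from it, independently of the coded factors.
#'
#' @param object an `hfacs_bn` with valid CPTs.
#' @param nsim number of incidents to draw.
#' @param seed integer master seed; if `NULL`, one is drawn from the session
#'   RNG. The caller's RNG state is left untouched either way.
#' @param ... ignored.
#' @return An `hfacs_cases` database of `nsim` records with incident ids
#'   `S0001`, `S0002`, ...
#' @export
simulate.hfacs_bn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.numeric(nsim) || length(nsim) != 1 || is.na(nsim) || nsim < 1)
    stop("nsim must be a positive integer")
  nsim <- as.integer(nsim)
  net <- object$network
  with_preserved_rng({
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
    cols <- list()
    for (code in topological_order(net)) {
      cpt <- object$cpts[[code]]
      states <- node_states(net, code)
      ridx <- if (length(cpt$parents)) {
        key <- do.call(paste, c(cols[cpt$parents], sep = "\x1f"))
        match(key, config_key(cpt$configs))
      } else rep(1L, nsim)
      cmat <- t(apply(cpt$prob, 1, cumsum))
      cmat[, ncol(cmat)] <- 1  # guard against cumulative rounding in the last bin
      set.seed(node_seed(seed, code))
      u <- stats::runif(nsim)
      si <- max.col(u <= cmat[ridx, , drop = FALSE], ties.method = "first")
      cols[[code]] <- states[si]
    }
    rec <- data.frame(incident_id = sprintf("S%04d", seq_len(nsim)),
                      stringsAsFactors = FALSE)
    lw <- attr(object, "label_weights")
    if (!is.null(lw)) {
      set.seed(node_seed(seed, ".labels"))
      li <- sample.int(nrow(lw), nsim, replace = TRUE, prob = lw$count)
      rec$phase <- lw$phase[li]
      rec$error_type <- lw$error_type[li]
    } else {
      rec$phase <- NA_character_
      rec$error_type <- NA_character_
    }
    for (code in topological_order(net)) rec[[code]] <- cols[[code]]
    as_case_db(rec, net)
  })
}

#' @rdname simulate.hfacs_bn
#' @param truth an `hfacs_bn` ground-truth model (e.g. [default_truth()]).
#' @param n number of incidents.
#' @export
sample_incidents <- function(truth, n, seed = NULL) {
  simulate(truth, nsim = n, seed = seed)
}

# ---- parameter recovery -----------------------------------------------------

#' Parameter-recovery experiment: sample, refit, compare CPTs
#'
#' Samples `n` incidents from a ground-truth model, refits the CPTs with
#' [hfacs_bn()], and scores recovery by total-variation distance (half the L1
#' distance) between the true and refitted probability vector of every parent
#' configuration. The headline summary is the maximum distance over
#' configurations observed at least `min_obs` times, since rarely observed
#' rows carry little information.
#'
#' @param truth an `hfacs_bn` ground-truth model.
#' @param n number of incidents to sample (>= 1).
#' @param alpha pseudo-count for the refit (default 1).
#' @param seed integer master seed for the sampling draw.
#' @param min_obs observation threshold for the headline maximum (default 50).
#' @return An object of class `recovery_report`: list with `rows` (data.frame
#'   node / config / n_obs / tv), `headline_max_tv`, `mean_tv`, `n`, `alpha`,
#'   `seed`, `min_obs`.
#' @export
#' @examples
#' rep <- recovery_experiment(default_truth(), n = 500, alpha = 1, seed = 11)
#' rep$headline_max_tv
recovery_experiment <- function(truth, n, alpha = 1, seed = NULL, min_obs = 50) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    stop("n must be a positive integer")
  db <- sample_incidents(truth, n, seed = seed)
  fit <- hfacs_bn(db, truth$network, alpha = alpha)
  rows <- list()
  for (code in topological_order(truth$network)) {
    pt <- truth$cpts[[code]]$prob
    pf <- fit$cpts[[code]]$prob
    nobs <- rowSums(fit$cpts[[code]]$counts)
    tv <- 0.5 * rowSums(abs(pt - pf))
    rows[[code]] <- data.frame(node = code,
                               config = config_key(truth$cpts[[code]]$configs),
                               n_obs = as.vector(nobs), tv = as.vector(tv),
                               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  sel <- rows$n_obs >= min_obs
  structure(list(rows = rows,
                 headline_max_tv = if (any(sel)) max(rows$tv[sel]) else NA_real_,
                 mean_tv = mean(rows$tv), n = n, alpha = alpha, seed = seed,
                 min_obs = min_obs),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("CPT recovery from", x$n, "sampled incidents (alpha =", x$alpha, ")\n")
  cat("max TV over rows with >=", x$min_obs, "observations:",
      format(x$headline_max_tv, digits = 4), "\n")
  cat("mean TV over all", nrow(x$rows), "rows:",
      format(x$mean_tv, digits = 4), "\n")
  invisible(x)
}
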