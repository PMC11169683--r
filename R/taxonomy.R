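#' Construct a layered causal-factor network
#'
#' A layered network is a directed acyclic graph in which nodes live on
#' numbered levels (level 1 at the bottom, higher numbers above) and every node
#' on level L+1 is a parent of every node on level L; no other edges exist.
#' This is the structure the HFACS incident-causation hierarchy implies when
#' each level's factors are treated as mutually independent given the level
#' above.
#'
#' @param nodes data.frame with columns `code` (unique short identifier),
#'   `label` (human-readable name) and `level` (integer; 1 = bottom).
#' @param states named list mapping each code to its ordered character vector
#'   of state names.
#' @return An object of class `hfacs_network`: a list with elements `nodes`
#'   (the node table, ordered top level first), `states`, and `edges`
#'   (data.frame of `parent`, `child` code pairs implied by the layering).
#' @seealso [hfacs_network()] for the canonical HFACS taxonomy,
#'   [validate_network()] for invariant checking.
#' @export
#' @examples
#' chain <- layered_network(
#'   data.frame(code = c("A", "B", "C"), label = c("A", "B", "C"),
#'              level = c(3, 2, 1)),
#'   list(A = c("yes", "no"), B = c("yes", "no"), C = c("yes", "no")))
#' validate_network(chain)
layered_network <- function(nodes, states) {
  stopifnot(is.data.frame(nodes), all(c("code", "label", "level") %in% names(nodes)))
  nodes <- data.frame(code = as.character(nodes$code),
                      label = as.character(nodes$label),
                      level = as.integer(nodes$level),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$code))
    stop("duplicate node codes: ", paste(unique(nodes$code[duplicated(nodes$code)]), collapse = ", "))
  missing_states <- setdiff(nodes$code, names(states))
  if (length(missing_states))
    stop("no states given for node(s): ", paste(missing_states, collapse = ", "))
  # order: top level first, original order within a level
  nodes <- nodes[order(-nodes$level, seq_len(nrow(nodes))), , drop = FALSE]
  rownames(nodes) <- NULL
  states <- lapply(states[nodes$code], as.character)
  net <- structure(list(nodes = nodes, states = states,
                        edges = complete_layer_edges(nodes)),
                   class = "hfacs_network")
  net
}

# all (parent, child) pairs between adjacent levels, parents one level up
complete_layer_edges <- function(nodes) {
  lvls <- sort(unique(nodes$level), decreasing = TRUE)
  out <- list()
  for (l in lvls) {
    if (!((l - 1) %in% lvls)) next
    up <- nodes$code[nodes$level == l]
    dn <- nodes$code[nodes$level == l - 1]
    out[[length(out) + 1L]] <- expand.grid(child = dn, parent = up,
                                           KEEP.OUT.ATTRS = FALSE,
                                           stringsAsFactors = FALSE)[, c("parent", "child")]
  }
  if (!length(out)) return(data.frame(parent = character(), child = character()))
  ed <- do.call(rbind, out)
  rownames(ed) <- NULL
  ed
}

#' The canonical four-level HFACS network
#'
#' Returns the 12-node layered network used throughout the package:
#' level 4, organizational influences: resource management (RM), organizational
#' climate (OC), organizational process (OP); level 3, unsafe supervision:
#' inadequate supervision (IS), planned inappropriate operations (PIO), failure
#' to correct known problems (FCP), supervisory violations (SV); level 2,
#' preconditions for unsafe acts: condition of operators (CO), personnel
#' factors (PF), environmental factors (EF); level 1, unsafe acts: the
#' error-type node ERR with states skill/decision/perception/none and the
#' violation-type node VIO with states routine/exceptional/none.
#'
#' All binary nodes have states `c("yes", "no")`. Edges are the complete
#' bipartite connections between adjacent levels (30 edges; joint state space
#' 2^10 * 4 * 3 = 12288).
#'
#' @return An `hfacs_network` object.
#' @export
#' @examples
#' net <- hfacs_network()
#' nrow(net$nodes)   # 12
#' nrow(net$edges)   # 30
hfacs_network <- function() {
  yn <- c("yes", "no")
  nodes <- data.frame(
    code = c("RM", "OC", "OP",
             "IS", "PIO", "FCP", "SV",
             "CO", "PF", "EF",
             "ERR", "VIO"),
    label = c("Resource management", "Organizational climate", "Organizational process",
              "Inadequate supervision", "Planned inappropriate operations",
              "Failure to correct known problems", "Supervisory violations",
              "Condition of operators", "Personnel factors", "Environmental factors",
              "Error type", "Violation type"),
    level = c(4L, 4L, 4L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
  states <- c(
    stats::setNames(rep(list(yn), 10), nodes$code[1:10]),
    list(ERR = c("skill", "decision", "perception", "none"),
         VIO = c("routine", "exceptional", "none")))
  layered_network(nodes, states)
}

#' Validate the structural invariants of a layered network
#'
#' Checks a (possibly hand-edited) network against the layered-model
#' invariants: unique codes; binary yes/no states on every level above the
#' bottom; the canonical multi-state definitions for ERR and VIO when present;
#' at least two states per bottom-level node; every edge directed from a node
#' one level up to a node one level down; and layered completeness (every
#' adjacent-level pair connected, nothing else). Violations are returned, not
#' raised, so the function can be used to diagnose bad inputs.
#'
#' @param net an `hfacs_network` (or a structurally similar list).
#' @return Character vector of human-readable violation messages; empty when
#'   all invariants hold.
#' @export
validate_network <- function(net) {
  msgs <- character()
  nodes <- net$nodes
  if (anyDuplicated(nodes$code))
    msgs <- c(msgs, paste0("duplicate node code(s): ",
                           paste(unique(nodes$code[duplicated(nodes$code)]), collapse = ", ")))
  bottom <- min(nodes$level)
  for (i in seq_len(nrow(nodes))) {
    code <- nodes$code[i]
    st <- net$states[[code]]
    if (is.null(st) || length(st) < 2) {
      msgs <- c(msgs, paste0("node ", code, " has fewer than two states"))
      next
    }
    if (nodes$level[i] > bottom && !identical(st, c("yes", "no")))
      msgs <- c(msgs, paste0("node ", code, " above the bottom level must have states yes/no"))
    if (code == "ERR" && !identical(st, c("skill", "decision", "perception", "none")))
      msgs <- c(msgs, "node ERR must have states skill/decision/perception/none")
    if (code == "VIO" && !identical(st, c("routine", "exceptional", "none")))
      msgs <- c(msgs, "node VIO must have states routine/exceptional/none")
  }
  lvl <- stats::setNames(nodes$level, nodes$code)
  ed <- net$edges
  have <- character()
  for (i in seq_len(nrow(ed))) {
    p <- ed$parent[i]; ch <- ed$child[i]
    if (!(p %in% nodes$code) || !(ch %in% nodes$code)) {
      msgs <- c(msgs, paste0("edge (", p, " -> ", ch, ") references an unknown node"))
      next
    }
    if (lvl[[p]] != lvl[[ch]] + 1L)
      msgs <- c(msgs, paste0("edge (", p, " -> ", ch, ") does not connect adjacent levels downward (levels ",
                             lvl[[p]], " -> ", lvl[[ch]], ")"))
    have <- c(have, paste(p, ch, sep = "->"))
  }
  if (anyDuplicated(have))
    msgs <- c(msgs, paste0("duplicated edge(s): ", paste(unique(have[duplicated(have)]), collapse = ", ")))
  want_ed <- complete_layer_edges(nodes)
  want <- paste(want_ed$parent, want_ed$child, sep = "->")
  miss <- setdiff(want, have)
  if (length(miss))
    msgs <- c(msgs, paste0("missing required edge(s): ", paste(miss, collapse = ", ")))
  msgs
}

#' @export
print.hfacs_network <- function(x, ...) {
  cat("Layered factor network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  for (l in sort(unique(x$nodes$level), decreasing = TRUE)) {
    sel <- x$nodes$level == l
    cat("  level ", l, ": ", paste(x$nodes$code[sel], collapse = ", "), "\n", sep = "")
  }
  cat("joint state space:", format(joint_size(x), big.mark = ","), "configurations\n")
  invisible(x)
}

#' Number of joint configurations of a network
#'
#' @param net an `hfacs_network`.
#' @return Product of the per-node state-space sizes.
#' @export
joint_size <- function(net) prod(vapply(net$states, length, 1L))

node_level <- function(net, code) net$nodes$level[match(code, net$nodes$code)]

node_states <- function(net, code) net$states[[code]]

# parent codes in canonical (network node) order
parents_of <- function(net, code) {
  l <- node_level(net, code)
  net$nodes$code[net$nodes$level == l + 1L]
}

# nodes in topological order (top level first); the canonical node order
topological_order <- function(net) net$nodes$code

#' Read / write a layered network as JSON
#'
#' The file stores, per level, the nodes with their labels and state lists;
#' edges are implied by the layering and never listed. This lets other
#' facilities define alternative layered taxonomies in a plain text file.
#'
#' @param net an `hfacs_network`.
#' @param path file path.
#' @return `read_network_json()` returns an `hfacs_network`;
#'   `write_network_json()` returns `path` invisibly.
#' @export
write_network_json <- function(net, path) {
  lvls <- sort(unique(net$nodes$level), decreasing = TRUE)
  levels_out <- lapply(lvls, function(l) {
    sel <- which(net$nodes$level == l)
    list(level = l,
         nodes = lapply(sel, function(i) {
           code <- net$nodes$code[i]
           list(code = code, label = net$nodes$label[i],
                states = as.list(net$states[[code]]))
         }))
  })
  jsonlite::write_json(list(format = "bnhfacs-network-1", levels = levels_out),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "bnhfacs-network-1"))
    stop("not a bnhfacs network file: ", path)
  rows <- list(); states <- list()
  for (lv in obj$levels) {
    for (nd in lv$nodes) {
      rows[[length(rows) + 1L]] <- data.frame(code = nd$code, label = nd$label,
                                              level = as.integer(lv$level),
                                              stringsAsFactors = FALSE)
      states[[nd$code]] <- unlist(nd$states)
    }
  }
  layered_network(do.call(rbind, rows), states)
}

#' Plot a layered network
#'
#' Draws the nodes on their levels with the complete adjacent-level edge set,
#' using base graphics.
#'
#' @param x an `hfacs_network`.
#' @param ... ignored.
#' @export
plot.hfacs_network <- function(x, ...) {
  lvls <- sort(unique(x$nodes$level))
  xs <- ys <- numeric(nrow(x$nodes))
  for (l in lvls) {
    sel <- which(x$nodes$level == l)
    xs[sel] <- seq(0, 1, length.out = length(sel) + 2)[-c(1, length(sel) + 2)]
    ys[sel] <- (l - min(lvls)) / max(1, diff(range(lvls)))
  }
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(-0.1, 1.1))
  for (i in seq_len(nrow(x$edges))) {
    p <- match(x$edges$parent[i], x$nodes$code)
    ch <- match(x$edges$child[i], x$nodes$code)
    graphics::arrows(xs[p], ys[p] - 0.04, xs[ch], ys[ch] + 0.04,
                     length = 0.06, col = "grey60")
  }
  graphics::points(xs, ys, pch = 21, bg = "white", cex = 4)
  graphics::text(xs, ys, x$nodes$code, cex = 0.7)
  invisible(x)
}
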