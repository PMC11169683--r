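# ---- the sensitivity statistic ---------------------------------------------

#' Relative risk-change sensitivity of a pair of conditional probabilities
#'
#' The kernel of the sensitivity analysis: given the occurrence probability of
#' a lower-level factor when an upper-level factor is asserted present (`p1`)
#' and when it is asserted absent (`p0`), the sensitivity is the relative
#' increase (p1 - p0) / p0, truncated to 0 whenever the change is negative.
#' Only positive contributions of an upper factor are counted.
#'
#' @param p1 P(lower factor occurs | upper factor = "yes").
#' @param p0 P(lower factor occurs | upper factor = "no").
#' @return A single non-negative number.
#' @export
#' @examples
#' relative_sensitivity(0.624, 0.571)   # 0.0928..., rounds to 0.09
#' relative_sensitivity(0.3, 0.5)       # negative change: truncated to 0
relative_sensitivity <- function(p1, p0) {
  stopifnot(is.numeric(p1), is.numeric(p0), length(p1) == 1, length(p0) == 1,
            p1 >= 0, p1 <= 1, p0 >= 0, p0 <= 1)
  dp <- p1 - p0
  if (dp <= 0) return(0)
  if (p0 == 0)
    stop("undefined relative sensitivity: baseline probability p0 = 0 with p1 > 0")
  dp / p0
}

#' Sensitivity of a lower-level factor to an upper-level factor
#'
#' Computes the two posteriors P(lower = lower_state | upper = "yes") and
#' P(lower = lower_state | upper = "no") by exact inference through the full
#' network (the pair need not be parent and child) and applies
#' [relative_sensitivity()].
#'
#' @param bn an `hfacs_bn`.
#' @param upper code of a binary (yes/no) node whose level is strictly above
#'   the lower node's level.
#' @param lower code of the affected node.
#' @param lower_state the state of `lower` counting as an occurrence: "yes"
#'   for binary nodes (the default), or one named subtype state of a
#'   multi-state node (e.g. ERR = "skill"); never "no"/"none".
#' @return A single non-negative sensitivity value (full precision; round only
#'   for presentation).
#' @export
#' @examples
#' bn <- default_truth()
#' sensitivity(bn, upper = "RM", lower = "IS")           # level 4 on level 3
#' sensitivity(bn, upper = "CO", lower = "ERR", "skill") # level 2 on level 1
sensitivity <- function(bn, upper, lower, lower_state = "yes") {
  net <- bn$network
  if (!upper %in% net$nodes$code) stop("unknown upper node: ", upper)
  if (!lower %in% net$nodes$code) stop("unknown lower node: ", lower)
  if (!identical(node_states(net, upper), c("yes", "no")))
    stop("upper node ", upper, " must be binary with states yes/no")
  if (node_level(net, upper) <= node_level(net, lower))
    stop("upper node ", upper, " is not on a level above ", lower)
  if (lower_state %in% c("no", "none") ||
      !lower_state %in% node_states(net, lower))
    stop("lower_state must be an occurrence state of ", lower)
  p1 <- query(bn, lower, stats::setNames(list("yes"), upper))[[lower_state]]
  p0 <- query(bn, lower, stats::setNames(list("no"), upper))[[lower_state]]
  relative_sensitivity(p1, p0)
}

# ---- the full matrix --------------------------------------------------------

# row definitions: one row per occurrence state of every node below the top
# level; canonical subtype labels for the error/violation states
subtype_label <- function(code, state) {
  lbl <- c("ERR.skill" = "SBE", "ERR.decision" = "DE", "ERR.perception" = "PE",
           "VIO.routine" = "RV", "VIO.exceptional" = "EV")
  lbl[[paste(code, state, sep = ".")]] %||% paste(code, state, sep = ":")
}

sensitivity_rows <- function(net) {
  top <- max(net$nodes$level)
  rows <- list()
  for (i in seq_len(nrow(net$nodes))) {
    code <- net$nodes$code[i]; l <- net$nodes$level[i]
    if (l == top) next
    st <- node_states(net, code)
    occ <- if (identical(st, c("yes", "no"))) "yes" else setdiff(st, "none")
    for (s in occ)
      rows[[length(rows) + 1L]] <- data.frame(
        row = if (identical(st, c("yes", "no"))) code else subtype_label(code, s),
        node = code, state = s, level = l, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(-out$level, match(out$node, net$nodes$code)), , drop = FALSE]
}

#' Full upper-by-lower sensitivity matrix
#'
#' Computes [sensitivity()] for every (upper factor, lower factor) pair with
#' the upper node on a strictly higher level, expanding multi-state bottom
#' nodes into one row per occurrence state (skill-based errors SBE, decision
#' errors DE, perceptual errors PE, routine violations RV, exceptional
#' violations EV). Cells where the column's level is not above the row's
#' level are structurally empty (`NA` with `filled = FALSE`); cells whose
#' baseline probability is exactly zero are reported `NA` with a warning.
#'
#' @param bn an `hfacs_bn` fitted on a layered network.
#' @return An object of class `hfacs_sensitivity`: a numeric matrix (rows =
#'   lower factors/states grouped by level, columns = binary upper factors in
#'   top-down order) with attributes `rows` (data.frame row/node/state/level),
#'   `col_levels`, and `filled` (logical matrix marking structural cells).
#'   Values are full precision; printing rounds half-up to 2 decimals.
#' @export
sensitivity_matrix <- function(bn) {
  net <- bn$network
  rows <- sensitivity_rows(net)
  is_binary <- vapply(net$nodes$code, function(code)
    identical(node_states(net, code), c("yes", "no")), TRUE)
  cols <- net$nodes$code[is_binary & net$nodes$level > min(net$nodes$level)]
  col_lvl <- node_level(net, cols)
  m <- matrix(NA_real_, nrow(rows), length(cols),
              dimnames = list(rows$row, cols))
  filled <- matrix(FALSE, nrow(rows), length(cols),
                   dimnames = dimnames(m))
  for (j in seq_along(cols)) for (i in seq_len(nrow(rows))) {
    if (col_lvl[j] <= rows$level[i]) next
    filled[i, j] <- TRUE
    m[i, j] <- tryCatch(
      sensitivity(bn, cols[j], rows$node[i], rows$state[i]),
      error = function(e) {
        warning("sensitivity undefined for ", cols[j], " -> ", rows$row[i],
                ": ", conditionMessage(e), call. = FALSE)
        NA_real_
      })
  }
  structure(m, rows = rows, col_levels = col_lvl, filled = filled,
            class = c("hfacs_sensitivity", "matrix"))
}

# half-up rounding for presentation (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  ifelse(is.na(x), NA_real_, floor(x * s + 0.5) / s)
}

#' @export
print.hfacs_sensitivity <- function(x, digits = 2, ...) {
  m <- round_half_up(unclass(x), digits)
  disp <- format(m, nsmall = digits)
  disp[!attr(x, "filled")] <- ""
  rows <- attr(x, "rows")
  cat("Sensitivity of lower factors (rows) to upper factors (columns):\n")
  print(data.frame(level = rows$level, disp, check.names = FALSE),
        right = TRUE)
  invisible(x)
}

#' Export a sensitivity matrix as CSV
#'
#' In wide form the file mirrors the on-screen matrix (rows grouped by level,
#' blank cells for structurally empty entries, values rounded half-up); in
#' long form each computed cell becomes a row `(upper, lower, lower_state,
#' value, status)` at full precision, with status `ok` or `undefined`.
#'
#' @param sm an `hfacs_sensitivity` matrix.
#' @param path output path.
#' @param digits decimals for the wide form (default 2).
#' @param long write the long form instead of the wide table.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(sm, path, digits = 2, long = FALSE) {
  rows <- attr(sm, "rows")
  if (long) {
    filled <- attr(sm, "filled")
    idx <- which(filled, arr.ind = TRUE)
    out <- data.frame(upper = colnames(sm)[idx[, 2]],
                      lower = rows$node[idx[, 1]],
                      lower_state = rows$state[idx[, 1]],
                      value = sm[filled],
                      status = ifelse(is.na(sm[filled]), "undefined", "ok"),
                      stringsAsFactors = FALSE)
    out <- out[order(match(out$upper, colnames(sm)),
                     match(out$lower, rows$node)), , drop = FALSE]
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    m <- round_half_up(unclass(sm), digits)
    disp <- matrix(sprintf(paste0("%.", digits, "f"), m), nrow(m),
                   dimnames = dimnames(m))
    disp[!attr(sm, "filled") | is.na(m)] <- ""
    out <- data.frame(level = rows$level, factor = rows$row, disp,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

# ---- aggregation over error / violation states -----------------------------

#' Overall sensitivity of errors and violations to each upper factor
#'
#' Aggregates the sensitivity matrix over the occurrence states of the
#' multi-state bottom nodes: for each upper factor, the errors score is the
#' mean sensitivity over the three error states (SBE, DE, PE) and the
#' violations score the mean over the two violation states (RV, EV). Values
#' are non-negative by construction, so the mean of absolute values equals the
#' plain mean. `NA` cells are excluded with a warning; an all-`NA` group
#' yields an `NA` score.
#'
#' @param bn an `hfacs_bn`, or a precomputed `hfacs_sensitivity` matrix.
#' @return An object of class `hfacs_overall`: data.frame with columns
#'   `factor`, `level`, `errors`, `violations`.
#' @export
overall_sensitivity <- function(bn) {
  sm <- if (inherits(bn, "hfacs_sensitivity")) bn else sensitivity_matrix(bn)
  rows <- attr(sm, "rows")
  bottom <- min(rows$level)
  groups <- list(errors = rows$node == "ERR" & rows$level == bottom,
                 violations = rows$node == "VIO" & rows$level == bottom)
  score <- function(sel, j) {
    sel <- sel & attr(sm, "filled")[, j]
    if (!any(sel)) return(NA_real_)
    v <- sm[sel, j]
    if (anyNA(v)) {
      warning("excluding undefined cells from the overall mean", call. = FALSE)
      v <- v[!is.na(v)]
    }
    if (!length(v)) NA_real_ else mean(abs(v))
  }
  out <- data.frame(factor = colnames(sm), level = attr(sm, "col_levels"),
                    errors = vapply(seq_len(ncol(sm)), function(j)
                      score(groups$errors, j), 1),
                    violations = vapply(seq_len(ncol(sm)), function(j)
                      score(groups$violations, j), 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("hfacs_overall", "data.frame")
  out
}

#' @export
print.hfacs_overall <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$errors <- round_half_up(y$errors, digits)
  y$violations <- round_half_up(y$violations, digits)
  cat("Mean sensitivity of overall errors / violations to each upper factor:\n")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Bubble plot of overall sensitivities
#'
#' Circle area reflects the mean sensitivity of overall errors (top row) and
#' overall violations (bottom row) to each upper-level factor.
#'
#' @param x an `hfacs_overall` table.
#' @param ... ignored.
#' @export
plot.hfacs_overall <- function(x, ...) {
  n <- nrow(x)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, n + 0.5), ylim = c(0.5, 2.5))
  vals <- rbind(x$errors, x$violations)
  mx <- max(vals, na.rm = TRUE)
  for (i in seq_len(n)) for (r in 1:2) {
    v <- vals[r, i]
    if (!is.na(v) && mx > 0)
      graphics::symbols(i, 3 - r, circles = 0.4 * sqrt(v / mx),
                        inches = FALSE, add = TRUE, bg = "grey70")
  }
  graphics::axis(1, at = seq_len(n), labels = x$factor, las = 2)
  graphics::axis(2, at = c(2, 1), labels = c("errors", "violations"), las = 1)
  graphics::title(main = "Overall sensitivity of unsafe acts")
  invisible(x)
}
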