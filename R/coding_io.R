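#' Assemble a validated case database of coded incidents
#'
#' A case database is the learning input: one fully observed categorical
#' assignment over the network's nodes per incident, optionally annotated with
#' the treatment phase and a free-text error type. State strings are matched
#' case-insensitively and trimmed; canonical forms are lowercase.
#'
#' @param records data.frame with a character `incident_id` column, one column
#'   per network node, and optional `phase` / `error_type` columns.
#' @param network the governing `hfacs_network` (default: [hfacs_network()]).
#' @param missing how to treat rows with an empty/NA cell in a node column:
#'   `"strict"` (default) raises an error; `"drop"` skips the row with a
#'   warning. There is no missing-data estimation: learning assumes complete
#'   cases.
#' @return An object of class `hfacs_cases`: list with elements `network` and
#'   `records` (normalized data.frame).
#' @export
as_case_db <- function(records, network = hfacs_network(),
                       missing = c("strict", "drop")) {
  missing <- match.arg(missing)
  stopifnot(is.data.frame(records))
  codes <- network$nodes$code
  absent <- setdiff(c("incident_id", codes), names(records))
  if (length(absent))
    stop("case database is missing required column(s): ",
         paste(absent, collapse = ", "))
  if (!"phase" %in% names(records))
    records$phase <- rep(NA_character_, nrow(records))
  if (!"error_type" %in% names(records))
    records$error_type <- rep(NA_character_, nrow(records))

  norm <- function(x) tolower(trimws(as.character(x)))
  ids <- trimws(as.character(records$incident_id))
  if (anyDuplicated(ids))
    stop("duplicate incident_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  node_mat <- lapply(codes, function(code) norm(records[[code]]))
  names(node_mat) <- codes
  empty <- Reduce(`|`, lapply(node_mat, function(v) is.na(v) | v == "" | v == "na"))
  if (any(empty)) {
    if (missing == "strict")
      stop("row(s) ", paste(which(empty), collapse = ", "),
           " have empty cells in node columns (strict missing policy)")
    warning(sum(empty), " record(s) dropped for empty node cells")
  }
  keep <- !empty
  out <- data.frame(incident_id = ids,
                    phase = as.character(records$phase),
                    error_type = as.character(records$error_type),
                    stringsAsFactors = FALSE)
  for (code in codes) {
    v <- node_mat[[code]]
    legal <- node_states(network, code)
    bad <- keep & !(v %in% legal)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("illegal state \"", records[[code]][i], "\" for node ", code,
           " in row ", i, " (incident ", ids[i], "); legal states: ",
           paste(legal, collapse = ", "))
    }
    out[[code]] <- v
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(network = network, records = out), class = "hfacs_cases")
}

#' Read a coded-incident case database from CSV
#'
#' The file must have a header row naming `incident_id` and every node code of
#' the governing network; `phase` and `error_type` columns are optional.
#' Binary node columns hold yes/no; the ERR column holds
#' skill/decision/perception/none and VIO routine/exceptional/none (matched
#' case-insensitively, whitespace-trimmed).
#'
#' @inheritParams as_case_db
#' @param path path to a UTF-8 comma-separated file.
#' @return An `hfacs_cases` object.
#' @export
read_case_db <- function(path, network = hfacs_network(),
                         missing = c("strict", "drop")) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  as_case_db(df, network, missing)
}

#' Write a case database to CSV
#'
#' Writes columns `incident_id`, `phase`, `error_type`, then one column per
#' node in canonical order. Output is deterministic, so identical databases
#' produce byte-identical files.
#'
#' @param db an `hfacs_cases` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_db <- function(db, path) {
  cols <- c("incident_id", "phase", "error_type", topological_order(db$network))
  utils::write.csv(db$records[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @export
print.hfacs_cases <- function(x, ...) {
  cat("HFACS case database:", nrow(x$records), "incidents over",
      nrow(x$network$nodes), "nodes\n")
  invisible(x)
}

#' @export
as.data.frame.hfacs_cases <- function(x, ...) x$records

# occurrence indicator matrix: one column per factor occurrence unit
# (binary node = "yes"; each non-"none" state of a multi-state node separately)
occurrence_matrix <- function(db) {
  net <- db$network
  cols <- list()
  for (code in topological_order(net)) {
    st <- node_states(net, code)
    if (identical(st, c("yes", "no"))) {
      cols[[code]] <- list(code = code, state = "yes",
                           ind = db$records[[code]] == "yes")
    } else {
      for (s in setdiff(st, "none"))
        cols[[paste(code, s, sep = ":")]] <-
          list(code = code, state = s, ind = db$records[[code]] == s)
    }
  }
  cols
}

#' Summarize factor frequencies in a case database
#'
#' A factor "occurs" in an incident when a binary node is "yes", or when a
#' multi-state node (ERR/VIO) is in a non-"none" state; each non-none state is
#' counted as one occurrence of that subtype. Reports per-factor occurrence
#' counts, per-level totals and proportions of all occurrences, the histogram
#' of factors per incident, and the grand totals.
#'
#' @param db a non-empty `hfacs_cases` object.
#' @return An object of class `hfacs_freq`: list with elements `factors`
#'   (data.frame: factor, node, state, level, count), `levels` (data.frame:
#'   level, count, proportion; proportions are `NA` when no factor occurred),
#'   `per_incident` (named integer histogram of factors per incident),
#'   `total_occurrences`, `n_incidents`.
#' @export
summarize_frequencies <- function(db) {
  if (nrow(db$records) == 0) stop("empty case database")
  net <- db$network
  occ <- occurrence_matrix(db)
  fac <- data.frame(
    factor = names(occ),
    node = vapply(occ, function(o) o$code, ""),
    state = vapply(occ, function(o) o$state, ""),
    count = vapply(occ, function(o) sum(o$ind), 0L),
    stringsAsFactors = FALSE)
  fac$level <- node_level(net, fac$node)
  rownames(fac) <- NULL
  total <- sum(fac$count)
  lev <- stats::aggregate(count ~ level, fac, sum)
  lev <- lev[order(-lev$level), , drop = FALSE]
  lev$proportion <- if (total > 0) lev$count / total else NA_real_
  rownames(lev) <- NULL
  per_rec <- Reduce(`+`, lapply(occ, function(o) as.integer(o$ind)))
  hist <- table(factor(per_rec, levels = sort(unique(per_rec))))
  structure(list(factors = fac[, c("factor", "node", "state", "level", "count")],
                 levels = lev, per_incident = hist,
                 total_occurrences = total, n_incidents = nrow(db$records)),
            class = "hfacs_freq")
}

#' @export
print.hfacs_freq <- function(x, ...) {
  cat("Factor occurrences:", x$total_occurrences, "in", x$n_incidents, "incidents\n")
  cat("Per level (proportion of all occurrences):\n")
  lv <- x$levels
  lv$proportion <- round(lv$proportion, 3)
  print(lv, row.names = FALSE)
  cat("Factors per incident:\n")
  print(x$per_incident)
  invisible(x)
}

#' Tabulate incidents by treatment phase and error type
#'
#' Groups the records of a case database by their `(phase, error_type)`
#' annotations; records without annotations are pooled under "unspecified".
#' The ratio column divides each count by the total number of incidents.
#'
#' @param db an `hfacs_cases` object.
#' @return data.frame with columns `phase`, `error_type`, `count`, `ratio`;
#'   counts sum to the number of records.
#' @export
summarize_phases <- function(db) {
  r <- db$records
  phase <- ifelse(is.na(r$phase) | trimws(r$phase) == "", "unspecified", r$phase)
  etype <- ifelse(is.na(r$error_type) | trimws(r$error_type) == "",
                  "unspecified", r$error_type)
  tab <- stats::aggregate(list(count = seq_len(nrow(r))),
                          by = list(phase = phase, error_type = etype), FUN = length)
  tab <- tab[order(tab$phase, tab$error_type), , drop = FALSE]
  tab$ratio <- tab$count / nrow(r)
  rownames(tab) <- NULL
  tab
}

#' Reference phase/error-type distribution of 81 radiotherapy incidents
#'
#' Counts of 81 publicly reported radiotherapy incidents from a national
#' incident-learning system, grouped by treatment stage, phase and error type.
#' Used as the default label distribution by the synthetic incident generator
#' and as a fixture for the phase summaries.
#'
#' @return data.frame with columns `stage`, `phase`, `error_type`, `count`
#'   (16 rows; counts sum to 81).
#' @export
phase_error_counts <- function() {
  path <- system.file("extdata", "phase_error_counts.csv", package = "bnhfacs",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Frozen synthetic 81-incident case database
#'
#' Loads the packaged synthetic database of 81 coded incidents sampled from
#' [default_truth()] with seed 42, sized to match the reference study for
#' demonstration runs. The file is fully synthetic; regenerate it with
#' `sample_incidents(default_truth(), 81, seed = 42)`.
#'
#' @return An `hfacs_cases` object with 81 records.
#' @export
synthetic_cases <- function() {
  path <- system.file("extdata", "synthetic_cases_81.csv", package = "bnhfacs",
                      mustWork = TRUE)
  read_case_db(path)
}
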