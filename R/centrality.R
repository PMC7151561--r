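#' Node centrality report
#'
#' Computes degree, betweenness, and closeness for every node of a network.
#' Betweenness is unnormalized Brandes betweenness on the undirected graph:
#' each unordered pair (s, t) with s != t != v contributes
#' sigma_st(v) / sigma_st, and disconnected pairs contribute 0. Closeness is
#' the Wasserman-Faust component-scaled form
#' ((r - 1) / sum of distances) * ((r - 1) / (n - 1)), where r is the number
#' of nodes reachable from v (v included); it stays finite and comparable in
#' \[0, 1\] on disconnected graphs, and isolated nodes score 0.
#'
#' @param net A [pharm_network()].
#' @return A data frame of class `centrality_report` with columns `id`,
#'   `role`, `degree`, `betweenness`, `closeness`, ordered by decreasing
#'   degree (ties by id).
#' @seealso [centrality_summary()], [select_key_nodes()]
#' @export
centrality_report <- function(net) {
  g <- as_igraph(net)
  deg <- degree_centrality(net)
  btw <- betweenness_centrality(net)
  clo <- closeness_centrality(net)
  ids <- names(deg)
  report <- data.frame(
    id = ids,
    role = igraph::V(g)$role[match(ids, igraph::V(g)$name)],
    degree = as.integer(deg),
    betweenness = as.numeric(btw[ids]),
    closeness = as.numeric(clo[ids]),
    stringsAsFactors = FALSE)
  report <- report[order(-report$degree, report$id), , drop = FALSE]
  rownames(report) <- NULL
  class(report) <- c("centrality_report", "data.frame")
  report
}

#' @rdname centrality_report
#' @export
degree_centrality <- function(net) {
  g <- as_igraph(net)
  igraph::degree(g, loops = FALSE)
}

#' @rdname centrality_report
#' @export
betweenness_centrality <- function(net) {
  g <- as_igraph(net)
  # unweighted shortest paths even when PPI edges carry confidence weights
  igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
}

#' @rdname centrality_report
#' @export
closeness_centrality <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  d <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach) + 1          # reachable set includes v itself
    if (r == 1 || n == 1) return(0)
    ((r - 1) / sum(reach)) * ((r - 1) / (n - 1))
  }, numeric(1))
  stats::setNames(clo, igraph::V(g)$name)
}

#' Summary statistics of a centrality report
#'
#' @param report A [centrality_report()].
#' @return Data frame with one row per measure and columns `measure`,
#'   `mean`, `median`.
#' @export
centrality_summary <- function(report) {
  measures <- c("degree", "betweenness", "closeness")
  data.frame(
    measure = measures,
    mean = vapply(measures, function(m) mean(report[[m]]), numeric(1)),
    median = vapply(measures, function(m)
      stats::median(report[[m]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Key-node selection rules
#'
#' A rule selects nodes whose centrality measure is *strictly greater* than
#' `multiplier` times a reference value. The reference is the mean or the
#' median of the measure over the report, or an explicitly supplied fixed
#' value (used to consume thresholds printed by an upstream tool rather than
#' recomputed from data).
#'
#' `parse_selection_rule()` accepts the compact grammar
#' `"measure>MULTxREF"`, e.g. `"degree>2xmean"`, `"degree>2xmedian"`,
#' `"degree>2xfixed:13.833"`, or a bare numeric threshold `"degree>8.09"`
#' (fixed reference, multiplier 1).
#'
#' @param measure One of `"degree"`, `"betweenness"`, `"closeness"`.
#' @param reference `"mean"`, `"median"`, or `"fixed"`.
#' @param multiplier Positive unitless multiplier.
#' @param fixed_value Required iff `reference = "fixed"`.
#' @return An object of class `selection_rule`.
#' @export
selection_rule <- function(measure = c("degree", "betweenness", "closeness"),
                           reference = c("mean", "median", "fixed"),
                           multiplier = 1, fixed_value = NULL) {
  measure <- match.arg(measure)
  reference <- match.arg(reference)
  stopifnot(is.numeric(multiplier), length(multiplier) == 1, multiplier > 0)
  if (reference == "fixed") {
    if (is.null(fixed_value) || !is.numeric(fixed_value))
      stop("fixed_value is required for a fixed-reference rule",
           call. = FALSE)
  } else if (!is.null(fixed_value)) {
    stop("fixed_value only applies when reference = \"fixed\"", call. = FALSE)
  }
  structure(list(measure = measure, reference = reference,
                 multiplier = multiplier, fixed_value = fixed_value),
            class = "selection_rule")
}

#' @rdname selection_rule
#' @param text Rule string in the mini-grammar.
#' @export
parse_selection_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regmatches(text, regexec(
    "^\\s*(degree|betweenness|closeness)\\s*>\\s*(?:([0-9.]+)x)?(mean|median|fixed:([0-9.eE+-]+)|[0-9.]+)\\s*$",
    text))[[1]]
  if (!length(m)) stop("cannot parse selection rule: ", text, call. = FALSE)
  measure <- m[2]
  multiplier <- if (nzchar(m[3])) as.numeric(m[3]) else 1
  ref <- m[4]
  if (ref %in% c("mean", "median"))
    return(selection_rule(measure, ref, multiplier))
  fixed <- if (nzchar(m[5])) as.numeric(m[5]) else as.numeric(ref)
  selection_rule(measure, "fixed", multiplier, fixed)
}

#' @export
print.selection_rule <- function(x, ...) {
  ref <- if (x$reference == "fixed") x$fixed_value else x$reference
  cat("selection rule:", x$measure, ">", x$multiplier, "x", ref, "\n")
  invisible(x)
}

#' Select key nodes by a centrality threshold rule
#'
#' Retains nodes whose measure strictly exceeds `multiplier * reference`.
#' Ties at exactly the threshold are excluded. With a role filter the
#' candidate set is restricted to the given roles; the mean/median reference
#' is still computed over all rows unless `reference_within_roles = TRUE`.
#'
#' @param report A [centrality_report()] or any data frame with an `id`
#'   column and a column named after the rule's measure.
#' @param rule A [selection_rule()] or a rule string for
#'   [parse_selection_rule()].
#' @param roles Optional character vector of node roles to consider.
#' @param reference_within_roles Compute the mean/median reference over the
#'   role-filtered rows instead of all rows (default `FALSE`).
#' @return Character vector of selected node ids, ordered by decreasing
#'   measure then id.
#' @examples
#' rep <- data.frame(id = c("a", "b", "c"), degree = c(5, 2, 1))
#' select_key_nodes(rep, "degree>2xfixed:1.5")
#' @export
select_key_nodes <- function(report, rule, roles = NULL,
                             reference_within_roles = FALSE) {
  if (is.character(rule)) rule <- parse_selection_rule(rule)
  stopifnot(inherits(rule, "selection_rule"), is.data.frame(report))
  if (nrow(report) == 0) stop("empty centrality report", call. = FALSE)
  if (!rule$measure %in% names(report))
    stop("report has no column '", rule$measure, "'", call. = FALSE)
  candidates <- report
  if (!is.null(roles)) {
    if (!"role" %in% names(report))
      stop("role filter requested but report has no 'role' column",
           call. = FALSE)
    candidates <- report[report$role %in% roles, , drop = FALSE]
  }
  pop <- if (reference_within_roles) candidates else report
  ref <- switch(rule$reference,
                mean = mean(pop[[rule$measure]]),
                median = stats::median(pop[[rule$measure]]),
                fixed = rule$fixed_value)
  threshold <- rule$multiplier * ref
  hit <- candidates[candidates[[rule$measure]] > threshold, , drop = FALSE]
  hit <- hit[order(-hit[[rule$measure]], hit$id), , drop = FALSE]
  as.character(hit$id)
}
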