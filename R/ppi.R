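#' Read a protein-protein interaction table
#'
#' Tab-separated with a header and columns `protein_a`, `protein_b`,
#' `combined_score`. STRING-style exports score on 0-1000; `score_scale`
#' controls conversion: `"unit"` takes scores as 0-1 confidences, `"string"`
#' divides by 1000, `"auto"` (default) divides by 1000 when any score
#' exceeds 1.
#'
#' @param path File path.
#' @param score_scale `"auto"`, `"unit"` or `"string"`.
#' @return Data frame with columns `protein_a`, `protein_b`, `confidence`.
#' @export
read_interactions <- function(path, score_scale = c("auto", "unit", "string")) {
  score_scale <- match.arg(score_scale)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_a", "protein_b", "combined_score") %in% names(tab)))
  score <- suppressWarnings(as.numeric(tab$combined_score))
  if (anyNA(score)) stop("non-numeric combined_score", call. = FALSE)
  if (score_scale == "string" ||
      (score_scale == "auto" && length(score) && max(score) > 1))
    score <- score / 1000
  out <- data.frame(protein_a = as.character(tab$protein_a),
                    protein_b = as.character(tab$protein_b),
                    confidence = score, stringsAsFactors = FALSE)
  validate_interactions(out)
  out
}

#' @rdname read_interactions
#' @param interactions Interaction data frame.
#' @export
validate_interactions <- function(interactions) {
  stopifnot(is.data.frame(interactions),
            all(c("protein_a", "protein_b", "confidence") %in%
                  names(interactions)))
  if (nrow(interactions) == 0) return(invisible(interactions))
  conf <- as.numeric(interactions$confidence)
  if (anyNA(conf) || any(conf < 0 | conf > 1))
    stop("interaction confidence outside [0, 1] at row ",
         which(is.na(conf) | conf < 0 | conf > 1)[1], call. = FALSE)
  loop <- which(interactions$protein_a == interactions$protein_b)
  if (length(loop))
    stop("self-interaction for protein ",
         interactions$protein_a[loop[1]], call. = FALSE)
  invisible(interactions)
}

#' Build a confidence-filtered PPI subnetwork
#'
#' Keeps interactions whose endpoints both lie in the seed set and whose
#' confidence strictly exceeds `min_confidence` ("highest confidence" in
#' STRING terms at 0.9). Symmetric A-B / B-A duplicates collapse to one
#' undirected edge keeping the maximum confidence. Seeds left without a
#' single retained interaction are excluded from the network and reported,
#' mirroring the audit of non-interacting targets.
#'
#' @param interactions Data frame with `protein_a`, `protein_b`,
#'   `confidence` in \[0, 1\] (see [read_interactions()]).
#' @param seeds Character vector of target ids; `NULL` (default) uses every
#'   protein appearing in the table.
#' @param min_confidence Strict lower confidence bound, default 0.9.
#' @param role Node role given to retained proteins, default `"target"`.
#' @return List with elements `network` (a [pharm_network()] of `ppi` edges
#'   weighted by confidence) and `excluded` (seed ids without retained
#'   interactions, sorted).
#' @export
build_ppi <- function(interactions, seeds = NULL, min_confidence = 0.9,
                      role = "target") {
  validate_interactions(interactions)
  if (is.null(seeds))
    seeds <- unique(c(as.character(interactions$protein_a),
                      as.character(interactions$protein_b)))
  seeds <- unique(as.character(seeds))
  keep <- interactions$protein_a %in% seeds &
    interactions$protein_b %in% seeds &
    interactions$confidence > min_confidence
  kept <- interactions[keep, , drop = FALSE]
  connected <- unique(c(kept$protein_a, kept$protein_b))
  net <- pharm_network(
    data.frame(id = connected,
               role = rep(role, length(connected))),
    data.frame(from = kept$protein_a, to = kept$protein_b,
               kind = rep("ppi", nrow(kept)), weight = kept$confidence))
  list(network = net, excluded = sort(setdiff(seeds, connected)))
}

#' Detect hub nodes of a PPI network
#'
#' Delegates to [select_key_nodes()] with a degree rule; the conventional
#' hub rule is degree strictly greater than twice the median degree.
#'
#' @param net A non-empty [pharm_network()].
#' @param rule A [selection_rule()] or rule string; default
#'   `"degree>2xmedian"`.
#' @return Character vector of hub node ids.
#' @export
select_hubs <- function(net, rule = "degree>2xmedian") {
  stopifnot(inherits(net, "pharm_network"))
  if (nrow(net$nodes) == 0) stop("empty network", call. = FALSE)
  deg <- degree_centrality(net)
  report <- data.frame(id = names(deg), degree = as.numeric(deg),
                       stringsAsFactors = FALSE)
  select_key_nodes(report, rule)
}
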