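#' Typed undirected networks
#'
#' All pipeline stages share one light graph container: a node table with a
#' role per node and an undirected, deduplicated edge table with a kind per
#' edge and an optional unitless weight (used for PPI confidence). Node
#' identity is the pair (id, role), so a protein can appear both as a
#' formula target and as a disease gene; graph algorithms operate on ids,
#' collapsing multi-role nodes to a single vertex.
#'
#' @param nodes Data frame with columns `id`, `role`; roles are one of
#'   `herb`, `ingredient`, `target`, `disease_gene`, `tissue`, `pathway`.
#' @param edges Data frame with columns `from`, `to`, `kind` and optional
#'   `weight`; kinds are one of `herb_ingredient`, `ingredient_target`,
#'   `ppi`, `target_disease`, `gene_tissue`. Edges are stored once per
#'   unordered pair (endpoints sorted lexicographically); duplicates are
#'   collapsed keeping the maximum weight. Self-loops are an error.
#' @return An object of class `pharm_network`.
#' @export
pharm_network <- function(nodes = data.frame(id = character(0),
                                             role = character(0)),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             kind = character(0))) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  nodes <- data.frame(id = as.character(nodes$id),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  bad <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad)) stop("unknown node role: ", bad[1], call. = FALSE)
  nodes <- unique(nodes)
  if (nrow(edges)) {
    weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight)
              else rep(NA_real_, nrow(edges))
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        kind = as.character(edges$kind),
                        weight = weight, stringsAsFactors = FALSE)
    bad <- setdiff(unique(edges$kind), EDGE_KINDS)
    if (length(bad)) stop("unknown edge kind: ", bad[1], call. = FALSE)
    if (any(edges$from == edges$to))
      stop("self-loop edge on node ",
           edges$from[edges$from == edges$to][1], call. = FALSE)
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to, edges$kind, sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(edges$weight, key, function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      edges <- edges[!duplicated(key), , drop = FALSE]
      edges$weight <- as.numeric(w[paste(edges$from, edges$to, edges$kind,
                                         sep = "\r")])
    }
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
    if (length(missing))
      stop("edge endpoint not in node table: ", missing[1], call. = FALSE)
    edges <- edges[order(edges$from, edges$to, edges$kind), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0), weight = numeric(0),
                        stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$id, nodes$role), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "pharm_network")
}

NODE_ROLES <- c("herb", "ingredient", "target", "disease_gene", "tissue",
                "pathway")
EDGE_KINDS <- c("herb_ingredient", "ingredient_target", "ppi",
                "target_disease", "gene_tissue")

#' @export
print.pharm_network <- function(x, ...) {
  cat("pharm_network:", length(unique(x$nodes$id)), "nodes (",
      paste(names(table(x$nodes$role)), table(x$nodes$role),
            collapse = ", "), "),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' @rdname pharm_network
#' @param net A `pharm_network`.
#' @export
network_nodes <- function(net) net$nodes

#' @rdname pharm_network
#' @export
network_edges <- function(net) net$edges

#' Convert to an igraph graph
#'
#' Vertices are unique node ids (roles of multi-role nodes joined with
#' `";"`); edges keep their kind and weight attributes. The graph is
#' undirected.
#'
#' @param net A [pharm_network()].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "pharm_network"))
  roles <- tapply(net$nodes$role, net$nodes$id,
                  function(r) paste(sort(unique(r)), collapse = ";"))
  ids <- sort(unique(net$nodes$id))
  vertices <- data.frame(name = ids, role = as.character(roles[ids]),
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = vertices)
}

#' Build the herb-ingredient-target tripartite network
#'
#' Nodes are every herb appearing in any record, every ingredient, and every
#' mapped target; edges connect each ingredient to its herbs
#' (`herb_ingredient`) and to its targets (`ingredient_target`). The edge
#' count therefore equals the total herb-membership count plus the number of
#' distinct mapping pairs.
#'
#' @param ingredients Ingredient table (see [validate_ingredients()]).
#' @param target_map Data frame with columns `mol_id`, `target_id`; every
#'   `mol_id` must appear in `ingredients`.
#' @return A [pharm_network()].
#' @export
build_tripartite <- function(ingredients, target_map) {
  validate_ingredients(ingredients)
  stopifnot(is.data.frame(target_map),
            all(c("mol_id", "target_id") %in% names(target_map)))
  unknown <- setdiff(unique(as.character(target_map$mol_id)),
                     as.character(ingredients$mol_id))
  if (length(unknown))
    stop("target mapped to unknown ingredient: ", unknown[1], call. = FALSE)
  herbs <- split_herbs(ingredients$herbs)
  mol <- as.character(ingredients$mol_id)
  hi <- data.frame(
    from = unlist(herbs),
    to = rep(mol, vapply(herbs, length, 1L)),
    kind = "herb_ingredient", stringsAsFactors = FALSE)
  it <- unique(data.frame(from = as.character(target_map$mol_id),
                          to = as.character(target_map$target_id),
                          kind = "ingredient_target",
                          stringsAsFactors = FALSE))
  nodes <- rbind(
    data.frame(id = unique(unlist(herbs)), role = "herb"),
    data.frame(id = mol, role = "ingredient"),
    data.frame(id = unique(as.character(target_map$target_id)),
               role = "target"))
  pharm_network(nodes, rbind(hi, it))
}

#' Export / import a network as SIF-style edge and node-attribute files
#'
#' The edge file is a tab-separated SIF dialect with a header:
#' `source`, `kind`, `target`, `weight` (empty weight for unweighted edges).
#' Node attributes (`id`, `role`) go to a companion TSV. A read-back
#' round-trip reproduces an identical network.
#'
#' @param net A [pharm_network()].
#' @param edge_path,node_attr_path Output (input) file paths.
#' @return `export_network()` invisibly returns the two paths;
#'   `read_network()` returns the reconstructed network.
#' @export
export_network <- function(net, edge_path, node_attr_path) {
  stopifnot(inherits(net, "pharm_network"))
  edges <- net$edges[, c("from", "kind", "to", "weight")]
  names(edges) <- c("source", "kind", "target", "weight")
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(net$nodes, node_attr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, node_attr_path))
}

#' @rdname export_network
#' @export
read_network <- function(edge_path, node_attr_path) {
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                             colClasses = c(source = "character",
                                            kind = "character",
                                            target = "character"))
  nodes <- utils::read.delim(node_attr_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (nrow(edges)) {
    edges <- data.frame(from = edges$source, to = edges$target,
                        kind = edges$kind,
                        weight = suppressWarnings(as.numeric(edges$weight)),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0))
  }
  pharm_network(nodes, edges)
}
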