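#' Classify disease genes by PPI hop distance from formula targets
#'
#' A disease gene overlapping the formula target set is a *direct* target
#' (hop 0), regardless of the PPI. Otherwise its hop is the shortest PPI
#' path length from any formula target (breadth-first distances); genes at
#' hop 1..`max_hop` are *indirect*, genes further away or unreachable are
#' *unlinked*. For every classified gene one shortest witness path is
#' recorded; among equally short paths the lexicographically smallest node
#' sequence is chosen, so output is deterministic.
#'
#' @param formula_targets Non-empty character vector of formula target ids.
#' @param ppi_net A [pharm_network()] with `ppi` edges (same id namespace as
#'   both gene sets).
#' @param disease_genes Character vector of disease gene ids.
#' @param max_hop Maximum PPI path length still counted as indirect
#'   (default 2, "one or two protein interactions"). `max_hop = 0` keeps
#'   direct hits only.
#' @param intermediates_in_targets If `TRUE`, indirect paths may only pass
#'   through formula targets (restrictive reading; the permissive default
#'   allows any protein as intermediate).
#' @return Data frame with columns `gene`, `category`
#'   (`direct`/`indirect`/`unlinked`), `hop` (0 for direct, 1..`max_hop`
#'   for indirect, `NA` for unlinked) and `witness` (path as `"A|B|C"`,
#'   `NA` for unlinked), one row per distinct input gene, input order.
#' @export
classify_disease_targets <- function(formula_targets, ppi_net, disease_genes,
                                     max_hop = 2,
                                     intermediates_in_targets = FALSE) {
  formula_targets <- unique(as.character(formula_targets))
  if (length(formula_targets) == 0)
    stop("empty formula target set", call. = FALSE)
  stopifnot(inherits(ppi_net, "pharm_network"), max_hop >= 0)
  disease_genes <- unique(as.character(disease_genes))
  g <- as_igraph(ppi_net)
  vnames <- igraph::V(g)$name

  classify_one <- function(gene) {
    if (gene %in% formula_targets)
      return(list(category = "direct", hop = 0L, witness = gene))
    if (max_hop < 1 || !(gene %in% vnames))
      return(list(category = "unlinked", hop = NA_integer_,
                  witness = NA_character_))
    sub <- g
    if (intermediates_in_targets)
      sub <- igraph::induced_subgraph(
        g, igraph::V(g)$name[igraph::V(g)$name %in% c(formula_targets, gene)])
    sn <- igraph::V(sub)$name
    if (!(gene %in% sn))
      return(list(category = "unlinked", hop = NA_integer_,
                  witness = NA_character_))
    dvec <- as.numeric(igraph::distances(sub, to = gene, weights = NA))
    names(dvec) <- sn
    ft <- intersect(formula_targets, sn)
    if (!length(ft) || all(!is.finite(dvec[ft])))
      return(list(category = "unlinked", hop = NA_integer_,
                  witness = NA_character_))
    hop <- min(dvec[ft])
    if (hop > max_hop)
      return(list(category = "unlinked", hop = NA_integer_,
                  witness = NA_character_))
    # greedy lexicographically smallest shortest path from a formula target
    cur <- min(sort(ft[dvec[ft] == hop]))
    path <- cur
    while (dvec[cur] > 0) {
      nb <- igraph::neighbors(sub, cur)$name
      nxt <- min(sort(nb[dvec[nb] == dvec[cur] - 1]))
      path <- c(path, nxt)
      cur <- nxt
    }
    list(category = "indirect", hop = as.integer(hop),
         witness = paste(path, collapse = "|"))
  }

  res <- lapply(disease_genes, classify_one)
  data.frame(
    gene = disease_genes,
    category = vapply(res, `[[`, character(1), "category"),
    hop = vapply(res, `[[`, integer(1), "hop"),
    witness = vapply(res, `[[`, character(1), "witness"),
    stringsAsFactors = FALSE)
}

#' Summarize a target classification
#'
#' Counts distinct genes by category; the linked total is the direct plus
#' indirect count.
#'
#' @param classifications Data frame with columns `gene` and `category`
#'   (from [classify_disease_targets()] or a fixture table).
#' @return Named list `n_direct`, `n_indirect`, `n_total_linked`.
#' @export
summarize_classification <- function(classifications) {
  stopifnot(is.data.frame(classifications),
            all(c("gene", "category") %in% names(classifications)))
  cls <- classifications[!duplicated(classifications$gene), , drop = FALSE]
  n_direct <- sum(cls$category == "direct")
  n_indirect <- sum(cls$category == "indirect")
  list(n_direct = n_direct, n_indirect = n_indirect,
       n_total_linked = n_direct + n_indirect)
}

#' Combine the tripartite network with classified disease genes
#'
#' Unions the herb-ingredient-target network with the classified disease
#' genes: every direct or indirect gene is added with role `disease_gene`
#' (a gene already present as a target keeps both roles, merged by id), and
#' the PPI edges along each indirect gene's witness path are added with
#' their confidences. Witness intermediates absent from the tripartite
#' network enter with role `target`. Unlinked genes never appear. Ingredient
#' degrees in this combined network are the conventional per-component
#' connectivity to the disease module.
#'
#' @param tripartite A [pharm_network()] from [build_tripartite()].
#' @param classifications Output of [classify_disease_targets()].
#' @param ppi_net The [pharm_network()] the classification was computed on
#'   (source of edge confidences).
#' @return A [pharm_network()].
#' @export
build_combined_network <- function(tripartite, classifications, ppi_net) {
  stopifnot(inherits(tripartite, "pharm_network"),
            inherits(ppi_net, "pharm_network"))
  linked <- classifications[classifications$category %in%
                              c("direct", "indirect"), , drop = FALSE]
  nodes <- tripartite$nodes
  edges <- tripartite$edges
  if (nrow(linked)) {
    nodes <- rbind(nodes, data.frame(id = linked$gene, role = "disease_gene"))
    wkey <- paste(pmin(ppi_net$edges$from, ppi_net$edges$to),
                  pmax(ppi_net$edges$from, ppi_net$edges$to), sep = "\r")
    for (w in linked$witness[linked$category == "indirect"]) {
      p <- strsplit(w, "|", fixed = TRUE)[[1]]
      mids <- p[-c(1, length(p))]
      if (length(mids))
        nodes <- rbind(nodes, data.frame(id = mids, role = "target"))
      if (!(p[1] %in% nodes$id))
        nodes <- rbind(nodes, data.frame(id = p[1], role = "target"))
      a <- p[-length(p)]
      b <- p[-1]
      wt <- ppi_net$edges$weight[match(paste(pmin(a, b), pmax(a, b),
                                             sep = "\r"), wkey)]
      edges <- rbind(edges,
                     data.frame(from = a, to = b, kind = "ppi", weight = wt))
    }
  }
  pharm_network(nodes, edges)
}
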