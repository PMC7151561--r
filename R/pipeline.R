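#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one place. The defaults are
#' the reference operating point of the whole pipeline: OB >= 30% with the
#' Licorice override OB >= 50%, DL >= 0.18, PPI confidence > 0.9, indirect
#' targets within 2 PPI hops, enrichment filters p <= 0.05 with at least 4
#' overlap genes, chi-square alpha 0.05, and key nodes at degree strictly
#' above twice the mean.
#'
#' @param inputs Named list of stage inputs; recognised entries are
#'   `ingredients`, `target_map`, `interactions`, `formula_targets`,
#'   `disease_genes`, `classification`, `pathways`, `query`, `expression`. Each may be an in-memory
#'   object (data frame / matrix / [pathway_catalog()]) or a file path.
#' @param min_ob,herb_min_ob,min_dl ADME screen thresholds
#'   (see [screen_policy()]).
#' @param min_confidence Strict PPI confidence bound.
#' @param max_hop Maximum indirect hop distance.
#' @param max_p,min_genes Enrichment filters (see [filter_rank()]).
#' @param alpha Chi-square significance level.
#' @param key_rule Key-node rule string (see [parse_selection_rule()]).
#' @param hub_rule PPI hub rule string.
#' @param seed Integer seed forwarded to any synthetic stage.
#' @param out_dir Optional output directory; when set, every stage writes
#'   its TSV/SIF artifacts there.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), min_ob = 30,
                            herb_min_ob = c(LO = 50), min_dl = 0.18,
                            min_confidence = 0.9, max_hop = 2, max_p = 0.05,
                            min_genes = 4, alpha = 0.05,
                            key_rule = "degree>2xmean",
                            hub_rule = "degree>2xmedian",
                            seed = 1, out_dir = NULL) {
  structure(list(inputs = inputs, min_ob = min_ob,
                 herb_min_ob = herb_min_ob, min_dl = min_dl,
                 min_confidence = min_confidence, max_hop = max_hop,
                 max_p = max_p, min_genes = min_genes, alpha = alpha,
                 key_rule = key_rule, hub_rule = hub_rule, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Frozen reference thresholds of the default operating point
#'
#' @return Named list of the documented default thresholds; tests diff
#'   [pipeline_config()] defaults against this record.
#' @export
paper_defaults <- function() {
  list(min_ob = 30, herb_min_ob = c(LO = 50), min_dl = 0.18,
       min_confidence = 0.9, max_hop = 2, max_p = 0.05, min_genes = 4,
       alpha = 0.05, key_rule = "degree>2xmean",
       hub_rule = "degree>2xmedian")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

log_event <- function(log, stage, event, n_in, n_out) {
  c(log, list(list(stage = stage, event = event, n_in = n_in, n_out = n_out)))
}

#' Run the full inference pipeline
#'
#' Executes, in order and for every input present in the configuration:
#' ADME screening, tripartite network construction with centrality and
#' key-node selection, PPI subnetwork construction with hub detection,
#' disease-target classification (or adoption of a precomputed
#' classification table), combined-network assembly, pathway enrichment,
#' and the chi-square immune screen with its gene-tissue network. Stages
#' whose inputs are absent are skipped. Each filter logs its in/out counts;
#' the returned summary is fully deterministic for a given configuration.
#'
#' @param config A [pipeline_config()].
#' @return List with the per-stage result objects (`screened`, `tripartite`,
#'   `centrality`, `key_nodes`, `ppi`, `hubs`, `classification`, `combined`,
#'   `enrichment`, `immune`, `gene_tissue`) and `summary`, a named list of
#'   scalar counts and thresholds (written to `summary.json` under
#'   `out_dir` when configured).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- config$inputs
  out <- list()
  log <- list()
  summary <- list(seed = config$seed)
  summary$thresholds <- list(
    min_ob = config$min_ob, herb_min_ob = as.list(config$herb_min_ob),
    min_dl = config$min_dl, min_confidence = config$min_confidence,
    max_hop = config$max_hop, max_p = config$max_p,
    min_genes = config$min_genes, alpha = config$alpha,
    key_rule = config$key_rule, hub_rule = config$hub_rule)

  dir_out <- config$out_dir
  if (!is.null(dir_out) && !dir.exists(dir_out))
    dir.create(dir_out, recursive = TRUE)
  emit <- function(obj, name) {
    if (is.null(dir_out)) return(invisible(NULL))
    if (inherits(obj, "pharm_network"))
      export_network(obj, file.path(dir_out, paste0(name, ".sif")),
                     file.path(dir_out, paste0(name, "_nodes.tsv")))
    else
      utils::write.table(obj, file.path(dir_out, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- screen ---------------------------------------------------------------
  if (!is.null(inp$ingredients)) {
    ingredients <- resolve_input(inp$ingredients, read_ingredients)
    policy <- screen_policy(config$min_ob, config$min_dl, config$herb_min_ob)
    screened <- apply_screen(ingredients, policy)
    log <- log_event(log, "screen", "ob_dl_filter", nrow(ingredients),
                     nrow(screened))
    out$screened <- screened
    summary$retained <- nrow(screened)
    summary$herb_counts <- as.list(per_herb_counts(screened))
    emit(screened, "screened_ingredients")
  }

  # -- netbuild + centrality ------------------------------------------------
  if (!is.null(out$screened) && !is.null(inp$target_map)) {
    target_map <- resolve_input(inp$target_map, function(p)
      utils::read.delim(p, stringsAsFactors = FALSE,
                        colClasses = "character"))
    tri <- build_tripartite(out$screened, target_map)
    out$tripartite <- tri
    report <- centrality_report(tri)
    out$centrality <- report
    out$key_nodes <- select_key_nodes(report, config$key_rule)
    log <- log_event(log, "centrality", "key_node_rule", nrow(report),
                     length(out$key_nodes))
    summary$n_nodes <- length(unique(tri$nodes$id))
    summary$n_edges <- nrow(tri$edges)
    summary$n_key_nodes <- length(out$key_nodes)
    emit(tri, "tripartite")
    emit(report, "centrality")
  }

  # -- ppi ------------------------------------------------------------------
  interactions <- NULL
  if (!is.null(inp$interactions)) {
    interactions <- resolve_input(inp$interactions, read_interactions)
    seeds <- if (!is.null(out$tripartite))
      out$tripartite$nodes$id[out$tripartite$nodes$role == "target"]
    else NULL
    ppi <- build_ppi(interactions, seeds = seeds,
                     min_confidence = config$min_confidence)
    out$ppi <- ppi
    out$hubs <- if (nrow(ppi$network$nodes)) select_hubs(ppi$network,
                                                         config$hub_rule)
                else character(0)
    log <- log_event(log, "ppi", "confidence_filter", nrow(interactions),
                     nrow(ppi$network$edges))
    summary$ppi_nodes <- length(unique(ppi$network$nodes$id))
    summary$ppi_edges <- nrow(ppi$network$edges)
    summary$ppi_excluded <- length(ppi$excluded)
    summary$n_hubs <- length(out$hubs)
    emit(ppi$network, "ppi")
  }

  # -- disease link ---------------------------------------------------------
  if (!is.null(inp$classification)) {
    cls <- resolve_input(inp$classification, function(p)
      utils::read.delim(p, stringsAsFactors = FALSE))
    out$classification <- cls
  } else if (!is.null(inp$disease_genes) && !is.null(interactions)) {
    disease <- resolve_input(inp$disease_genes, readLines)
    targets <- if (!is.null(inp$formula_targets))
      resolve_input(inp$formula_targets, readLines)
    else if (!is.null(out$tripartite))
      out$tripartite$nodes$id[out$tripartite$nodes$role == "target"]
    else stop("disease classification needs formula targets: provide ",
              "inputs$formula_targets or run the tripartite stage",
              call. = FALSE)
    full_ppi <- build_ppi(interactions,
                          min_confidence = config$min_confidence)$network
    out$classification <- classify_disease_targets(
      targets, full_ppi, disease, max_hop = config$max_hop)
    log <- log_event(log, "disease_link", "hop_classification",
                     length(disease),
                     sum(out$classification$category != "unlinked"))
  }
  if (!is.null(out$classification)) {
    s <- summarize_classification(out$classification)
    summary$direct <- s$n_direct
    summary$indirect <- s$n_indirect
    summary$linked_total <- s$n_total_linked
    emit(out$classification, "classification")
    if (!is.null(out$tripartite) && !is.null(out$ppi) &&
        "witness" %in% names(out$classification)) {
      out$combined <- build_combined_network(out$tripartite,
                                             out$classification,
                                             out$ppi$network)
      emit(out$combined, "combined")
    }
  }

  # -- enrichment -----------------------------------------------------------
  if (!is.null(inp$pathways)) {
    catalog <- resolve_input(inp$pathways, read_gmt)
    query <- if (!is.null(inp$query)) resolve_input(inp$query, readLines)
    else if (!is.null(out$classification))
      out$classification$gene[out$classification$category != "unlinked"]
    else stop("enrichment stage needs a query or a classification",
              call. = FALSE)
    rows <- hypergeom_enrich(query, catalog)
    ranked <- filter_rank(rows, max_p = config$max_p,
                          min_genes = config$min_genes, top_n = 10)
    out$enrichment <- rows
    out$top_pathways <- ranked
    log <- log_event(log, "enrichment", "p_and_size_filter", nrow(rows),
                     nrow(ranked))
    summary$pathways_tested <- nrow(rows)
    summary$pathways_top <- nrow(ranked)
    emit(rows, "enrichment")
    emit(ranked, "top_pathways")
  }

  # -- immune screen --------------------------------------------------------
  if (!is.null(inp$expression)) {
    mat <- resolve_input(inp$expression, read_expression)
    res <- chi_square_screen(mat, alpha = config$alpha)
    out$immune <- res
    selected <- res$gene[res$significant]
    out$gene_tissue <- build_gene_tissue_network(mat, selected)
    log <- log_event(log, "immune", "chi_square_screen", nrow(res),
                     length(selected))
    summary$immune_tested <- nrow(res)
    summary$immune_significant <- length(selected)
    emit(res, "immune_screen")
    emit(out$gene_tissue, "gene_tissue")
  }

  summary$log <- log
  out$summary <- summary
  if (!is.null(dir_out))
    jsonlite::write_json(summary, file.path(dir_out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}

#' Load a packaged example table
#'
#' Curated tables for the eight-herb XQD formula example shipped under
#' `inst/extdata/`: the 112-ingredient ADME table, the key-component and
#' key-target centrality tables, the direct/indirect disease-target tables,
#' and the 8-gene x 14-tissue immune expression matrix.
#'
#' @param name One of `table1_ingredients`, `table2_components`,
#'   `table3_targets`, `table4_key_components`, `table5_direct`,
#'   `table6_indirect`, `table7_expression`.
#' @return A validated data frame, or a numeric matrix for
#'   `table7_expression`. The classification tables (`table5_direct`,
#'   `table6_indirect`) carry `gene`, `category`, `hop` (0 for direct, `NA`
#'   for indirect rows, whose exact hop the source tables do not state),
#'   `uniprot` and `degree`.
#' @export
load_fixture <- function(name) {
  known <- c("table1_ingredients", "table2_components", "table3_targets",
             "table4_key_components", "table5_direct", "table6_indirect",
             "table7_expression")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "netpharm",
                      mustWork = TRUE)
  switch(name,
    table1_ingredients = read_ingredients(path),
    table7_expression = read_expression(path),
    table5_direct = ,
    table6_indirect = {
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      data.frame(gene = tab$gene, category = tab$category,
                 hop = ifelse(tab$category == "direct", 0L, NA_integer_),
                 uniprot = tab$uniprot, degree = tab$degree,
                 stringsAsFactors = FALSE)
    },
    utils::read.delim(path, stringsAsFactors = FALSE))
}
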