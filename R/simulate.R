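#' Deterministic per-generator random streams
#'
#' Every generator derives its own RNG seed from the user seed and a stream
#' label, so adding a generator (or calling them in a different order) never
#' perturbs the output of another. The derivation is a simple polynomial
#' string hash folded into the user seed, modulo 2^31 - 1.
#'
#' @param seed Integer user seed.
#' @param label Stream label (one per generator).
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer(h)
}

#' Simulate an ADME ingredient table
#'
#' Emulates the structure of a screened ingredient table: OB uniform on
#' `ob_range` (percent), DL uniform on `dl_range`, one primary herb per
#' ingredient plus each additional herb independently with probability
#' `share_prob`. Same seed, same byte-identical table.
#'
#' @param n Number of ingredients (>= 0).
#' @param herbs Non-empty character vector of herb codes.
#' @param ob_range,dl_range Length-2 numeric ranges.
#' @param share_prob Probability an ingredient also belongs to each
#'   additional herb, default 0.1.
#' @param seed Integer seed.
#' @return Ingredient data frame (see [validate_ingredients()]).
#' @export
simulate_ingredients <- function(n, herbs = c("LO", "SC", "PC", "AT", "CR",
                                              "FR", "PR", "AC"),
                                 ob_range = c(0, 100), dl_range = c(0, 1),
                                 share_prob = 0.1, seed = 1) {
  stopifnot(n >= 0, length(ob_range) == 2, length(dl_range) == 2,
            share_prob >= 0, share_prob <= 1)
  if (length(herbs) == 0) stop("empty herb list", call. = FALSE)
  if (n == 0)
    return(data.frame(id = character(0), mol_id = character(0),
                      name = character(0), ob = numeric(0), dl = numeric(0),
                      herbs = character(0), stringsAsFactors = FALSE))
  withr::with_seed(derive_seed(seed, "ingredients"), {
    primary <- sample(herbs, n, replace = TRUE)
    herb_col <- vapply(seq_len(n), function(i) {
      others <- setdiff(herbs, primary[i])
      extra <- others[stats::runif(length(others)) < share_prob]
      paste(c(primary[i], extra), collapse = ",")
    }, character(1))
    data.frame(
      id = sprintf("SID%04d", seq_len(n)),
      mol_id = sprintf("SMOL%05d", seq_len(n)),
      name = sprintf("compound_%04d", seq_len(n)),
      ob = round(stats::runif(n, ob_range[1], ob_range[2]), 2),
      dl = round(stats::runif(n, dl_range[1], dl_range[2]), 2),
      herbs = herb_col, stringsAsFactors = FALSE)
  })
}

#' Simulate an ingredient-to-target map
#'
#' Synthetic stand-in for a compound-target prediction table: each
#' ingredient hits 1 + Poisson(`mean_targets` - 1) targets drawn uniformly
#' from a pool of `n_targets` protein ids.
#'
#' @param ingredients Ingredient data frame.
#' @param n_targets Size of the target pool.
#' @param mean_targets Mean number of targets per ingredient (>= 1).
#' @param seed Integer seed.
#' @return Data frame with columns `mol_id`, `target_id`.
#' @export
simulate_target_map <- function(ingredients, n_targets = 96,
                                mean_targets = 3, seed = 1) {
  validate_ingredients(ingredients)
  stopifnot(n_targets >= 1, mean_targets >= 1)
  pool <- sprintf("T%04d", seq_len(n_targets))
  withr::with_seed(derive_seed(seed, "target_map"), {
    rows <- lapply(as.character(ingredients$mol_id), function(m) {
      k <- min(1 + stats::rpois(1, mean_targets - 1), n_targets)
      data.frame(mol_id = m, target_id = sample(pool, k),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a PPI scenario with planted disease-gene distances
#'
#' Generates an interaction table, a formula target set, and a disease gene
#' set in which exactly `truth["d"]` disease genes are formula targets,
#' `truth["i1"]` sit at PPI distance 1 from the target set, `truth["i2"]`
#' at distance 2 (through a non-target intermediate), and `truth["u"]` are
#' disconnected from it. Background edges follow the chosen model among
#' targets and filler proteins (Erdos-Renyi `edge_prob` or preferential
#' attachment `pa_m`); planted and background interactions get confidences
#' uniform on `conf_range` (above the 0.9 filter), plus `n_noise_edges`
#' random low-confidence interactions (uniform below 0.9) that a
#' `min_confidence = 0.9` filter must remove. The planted distances are
#' re-verified internally by breadth-first search before the scenario is
#' returned.
#'
#' @param truth Named integer vector `c(d=, i1=, i2=, u=)`.
#' @param n_proteins Total protein pool size.
#' @param n_formula_targets Number of formula targets (>= `truth["d"]`).
#' @param edge_model `"er"` or `"pa"`.
#' @param edge_prob Erdos-Renyi edge probability (background and
#'   within-unlinked edges).
#' @param pa_m Preferential-attachment edges per node (model `"pa"`).
#' @param conf_range Confidence range for real interactions; must lie above
#'   0.9 so the planted structure survives the paper-mode filter.
#' @param n_noise_edges Number of sub-threshold noise interactions.
#' @param seed Integer seed.
#' @return List with `interactions` (data frame `protein_a`, `protein_b`,
#'   `confidence`), `formula_targets`, `disease_genes`, and `truth` (a
#'   `scenario_truth` list recording the planted memberships, counts, the
#'   filter the scenario is calibrated to, and the seed).
#' @export
simulate_ppi_scenario <- function(truth = c(d = 5, i1 = 7, i2 = 6, u = 10),
                                  n_proteins = 120, n_formula_targets = 20,
                                  edge_model = c("er", "pa"),
                                  edge_prob = 0.05, pa_m = 2,
                                  conf_range = c(0.905, 0.999),
                                  n_noise_edges = 40, seed = 1) {
  edge_model <- match.arg(edge_model)
  stopifnot(all(c("d", "i1", "i2", "u") %in% names(truth)),
            all(truth >= 0), conf_range[1] > 0.9, conf_range[2] <= 1)
  d <- truth[["d"]]; i1 <- truth[["i1"]]; i2 <- truth[["i2"]]
  u <- truth[["u"]]
  n_filler <- n_proteins - n_formula_targets - i1 - i2 - u
  if (d > n_formula_targets || n_filler < (i2 > 0))
    stop("infeasible plant: need n_proteins >= n_formula_targets + i1 + i2",
         " + u (+ 1 intermediate) and d <= n_formula_targets", call. = FALSE)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  withr::with_seed(derive_seed(seed, "ppi_scenario"), {
    ids <- sample(ids)
    ft <- sort(ids[seq_len(n_formula_targets)])
    rest <- ids[-seq_len(n_formula_targets)]
    g_i1 <- sort(rest[seq_len(i1)]); rest <- rest[-seq_len(i1)]
    g_i2 <- if (i2) sort(rest[seq_len(i2)]) else character(0)
    if (i2) rest <- rest[-seq_len(i2)]
    g_u <- if (u) sort(rest[seq_len(u)]) else character(0)
    if (u) rest <- rest[-seq_len(u)]
    filler <- rest
    g_d <- sort(sample(ft, d))

    edges <- NULL
    core <- c(ft, filler)
    if (length(core) >= 2) {
      bg <- if (edge_model == "er")
        igraph::sample_gnp(length(core), edge_prob)
      else
        igraph::sample_pa(length(core), m = pa_m, directed = FALSE)
      el <- igraph::as_edgelist(bg)
      if (nrow(el))
        edges <- data.frame(a = core[as.integer(el[, 1])],
                            b = core[as.integer(el[, 2])],
                            stringsAsFactors = FALSE)
    }
    if (i1)
      edges <- rbind(edges, data.frame(a = g_i1, b = sample(ft, i1,
                                                            replace = TRUE)))
    if (i2) {
      mids <- sample(filler, i2, replace = TRUE)
      edges <- rbind(edges,
                     data.frame(a = mids, b = sample(ft, i2, replace = TRUE)),
                     data.frame(a = g_i2, b = mids))
    }
    if (u >= 2) {
      ug <- igraph::sample_gnp(u, edge_prob)
      el <- igraph::as_edgelist(ug)
      if (nrow(el))
        edges <- rbind(edges, data.frame(a = g_u[as.integer(el[, 1])],
                                         b = g_u[as.integer(el[, 2])]))
    }
    if (is.null(edges))
      edges <- data.frame(a = character(0), b = character(0),
                          stringsAsFactors = FALSE)
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
    edges <- edges[!duplicated(key), , drop = FALSE]
    interactions <- data.frame(
      protein_a = edges$a, protein_b = edges$b,
      confidence = round(stats::runif(nrow(edges), conf_range[1],
                                      conf_range[2]), 4),
      stringsAsFactors = FALSE)
    if (n_noise_edges > 0) {
      na_ <- sample(ids, n_noise_edges, replace = TRUE)
      nb <- sample(ids, n_noise_edges, replace = TRUE)
      ok <- na_ != nb
      interactions <- rbind(interactions, data.frame(
        protein_a = na_[ok], protein_b = nb[ok],
        confidence = round(stats::runif(sum(ok), 0, 0.9), 4),
        stringsAsFactors = FALSE))
    }
    disease <- c(g_d, g_i1, g_i2, g_u)
    scenario <- list(
      interactions = interactions,
      formula_targets = ft,
      disease_genes = disease,
      truth = structure(list(
        d = d, i1 = i1, i2 = i2, u = u,
        direct_genes = g_d, hop1_genes = g_i1, hop2_genes = g_i2,
        unlinked_genes = g_u, formula_targets = ft,
        min_confidence = 0.9, seed = seed), class = "scenario_truth"))
  })
  verify_ppi_scenario(scenario)
  scenario
}

# BFS certificate: the emitted scenario must reproduce its own truth.
verify_ppi_scenario <- function(scenario) {
  net <- build_ppi(scenario$interactions,
                   min_confidence = scenario$truth$min_confidence)$network
  cls <- classify_disease_targets(scenario$formula_targets, net,
                                  scenario$disease_genes)
  tr <- scenario$truth
  ok <- setequal(cls$gene[cls$hop %in% 0], tr$direct_genes) &&
    setequal(cls$gene[cls$hop %in% 1], tr$hop1_genes) &&
    setequal(cls$gene[cls$hop %in% 2], tr$hop2_genes) &&
    setequal(cls$gene[cls$category == "unlinked"], tr$unlinked_genes)
  if (!ok)
    stop("internal error: planted PPI scenario failed its BFS certificate",
         call. = FALSE)
  invisible(scenario)
}

#' Simulate a gene x tissue expression matrix with planted dominant genes
#'
#' Baseline counts are Poisson with mean `baseline`; each planted gene has
#' one designated tissue whose mean is inflated by `inflation` (>= 1).
#'
#' @param n_genes Number of genes.
#' @param tissues Number of tissues or a character vector of labels.
#' @param baseline Poisson baseline mean.
#' @param planted Number of planted tissue-dominant genes, or a character
#'   vector of gene ids (`G0001`-style, must be among the generated ids).
#' @param inflation Mean inflation factor for the dominant tissue (>= 1;
#'   1 plants no signal).
#' @param seed Integer seed.
#' @return List with `mat` (the expression matrix) and `truth` (a
#'   `scenario_truth` list with the planted gene -> tissue map, the
#'   inflation factor and the seed).
#' @export
simulate_expression <- function(n_genes = 41, tissues = 14, baseline = 20,
                                planted = 8, inflation = 10, seed = 1) {
  if (inflation < 1) stop("inflation factor must be >= 1", call. = FALSE)
  stopifnot(n_genes >= 2, baseline > 0)
  labels <- if (is.character(tissues)) tissues
            else sprintf("tissue_%02d", seq_len(tissues))
  K <- length(labels)
  stopifnot(K >= 2)
  genes <- sprintf("G%04d", seq_len(n_genes))
  withr::with_seed(derive_seed(seed, "expression"), {
    planted_genes <- if (is.character(planted)) planted
                     else sort(sample(genes, planted))
    if (!all(planted_genes %in% genes))
      stop("planted genes must be among the generated gene ids",
           call. = FALSE)
    mat <- matrix(stats::rpois(n_genes * K, baseline), nrow = n_genes,
                  dimnames = list(genes, labels))
    planted_tissue <- character(0)
    if (length(planted_genes) && inflation > 1) {
      planted_tissue <- sample(labels, length(planted_genes), replace = TRUE)
      names(planted_tissue) <- planted_genes
      for (g in planted_genes)
        mat[g, planted_tissue[[g]]] <-
          stats::rpois(1, baseline * inflation)
    }
    list(mat = mat,
         truth = structure(list(
           planted_genes = if (inflation > 1) planted_genes else character(0),
           planted_tissue = as.list(planted_tissue),
           inflation = inflation, baseline = baseline, seed = seed),
           class = "scenario_truth"))
  })
}

#' Simulate a pathway catalog with one planted enriched pathway
#'
#' Builds `n_pathways` gene sets over a universe of `universe_size` genes;
#' the first pathway is the planted one (size `planted_size`). The query
#' draws `ceiling(overlap_fraction * query_size)` genes from the planted
#' pathway and the remainder uniformly from the rest of the universe.
#'
#' @param n_pathways Number of pathways.
#' @param size_range Length-2 range of pathway sizes.
#' @param universe_size Background universe size.
#' @param planted_size Size of the planted pathway (default
#'   `max(size_range)`).
#' @param query_size Query gene-set size.
#' @param overlap_fraction Fraction of the query drawn from the planted
#'   pathway, in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `catalog` (a [pathway_catalog()]), `query` (character
#'   vector) and `truth` (a `scenario_truth` list naming the planted
#'   pathway).
#' @export
simulate_pathways <- function(n_pathways = 50, size_range = c(10, 40),
                              universe_size = 1000,
                              planted_size = max(size_range),
                              query_size = 41, overlap_fraction = 0.8,
                              seed = 1) {
  stopifnot(n_pathways >= 1, universe_size >= max(size_range),
            overlap_fraction >= 0, overlap_fraction <= 1)
  if (query_size > universe_size)
    stop("query size exceeds the universe", call. = FALSE)
  n_from_planted <- ceiling(overlap_fraction * query_size)
  if (n_from_planted > planted_size)
    stop("planted pathway too small for the requested overlap", call. = FALSE)
  universe <- sprintf("U%05d", seq_len(universe_size))
  ids <- sprintf("PW%03d", seq_len(n_pathways))
  withr::with_seed(derive_seed(seed, "pathways"), {
    sizes <- c(planted_size,
               sample(seq(size_range[1], size_range[2]), n_pathways - 1,
                      replace = TRUE))
    sets <- stats::setNames(
      lapply(sizes, function(s) sort(sample(universe, s))), ids)
    from_planted <- sample(sets[[1]], n_from_planted)
    rest <- sample(setdiff(universe, from_planted),
                   query_size - n_from_planted)
    query <- sort(c(from_planted, rest))
    list(catalog = pathway_catalog(sets, universe = universe),
         query = query,
         truth = structure(list(
           planted_pathway = ids[1], overlap_fraction = overlap_fraction,
           query_size = query_size, seed = seed),
           class = "scenario_truth"))
  })
}

#' Persist / reload a scenario truth record
#'
#' Generators return their planted ground truth as a `scenario_truth` list;
#' recovery tests are expected to read the truth back from the emitted file
#' rather than reach into generator internals.
#'
#' @param truth A `scenario_truth` list.
#' @param path JSON file path.
#' @return `read_scenario_truth()` returns the truth list.
#' @export
write_scenario_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scenario_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scenario_truth
#' @export
read_scenario_truth <- function(path) {
  truth <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  truth <- lapply(truth, function(x) if (is.list(x) && !length(x)) list() else x)
  structure(truth, class = "scenario_truth")
}
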