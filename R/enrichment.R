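#' Pathway catalogs
#'
#' A catalog is a named list of pathway gene sets plus a background universe.
#' The universe defaults to the union of all catalog genes; pathway members
#' outside an explicit universe are dropped (with a warning reporting how
#' many).
#'
#' @param sets Named list of character vectors (pathway id -> gene set).
#' @param names Optional named character vector of human-readable pathway
#'   names (defaults to the ids).
#' @param universe Optional character vector of background gene ids.
#' @return Object of class `pathway_catalog` with elements `sets`, `names`,
#'   `universe`.
#' @export
pathway_catalog <- function(sets, names = NULL, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) == 0) stop("empty pathway catalog", call. = FALSE)
  ids <- base::names(sets)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("pathway ids must be unique non-empty names", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- unique(as.character(universe))
    dropped <- sum(vapply(sets, function(s) sum(!s %in% universe), 1L))
    if (dropped > 0) {
      warning(dropped, " pathway gene(s) outside the universe dropped",
              call. = FALSE)
      sets <- lapply(sets, function(s) s[s %in% universe])
    }
  }
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (is.null(names)) names <- stats::setNames(ids, ids)
  structure(list(sets = sets, names = names, universe = universe),
            class = "pathway_catalog")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @param universe Optional background gene universe (default: all genes in
#'   the file).
#' @return A [pathway_catalog()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields", call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  pathway_catalog(sets, names = stats::setNames(desc, ids),
                  universe = universe)
}

#' @rdname read_gmt
#' @param catalog A [pathway_catalog()].
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  ids <- names(catalog$sets)
  lines <- vapply(ids, function(id)
    paste(c(id, catalog$names[[id]], catalog$sets[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric pathway over-representation
#'
#' For a query of n genes drawn against a universe of N genes, the
#' enrichment p-value of a pathway with K members and k query hits is the
#' hypergeometric upper tail
#' P(X >= k) = sum over i = k..min(K, n) of C(K,i) C(N-K, n-i) / C(N, n),
#' evaluated via [stats::phyper] (log-space internals, no overflow).
#' Benjamini-Hochberg q-values are computed across the whole catalog.
#' Query ids outside the universe are dropped with a warning.
#'
#' @param query Character vector of query gene ids.
#' @param catalog A [pathway_catalog()].
#' @return Data frame with one row per pathway with k >= 1 and columns
#'   `pathway_id`, `pathway_name`, `k`, `K`, `n`, `N`, `p`, `q`, `genes`
#'   (overlap ids joined with `"|"`), ordered by ascending p (ties by
#'   descending k then pathway id).
#' @examples
#' cat10 <- pathway_catalog(list(pw = as.character(1:5)),
#'                          universe = as.character(1:10))
#' hypergeom_enrich(as.character(1:5), cat10)$p  # 1 / choose(10, 5)
#' @export
hypergeom_enrich <- function(query, catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  query <- unique(as.character(query))
  outside <- setdiff(query, catalog$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  N <- length(catalog$universe)
  n <- length(query)
  ids <- names(catalog$sets)
  K <- vapply(catalog$sets, length, 1L)
  overlap <- lapply(catalog$sets, function(s) sort(intersect(s, query)))
  k <- vapply(overlap, length, 1L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  rows <- data.frame(
    pathway_id = ids,
    pathway_name = as.character(catalog$names[ids]),
    k = k, K = K, n = n, N = N, p = p, q = q,
    genes = vapply(overlap, paste, character(1), collapse = "|"),
    row.names = NULL, stringsAsFactors = FALSE)
  rows <- rows[rows$k >= 1, , drop = FALSE]
  rows <- rows[order(rows$p, -rows$k, rows$pathway_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Filter and rank enrichment rows
#'
#' Keeps rows with `p <= max_p` and at least `min_genes` overlap genes
#' ("more than three genes" = k >= 4 with the defaults), sorts by ascending
#' p with ties broken by descending k then pathway id, and optionally
#' truncates to the top `top_n`.
#'
#' @param rows Output of [hypergeom_enrich()].
#' @param max_p Raw p-value cutoff (inclusive), default 0.05.
#' @param min_genes Minimum overlap size (inclusive), default 4.
#' @param top_n Optional row count after ranking.
#' @return The filtered, ordered subset of `rows`.
#' @export
filter_rank <- function(rows, max_p = 0.05, min_genes = 4, top_n = NULL) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0) return(rows)
  keep <- rows$p <= max_p & rows$k >= min_genes
  out <- rows[keep, , drop = FALSE]
  out <- out[order(out$p, -out$k, out$pathway_id), , drop = FALSE]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
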