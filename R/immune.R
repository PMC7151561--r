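#' Read a gene x tissue expression table
#'
#' Tab-separated with a header: first column the gene id, remaining columns
#' one per tissue/cell type. Values are non-negative expression units
#' treated as counts by the chi-square screen.
#'
#' @param path File path.
#' @return Numeric matrix, genes as rows, tissues as columns.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  validate_expression(mat)
  mat
}

#' @rdname read_expression
#' @param mat Expression matrix.
#' @export
validate_expression <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("expression matrix needs at least 2 genes and 2 tissues",
         call. = FALSE)
  if (anyNA(mat) || any(mat < 0))
    stop("expression values must be non-negative numbers", call. = FALSE)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("gene labels must be present and unique", call. = FALSE)
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop("tissue labels must be present and unique", call. = FALSE)
  invisible(mat)
}

#' Chi-square screen for tissue-specific expression
#'
#' For each gene g the default `"contingency"` construction builds the 2 x K
#' table whose first row is g's expression profile and whose second row is
#' the column-wise sum of all other genes (the pooled background); expected
#' counts come from the table margins and the statistic is the Pearson sum
#' over all 2K cells of (O - E)^2 / E, referred to a chi-square distribution
#' with K - 1 degrees of freedom. The `"goodness_of_fit"` variant instead
#' tests g's profile against a uniform expectation across the K tissues
#' (same degrees of freedom).
#'
#' A gene whose row is entirely zero gets the formula's limiting statistic 0
#' (0/0 cells contribute nothing) and is flagged degenerate; a tissue column
#' whose total is zero makes expected counts zero and is an error.
#'
#' @param mat Expression matrix (genes x tissues), see [read_expression()].
#' @param alpha Significance level for the flag, default 0.05.
#' @param method `"contingency"` (default) or `"goodness_of_fit"`.
#' @param adjust If `TRUE`, flag significance on Benjamini-Hochberg adjusted
#'   p-values instead of raw ones (raw p is what the screen reports either
#'   way; a `q` column is added when `adjust = TRUE`).
#' @return Data frame with columns `gene`, `statistic`, `df`, `p`,
#'   `significant`, `degenerate`, ordered by descending statistic (stable in
#'   input order on ties).
#' @export
chi_square_screen <- function(mat, alpha = 0.05,
                              method = c("contingency", "goodness_of_fit"),
                              adjust = FALSE) {
  method <- match.arg(method)
  validate_expression(mat)
  K <- ncol(mat)
  col_tot <- colSums(mat)
  if (method == "contingency" && any(col_tot == 0))
    stop("zero expected count: tissue column '",
         colnames(mat)[which(col_tot == 0)[1]], "' has zero total",
         call. = FALSE)
  stat <- numeric(nrow(mat))
  degenerate <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, ]
    if (sum(row) == 0) {
      degenerate[i] <- TRUE
      stat[i] <- 0
      next
    }
    if (method == "contingency") {
      other <- col_tot - row
      if (sum(other) == 0)
        stop("zero expected count: pooled background row is all zero for gene '",
             rownames(mat)[i], "'", call. = FALSE)
      O <- rbind(row, other)
      E <- outer(rowSums(O), colSums(O)) / sum(O)
      cells <- (O - E)^2 / E
      cells[E == 0] <- 0      # a zero column would have errored above
      stat[i] <- sum(cells)
    } else {
      E <- rep(sum(row) / K, K)
      stat[i] <- sum((row - E)^2 / E)
    }
  }
  df <- K - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  res <- data.frame(gene = rownames(mat), statistic = stat, df = df, p = p,
                    stringsAsFactors = FALSE)
  if (adjust) {
    res$q <- stats::p.adjust(p, method = "BH")
    res$significant <- res$q < alpha & !degenerate
  } else {
    res$significant <- p < alpha & !degenerate
  }
  res$degenerate <- degenerate
  res <- res[order(-res$statistic), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene-tissue linking rules
#'
#' @param method `"median"` (link tissues at or above the gene's row
#'   median, the default), `"top_n"` (the `value` highest tissues, ties
#'   resolved by column order), `"quantile"` (at or above the row quantile
#'   `value`), or `"absolute"` (at or above the fixed cutoff `value`).
#' @param value Rule parameter (unused for `"median"`).
#' @return Object of class `link_rule`.
#' @export
link_rule <- function(method = c("median", "top_n", "quantile", "absolute"),
                      value = NULL) {
  method <- match.arg(method)
  if (method != "median" && (is.null(value) || !is.numeric(value)))
    stop("link_rule method '", method, "' needs a numeric value",
         call. = FALSE)
  structure(list(method = method, value = value), class = "link_rule")
}

#' Build the bipartite gene-tissue network
#'
#' Connects each selected gene to the tissues where its expression satisfies
#' the linking rule; with the default median rule a tissue is linked when
#' the gene's value there is at or above the median of its row (so a
#' constant row links everywhere).
#'
#' @param mat Expression matrix (genes x tissues).
#' @param genes Character vector of selected genes (subset of rownames);
#'   default all.
#' @param rule A [link_rule()].
#' @return A [pharm_network()] with `disease_gene` and `tissue` nodes and
#'   `gene_tissue` edges. Empty selection gives an empty network.
#' @export
build_gene_tissue_network <- function(mat, genes = rownames(mat),
                                      rule = link_rule("median")) {
  validate_expression(mat)
  stopifnot(inherits(rule, "link_rule"))
  genes <- as.character(genes)
  unknown <- setdiff(genes, rownames(mat))
  if (length(unknown))
    stop("unknown gene: ", unknown[1], call. = FALSE)
  if (length(genes) == 0) return(pharm_network())
  edges <- do.call(rbind, lapply(genes, function(g) {
    row <- mat[g, ]
    linked <- switch(rule$method,
      median = colnames(mat)[row >= stats::median(row)],
      top_n = colnames(mat)[order(-row)[seq_len(min(rule$value, length(row)))]],
      quantile = colnames(mat)[row >= stats::quantile(row, rule$value)],
      absolute = colnames(mat)[row >= rule$value])
    if (length(linked) == 0) return(NULL)
    data.frame(from = g, to = linked, kind = "gene_tissue",
               stringsAsFactors = FALSE)
  }))
  tissues <- if (is.null(edges)) character(0) else unique(edges$to)
  nodes <- rbind(
    data.frame(id = genes, role = "disease_gene"),
    if (length(tissues)) data.frame(id = tissues, role = "tissue"))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0))
  pharm_network(nodes, edges)
}
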