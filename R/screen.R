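#' Screening policy for ADME ingredient filtering
#'
#' A policy bundles the oral-bioavailability (OB) and drug-likeness (DL)
#' thresholds used to retain candidate ingredients, plus optional per-herb
#' OB overrides (e.g. tightening Licorice to OB >= 50 while every other herb
#' stays at OB >= 30).
#'
#' @param default_min_ob Default OB threshold in percent (0-100 scale).
#' @param min_dl DL threshold, unitless in \[0, 1\].
#' @param herb_min_ob Named numeric vector of per-herb OB overrides, on the
#'   same percent scale (names are herb codes).
#' @return An object of class `screen_policy`.
#' @examples
#' screen_policy(30, 0.18, c(LO = 50))
#' @export
screen_policy <- function(default_min_ob = 30, min_dl = 0.18,
                          herb_min_ob = c(LO = 50)) {
  stopifnot(is.numeric(default_min_ob), length(default_min_ob) == 1,
            is.numeric(min_dl), length(min_dl) == 1)
  if (default_min_ob < 0 || min_dl < 0)
    stop("screen_policy thresholds must be >= 0", call. = FALSE)
  herb_min_ob <- as.numeric_named(herb_min_ob)
  if (length(herb_min_ob) && (is.null(names(herb_min_ob)) ||
                              any(!nzchar(names(herb_min_ob)))))
    stop("herb_min_ob must be a named vector of herb codes", call. = FALSE)
  if (length(herb_min_ob) && any(herb_min_ob < 0))
    stop("herb_min_ob overrides must be >= 0", call. = FALSE)
  structure(list(default_min_ob = default_min_ob, min_dl = min_dl,
                 herb_min_ob = herb_min_ob),
            class = "screen_policy")
}

as.numeric_named <- function(x) {
  if (is.null(x)) return(numeric(0))
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

#' @export
print.screen_policy <- function(x, ...) {
  cat("ADME screen policy: OB >=", x$default_min_ob, "% , DL >=", x$min_dl, "\n")
  if (length(x$herb_min_ob))
    cat("  per-herb OB overrides:",
        paste0(names(x$herb_min_ob), " >= ", x$herb_min_ob, "%", collapse = ", "),
        "\n")
  invisible(x)
}

# Split a comma-separated herb field into a character vector of codes.
split_herbs <- function(herbs) {
  lapply(strsplit(as.character(herbs), ","), function(h) {
    h <- trimws(h)
    h[nzchar(h)]
  })
}

#' Validate an ingredient table
#'
#' Checks the structural invariants of an ingredient table: numeric
#' non-negative OB, numeric DL in \[0, 1\], a non-empty herb set per row and
#' unique molecule ids. Errors identify the offending row by `mol_id` (or row
#' number when the id itself is broken).
#'
#' @param records Data frame with columns `mol_id`, `name`, `ob`, `dl`,
#'   `herbs` (herbs as a comma-separated string of codes). An optional `id`
#'   column is carried along untouched.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_ingredients <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("mol_id", "name", "ob", "dl", "herbs")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("ingredient table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0) return(invisible(records))
  row_id <- ifelse(is.na(records$mol_id) | !nzchar(as.character(records$mol_id)),
                   paste0("row ", seq_len(nrow(records))),
                   as.character(records$mol_id))
  ob <- suppressWarnings(as.numeric(records$ob))
  dl <- suppressWarnings(as.numeric(records$dl))
  bad <- which(is.na(ob) | ob < 0)
  if (length(bad))
    stop("malformed OB value for ", row_id[bad[1]],
         " (must be numeric and >= 0)", call. = FALSE)
  bad <- which(is.na(dl) | dl < 0 | dl > 1)
  if (length(bad))
    stop("malformed DL value for ", row_id[bad[1]],
         " (must be numeric in [0, 1])", call. = FALSE)
  herbs <- split_herbs(records$herbs)
  bad <- which(vapply(herbs, length, 1L) == 0)
  if (length(bad))
    stop("empty herb set for ", row_id[bad[1]], call. = FALSE)
  dup <- records$mol_id[duplicated(records$mol_id)]
  if (length(dup))
    stop("duplicated mol_id in ingredient table: ", dup[1], call. = FALSE)
  invisible(records)
}

#' Read / write ingredient tables
#'
#' Tab-separated with a header row and columns `id` (optional), `mol_id`,
#' `name`, `ob`, `dl`, `herbs` (comma-separated herb codes).
#'
#' @param path File path.
#' @return `read_ingredients()` returns a validated data frame.
#' @export
read_ingredients <- function(path) {
  records <- utils::read.delim(path, stringsAsFactors = FALSE,
                               check.names = FALSE)
  records$ob <- suppressWarnings(as.numeric(records$ob))
  records$dl <- suppressWarnings(as.numeric(records$dl))
  validate_ingredients(records)
  records
}

#' @rdname read_ingredients
#' @param records Ingredient data frame.
#' @export
write_ingredients <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply an OB/DL screen to an ingredient table
#'
#' A record is retained iff its DL meets `min_dl` and at least one of its
#' herbs grants it passage on OB: the OB threshold for herb `h` is
#' `herb_min_ob[h]` when an override exists, otherwise `default_min_ob`.
#' All comparisons are inclusive (`>=`). Input order is preserved and the
#' input is never modified.
#'
#' @param records Ingredient data frame (see [validate_ingredients()]).
#' @param policy A [screen_policy()].
#' @return The retained subset of `records`, original order.
#' @examples
#' tab <- data.frame(mol_id = c("M1", "M2"), name = c("a", "b"),
#'                   ob = c(59.3, 45), dl = c(0.21, 0.3),
#'                   herbs = c("CR,LO", "LO"))
#' apply_screen(tab, screen_policy(30, 0.18, c(LO = 50)))  # keeps M1 only
#' @export
apply_screen <- function(records, policy = screen_policy()) {
  stopifnot(inherits(policy, "screen_policy"))
  validate_ingredients(records)
  if (nrow(records) == 0) return(records)
  herbs <- split_herbs(records$herbs)
  ob <- as.numeric(records$ob)
  dl <- as.numeric(records$dl)
  keep <- vapply(seq_len(nrow(records)), function(i) {
    if (dl[i] < policy$min_dl) return(FALSE)
    thr <- vapply(herbs[[i]], function(h) {
      if (h %in% names(policy$herb_min_ob)) policy$herb_min_ob[[h]]
      else policy$default_min_ob
    }, numeric(1))
    any(ob[i] >= thr)
  }, logical(1))
  records[keep, , drop = FALSE]
}

#' Count ingredients per herb
#'
#' An ingredient shared by several herbs contributes one count to each, so
#' the counts sum to at least the number of records.
#'
#' @param records Ingredient data frame.
#' @return Named integer vector, herb code -> count, decreasing by count
#'   (ties by herb code). Empty input gives an empty vector.
#' @export
per_herb_counts <- function(records) {
  validate_ingredients(records)
  if (nrow(records) == 0) return(stats::setNames(integer(0), character(0)))
  herbs <- unlist(split_herbs(records$herbs))
  tab <- table(herbs)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(-counts, names(counts))]
}
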