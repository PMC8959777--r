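#' Gene-set collections and GMT input
#'
#' A gene-set collection is a named list of term member vectors plus a gene
#' universe. `read_gmt()` parses the tab-separated GMT format
#' (`term_id<TAB>description<TAB>gene1<TAB>gene2...`).
#'
#' @param sets Named list of character member vectors.
#' @param universe Character vector of background genes; members outside it
#'   are dropped with a warning.
#' @param descriptions Optional named term descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  outside <- unique(unlist(lapply(sets, setdiff, y = universe)))
  if (length(outside)) {
    warning(length(outside), " member gene(s) outside the universe dropped")
    sets <- lapply(sets, intersect, y = universe)
  }
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' @rdname gene_set_collection
#' @param path GMT file path.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("GMT lines without members: ", paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- ids
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, stats::setNames(desc, ids))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "terms over",
      length(x$universe), "universe genes\n")
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each term with `K` members in a universe of `N` genes and a query of
#' `n` genes overlapping the term in `k`, computes the upper-tail
#' hypergeometric probability `p = P(X >= k)` (over-representation only),
#' BH-adjusts across terms, and reports `gene_ratio = k / n`. Terms are
#' sorted by gene ratio, then p.
#'
#' @param query Character vector of genes; entries outside the universe are
#'   dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param p_max Significance cutoff applied to the raw p (default 0.05),
#'   recorded in the `significant` column; no rows are removed.
#' @return data.frame `term_id, term_name, k, K, n, N, gene_ratio, p, fdr,
#'   genes, significant`.
#' @examples
#' coll <- gene_set_collection(list(T1 = letters[1:4]), letters[1:20])
#' ora(letters[c(1:3, 10, 11)], coll)   # p = P(X >= 3) ~ 0.032
#' @export
ora <- function(query, collection, p_max = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  out_cols <- data.frame(term_id = character(), term_name = character(),
                         k = integer(), K = integer(), n = integer(),
                         N = integer(), gene_ratio = numeric(),
                         p = numeric(), fdr = numeric(), genes = character(),
                         significant = logical(), stringsAsFactors = FALSE)
  if (!length(query)) return(out_cols)
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
    if (!length(query)) return(out_cols)
  }
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    members <- collection$sets[[term]]
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term,
               term_name = unname(collection$descriptions[term]),
               k = k, K = K, n = n, N = N,
               gene_ratio = k / n, p = p,
               genes = paste(sort(hit), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  out$significant <- out$p < p_max
  out <- out[order(-out$gene_ratio, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out[c("term_id", "term_name", "k", "K", "n", "N", "gene_ratio", "p",
        "fdr", "genes", "significant")]
}
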