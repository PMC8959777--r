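#' TPM normalization
#'
#' Converts raw counts to transcripts per kilobase million. For gene g in a
#' sample, `TPM_g = 1e6 * (count_g / length_g) / sum_h(count_h / length_h)`,
#' so every column sums to one million.
#'
#' @param counts Numeric matrix of nonnegative counts, genes in rows (rownames
#'   are gene ids), samples in columns.
#' @param lengths Positive gene lengths in bp, either a named vector covering
#'   every gene or in row order of `counts`.
#' @return Matrix of TPM values with the dimensions of `counts`.
#' @examples
#' m <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' compute_tpm(m, c(g1 = 1000, g2 = 2000))
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss)) stop("gene lengths missing for: ", paste(miss, collapse = ", "))
    lengths <- lengths[rownames(counts)]
  } else if (length(lengths) != nrow(counts)) {
    stop("lengths must be named or match nrow(counts)")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- which(tot == 0)
  if (length(zero))
    stop("all-zero sample column(s): ", paste(colnames(counts)[zero], collapse = ", "))
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1 and
#' returned in the original order. `NaN`/`NA` entries are propagated with a
#' warning and excluded from the multiplicity count.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric())
  if (any(bad <- is.na(p))) {
    warning("NaN/NA p-values propagated unadjusted")
    out <- rep(NA_real_, length(p))
    out[bad] <- p[bad]  # keeps NaN as NaN
    out[!bad] <- stats::p.adjust(p[!bad], method = "BH")
    return(out)
  }
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression by per-gene t-test
#'
#' Calls differential expression for one case/control contrast. Counts are
#' TPM-normalized (requires `lengths`), the fold change is computed on the
#' normalized scale with a pseudocount,
#' `log2fc = log2((mean_case + c) / (mean_ctrl + c))`, and the per-gene
#' two-sided t-test (Welch by default) is run on `log2(TPM + 1)` values.
#' P-values are BH-adjusted across all genes; a gene is `significant` iff
#' `fdr < alpha` and `|log2fc| > min_lfc`, and its `direction` is the sign of
#' its fold change when significant, `"none"` otherwise.
#'
#' Degenerate genes with zero variance in both groups and equal means get
#' `p = 1` (no evidence), and zero variance with unequal means gets `p = 0`
#' (the t statistic diverges).
#'
#' @param counts Count matrix (genes x samples, rownames = gene ids).
#' @param contrast List with `label`, `case`, `control` (sample id vectors,
#'   disjoint, each of size >= 2, all present in `counts`).
#' @param lengths Gene lengths for TPM (see [compute_tpm()]); may be `NULL`
#'   with `normalize = "none"`.
#' @param alpha FDR significance cutoff (default 0.05).
#' @param min_lfc Minimum `|log2fc|` for significance (default 1).
#' @param pseudocount Pseudocount on the normalized scale (default 1).
#' @param var_equal Use the pooled-variance Student's t (default `TRUE`);
#'   `FALSE` gives Welch's unequal-variance t. With triplicate designs the
#'   Welch degrees of freedom collapse to 2-3 and the test becomes markedly
#'   conservative, so the pooled variant is the calibrated default.
#' @param normalize `"tpm"` (default) or `"none"` (test raw counts, log2+1).
#' @return A data.frame of class `de_table` with columns
#'   `gene_id, log2fc, p_value, fdr, direction, significant` and the contrast
#'   label as attribute `contrast`.
#' @export
differential_expression <- function(counts, contrast, lengths = NULL,
                                    alpha = 0.05, min_lfc = 1,
                                    pseudocount = 1, var_equal = TRUE,
                                    normalize = c("tpm", "none")) {
  normalize <- match.arg(normalize)
  counts <- as.matrix(counts)
  stopifnot(is.list(contrast), all(c("case", "control") %in% names(contrast)))
  case <- contrast$case; ctrl <- contrast$control
  if (length(intersect(case, ctrl))) stop("case and control samples overlap")
  if (length(case) < 2L || length(ctrl) < 2L)
    stop("need >= 2 samples on each side of the contrast")
  miss <- setdiff(c(case, ctrl), colnames(counts))
  if (length(miss)) stop("samples absent from count matrix: ", paste(miss, collapse = ", "))

  expr <- switch(normalize,
                 tpm = compute_tpm(counts, lengths),
                 none = counts)
  x <- expr[, case, drop = FALSE]
  y <- expr[, ctrl, drop = FALSE]
  log2fc <- log2((rowMeans(x) + pseudocount) / (rowMeans(y) + pseudocount))

  lx <- log2(x + 1); ly <- log2(y + 1)
  p <- welch_t_rows(lx, ly, var_equal = var_equal)
  fdr <- benjamini_hochberg(p)
  sig <- fdr < alpha & abs(log2fc) > min_lfc
  dir <- ifelse(sig, ifelse(log2fc > 0, "up", "down"), "none")
  out <- data.frame(gene_id = rownames(counts), log2fc = log2fc,
                    p_value = p, fdr = fdr, direction = dir,
                    significant = sig, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast$label %||% ""
  class(out) <- c("de_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise two-sided t-test p-values (Welch or pooled variance).
welch_t_rows <- function(x, y, var_equal = FALSE) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  # se == 0: both groups constant; equal means -> p = 1, unequal -> p = 0
  flat <- se == 0
  p[flat & m1 == m2] <- 1
  p[flat & m1 != m2] <- 0
  unname(p)
}

#' Signed gene sets
#'
#' `signed_set()` builds a signed gene set (gene -> up/down) from a `de_table`
#' (its significant genes) or from parallel id/direction vectors.
#' `intersect_signed()` intersects two signed sets, optionally requiring the
#' direction to agree (in which case the shared direction is retained;
#' otherwise genes present in both sets are kept with the direction from `a`).
#'
#' @param x A `de_table` or a character vector of gene ids.
#' @param direction Directions (`"up"`/`"down"`) when `x` is a plain vector.
#' @param name Set label.
#' @return A named character vector of directions with class
#'   `signed_gene_set` and attribute `name`.
#' @examples
#' a <- signed_set(c("g1", "g2", "g3"), c("up", "down", "up"))
#' b <- signed_set(c("g1", "g2", "g4"), c("up", "up", "down"))
#' intersect_signed(a, b)                                # g1 (up)
#' intersect_signed(a, b, require_consistent_direction = FALSE)  # g1, g2
#' @export
signed_set <- function(x, direction = NULL, name = "") {
  if (inherits(x, "de_table")) {
    keep <- x$significant
    members <- stats::setNames(x$direction[keep], x$gene_id[keep])
    name <- if (nzchar(name)) name else attr(x, "contrast") %||% ""
  } else {
    stopifnot(length(x) == length(direction))
    if (anyDuplicated(x)) stop("duplicate gene ids in signed set")
    if (!all(direction %in% c("up", "down")))
      stop("directions must be 'up' or 'down'")
    members <- stats::setNames(as.character(direction), x)
  }
  structure(members, class = "signed_gene_set", name = name)
}

#' @rdname signed_set
#' @param a,b Signed gene sets.
#' @param require_consistent_direction Keep only genes whose direction agrees
#'   (default `TRUE`).
#' @export
intersect_signed <- function(a, b, require_consistent_direction = TRUE) {
  common <- intersect(names(a), names(b))
  if (require_consistent_direction)
    common <- common[unclass(a)[common] == unclass(b)[common]]
  structure(stats::setNames(unclass(a)[common], common),
            class = "signed_gene_set",
            name = paste0(attr(a, "name"), "&", attr(b, "name")))
}

#' @export
print.signed_gene_set <- function(x, ...) {
  cat("signed_gene_set '", attr(x, "name"), "': ", length(x), " genes (",
      sum(x == "up"), " up, ", sum(x == "down"), " down)\n", sep = "")
  invisible(x)
}
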