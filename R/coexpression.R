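#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the t-transform p-value,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom;
#' `|r| = 1` gives `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return Named numeric vector `c(r = , p = )`.
#' @examples
#' pearson_with_p(c(1, 2, 3), c(2, 4, 6))   # r = 1, p = 0
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), n - 2)
  }
  c(r = r, p = p)
}

#' Thresholded Pearson co-expression network
#'
#' Correlates every gene of `set_a` with every gene of `set_b` across all
#' columns of `tpm` (samples pooled over groups) and keeps pairs passing the
#' correlation and p-value thresholds. With `signed = TRUE` (default) the
#' magnitude is thresholded (`|r| > r_min`) and the sign is recorded on the
#' edge; `signed = FALSE` keeps positive correlations only (`r > r_min`).
#' Self-pairs from genes in both sets are excluded; constant genes are
#' skipped with a warning.
#'
#' @param tpm Expression matrix (genes x samples), e.g. from
#'   [compute_tpm()].
#' @param set_a,set_b Character vectors of gene ids present in `tpm` (e.g.
#'   force-sensitive mRNAs and force-related lncRNAs).
#' @param r_min Correlation threshold (default 0.8, exclusive).
#' @param p_max P-value threshold (default 0.05, exclusive; raw p, no
#'   multiplicity correction by default).
#' @param signed Threshold `|r|` and keep the sign (default `TRUE`).
#' @param adjust_p Apply BH across all tested pairs before thresholding
#'   (default `FALSE`).
#' @param type_a,type_b Node types for the two sets (defaults `"mRNA"`,
#'   `"lncRNA"`).
#' @return A [typed_network()] with `coexpr` edges carrying
#'   `r`, `p`, `sign` and `weight` (= r); the edge table orients
#'   `from`/`to` as (set_a gene, set_b gene) with the canonical pair listed
#'   once.
#' @export
build_coexpression_network <- function(tpm, set_a, set_b, r_min = 0.8,
                                       p_max = 0.05, signed = TRUE,
                                       adjust_p = FALSE,
                                       type_a = "mRNA", type_b = "lncRNA") {
  tpm <- as.matrix(tpm)
  miss <- setdiff(c(set_a, set_b), rownames(tpm))
  if (length(miss))
    stop("genes absent from the expression matrix: ",
         paste(miss, collapse = ", "))
  n <- ncol(tpm)
  if (n < 3) stop("need >= 3 samples to correlate")
  a <- t(tpm[set_a, , drop = FALSE])
  b <- t(tpm[set_b, , drop = FALSE])
  const_a <- apply(a, 2L, stats::sd) == 0
  const_b <- apply(b, 2L, stats::sd) == 0
  if (any(const_a) || any(const_b)) {
    warning("constant gene(s) skipped: ",
            paste(c(colnames(a)[const_a], colnames(b)[const_b]),
                  collapse = ", "))
    a <- a[, !const_a, drop = FALSE]
    b <- b[, !const_b, drop = FALSE]
  }
  if (!ncol(a) || !ncol(b)) return(typed_network())
  r <- stats::cor(a, b)
  rc <- pmin(pmax(r, -1), 1)
  t <- rc * sqrt(n - 2) / sqrt(1 - rc^2)
  p <- 2 * stats::pt(-abs(t), n - 2)
  p[abs(rc) >= 1] <- 0
  if (adjust_p) p[] <- benjamini_hochberg(as.vector(p))

  self <- outer(rownames(r), colnames(r), "==")
  pass <- (if (signed) abs(r) > r_min else r > r_min) & p < p_max & !self
  idx <- which(pass, arr.ind = TRUE)
  if (!nrow(idx)) return(typed_network())
  ga <- rownames(r)[idx[, 1]]; gb <- colnames(r)[idx[, 2]]
  # a gene in both sets can yield the same unordered pair twice; keep one
  pair_key <- ifelse(ga < gb, paste(ga, gb, sep = "\r"),
                     paste(gb, ga, sep = "\r"))
  keep <- !duplicated(pair_key)
  ga <- ga[keep]; gb <- gb[keep]; idx <- idx[keep, , drop = FALSE]
  rv <- r[idx]; pv <- p[idx]
  ord <- order(ga, gb)
  ga <- ga[ord]; gb <- gb[ord]; rv <- rv[ord]; pv <- pv[ord]
  nodes <- rbind(
    data.frame(id = sort(unique(ga)), type = type_a, stringsAsFactors = FALSE),
    data.frame(id = sort(unique(setdiff(gb, ga))), type = type_b,
               stringsAsFactors = FALSE))
  edges <- data.frame(from = ga, to = gb, relation = "coexpr",
                      r = rv, p = pv,
                      sign = ifelse(rv > 0, "positive", "negative"),
                      weight = rv, stringsAsFactors = FALSE)
  typed_network(nodes, edges)
}
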