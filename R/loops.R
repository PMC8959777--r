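#' Enumerate closed TF-lncRNA-miRNA-TF feedback circuits
#'
#' A circuit (t, L, m) is reported iff the TF network has a `tfbs` edge
#' t -> L, the ceRNA network has a `sponge` edge L - m, and a `target` edge
#' m -> g(t) where g(t) is the TF's own mRNA (identity mapping on gene
#' symbols by default, or an explicit two-column map). Such a circuit closes
#' the loop: the TF drives the lncRNA's transcription, the lncRNA sponges
#' the miRNA, and the miRNA represses the TF's mRNA.
#'
#' @param cerna_net A ceRNA [typed_network()] (with `sponge`/`target`
#'   edges).
#' @param tf_net A TF-lncRNA [typed_network()] (with `tfbs` edges), e.g.
#'   from [build_tf_lncrna_network()].
#' @param tf_gene_map Optional data.frame with columns `tf_id`, `gene_id`
#'   mapping TF protein ids to mRNA ids; defaults to the identity on gene
#'   symbols. TFs without a mapping are skipped with a warning.
#' @return data.frame of class `regulatory_loops` with columns
#'   `tf, lncrna, mirna`, canonically sorted.
#' @export
find_feedback_circuits <- function(cerna_net, tf_net, tf_gene_map = NULL) {
  stopifnot(inherits(cerna_net, "typed_network"),
            inherits(tf_net, "typed_network"))
  empty <- data.frame(tf = character(), lncrna = character(),
                      mirna = character(), stringsAsFactors = FALSE)
  class(empty) <- c("regulatory_loops", "data.frame")
  tfbs <- tf_net$edges[tf_net$edges$relation == "tfbs", , drop = FALSE]
  sp <- cerna_net$edges[cerna_net$edges$relation == "sponge", , drop = FALSE]
  tp <- cerna_net$edges[cerna_net$edges$relation == "target", , drop = FALSE]
  if (!nrow(tfbs) || !nrow(sp) || !nrow(tp)) return(empty)

  tfs <- unique(tfbs$from)
  if (is.null(tf_gene_map)) {
    gene_of <- stats::setNames(tfs, tfs)
  } else {
    stopifnot(all(c("tf_id", "gene_id") %in% names(tf_gene_map)))
    gene_of <- stats::setNames(tf_gene_map$gene_id, tf_gene_map$tf_id)[tfs]
    names(gene_of) <- tfs
    if (any(bad <- is.na(gene_of))) {
      for (tf in tfs[bad]) warning("no mRNA mapping for TF ", tf, "; skipped")
      gene_of <- gene_of[!bad]
    }
  }

  target_key <- paste(tp$from, tp$to, sep = "\r")
  # join tfbs(t -> L) with sponge(L - m), then require target(m -> gene(t))
  cand <- merge(data.frame(tf = tfbs$from, lncrna = tfbs$to,
                           stringsAsFactors = FALSE),
                data.frame(lncrna = sp$from, mirna = sp$to,
                           stringsAsFactors = FALSE),
                by = "lncrna")
  cand <- cand[cand$tf %in% names(gene_of), , drop = FALSE]
  if (!nrow(cand)) return(empty)
  keep <- paste(cand$mirna, gene_of[cand$tf], sep = "\r") %in% target_key
  out <- unique(cand[keep, c("tf", "lncrna", "mirna"), drop = FALSE])
  out <- out[order(out$tf, out$mirna, out$lncrna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regulatory_loops", "data.frame")
  out
}

#' Group feedback circuits for display
#'
#' Collapses circuits sharing a (TF, miRNA) pair into the conventional
#' `TF-(L1/L2/...)-miR-x-TF` rendering, one line per group.
#'
#' @param loops A `regulatory_loops` table from [find_feedback_circuits()].
#' @return Character vector of grouped circuit strings.
#' @examples
#' loops <- data.frame(tf = "NFIA",
#'                     lncrna = c("MIR4458HG", "H19", "MIR497HG"),
#'                     mirna = "miR-29a")
#' class(loops) <- c("regulatory_loops", "data.frame")
#' format_circuits(loops)
#' @export
format_circuits <- function(loops) {
  if (!nrow(loops)) return(character())
  key <- paste(loops$tf, loops$mirna, sep = "\r")
  vapply(unique(key), function(k) {
    rows <- loops[key == k, , drop = FALSE]
    sprintf("%s-(%s)-%s-%s", rows$tf[1],
            paste(sort(unique(rows$lncrna)), collapse = "/"),
            rows$mirna[1], rows$tf[1])
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.regulatory_loops <- function(x, ...) {
  cat("regulatory_loops:", nrow(x), "circuit(s)\n")
  for (s in format_circuits(x)) cat(" ", s, "\n")
  invisible(x)
}
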