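#' Typed molecular interaction network
#'
#' A light container for heterogeneous regulatory networks whose nodes are
#' typed molecular species (`lncRNA`, `miRNA`, `mRNA`, `TF`, `pathway`) and
#' whose edges carry a relation label (`sponge`, `target`, `direct`, `tfbs`,
#' `pathway`) plus optional numeric attributes. Edges are stored undirected;
#' `from`/`to` record the conventional reading direction of the relation
#' (e.g. `tfbs` reads TF -> lncRNA).
#'
#' @param nodes data.frame with columns `id`, `type` and optionally
#'   `regulation` (one of `"up"`, `"down"`, `"none"`).
#' @param edges data.frame with columns `from`, `to`, `relation` and any
#'   additional attribute columns (e.g. `weight`, `evidence_count`).
#' @return An object of class `typed_network`.
#' @examples
#' net <- typed_network(
#'   nodes = data.frame(id = c("H19", "miR-138"), type = c("lncRNA", "miRNA")),
#'   edges = data.frame(from = "H19", to = "miR-138", relation = "sponge")
#' )
#' net
#' @export
typed_network <- function(nodes = data.frame(id = character(), type = character()),
                          edges = data.frame(from = character(), to = character(),
                                             relation = character())) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "type") %in% names(nodes)),
            all(c("from", "to", "relation") %in% names(edges)))
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_type <- setdiff(unique(nodes$type), c("lncRNA", "miRNA", "mRNA", "TF", "pathway"))
  if (length(bad_type))
    stop("unknown node types: ", paste(bad_type, collapse = ", "))
  if (!"regulation" %in% names(nodes))
    nodes$regulation <- rep("none", nrow(nodes))
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ep))
    stop("edge endpoints absent from node table: ", paste(missing_ep, collapse = ", "))
  check_edge_types(nodes, edges)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "typed_network")
}

# relation -> admissible unordered endpoint type pair; "coexpr" links any
# two expressed genes (lncRNA or mRNA)
.relation_types <- list(
  sponge  = c("lncRNA", "miRNA"),
  target  = c("miRNA", "mRNA"),
  direct  = c("lncRNA", "mRNA"),
  tfbs    = c("TF", "lncRNA"),
  pathway = c("pathway", "lncRNA"),
  coexpr  = NA
)

check_edge_types <- function(nodes, edges) {
  if (!nrow(edges)) return(invisible(TRUE))
  type_of <- stats::setNames(nodes$type, nodes$id)
  for (rel in unique(edges$relation)) {
    if (!rel %in% names(.relation_types))
      stop("unknown edge relation: ", rel)
    want <- .relation_types[[rel]]
    idx <- which(edges$relation == rel)
    got <- cbind(type_of[edges$from[idx]], type_of[edges$to[idx]])
    ok <- if (rel == "coexpr") {
      apply(got, 1L, function(tt) all(tt %in% c("lncRNA", "mRNA")))
    } else {
      apply(got, 1L, function(tt) setequal(tt, want))
    }
    if (!all(ok))
      stop("relation '", rel, "' with incompatible endpoint types at rows: ",
           paste(idx[!ok], collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.typed_network <- function(x, ...) {
  cat("typed_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$type)
    cat("  nodes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (nrow(x$edges)) {
    tab <- table(x$edges$relation)
    cat("  edges:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a typed network to an igraph graph
#'
#' Node `type`/`regulation` and edge `relation` (plus any extra edge columns)
#' become igraph attributes. The graph is undirected.
#'
#' @param net A [typed_network()].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a typed network in SIF format
#'
#' One line per edge: `source relation target`, tab separated; isolated nodes
#' are written as a bare node line, matching network-viewer import behaviour.
#'
#' @param net A [typed_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "typed_network"))
  lines <- character()
  if (nrow(net$edges))
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$relation, net$edges$to)
  iso <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Write a typed network in GraphML format
#'
#' @param net A [typed_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read / write a typed interaction table
#'
#' Interaction tables are TSV files with columns
#' `source_id, source_type, target_id, target_type, evidence_count, db_name`.
#'
#' @param path File path.
#' @return A data.frame with the six canonical columns.
#' @export
read_interactions <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_id", "source_type", "target_id", "target_type",
            "evidence_count", "db_name")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("interaction table missing columns: ", paste(miss, collapse = ", "))
  tbl[need]
}

#' @rdname read_interactions
#' @param tbl Interaction data.frame.
#' @export
write_interactions <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: validate an interaction table slice against expected endpoint types.
check_interaction_types <- function(tbl, source_type, target_type, what) {
  bad <- which(tbl$source_type != source_type | tbl$target_type != target_type)
  if (length(bad))
    stop(what, ": expected ", source_type, "->", target_type,
         " rows, violated at rows: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
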