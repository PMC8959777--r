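#' Filter lncRNA-miRNA sponge pairs by CLIP evidence
#'
#' Keeps pairs whose supporting CLIP experiment count reaches
#' `min_evidence`; the default 3 is the conventional high-stringency cutoff.
#'
#' @param tbl Interaction table (six canonical columns) with rows typed
#'   lncRNA -> miRNA.
#' @param min_evidence Minimum `evidence_count` (default 3).
#' @return data.frame with columns `lncrna`, `mirna` (unique pairs).
#' @export
filter_sponge_pairs <- function(tbl, min_evidence = 3) {
  if (!nrow(tbl))
    return(data.frame(lncrna = character(), mirna = character(),
                      stringsAsFactors = FALSE))
  check_interaction_types(tbl, "lncRNA", "miRNA", "sponge table")
  keep <- tbl$evidence_count >= min_evidence
  unique(data.frame(lncrna = tbl$source_id[keep], mirna = tbl$target_id[keep],
                    stringsAsFactors = FALSE))
}

#' Three-database consensus of miRNA-mRNA target pairs
#'
#' Exact intersection: a pair is kept iff it occurs in all three tables,
#' emulating the requirement that a predicted target be supported by three
#' independent prediction databases.
#'
#' @param db1,db2,db3 Interaction tables with rows typed miRNA -> mRNA.
#' @return data.frame with columns `mirna`, `mrna` (unique consensus pairs).
#' @export
consensus_targets <- function(db1, db2, db3) {
  pairs <- lapply(list(db1, db2, db3), function(tbl) {
    if (!nrow(tbl)) return(character())
    check_interaction_types(tbl, "miRNA", "mRNA", "target table")
    unique(paste(tbl$source_id, tbl$target_id, sep = "\r"))
  })
  common <- Reduce(intersect, pairs)
  if (!length(common))
    return(data.frame(mirna = character(), mrna = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  out <- data.frame(mirna = parts[, 1], mrna = parts[, 2],
                    stringsAsFactors = FALSE)
  out[order(out$mirna, out$mrna), , drop = FALSE]
}

#' Assemble the force-responsive ceRNA network
#'
#' Builds the lncRNA-miRNA-mRNA network from evidence-filtered sponge pairs
#' and consensus target pairs, applying the triplet and degree constraints:
#'
#' 1. target pairs are restricted to force-sensitive mRNAs (`fs_mrnas`) and
#'    sponge/target pairs to the curated miRNA set (`cfs_mirnas`);
#' 2. only pairs participating in a complete lncRNA-miRNA-mRNA triplet are
#'    kept (a miRNA must retain at least one sponge partner and one target);
#' 3. lncRNA nodes with sponge degree below `min_lnc_degree` are removed in
#'    a single pass (as a one-shot network-viewer filter would), after which
#'    newly orphaned miRNA and mRNA nodes are dropped. Set
#'    `iterate = TRUE` to re-apply the degree filter to a fixed point.
#'
#' mRNA nodes carry the DE direction from `fs_mrnas` as their `regulation`
#' attribute; lncRNA and miRNA regulation is `"none"` unless supplied via
#' `lnc_regulation`.
#'
#' @param sponge_pairs data.frame `lncrna, mirna` (from
#'   [filter_sponge_pairs()]).
#' @param target_pairs data.frame `mirna, mrna` (from
#'   [consensus_targets()]).
#' @param fs_mrnas A [signed_set()] (or named direction vector) of
#'   force-sensitive mRNAs.
#' @param cfs_mirnas Character vector of curated force-sensitive miRNA ids,
#'   or `NULL` to skip the restriction.
#' @param min_lnc_degree Minimum lncRNA sponge degree (default 3).
#' @param iterate Iterate the degree filter to a fixed point (default
#'   `FALSE`, single pass).
#' @param lnc_regulation Optional named direction vector for lncRNAs.
#' @return A [typed_network()] with `sponge` and `target` edges.
#' @export
assemble_cerna <- function(sponge_pairs, target_pairs, fs_mrnas,
                           cfs_mirnas = NULL, min_lnc_degree = 3,
                           iterate = FALSE, lnc_regulation = NULL) {
  sp <- unique(as.data.frame(sponge_pairs, stringsAsFactors = FALSE))
  tp <- unique(as.data.frame(target_pairs, stringsAsFactors = FALSE))
  stopifnot(all(c("lncrna", "mirna") %in% names(sp)),
            all(c("mirna", "mrna") %in% names(tp)))
  fs_dir <- unclass(fs_mrnas)
  if (!length(fs_dir)) {
    warning("empty force-sensitive mRNA set; returning an empty network")
    return(typed_network())
  }
  # (1) restrict to FS mRNAs and curated miRNAs
  tp <- tp[tp$mrna %in% names(fs_dir), , drop = FALSE]
  if (!is.null(cfs_mirnas)) {
    tp <- tp[tp$mirna %in% cfs_mirnas, , drop = FALSE]
    sp <- sp[sp$mirna %in% cfs_mirnas, , drop = FALSE]
  }
  # (2) triplet constraint: miRNA needs >= 1 surviving sponge AND target pair
  good_mir <- intersect(sp$mirna, tp$mirna)
  sp <- sp[sp$mirna %in% good_mir, , drop = FALSE]
  tp <- tp[tp$mirna %in% good_mir, , drop = FALSE]
  # (3) degree pruning on lncRNAs (sponge edges are their only edge type)
  prune <- function(sp, tp) {
    deg <- table(sp$lncrna)
    drop_lnc <- names(deg)[deg < min_lnc_degree]
    sp <- sp[!sp$lncrna %in% drop_lnc, , drop = FALSE]
    keep_mir <- intersect(sp$mirna, tp$mirna)
    list(sp = sp[sp$mirna %in% keep_mir, , drop = FALSE],
         tp = tp[tp$mirna %in% keep_mir, , drop = FALSE])
  }
  res <- prune(sp, tp)
  if (iterate) {
    repeat {
      nxt <- prune(res$sp, res$tp)
      if (nrow(nxt$sp) == nrow(res$sp) && nrow(nxt$tp) == nrow(res$tp)) break
      res <- nxt
    }
  }
  sp <- res$sp; tp <- res$tp
  if (!nrow(sp) || !nrow(tp)) {
    warning("no complete triplets survive the filters; returning an empty network")
    return(typed_network())
  }
  sp <- sp[order(sp$lncrna, sp$mirna), , drop = FALSE]
  tp <- tp[order(tp$mirna, tp$mrna), , drop = FALSE]
  lnc <- sort(unique(sp$lncrna)); mir <- sort(unique(sp$mirna))
  mr <- sort(unique(tp$mrna))
  reg_of <- function(ids, map) {
    if (is.null(map)) return(rep("none", length(ids)))
    out <- unname(unclass(map)[ids])
    ifelse(is.na(out), "none", out)
  }
  nodes <- rbind(
    data.frame(id = lnc, type = "lncRNA",
               regulation = reg_of(lnc, lnc_regulation),
               stringsAsFactors = FALSE),
    data.frame(id = mir, type = "miRNA", regulation = "none",
               stringsAsFactors = FALSE),
    data.frame(id = mr, type = "mRNA", regulation = reg_of(mr, fs_dir),
               stringsAsFactors = FALSE))
  edges <- rbind(
    data.frame(from = sp$lncrna, to = sp$mirna, relation = "sponge",
               stringsAsFactors = FALSE),
    data.frame(from = tp$mirna, to = tp$mrna, relation = "target",
               stringsAsFactors = FALSE))
  typed_network(nodes, edges)
}

#' Enumerate the lncRNA-miRNA-mRNA triplets of a ceRNA network
#'
#' A triplet is any (lncRNA, miRNA, mRNA) with a `sponge` edge
#' lncRNA-miRNA and a `target` edge miRNA-mRNA.
#'
#' @param net A [typed_network()].
#' @return data.frame `lncrna, mirna, mrna`, canonically sorted.
#' @export
cerna_triplets <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  sp <- net$edges[net$edges$relation == "sponge", , drop = FALSE]
  tp <- net$edges[net$edges$relation == "target", , drop = FALSE]
  if (!nrow(sp) || !nrow(tp))
    return(data.frame(lncrna = character(), mirna = character(),
                      mrna = character(), stringsAsFactors = FALSE))
  out <- merge(data.frame(lncrna = sp$from, mirna = sp$to,
                          stringsAsFactors = FALSE),
               data.frame(mirna = tp$from, mrna = tp$to,
                          stringsAsFactors = FALSE), by = "mirna")
  out <- out[c("lncrna", "mirna", "mrna")]
  out <- out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node centralities with deterministic dense ranks
#'
#' Computes, on the undirected graph, the degree (incident edge count),
#' shortest-path betweenness, and component-local closeness
#' `(reachable - 1) / sum(d)` (0 for isolated nodes) of every node, plus a
#' dense 1-based rank per metric (highest centrality = rank 1; ties share a
#' rank; row order is deterministic, nodes sorted by id).
#'
#' @param net A [typed_network()] (non-empty).
#' @return data.frame of class `centrality_table`:
#'   `id, type, degree, betweenness, closeness, rank_degree,
#'    rank_betweenness, rank_closeness`.
#' @export
centrality_table <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  if (!nrow(net$nodes)) stop("cannot rank an empty network")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  cls <- suppressWarnings(igraph::closeness(g, normalized = TRUE, weights = NA))
  cls[!is.finite(cls)] <- 0  # isolated nodes: closeness 0 by convention
  ord <- order(names(deg))
  dense_rank <- function(x) match(x, sort(unique(x), decreasing = TRUE))
  out <- data.frame(
    id = names(deg)[ord],
    type = net$nodes$type[match(names(deg)[ord], net$nodes$id)],
    degree = as.integer(deg[ord]),
    betweenness = unname(btw[ord]),
    closeness = unname(cls[ord]),
    stringsAsFactors = FALSE)
  out$rank_degree <- dense_rank(out$degree)
  out$rank_betweenness <- dense_rank(out$betweenness)
  out$rank_closeness <- dense_rank(out$closeness)
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Consensus top-k nodes across the three centrality metrics
#'
#' Restricts the centrality table to one node type, takes the top `k` nodes
#' under each metric (ordering by the metric, ties broken by node id), and
#' returns the intersection — the nodes that are central no matter which
#' indicator is used.
#'
#' @param tbl A `centrality_table`.
#' @param node_type Node type to rank (default `"lncRNA"`).
#' @param k Size of each per-metric top list (default 15).
#' @return Sorted character vector of consensus node ids.
#' @export
consensus_top_k <- function(tbl, node_type = "lncRNA", k = 15) {
  stopifnot(inherits(tbl, "centrality_table"))
  sub <- tbl[tbl$type == node_type, , drop = FALSE]
  if (!nrow(sub)) return(character())
  if (k > nrow(sub))
    warning("k exceeds the number of ", node_type,
            " nodes; all are eligible")
  top <- function(metric) {
    ord <- order(-sub[[metric]], sub$id)
    sub$id[ord][seq_len(min(k, nrow(sub)))]
  }
  sort(Reduce(intersect, list(top("degree"), top("betweenness"),
                              top("closeness"))))
}

#' Overlay direct lncRNA-mRNA interactions on a ceRNA network
#'
#' Adds `direct` edges for experimentally supported lncRNA-mRNA pairs whose
#' endpoints are already in the network (pairs with absent endpoints are
#' ignored: the overlay annotates the ceRNA network, it does not grow it).
#'
#' @param net A [typed_network()] ceRNA network.
#' @param direct_pairs Interaction table typed lncRNA -> mRNA, or a
#'   data.frame with columns `lncrna`, `mrna`.
#' @return The network with `direct` edges added.
#' @export
overlay_direct_interactions <- function(net, direct_pairs) {
  stopifnot(inherits(net, "typed_network"))
  dp <- as.data.frame(direct_pairs, stringsAsFactors = FALSE)
  if (all(c("source_id", "target_id") %in% names(dp))) {
    check_interaction_types(dp, "lncRNA", "mRNA", "direct-interaction table")
    dp <- data.frame(lncrna = dp$source_id, mrna = dp$target_id,
                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("lncrna", "mrna") %in% names(dp)))
  dp <- unique(dp[c("lncrna", "mrna")])
  type_of <- stats::setNames(net$nodes$type, net$nodes$id)
  ok <- !is.na(type_of[dp$lncrna]) & type_of[dp$lncrna] == "lncRNA" &
        !is.na(type_of[dp$mrna]) & type_of[dp$mrna] == "mRNA"
  dp <- dp[ok, , drop = FALSE]
  if (!nrow(dp)) return(net)
  edges <- net$edges
  extra_cols <- setdiff(names(edges), c("from", "to", "relation"))
  new <- data.frame(from = dp$lncrna, to = dp$mrna, relation = "direct",
                    stringsAsFactors = FALSE)
  for (cc in extra_cols) new[[cc]] <- NA
  typed_network(net$nodes, rbind(edges, new[names(edges)]))
}

#' Extract Ce-loops from an overlaid ceRNA network
#'
#' A Ce-loop is a ceRNA triplet (lncRNA, miRNA, mRNA) whose lncRNA and mRNA
#' additionally interact directly — the indirect sponge route and the direct
#' interaction close a loop.
#'
#' @param net A [typed_network()] with `sponge`, `target` and `direct` edges
#'   (see [overlay_direct_interactions()]).
#' @return data.frame `lncrna, mirna, mrna`, canonically sorted.
#' @export
find_ce_loops <- function(net) {
  trips <- cerna_triplets(net)
  de <- net$edges[net$edges$relation == "direct", , drop = FALSE]
  if (!nrow(trips) || !nrow(de)) return(trips[0, , drop = FALSE])
  direct_key <- paste(de$from, de$to, sep = "\r")
  keep <- paste(trips$lncrna, trips$mrna, sep = "\r") %in% direct_key
  out <- trips[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
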