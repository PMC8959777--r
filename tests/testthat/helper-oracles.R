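# Independent definitional oracles used to check the package's fast paths.
# These deliberately use naive loops / explicit formulas and share no code
# with the implementation.

# Benjamini-Hochberg by the literal step-up definition:
# q_(i) = min over j >= i of m * p_(j) / j, clipped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Upper-tail hypergeometric by explicit combinatorial summation.
hyper_oracle <- function(k, K, n, N) {
  tot <- 0
  for (j in k:min(K, n))
    tot <- tot + choose(K, j) * choose(N - K, n - j)
  tot / choose(N, n)
}

# Naive per-window PWM scan: re-scores every window on both strands with
# an explicit base-by-base sum.
comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
naive_scan <- function(pwm, seq, rel_threshold) {
  lo <- pwm$log_odds
  L <- ncol(lo)
  chars <- strsplit(toupper(seq), "")[[1]]
  hits <- list()
  for (pos in seq_len(length(chars) - L + 1L)) {
    win <- chars[pos:(pos + L - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    rc <- rev(unname(comp_base[win]))
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rc
      s <- 0
      for (j in seq_len(L)) s <- s + lo[w[j], j]
      r <- (s - pwm$s_min) / (pwm$s_max - pwm$s_min)
      if (r >= rel_threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          position = pos, strand = strand, score = s, rel_score = r,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(position = integer(), strand = character(),
                      score = numeric(), rel_score = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

# Brute-force circuit enumeration: try every (TF, lncRNA, miRNA) triple.
brute_circuits <- function(tfbs, sponge, target, gene_of = NULL) {
  tfs <- unique(tfbs$from)
  lncs <- unique(sponge$from)
  mirs <- unique(sponge$to)
  if (is.null(gene_of)) gene_of <- stats::setNames(tfs, tfs)
  has <- function(tab, a, b) any(tab$from == a & tab$to == b)
  out <- list()
  for (t in tfs) for (L in lncs) for (m in mirs) {
    if (!t %in% names(gene_of)) next
    if (has(tfbs, t, L) && has(sponge, L, m) &&
        has(target, m, gene_of[[t]]))
      out[[length(out) + 1L]] <- data.frame(tf = t, lncrna = L, mirna = m,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tf = character(), lncrna = character(),
                      mirna = character(), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res[order(res$tf, res$mirna, res$lncrna), , drop = FALSE]
}

# Three-way pair intersection by nested membership loops.
consensus_oracle <- function(db1, db2, db3) {
  in_tbl <- function(tbl, m, g) any(tbl$source_id == m & tbl$target_id == g)
  out <- list()
  for (i in seq_len(nrow(db1))) {
    m <- db1$source_id[i]; g <- db1$target_id[i]
    if (in_tbl(db2, m, g) && in_tbl(db3, m, g))
      out[[length(out) + 1L]] <- data.frame(mirna = m, mrna = g,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mirna = character(), mrna = character(),
                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res[order(res$mirna, res$mrna), , drop = FALSE]
}

# Random interaction-table builders over small id namespaces.
random_target_table <- function(n, mirnas, mrnas, db = "db") {
  data.frame(source_id = sample(mirnas, n, replace = TRUE),
             source_type = "miRNA",
             target_id = sample(mrnas, n, replace = TRUE),
             target_type = "mRNA",
             evidence_count = 1L, db_name = db,
             stringsAsFactors = FALSE)
}

triplet_key <- function(d) paste(d$lncrna, d$mirna, d$mrna, sep = "\r")
loop_key <- function(d) paste(d$tf, d$lncrna, d$mirna, sep = "\r")

# A small hand-checkable ceRNA network: two full triplets sharing lncRNA L1
# (degree 2) plus one dangling sponge pair.
tiny_cerna_inputs <- function() {
  list(
    sponge = data.frame(lncrna = c("L1", "L1", "L2"),
                        mirna = c("m1", "m2", "m3"),
                        stringsAsFactors = FALSE),
    target = data.frame(mirna = c("m1", "m2"),
                        mrna = c("g1", "g2"),
                        stringsAsFactors = FALSE),
    fs = signed_set(c("g1", "g2"), c("up", "down"), "fs")
  )
}
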