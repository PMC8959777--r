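#' Read and write JASPAR-format PFM text files
#'
#' The JASPAR text format holds one motif per block: a header line
#' `>ID name` followed by four labeled count rows, e.g.
#' `A [ 4 19 0 ... ]`. `read_jaspar()` also accepts the bracket-less raw
#' variant. Matrices are returned as 4 x L integer matrices with rows
#' A, C, G, T.
#'
#' @param path File path.
#' @return `read_jaspar()`: a named list of PFM count matrices.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records ('>' headers) in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    end <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    body <- lines[(starts[i] + 1L):end]
    if (length(body) != 4L)
      stop("motif ", id, ": expected 4 base rows, got ", length(body))
    bases <- toupper(substr(body, 1, 1))
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("motif ", id, ": rows must be labeled A, C, G, T")
    rows <- lapply(body, function(l) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1L) stop("motif ", id, ": ragged count rows")
    m <- do.call(rbind, rows)
    rownames(m) <- bases
    out[[id]] <- m[c("A", "C", "G", "T"), , drop = FALSE]
  }
  out
}

#' @rdname read_jaspar
#' @param pfms Named list of 4 x L count matrices (rows A, C, G, T).
#' @export
write_jaspar <- function(pfms, path) {
  lines <- unlist(lapply(names(pfms), function(id) {
    m <- pfms[[id]]
    c(paste0(">", id, " ", id),
      vapply(c("A", "C", "G", "T"), function(b)
        sprintf("%s [ %s ]", b, paste(m[b, ], collapse = " ")),
        character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Build a log-odds PWM from a position frequency matrix
#'
#' Converts base counts to a log2-odds scoring matrix with a background
#' distributed pseudocount:
#' `log_odds[b, j] = log2( ((counts[b, j] + pc * bg_b) / (N_j + pc)) / bg_b )`
#' where `N_j` is the column total. The minimum and maximum attainable window
#' scores (`s_min`, `s_max`, the column-wise extremes) are precomputed for
#' min-max relative scoring.
#'
#' @param pfm 4 x L nonnegative count matrix with rows A, C, G, T; every
#'   column must have a positive sum.
#' @param background Base composition (A, C, G, T), summing to 1.
#' @param pseudocount Positive pseudocount mass (default 0.8), split across
#'   bases proportionally to the background.
#' @return An object of class `pwm_model`: list with `log_odds`,
#'   `background`, `pseudocount`, `s_min`, `s_max`, `width`, `consensus`.
#' @examples
#' pfm <- matrix(c(10, 0, 0, 0,  0, 10, 0, 0), nrow = 4,
#'               dimnames = list(c("A", "C", "G", "T"), NULL))
#' pwm <- pfm_to_pwm(pfm)
#' pwm$consensus
#' @export
pfm_to_pwm <- function(pfm, background = c(0.25, 0.25, 0.25, 0.25),
                       pseudocount = 0.8) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(pfm))) rownames(pfm) <- c("A", "C", "G", "T")
  pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(pfm < 0)) stop("PFM counts must be nonnegative")
  nj <- colSums(pfm)
  if (any(nj == 0)) stop("PFM has zero-sum column(s)")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 positive values summing to 1")
  bg <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
  prob <- sweep(pfm + pseudocount * bg, 2L, nj + pseudocount, "/")
  lo <- log2(prob / bg)
  cons <- rownames(lo)[apply(lo, 2L, which.max)]
  structure(list(log_odds = lo, background = bg, pseudocount = pseudocount,
                 s_min = sum(apply(lo, 2L, min)),
                 s_max = sum(apply(lo, 2L, max)),
                 width = ncol(lo),
                 consensus = paste(cons, collapse = "")),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat("pwm_model: width", x$width, " consensus", x$consensus,
      sprintf(" score range [%.3f, %.3f]\n", x$s_min, x$s_max))
  invisible(x)
}

#' Consensus string of a PFM
#'
#' The per-column maximum-count base (ties broken A < C < G < T). The
#' consensus attains the PWM maximum score `s_max` exactly.
#'
#' @param pfm 4 x L count matrix with rows A, C, G, T.
#' @return Character consensus of length L.
#' @export
pwm_consensus <- function(pfm) {
  pfm <- as.matrix(pfm)
  rn <- rownames(pfm) %||% c("A", "C", "G", "T")
  paste(rn[apply(pfm, 2L, which.max)], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param seq A character DNA sequence over A, C, G, T, N.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Encode a sequence as indices into the A/C/G/T rows; N and other
# ambiguity codes become NA so windows containing them score NA.
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

# Score every window of width L on the encoded plus strand.
score_windows <- function(lo, code) {
  L <- ncol(lo)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric())
  s <- numeric(n)
  for (j in seq_len(L)) s <- s + lo[, j][code[j:(j + n - 1L)]]
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window of the motif width on the forward sequence and on its
#' reverse complement, and reports windows whose min-max relative score
#' `(score - s_min) / (s_max - s_min)` reaches `rel_threshold` (or, in
#' absolute mode, whose raw log-odds score reaches `abs_threshold`).
#' Reverse-strand hits are reported at the forward-strand start coordinate
#' of the window (1-based). Windows containing `N` are skipped.
#'
#' @param pwm A `pwm_model` from [pfm_to_pwm()].
#' @param seq Character sequence over A, C, G, T, N.
#' @param rel_threshold Relative score cutoff in `[0, 1]` (default 0.95, the
#'   conventional stringent PWM cutoff).
#' @param abs_threshold If non-`NULL`, threshold raw scores instead.
#' @return data.frame `position, strand, score, rel_score`, ordered by
#'   position then strand.
#' @export
scan_sequence <- function(pwm, seq, rel_threshold = 0.95,
                          abs_threshold = NULL) {
  stopifnot(inherits(pwm, "pwm_model"))
  code <- encode_dna(seq)
  L <- pwm$width
  if (length(code) < L) {
    warning("sequence shorter than motif width; no windows to scan")
    return(data.frame(position = integer(), strand = character(),
                      score = numeric(), rel_score = numeric()))
  }
  span <- pwm$s_max - pwm$s_min
  degenerate <- span <= 0
  if (degenerate)
    warning("uninformative motif (s_max == s_min); all windows score rel 1")
  rel <- function(s) {
    if (degenerate) return(rep(1, length(s)))
    pmin(pmax((s - pwm$s_min) / span, 0), 1)  # guard fp epsilon at the extremes
  }

  fwd <- score_windows(pwm$log_odds, code)
  # minus strand: score the reverse complement matrix on the forward code;
  # equivalent to scoring revcomp windows, at the same forward coordinate
  lo_rc <- pwm$log_odds[4:1, ncol(pwm$log_odds):1, drop = FALSE]
  rownames(lo_rc) <- c("A", "C", "G", "T")
  rev <- score_windows(lo_rc, code)

  keep <- function(s) {
    r <- rel(s)
    ok <- if (is.null(abs_threshold)) r >= rel_threshold else s >= abs_threshold
    which(!is.na(s) & ok)
  }
  i_f <- keep(fwd); i_r <- keep(rev)
  out <- rbind(
    data.frame(position = i_f, strand = rep("+", length(i_f)),
               score = fwd[i_f], rel_score = rel(fwd)[i_f]),
    data.frame(position = i_r, strand = rep("-", length(i_r)),
               score = rev[i_r], rel_score = rel(rev)[i_r])
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Scan a promoter set with a PFM collection
#'
#' Runs [scan_sequence()] for every (motif, promoter) combination and stacks
#' the hits into one table.
#'
#' @param pfms Named list of PFM count matrices, or of `pwm_model` objects.
#' @param promoters Named character vector of promoter sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param rel_threshold,abs_threshold,background,pseudocount Passed through
#'   to [pfm_to_pwm()] / [scan_sequence()].
#' @return data.frame `tf_id, gene_id, position, strand, score, rel_score`.
#' @export
scan_promoters <- function(pfms, promoters, rel_threshold = 0.95,
                           abs_threshold = NULL,
                           background = c(0.25, 0.25, 0.25, 0.25),
                           pseudocount = 0.8) {
  if (!is.character(promoters))  # e.g. a Biostrings::DNAStringSet
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  stopifnot(!is.null(names(pfms)), !is.null(names(promoters)))
  res <- list()
  for (tf in names(pfms)) {
    pwm <- if (inherits(pfms[[tf]], "pwm_model")) pfms[[tf]]
           else pfm_to_pwm(pfms[[tf]], background, pseudocount)
    for (g in names(promoters)) {
      h <- scan_sequence(pwm, promoters[[g]], rel_threshold, abs_threshold)
      if (nrow(h))
        res[[length(res) + 1L]] <- cbind(
          data.frame(tf_id = tf, gene_id = g, stringsAsFactors = FALSE), h)
    }
  }
  if (!length(res))
    return(data.frame(tf_id = character(), gene_id = character(),
                      position = integer(), strand = character(),
                      score = numeric(), rel_score = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' TF-lncRNA regulatory network from binding-site hits
#'
#' Collapses per-window hits to one `tfbs` edge per (TF, promoter gene) pair
#' and drops TFs binding fewer than `min_tf_degree` distinct promoters (the
#' display filter used when presenting TF regulons; degree >= 10 marks key
#' TFs). Edge attributes record the number of hits and the best relative
#' score; node attribute `tf_degree` retains the pre-filter degree.
#'
#' @param hits Hit table from [scan_promoters()].
#' @param min_tf_degree Minimum number of distinct target promoters
#'   (default 5).
#' @return A [typed_network()] with `TF` and `lncRNA` nodes and `tfbs` edges.
#' @export
build_tf_lncrna_network <- function(hits, min_tf_degree = 5) {
  need <- c("tf_id", "gene_id", "rel_score")
  stopifnot(all(need %in% names(hits)))
  if (!nrow(hits)) return(typed_network())
  key <- paste(hits$tf_id, hits$gene_id, sep = "\r")
  agg <- data.frame(
    tf_id = hits$tf_id[!duplicated(key)],
    gene_id = hits$gene_id[!duplicated(key)],
    n_hits = as.vector(table(key)[unique(key)]),
    best_rel_score = as.vector(tapply(hits$rel_score, key, max)[unique(key)]),
    stringsAsFactors = FALSE)
  deg <- table(agg$tf_id)
  keep_tf <- names(deg)[deg >= min_tf_degree]
  agg <- agg[agg$tf_id %in% keep_tf, , drop = FALSE]
  if (!nrow(agg)) return(typed_network())
  nodes <- rbind(
    data.frame(id = unique(agg$tf_id), type = "TF", stringsAsFactors = FALSE),
    data.frame(id = unique(agg$gene_id), type = "lncRNA",
               stringsAsFactors = FALSE))
  nodes$tf_degree <- ifelse(nodes$type == "TF",
                            as.integer(deg[nodes$id]), NA_integer_)
  edges <- data.frame(from = agg$tf_id, to = agg$gene_id, relation = "tfbs",
                      n_hits = agg$n_hits,
                      best_rel_score = agg$best_rel_score,
                      stringsAsFactors = FALSE)
  typed_network(nodes, edges)
}
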