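#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator into a validated
#' configuration. The defaults describe the package's reference simulation:
#' a triplicate two-force design (control, intermittent, static; 3 samples
#' per group), 2,000 genes of which 60 are lncRNAs, 30 miRNAs, negative
#' binomial counts at mean 100 with dispersion 0.05, a planted fold change
#' of 2 on the log2 scale for 10% of genes (half shared between the two
#' force contrasts), 15 planted ceRNA triplets, 3 planted TF-lncRNA-miRNA
#' feedback circuits, and noise-free interaction tables
#' (`decoy_pair_rate = 0`).
#'
#' @param n_genes Total genes in the count matrix (mRNA + lncRNA).
#' @param n_lncrna Number of lncRNA genes (subset of `n_genes`).
#' @param n_mirna Number of miRNAs (not in the count matrix).
#' @param samples_per_group Samples per group (default 3, a triplicate design).
#' @param mean_expression Negative binomial mean of the baseline counts.
#' @param dispersion NB dispersion; `variance = mu + mu^2 * dispersion`, so 0
#'   degenerates to Poisson.
#' @param planted_de_fraction Fraction of genes with a planted fold change.
#' @param planted_log2fc Magnitude of the planted log2 fold change (the sign
#'   is drawn at random per gene).
#' @param shared_fraction Fraction of planted DE genes shared (same sign)
#'   between the two force contrasts; these emulate force-sensitive mRNAs.
#' @param n_planted_triplets Planted lncRNA-miRNA-mRNA ceRNA triplets.
#' @param decoy_pair_rate Probability that any non-planted lncRNA-miRNA or
#'   miRNA-mRNA pair enters the interaction tables as a decoy.
#' @param db_overlap Probability that a decoy miRNA-mRNA pair appears in all
#'   three pseudo-databases (otherwise it appears in 1 or 2).
#' @param n_planted_loops Planted TF-lncRNA-miRNA-TF feedback circuits
#'   (derived from planted triplets; must not exceed `n_planted_triplets`).
#' @param promoter_length Length in bp of each simulated upstream sequence.
#' @param gc_content GC fraction of the promoter background.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_lncrna = 60, n_mirna = 30,
                       samples_per_group = 3, mean_expression = 100,
                       dispersion = 0.05, planted_de_fraction = 0.1,
                       planted_log2fc = 2, shared_fraction = 0.5,
                       n_planted_triplets = 15, decoy_pair_rate = 0,
                       db_overlap = 0, n_planted_loops = 3,
                       promoter_length = 1000, gc_content = 0.5, seed = 7) {
  cfg <- list(n_genes = n_genes, n_lncrna = n_lncrna, n_mirna = n_mirna,
              samples_per_group = samples_per_group,
              mean_expression = mean_expression, dispersion = dispersion,
              planted_de_fraction = planted_de_fraction,
              planted_log2fc = planted_log2fc,
              shared_fraction = shared_fraction,
              n_planted_triplets = n_planted_triplets,
              decoy_pair_rate = decoy_pair_rate, db_overlap = db_overlap,
              n_planted_loops = n_planted_loops,
              promoter_length = promoter_length, gc_content = gc_content,
              seed = seed)
  counts_ok <- c("n_genes", "n_lncrna", "n_mirna", "samples_per_group",
                 "n_planted_triplets", "n_planted_loops", "promoter_length")
  for (f in counts_ok)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("'", f, "' must be a single nonnegative integer")
  for (f in c("planted_de_fraction", "shared_fraction", "decoy_pair_rate",
              "db_overlap", "gc_content"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must lie in [0, 1]")
  if (mean_expression <= 0) stop("'mean_expression' must be positive")
  if (dispersion < 0) stop("'dispersion' must be nonnegative")
  if (n_lncrna >= n_genes) stop("'n_lncrna' must be smaller than 'n_genes'")
  if (samples_per_group < 2) stop("need >= 2 samples per group")
  if (n_planted_loops > n_planted_triplets)
    stop("'n_planted_loops' cannot exceed 'n_planted_triplets'")
  cfg$n_mrna <- n_genes - n_lncrna
  structure(cfg, class = "sim_config")
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

sim_gene_ids <- function(cfg) {
  list(mrna = sprintf("GENE%04d", seq_len(cfg$n_mrna)),
       lncrna = sprintf("LNC%03d", seq_len(cfg$n_lncrna)),
       mirna = sprintf("miR-%03d", seq_len(cfg$n_mirna)))
}

#' Simulate a two-force count matrix with planted fold changes
#'
#' Draws negative binomial counts for three groups (control, intermittent
#' force, static force) and multiplies the mean of each planted gene by
#' `2^(s * planted_log2fc)` (random sign `s`) in its force group(s). Planted
#' genes shared between the two contrasts (the synthetic force-sensitive
#' mRNAs) carry the same sign in both; contrast-specific genes are split
#' evenly between the two force groups.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (integer matrix, genes x samples), `lengths`
#'   (named gene lengths in bp), `groups` (sample annotation data.frame),
#'   `contrasts` (named list of `label`/`case`/`control` specs for the
#'   intermittent and static contrasts) and `truth`, which holds
#'   `de_genes_by_contrast` (named sign vectors per contrast) and
#'   `fs_genes` (the shared, direction-consistent planted set).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    ids <- sim_gene_ids(cfg)
    genes <- c(ids$mrna, ids$lncrna)
    k <- cfg$samples_per_group
    samples <- c(sprintf("ctrl_%d", 1:k), sprintf("intermittent_%d", 1:k),
                 sprintf("static_%d", 1:k))
    group <- rep(c("control", "intermittent", "static"), each = k)

    n_de <- round(cfg$planted_de_fraction * cfg$n_genes)
    n_shared <- round(cfg$shared_fraction * n_de)
    if (n_shared > cfg$n_mrna)
      stop("more shared planted DE genes than mRNA genes")
    shared <- sample(ids$mrna, n_shared)
    rest <- sample(setdiff(genes, shared), n_de - n_shared)
    n_int <- ceiling(length(rest) / 2)
    int_only <- rest[seq_len(n_int)]
    sta_only <- setdiff(rest, int_only)
    sgn <- function(n) sample(c("up", "down"), n, replace = TRUE)
    shared_sign <- stats::setNames(sgn(length(shared)), shared)
    int_sign <- c(shared_sign, stats::setNames(sgn(length(int_only)), int_only))
    sta_sign <- c(shared_sign, stats::setNames(sgn(length(sta_only)), sta_only))

    mu <- matrix(cfg$mean_expression, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
    bump <- function(mu, signs, cols) {
      fac <- ifelse(signs == "up", 2^cfg$planted_log2fc, 2^-cfg$planted_log2fc)
      mu[names(signs), cols] <- mu[names(signs), cols] * fac
      mu
    }
    mu <- bump(mu, int_sign, group == "intermittent")
    mu <- bump(mu, sta_sign, group == "static")

    counts <- if (cfg$dispersion == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
             nrow = nrow(mu))
    }
    dimnames(counts) <- dimnames(mu)
    lengths <- stats::setNames(sample(500:3000, length(genes), replace = TRUE),
                               genes)
    list(
      counts = counts,
      lengths = lengths,
      groups = data.frame(sample = samples, group = group,
                          stringsAsFactors = FALSE),
      contrasts = list(
        intermittent = list(label = "intermittent_vs_control",
                            case = samples[group == "intermittent"],
                            control = samples[group == "control"]),
        static = list(label = "static_vs_control",
                      case = samples[group == "static"],
                      control = samples[group == "control"])
      ),
      truth = list(
        de_genes_by_contrast = list(intermittent = int_sign, static = sta_sign),
        fs_genes = shared_sign
      )
    )
  })
}

#' Simulate sponge and target interaction tables with planted triplets
#'
#' Plants `n_planted_triplets` lncRNA-miRNA-mRNA triplets: the lncRNA-miRNA
#' (sponge) pair enters the sponge table with CLIP-style evidence count >= 3
#' and the miRNA-mRNA (target) pair enters all three pseudo-databases.
#' Triplets are allocated so that every planted lncRNA participates in at
#' least three of them (surviving the downstream degree filter), and each
#' triplet uses a distinct miRNA and mRNA when the namespaces allow it.
#' Decoy pairs are drawn from the same identifier namespaces: sponge decoys
#' carry evidence < 3 and target decoys appear in all three databases only
#' with probability `db_overlap`.
#'
#' @param config A [sim_config()].
#' @param de_truth Optional `truth` element from [simulate_counts()]; when
#'   given, planted triplet mRNAs are drawn from the shared planted DE genes
#'   so that triplets survive the force-sensitive mRNA restriction.
#' @return A list with interaction data.frames `sponge`, `db1`, `db2`, `db3`
#'   (canonical six-column layout), `cfs_mirnas` (the full simulated miRNA
#'   id set) and `truth` (`planted_triplets`, `sponge_pairs`, `target_pairs`).
#' @export
simulate_interactome <- function(config, de_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_mirna < 3)
    stop("impossible degree constraint: need n_mirna >= 3 for lncRNA degree 3")
  nt <- cfg$n_planted_triplets
  if (nt > 0 && nt < 3)
    stop("n_planted_triplets must be 0 or >= 3 so planted lncRNAs reach degree 3")
  if (nt > cfg$n_lncrna * cfg$n_mirna * cfg$n_mrna)
    stop("more planted triplets than possible lncRNA-miRNA-mRNA combinations")
  with_seed(cfg$seed + 1L, {
    ids <- sim_gene_ids(cfg)
    mrna_pool <- if (!is.null(de_truth)) names(de_truth$fs_genes) else ids$mrna
    if (nt > length(mrna_pool))
      stop("not enough eligible mRNAs (", length(mrna_pool),
           ") for ", nt, " planted triplets")

    if (nt > 0) {
      n_lnc <- max(1L, nt %/% 3L)
      lnc <- sample(ids$lncrna, n_lnc)
      sizes <- rep(3L, n_lnc)
      extra <- nt - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      trip_lnc <- rep(lnc, times = sizes)
      trip_mir <- if (cfg$n_mirna >= nt) sample(ids$mirna, nt)
                  else sample(ids$mirna, nt, replace = TRUE)
      trip_mrna <- sample(mrna_pool, nt)
      triplets <- data.frame(lncrna = trip_lnc, mirna = trip_mir,
                             mrna = trip_mrna, stringsAsFactors = FALSE)
    } else {
      triplets <- data.frame(lncrna = character(), mirna = character(),
                             mrna = character(), stringsAsFactors = FALSE)
    }

    sponge_pairs <- unique(triplets[c("lncrna", "mirna")])
    target_pairs <- unique(triplets[c("mirna", "mrna")])

    itab <- function(src, stype, tgt, ttype, evidence, db) {
      data.frame(source_id = src, source_type = stype, target_id = tgt,
                 target_type = ttype, evidence_count = evidence, db_name = db,
                 stringsAsFactors = FALSE)
    }

    sponge <- itab(sponge_pairs$lncrna, "lncRNA", sponge_pairs$mirna, "miRNA",
                   sample(3:8, nrow(sponge_pairs), replace = TRUE), "sponge_db")
    # sponge decoys: evidence below the CLIP threshold
    if (cfg$decoy_pair_rate > 0) {
      all_pairs <- expand.grid(lncrna = ids$lncrna, mirna = ids$mirna,
                               stringsAsFactors = FALSE)
      key <- paste(all_pairs$lncrna, all_pairs$mirna)
      planted_key <- paste(sponge_pairs$lncrna, sponge_pairs$mirna)
      cand <- all_pairs[!key %in% planted_key, ]
      take <- stats::runif(nrow(cand)) < cfg$decoy_pair_rate
      if (any(take)) {
        d <- cand[take, ]
        sponge <- rbind(sponge, itab(d$lncrna, "lncRNA", d$mirna, "miRNA",
                                     sample(1:2, nrow(d), replace = TRUE),
                                     "sponge_db"))
      }
    }

    dbs <- c("db1", "db2", "db3")
    db_rows <- lapply(dbs, function(db)
      itab(target_pairs$mirna, "miRNA", target_pairs$mrna, "mRNA",
           1L, db))
    if (cfg$decoy_pair_rate > 0) {
      all_tp <- expand.grid(mirna = ids$mirna, mrna = ids$mrna,
                            stringsAsFactors = FALSE)
      key <- paste(all_tp$mirna, all_tp$mrna)
      planted_key <- paste(target_pairs$mirna, target_pairs$mrna)
      cand <- all_tp[!key %in% planted_key, ]
      take <- which(stats::runif(nrow(cand)) < cfg$decoy_pair_rate)
      for (i in take) {
        in_all <- stats::runif(1) < cfg$db_overlap
        members <- if (in_all) dbs else sample(dbs, sample(1:2, 1))
        for (db in members) {
          j <- match(db, dbs)
          db_rows[[j]] <- rbind(db_rows[[j]],
                                itab(cand$mirna[i], "miRNA", cand$mrna[i],
                                     "mRNA", 1L, db))
        }
      }
    }

    list(sponge = sponge, db1 = db_rows[[1]], db2 = db_rows[[2]],
         db3 = db_rows[[3]], cfs_mirnas = ids$mirna,
         truth = list(planted_triplets = triplets,
                      sponge_pairs = sponge_pairs,
                      target_pairs = target_pairs))
  })
}

#' Simulate information-rich position frequency matrices
#'
#' One PFM per TF id: at every column a dominant base takes most of the 20
#' observation counts, giving a sharp motif whose consensus is unambiguous
#' (suitable for planting recoverable binding sites).
#'
#' @param tf_ids Character vector of TF identifiers.
#' @param width Motif width in bp (default 10).
#' @param seed Integer seed.
#' @param sharpness Count share of the dominant base per column (default 0.9).
#' @return A named list of 4 x `width` count matrices (rows A, C, G, T).
#' @export
simulate_pfms <- function(tf_ids, width = 10, seed = 1, sharpness = 0.9) {
  stopifnot(width >= 1, sharpness > 0.25, sharpness <= 1)
  with_seed(seed, {
    total <- 20L
    lapply(stats::setNames(tf_ids, tf_ids), function(id) {
      m <- sapply(seq_len(width), function(j) {
        dom <- sample(4L, 1L)
        n_dom <- round(sharpness * total)
        rest <- stats::rmultinom(1L, total - n_dom, prob = rep(1 / 3, 3))[, 1L]
        col <- integer(4L)
        col[dom] <- n_dom
        col[-dom] <- rest
        col
      })
      rownames(m) <- c("A", "C", "G", "T")
      m
    })
  })
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Generates one upstream sequence of `promoter_length` bp per lncRNA, with
#' i.i.d. background at the configured GC content, and inserts the PFM
#' consensus string of each requested site at a random non-overlapping
#' position (reverse-complemented for minus-strand sites). Positions are
#' 1-based offsets of the match start on the written (plus) strand.
#'
#' @param pfms Named list of PFM count matrices (4 x L, rows A/C/G/T).
#' @param config A [sim_config()].
#' @param site_requests Optional data.frame with columns `tf_id`, `gene_id`,
#'   `strand` (`"+"`/`"-"`); one consensus occurrence is planted per row.
#' @param max_tries Retry budget for drawing non-overlapping positions.
#' @return A list with `promoters` (named character vector of sequences) and
#'   `sites` (data.frame `tf_id, gene_id, position, strand`).
#' @export
simulate_promoters <- function(pfms, config, site_requests = NULL,
                               max_tries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  widths <- vapply(pfms, ncol, integer(1))
  if (length(widths) && max(widths) > cfg$promoter_length)
    stop("promoter_length shorter than the widest PFM")
  with_seed(cfg$seed + 2L, {
    ids <- sim_gene_ids(cfg)
    p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
           G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
    promoters <- vapply(ids$lncrna, function(g)
      paste(sample(names(p), cfg$promoter_length, replace = TRUE, prob = p),
            collapse = ""), character(1))

    sites <- data.frame(tf_id = character(), gene_id = character(),
                        position = integer(), strand = character(),
                        stringsAsFactors = FALSE)
    if (!is.null(site_requests) && nrow(site_requests)) {
      stopifnot(all(c("tf_id", "gene_id", "strand") %in% names(site_requests)))
      occupied <- lapply(stats::setNames(vector("list", length(promoters)),
                                         names(promoters)), identity)
      for (i in seq_len(nrow(site_requests))) {
        tf <- site_requests$tf_id[i]
        g <- site_requests$gene_id[i]
        strand <- site_requests$strand[i]
        if (is.null(pfms[[tf]])) stop("no PFM for TF ", tf)
        if (!g %in% names(promoters)) stop("unknown promoter gene ", g)
        cons <- pwm_consensus(pfms[[tf]])
        if (strand == "-") cons <- revcomp(cons)
        L <- nchar(cons)
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          pos <- sample.int(cfg$promoter_length - L + 1L, 1L)
          span <- pos:(pos + L - 1L)
          if (!length(intersect(span, occupied[[g]]))) {
            substr(promoters[[g]], pos, pos + L - 1L) <- cons
            occupied[[g]] <- c(occupied[[g]], span)
            sites <- rbind(sites, data.frame(
              tf_id = tf, gene_id = g, position = pos, strand = strand,
              stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place non-overlapping site for TF ", tf,
               " in promoter of ", g)
      }
    }
    list(promoters = promoters, sites = sites)
  })
}

#' Simulate a complete pipeline input bundle with ground truth
#'
#' Composes [simulate_counts()], [simulate_interactome()],
#' [simulate_pfms()] and [simulate_promoters()] into a coherent bundle:
#' feedback circuits are planted by construction, by electing the mRNA of
#' `n_planted_loops` planted triplets as a TF (identity TF-to-gene mapping),
#' assigning it a sharp PFM, and planting that PFM's consensus in the
#' promoter of the triplet's lncRNA. Every planted circuit is therefore
#' recoverable end-to-end: its TFBS edge, sponge pair (evidence >= 3),
#' three-database target pair and force-sensitive target mRNA all survive
#' the pipeline's filters.
#'
#' @param config A [sim_config()].
#' @param pfm_width Width of simulated TF motifs (default 10).
#' @return A list of class `force_sim` with elements `counts`, `lengths`,
#'   `groups`, `contrasts`, `sponge`, `db1`, `db2`, `db3`, `cfs_mirnas`,
#'   `pfms`, `promoters`, `truth` and `config`. `truth` carries
#'   `de_genes_by_contrast`, `fs_genes`, `planted_triplets`, `planted_sites`
#'   and `planted_loops`.
#' @examples
#' sim <- simulate_bundle(sim_config(n_genes = 200, n_lncrna = 12,
#'                                   n_mirna = 9, n_planted_triplets = 6,
#'                                   n_planted_loops = 2, seed = 1))
#' dim(sim$counts)
#' sim$truth$planted_loops
#' @export
simulate_bundle <- function(config = sim_config(), pfm_width = 10) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cnt <- simulate_counts(cfg)
  inter <- simulate_interactome(cfg, cnt$truth)

  nl <- cfg$n_planted_loops
  trips <- inter$truth$planted_triplets
  if (nl > 0) {
    # prefer loop triplets on distinct lncRNAs for a spread-out circuit set
    pick <- with_seed(cfg$seed + 3L, {
      ord <- sample.int(nrow(trips))
      first <- ord[!duplicated(trips$lncrna[ord])]
      if (length(first) >= nl) first[seq_len(nl)]
      else c(first, setdiff(ord, first))[seq_len(nl)]
    })
    loops <- data.frame(tf = trips$mrna[pick], lncrna = trips$lncrna[pick],
                        mirna = trips$mirna[pick], stringsAsFactors = FALSE)
  } else {
    loops <- data.frame(tf = character(), lncrna = character(),
                        mirna = character(), stringsAsFactors = FALSE)
  }

  pfms <- simulate_pfms(unique(loops$tf), width = pfm_width,
                        seed = cfg$seed + 4L)
  site_req <- if (nrow(loops)) {
    data.frame(tf_id = loops$tf, gene_id = loops$lncrna,
               strand = with_seed(cfg$seed + 5L,
                                  sample(c("+", "-"), nrow(loops),
                                         replace = TRUE)),
               stringsAsFactors = FALSE)
  } else NULL
  prom <- simulate_promoters(pfms, cfg, site_req)

  structure(list(
    counts = cnt$counts, lengths = cnt$lengths, groups = cnt$groups,
    contrasts = cnt$contrasts,
    sponge = inter$sponge, db1 = inter$db1, db2 = inter$db2, db3 = inter$db3,
    cfs_mirnas = inter$cfs_mirnas,
    pfms = pfms, promoters = prom$promoters,
    truth = list(de_genes_by_contrast = cnt$truth$de_genes_by_contrast,
                 fs_genes = cnt$truth$fs_genes,
                 planted_triplets = inter$truth$planted_triplets,
                 sponge_pairs = inter$truth$sponge_pairs,
                 target_pairs = inter$truth$target_pairs,
                 planted_sites = prom$sites,
                 planted_loops = loops),
    config = cfg), class = "force_sim")
}

#' @export
print.force_sim <- function(x, ...) {
  cat("force_sim bundle:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", nrow(x$truth$planted_triplets), "planted triplets;",
      nrow(x$truth$planted_loops), "planted circuits\n")
  invisible(x)
}

#' Write a simulation bundle to disk
#'
#' Emits the bundle in the package's plain-text exchange formats: counts and
#' gene lengths as TSV, sample groups as TSV, the four interaction tables as
#' canonical six-column TSVs, promoters as FASTA, motifs in JASPAR PFM text
#' format, the CFS miRNA list as one id per line, and the ground truth as a
#' JSON sidecar.
#'
#' @param sim A `force_sim` bundle from [simulate_bundle()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(sim, outdir) {
  stopifnot(inherits(sim, "force_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  counts_df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, fp("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(sim$lengths),
                                length_bp = unname(sim$lengths)),
                     fp("gene_lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$groups, fp("sample_groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (tb in c("sponge", "db1", "db2", "db3"))
    write_interactions(sim[[tb]], fp(paste0(tb, ".tsv")))
  writeLines(sim$cfs_mirnas, fp("cfs_mirnas.txt"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$promoters),
                              fp("promoters.fasta"))
  write_jaspar(sim$pfms, fp("motifs.jaspar"))
  jsonlite::write_json(sim$truth, fp("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE)
  invisible(outdir)
}
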