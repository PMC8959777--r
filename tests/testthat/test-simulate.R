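small_cfg <- function(...) {
  defaults <- list(n_genes = 300, n_lncrna = 15, n_mirna = 10,
                   n_planted_triplets = 6, n_planted_loops = 2, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg()
  a <- simulate_bundle(cfg)
  b <- simulate_bundle(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$sponge, b$sponge)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_bundle(small_cfg(seed = 12))
  expect_false(identical(a$counts, c2$counts))
})

test_that("count simulation conserves gene structure and planted truth", {
  cfg <- small_cfg()
  cnt <- simulate_counts(cfg)
  expect_equal(nrow(cnt$counts), cfg$n_genes)
  expect_false(anyDuplicated(rownames(cnt$counts)) > 0)
  expect_true(all(cnt$counts >= 0))
  expect_equal(ncol(cnt$counts), 3 * cfg$samples_per_group)
  # planted sets have the configured size and the shared genes agree in sign
  n_de <- round(cfg$planted_de_fraction * cfg$n_genes)
  truth <- cnt$truth$de_genes_by_contrast
  shared <- intersect(names(truth$intermittent), names(truth$static))
  expect_identical(truth$intermittent[shared], truth$static[shared])
  expect_equal(length(unique(c(names(truth$intermittent),
                               names(truth$static)))), n_de)

  null_cfg <- small_cfg(planted_de_fraction = 0)
  null_truth <- simulate_counts(null_cfg)$truth
  expect_length(null_truth$de_genes_by_contrast$intermittent, 0)
  expect_length(null_truth$fs_genes, 0)

  expect_error(sim_config(mean_expression = 0), "positive")
  expect_error(sim_config(mean_expression = -5), "positive")
})

test_that("planted fold changes hit the configured magnitude", {
  # low noise, high mean, >= 1000 planted genes: the empirical case/control
  # mean ratio of up-planted genes must sit within 5% of 2^2 = 4
  cfg <- sim_config(n_genes = 1500, n_lncrna = 10, n_mirna = 5,
                    mean_expression = 1000, dispersion = 0,
                    planted_de_fraction = 0.9, shared_fraction = 1,
                    planted_log2fc = 2, n_planted_triplets = 0,
                    n_planted_loops = 0, seed = 3)
  cnt <- simulate_counts(cfg)
  truth <- cnt$truth$de_genes_by_contrast$intermittent
  expect_gte(length(truth), 1000)
  case <- cnt$counts[, cnt$contrasts$intermittent$case]
  ctrl <- cnt$counts[, cnt$contrasts$intermittent$control]
  up <- names(truth)[truth == "up"]
  down <- names(truth)[truth == "down"]
  ratio_up <- mean(rowMeans(case[up, ]) / rowMeans(ctrl[up, ]))
  ratio_down <- mean(rowMeans(case[down, ]) / rowMeans(ctrl[down, ]))
  expect_equal(ratio_up, 4, tolerance = 0.05)
  expect_equal(ratio_down, 0.25, tolerance = 0.05)
})

test_that("interactome plants recoverable triplets and honest decoys", {
  cfg <- small_cfg()
  inter <- simulate_interactome(cfg, simulate_counts(cfg)$truth)
  expect_equal(nrow(inter$truth$planted_triplets), cfg$n_planted_triplets)
  # every planted lncRNA reaches sponge degree >= 3
  deg <- table(inter$truth$planted_triplets$lncrna)
  expect_true(all(deg >= 3))
  # planted sponge pairs carry high-stringency evidence
  sp_key <- paste(inter$sponge$source_id, inter$sponge$target_id)
  tr_key <- paste(inter$truth$sponge_pairs$lncrna,
                  inter$truth$sponge_pairs$mirna)
  expect_true(all(tr_key %in% sp_key))
  expect_true(all(inter$sponge$evidence_count[sp_key %in% tr_key] >= 3))
  # zero decoys: three-database consensus is exactly the planted target set
  cons <- consensus_targets(inter$db1, inter$db2, inter$db3)
  expect_identical(paste(sort(paste(cons$mirna, cons$mrna))),
                   paste(sort(paste(inter$truth$target_pairs$mirna,
                                    inter$truth$target_pairs$mrna))))

  expect_error(
    simulate_interactome(sim_config(n_genes = 50, n_lncrna = 5, n_mirna = 2,
                                    n_planted_triplets = 3)),
    "degree")
})

test_that("decoy target pairs never survive consensus when db_overlap = 0", {
  cfg <- small_cfg(decoy_pair_rate = 0.05, db_overlap = 0)
  inter <- simulate_interactome(cfg)
  cons <- consensus_targets(inter$db1, inter$db2, inter$db3)
  planted <- paste(inter$truth$target_pairs$mirna,
                   inter$truth$target_pairs$mrna)
  expect_true(all(paste(cons$mirna, cons$mrna) %in% planted))
  # decoys do exist in the raw tables
  expect_gt(nrow(inter$db1) + nrow(inter$db2) + nrow(inter$db3),
            3 * nrow(inter$truth$target_pairs))
  # and sponge decoys sit below the evidence cutoff
  sp_key <- paste(inter$sponge$source_id, inter$sponge$target_id)
  tr_key <- paste(inter$truth$sponge_pairs$lncrna,
                  inter$truth$sponge_pairs$mirna)
  expect_true(all(inter$sponge$evidence_count[!sp_key %in% tr_key] < 3))
})

test_that("promoters carry planted consensus sites at recorded coordinates", {
  cfg <- small_cfg()
  sim <- simulate_bundle(cfg)
  expect_true(all(nchar(sim$promoters) == cfg$promoter_length))
  sites <- sim$truth$planted_sites
  expect_equal(nrow(sites), cfg$n_planted_loops)
  for (i in seq_len(nrow(sites))) {
    pwm <- pfm_to_pwm(sim$pfms[[sites$tf_id[i]]])
    win <- substr(sim$promoters[[sites$gene_id[i]]], sites$position[i],
                  sites$position[i] + pwm$width - 1L)
    if (sites$strand[i] == "-") win <- revcomp(win)
    expect_identical(win, pwm$consensus)
    hits <- scan_sequence(pwm, sim$promoters[[sites$gene_id[i]]])
    hit <- hits[hits$position == sites$position[i] &
                  hits$strand == sites$strand[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$rel_score, 1.0)  # consensus maximizes the PWM score
  }
  expect_error(
    simulate_promoters(list(TF1 = matrix(5, 4, 2000,
                                         dimnames = list(c("A","C","G","T")))),
                       cfg),
    "promoter_length")
})

test_that("a written bundle round-trips through the plain-text readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_bundle(small_cfg())
  write_bundle(sim, dir)
  sponge <- read_interactions(file.path(dir, "sponge.tsv"))
  expect_equal(sponge, sim$sponge)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "promoters.fasta"))
  expect_identical(setNames(as.character(fa), names(fa)), sim$promoters)
  pfms <- read_jaspar(file.path(dir, "motifs.jaspar"))
  expect_identical(names(pfms), names(sim$pfms))
  for (tf in names(pfms))
    expect_equal(unname(pfms[[tf]]), unname(sim$pfms[[tf]]))
  counts <- utils::read.delim(file.path(dir, "counts.tsv"),
                              check.names = FALSE)
  expect_equal(as.matrix(counts[, -1]),
               sim$counts, ignore_attr = TRUE)
})
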