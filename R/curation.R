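#' Load a curated force-sensitive miRNA table
#'
#' Reads the literature-curation TSV (one row per printed miRNA mention)
#' and expands printed family notations into individual records:
#' `"miR-29 family (a,b,c)"` becomes miR-29a/miR-29b/miR-29c and slash
#' notation like `"miR-30b/c/d/e"` (optionally arm-suffixed, e.g.
#' `"miR-466i/f-5p"`) becomes one record per variant letter. Thousand
#' separators inside identifiers (`miR-1,297`) are removed.
#'
#' Required columns: `reference_key, evidence, cell_type, force_type,
#' mirna, osteo_sign`; optional: `included` (yes/no curation screen flag,
#' covering cross-species conservation and evidence reliability),
#' `target_pathways`. Rows with an unknown `osteo_sign` or `evidence` token
#' are rejected with their line number.
#'
#' @param path TSV file path; the packaged transcription ships at
#'   `system.file("extdata", "cfs_mirnas.tsv", package = "forcenet")`.
#' @return data.frame of expanded curation records (one row per miRNA and
#'   study).
#' @export
load_curation_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("reference_key", "evidence", "cell_type", "force_type",
            "mirna", "osteo_sign")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("curation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(tbl)) return(tbl)
  bad <- which(!tbl$osteo_sign %in% c("P", "N"))
  if (length(bad))
    stop("unknown osteo_sign token at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  bad <- which(!tbl$evidence %in% c("functional", "qPCR"))
  if (length(bad))
    stop("unknown evidence token at line(s): ", paste(bad + 1L, collapse = ", "))
  known_force <- c("CTS", "CF", "MG", "FSS", "OTM", "ESW", "other")
  tbl$force_type[!tbl$force_type %in% known_force] <- "other"

  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    ids <- expand_mirna_notation(tbl$mirna[i])
    out <- tbl[rep(i, length(ids)), , drop = FALSE]
    out$mirna <- ids
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Expand printed family / slash notation into individual miRNA ids.
expand_mirna_notation <- function(id) {
  id <- gsub("(\\d),(\\d)", "\\1\\2", trimws(id))  # miR-1,297 -> miR-1297
  fam <- regmatches(id, regexec("^(.*\\S)\\s+family\\s*\\(([^)]*)\\)$", id))[[1]]
  if (length(fam) == 3L) {
    letters_ <- trimws(strsplit(fam[3], ",")[[1]])
    return(paste0(fam[2], letters_))
  }
  if (grepl("/", id, fixed = TRUE)) {
    parts <- strsplit(id, "/", fixed = TRUE)[[1]]
    arm <- ""
    last <- parts[length(parts)]
    m <- regmatches(last, regexec("^(.*?)(-[35]p)$", last))[[1]]
    if (length(m) == 3L) {
      parts[length(parts)] <- m[2]
      arm <- m[3]
    }
    first <- parts[1]
    # the first token carries the shared stem; later tokens are variant letters
    stem_m <- regmatches(first, regexec("^(.*?)([a-z]?)(-[35]p)?$", first))[[1]]
    stem <- stem_m[2]
    first_letter <- stem_m[3]
    if (nzchar(stem_m[4])) arm <- stem_m[4]
    variants <- c(first_letter, parts[-1])
    return(paste0(stem, variants, arm))
  }
  id
}

# Identifier normalization for cross-study identity: strip species
# prefixes and the legacy star notation, resolve renamed ids.
.mirna_aliases <- c("miR-103" = "miR-103a", "miR-122a" = "miR-122")

normalize_mirna_id <- function(id) {
  id <- gsub("(\\d),(\\d)", "\\1\\2", trimws(id))
  id <- sub("^(hsa|mmu|rno)-", "", id)
  id <- sub("\\*$", "", id)
  hit <- match(id, names(.mirna_aliases))
  id[!is.na(hit)] <- .mirna_aliases[hit[!is.na(hit)]]
  id
}

#' Deduplicate curated miRNA records into a unique signed list
#'
#' Collapses the expanded curation records to one entry per miRNA and
#' resolves the osteogenesis sign across studies:
#'
#' * identity: species prefixes (`hsa-`/`mmu-`/`rno-`) and star notation
#'   are stripped, legacy names resolved (miR-103 -> miR-103a,
#'   miR-122a -> miR-122), and an armless id (miR-494) is collapsed onto
#'   its arm-resolved printing (miR-494-3p) when exactly one arm occurs
#'   across studies;
#' * sign precedence: functional evidence outranks qPCR-only; a unanimous
#'   top tier decides, otherwise the majority over all records; residual
#'   ties are flagged (`conflict = TRUE`, sign `NA`) or, under
#'   `strict = TRUE`, raise an error listing the offending rows.
#'
#' @param records Expanded records from [load_curation_table()].
#' @param included_only Honor the `included` curation-screen column when
#'   present (default `TRUE`).
#' @param strict Error on irreconcilable sign conflicts (default `FALSE`).
#' @return data.frame `mirna_id, osteo_sign, n_records, evidence, conflict`
#'   sorted by id, with a `sign_counts` attribute (`table` of P/N).
#' @export
dedupe_mirnas <- function(records, included_only = TRUE, strict = FALSE) {
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  if (included_only && "included" %in% names(rec))
    rec <- rec[tolower(rec$included) %in% c("yes", "y", "true", "1"), ,
               drop = FALSE]
  if (!nrow(rec))
    return(structure(data.frame(mirna_id = character(),
                                osteo_sign = character(),
                                n_records = integer(),
                                evidence = character(),
                                conflict = logical()),
                     sign_counts = table(factor(character(),
                                                levels = c("N", "P")))))
  rec$norm <- normalize_mirna_id(rec$mirna)
  base <- sub("-[35]p$", "", rec$norm)
  # collapse armless printings onto a unique arm-resolved form
  key <- rec$norm
  for (b in unique(base)) {
    members <- which(base == b)
    armed <- unique(rec$norm[members][grepl("-[35]p$", rec$norm[members])])
    if (length(armed) == 1L) key[members] <- armed
  }
  rec$key <- key

  rows <- lapply(split(rec, rec$key), function(grp) {
    tiers <- c(functional = 1L, qPCR = 2L)
    top <- min(tiers[grp$evidence])
    top_signs <- unique(grp$osteo_sign[tiers[grp$evidence] == top])
    if (length(top_signs) == 1L) {
      sign <- top_signs; conflict <- FALSE
    } else {
      tab <- table(grp$osteo_sign)
      if (length(tab) > 1L && tab[1] == tab[2]) {
        sign <- NA_character_; conflict <- TRUE
      } else {
        sign <- names(tab)[which.max(tab)]; conflict <- FALSE
      }
    }
    data.frame(mirna_id = grp$key[1], osteo_sign = sign,
               n_records = nrow(grp),
               evidence = if (top == 1L) "functional" else "qPCR",
               conflict = conflict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  if (strict && any(out$conflict)) {
    bad <- out$mirna_id[out$conflict]
    detail <- vapply(bad, function(id) {
      grp <- rec[rec$key == id, ]
      paste0(id, " [", paste(sprintf("%s:%s(%s)", grp$reference_key,
                                     grp$osteo_sign, grp$evidence),
                             collapse = ", "), "]")
    }, character(1))
    stop("irreconcilable osteo_sign conflict for: ",
         paste(detail, collapse = "; "))
  }
  attr(out, "sign_counts") <- table(factor(out$osteo_sign, levels = c("N", "P")))
  out
}

#' Load curated pathway-lncRNA annotations
#'
#' Reads the pathway-annotation TSV (columns `lncrna_id, pathway,
#' direction, context, reference_key`); unknown direction tokens become
#' `"unknown"`.
#'
#' @param path TSV file path; the packaged transcription ships at
#'   `system.file("extdata", "pathway_lncrna.tsv", package = "forcenet")`.
#' @return data.frame of annotations.
#' @export
load_pathway_annotations <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("lncrna_id", "pathway", "direction", "context", "reference_key")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!nzchar(tbl$lncrna_id)) || any(!nzchar(tbl$pathway)))
    stop("empty lncrna_id or pathway entries")
  tbl$direction[!tbl$direction %in% c("promotes", "inhibits")] <- "unknown"
  tbl
}

#' Bipartite pathway-lncRNA network
#'
#' One `pathway` edge per annotated (lncRNA, pathway) pair; annotations of
#' the same pair from several studies collapse to a single edge whose
#' `references` attribute merges the reference keys (and whose
#' `n_studies` counts them).
#'
#' @param annotations data.frame from [load_pathway_annotations()].
#' @return A [typed_network()] with `lncRNA` and `pathway` nodes.
#' @export
build_pathway_lncrna_network <- function(annotations) {
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!nrow(ann)) return(typed_network())
  key <- paste(ann$lncrna_id, ann$pathway, sep = "\r")
  first <- !duplicated(key)
  refs <- vapply(split(ann$reference_key, key), function(r)
    paste(sort(unique(r)), collapse = ","), character(1))
  nst <- vapply(split(ann$reference_key, key), function(r)
    length(unique(r)), integer(1))
  edges <- data.frame(
    from = ann$lncrna_id[first], to = ann$pathway[first],
    relation = "pathway",
    references = unname(refs[key[first]]),
    n_studies = unname(nst[key[first]]),
    stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(id = sort(unique(ann$lncrna_id)), type = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = sort(unique(ann$pathway)), type = "pathway",
               stringsAsFactors = FALSE))
  typed_network(nodes, edges)
}
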