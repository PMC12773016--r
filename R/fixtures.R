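# Seeded generators for every input the other modules consume, so the
# whole test surface runs offline.  All generators are pure functions of
# their parameters plus the seed (byte-identical reruns) and ship a truth
# sidecar that enables closed-loop tests.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                collapse = "")

#' Synthetic protein sequence database with planted homologs
#'
#' Generates random amino-acid records over the 20-letter alphabet and,
#' for each planted homolog, a query derived from a chosen record's
#' substring by point substitutions at rate `1 - identity` (the exact
#' number of substituted positions is `round((1 - identity) * length)`).
#' The source accession is recorded as ground truth.
#'
#' @param n_records Number of database records.
#' @param length_range Length range `c(min, max)` for records.
#' @param planted_homologs Data frame with columns `identity` (fraction in
#'   `[0, 1]`) and `query_length`, one row per planted query.
#' @param seed Integer seed.
#' @return List with `records` (sequence-record data frame) and `queries`
#'   (data frame: `query`, `identity`, `source_accession`,
#'   `source_gene`).
#' @export
make_sequence_db <- function(n_records = 25L, length_range = c(100L, 200L),
                             planted_homologs = NULL, seed = 1L) {
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(as.integer(seed))
  lens <- sample(length_range[1]:length_range[2], n_records, replace = TRUE)
  seqs <- vapply(lens, .random_aa, "")
  acc <- sprintf("SP%05d", seq_len(n_records))
  records <- sequence_records(
    full_accession = paste0(acc, "-1"), canonical_accession = acc,
    sequence = seqs,
    gene_symbol = sprintf("GENE%d", seq_len(n_records)),
    entrez_id = as.character(10000L + seq_len(n_records)))
  queries <- data.frame(query = character(), identity = numeric(),
                        source_accession = character(),
                        source_gene = character(), stringsAsFactors = FALSE)
  if (!is.null(planted_homologs) && nrow(planted_homologs)) {
    for (i in seq_len(nrow(planted_homologs))) {
      id_frac <- planted_homologs$identity[i]
      qlen <- planted_homologs$query_length[i]
      src <- sample(which(lens >= qlen), 1L)
      start <- sample.int(lens[src] - qlen + 1L, 1L)
      q <- substr(seqs[src], start, start + qlen - 1L)
      n_sub <- round((1 - id_frac) * qlen)
      if (n_sub > 0) {
        pos <- sample.int(qlen, n_sub)
        qc <- strsplit(q, "")[[1]]
        for (p in pos) {
          qc[p] <- sample(setdiff(AA_ALPHABET, qc[p]), 1L)
        }
        q <- paste(qc, collapse = "")
      }
      queries <- rbind(queries, data.frame(
        query = q, identity = id_frac,
        source_accession = records$full_accession[src],
        source_gene = records$gene_symbol[src], stringsAsFactors = FALSE))
    }
  }
  list(records = records, queries = queries)
}

#' Synthetic per-residue protein feature inputs
#'
#' Internally consistent residue-level inputs (pLDDT, polar/apolar SASA,
#' pockets, disorder and MoRF profiles, curated disorder regions, cysteine
#' flags) with known ground truth recorded alongside.
#'
#' @param length Fragment length in residues.
#' @param n_pockets Number of pockets.
#' @param disorder_profile `"all-ordered"`, `"all-disordered"` or
#'   `"mixed"`.
#' @param n_cys_flags Number of flagged cysteines.
#' @param seed Integer seed.
#' @return List of track inputs plus a `truth` list.
#' @export
make_protein_fixture <- function(length = 200L, n_pockets = 3L,
                                 disorder_profile = c("mixed", "all-ordered",
                                                      "all-disordered"),
                                 n_cys_flags = 2L, seed = 1L) {
  disorder_profile <- match.arg(disorder_profile)
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(as.integer(seed))
  plddt <- switch(disorder_profile,
    "all-ordered" = stats::runif(length, 80, 98),
    "all-disordered" = stats::runif(length, 30, 60),
    "mixed" = c(stats::runif(floor(length / 2), 80, 98),
                stats::runif(length - floor(length / 2), 30, 60)))
  polar <- stats::runif(length, 0, 80)
  apolar <- stats::runif(length, 0, 80)
  buried <- sample.int(length, max(1L, length %/% 20))
  polar[buried] <- 0; apolar[buried] <- 0
  pockets <- lapply(seq_len(n_pockets), function(i) {
    start <- sample.int(length - 9L, 1L)
    list(member_residues = start:(start + 9L),
         druggability = stats::runif(1))
  })
  iupred_short <- switch(disorder_profile,
    "all-ordered" = stats::runif(length, 0, 0.3),
    "all-disordered" = stats::runif(length, 0.7, 1),
    "mixed" = c(stats::runif(floor(length / 2), 0, 0.3),
                stats::runif(length - floor(length / 2), 0.7, 1)))
  iupred_long <- pmin(pmax(iupred_short +
                             stats::runif(length, -0.1, 0.1), 0), 1)
  anchor_short <- stats::runif(length, 0, 1)
  anchor_long <- stats::runif(length, 0, 1)
  disprot <- if (disorder_profile == "all-ordered") {
    data.frame(start = integer(), end = integer(), term_name = character(),
               namespace = character(), evidence = character(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  } else {
    n_reg <- 2L
    starts <- sort(sample.int(length - 20L, n_reg))
    data.frame(start = starts, end = pmin(starts + 15L, length),
               term_name = sprintf("disorder region %d", seq_len(n_reg)),
               namespace = "Structural state",
               evidence = sample(c("manual", "ambiguous"), n_reg,
                                 replace = TRUE),
               ambiguous = sample(c(TRUE, FALSE), n_reg, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  cys_pos <- sort(sample.int(length, n_cys_flags))
  cys <- data.frame(position = cys_pos, detected = TRUE,
                    hyperreactive = sample(c(TRUE, FALSE), n_cys_flags,
                                           replace = TRUE),
                    ligandable = sample(c(TRUE, FALSE), n_cys_flags,
                                        replace = TRUE),
                    active_site = FALSE, near_active_site = FALSE,
                    binding_site = FALSE,
                    near_binding_site = sample(c(TRUE, FALSE), n_cys_flags,
                                               replace = TRUE),
                    stringsAsFactors = FALSE)
  cys$neighbors <- lapply(cys$near_binding_site, function(nb)
    if (nb) "ATP pocket" else character())
  list(length = length, plddt = plddt, sasa_polar = polar,
       sasa_apolar = apolar, pockets = pockets,
       iupred_short = iupred_short, iupred_long = iupred_long,
       anchor_short = anchor_short, anchor_long = anchor_long,
       disprot = disprot, cysdb = cys,
       truth = list(disorder_profile = disorder_profile,
                    buried_residues = sort(buried),
                    mean_plddt = mean(plddt)))
}

.id_families <- list(
  rsid = function(i) sprintf("rs%d", 1000 + i * 37),
  ensembl = function(i) sprintf("ENSG%011d", 141510 + i * 13),
  pathway = function(i) sprintf("R-HSA-%d", 100000 + i * 91),
  hgnc = function(i) sprintf("HGNC:%d", 5000 + i * 7))

#' Synthetic grounded corpus with fully valid citations
#'
#' Builds entities whose documents carry identifier-bearing annotation
#' sentences, then statements that quote those sentences with proofs
#' pointing at the exact character spans, so every identifier referenced
#' in a statement occurs verbatim in its proofs.  Ground-truth labels are
#' all `"supported"`; the corpus is the clean control for the verifier and
#' adversary suites.  Identifier vocabularies are drawn from the same
#' regex families the verifier recognizes.
#'
#' @param n_entities Number of entities/documents.
#' @param n_statements Number of statements (cycled over entities).
#' @param seed Integer seed.
#' @return List with `documents`, `manifest`, `answer` (a
#'   `cited_answer`) and `truth` (expected labels).
#' @export
make_grounded_corpus <- function(n_entities = 4L, n_statements = 8L,
                                 seed = 1L) {
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(as.integer(seed))
  fams <- names(.id_families)
  entities <- lapply(seq_len(n_entities), function(i) {
    fam <- fams[1 + (i - 1) %% length(fams)]
    id <- .id_families[[fam]](i)
    score <- round(stats::runif(1, 1, 99), 1)
    ann <- sprintf(
      "The identifier %s is annotated with an evidence score of %s in this record and maps to the catalog entry shown here.",
      id, format(score))
    gg_entity(title = sprintf("Entity %d", i), kind = "gene",
              ids = stats::setNames(id, fam), annotations = ann)
  })
  ser <- serialize_entities(entities)
  statements <- lapply(seq_len(n_statements), function(j) {
    i <- 1 + (j - 1) %% n_entities
    doc_text <- ser$documents$text[i]
    ann <- entities[[i]]$annotations[1]
    start <- regexpr(ann, doc_text, fixed = TRUE)
    span_start <- as.integer(start) - 1L  # to 0-based
    span_end <- span_start + nchar(ann)
    list(text = ann,
         proofs = list(list(doc = ser$documents$index[i],
                            start = span_start, end = span_end,
                            cited_text = NA_character_, text = ann,
                            title = ser$documents$title[i],
                            valid = TRUE, fallback = FALSE)))
  })
  answer <- structure(
    list(statements = statements,
         plain_text = paste(vapply(statements, `[[`, "", "text"),
                            collapse = "\n")),
    class = "cited_answer")
  list(documents = ser$documents, manifest = ser$manifest, answer = answer,
       truth = list(labels = rep("supported", n_statements)))
}

#' Synthetic benchmark fixture tables
#'
#' One table per category with synthetic entities and attribute values,
#' sufficient for one key plus three distinct distractors per question.
#'
#' @param categories Character vector of category names (default: the
#'   bundled template categories).
#' @param rows_per_category Rows per table (must be at least 4).
#' @param seed Integer seed.
#' @return Named list of data frames with columns `entity`, `value`.
#' @export
make_benchmark_tables <- function(categories = names(benchmark_templates()),
                                  rows_per_category = 200L, seed = 1L) {
  if (rows_per_category < 4L)
    stop("rows_per_category must be at least 4 (one key + 3 distractors)")
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(as.integer(seed))
  out <- lapply(seq_along(categories), function(ci) {
    data.frame(
      entity = sprintf("%s_ENT%04d", toupper(substr(categories[ci], 1, 3)),
                       seq_len(rows_per_category)),
      value = sprintf("%s_VAL%04d", toupper(substr(categories[ci], 1, 3)),
                      sample.int(10 * rows_per_category,
                                 rows_per_category)),
      stringsAsFactors = FALSE)
  })
  names(out) <- categories
  out
}
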