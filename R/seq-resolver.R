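# Two-stage amino-acid-sequence-to-gene resolution.
#
# Stage 1 scans every same-length window of each database sequence for the
# best gapless match (per-position identity).  Stage 2 looks candidates up
# in a precomputed overlapping k-mer index and scores them by the fraction
# of shared query k-mers.  Hits from both stages are merged, thresholded,
# de-duplicated per (gene symbol, accession) pair, ranked deterministically
# and trimmed, and surviving gene symbols are turned into gene entities.

#' Construct a sequence record table
#'
#' @param full_accession,canonical_accession,sequence Character vectors.
#' @param gene_symbol,entrez_id Character vectors (`NA` allowed).
#' @return A data frame of sequence records.
#' @export
sequence_records <- function(full_accession, canonical_accession, sequence,
                             gene_symbol = NA_character_,
                             entrez_id = NA_character_) {
  stopifnot(all(nzchar(sequence)), !anyDuplicated(full_accession))
  data.frame(full_accession = full_accession,
             canonical_accession = canonical_accession,
             sequence = toupper(sequence),
             gene_symbol = gene_symbol, entrez_id = entrez_id,
             stringsAsFactors = FALSE)
}

#' Normalize a query sequence
#'
#' Uppercases and strips whitespace, digits and other non-letter characters
#' so FASTA-wrapped or numbered sequence text can be matched directly.
#'
#' @param query Character vector.
#' @return Cleaned character vector.
#' @export
normalize_query <- function(query) {
  toupper(gsub("[^A-Za-z]", "", query))
}

.as_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Build an overlapping k-mer index over sequence records
#'
#' Each record of length `L >= k` contributes all `L - k + 1` overlapping
#' k-mers; postings are sets of accessions (repeat k-mers within one record
#' count once).
#'
#' @param records A sequence-record data frame.
#' @param k K-mer length (default 5).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(records, k = 5L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be a single integer >= 1")
  k <- as.integer(k)
  postings <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(records))) {
    for (km in .as_kmers(records$sequence[i], k)) {
      postings[[km]] <- c(postings[[km]], records$full_accession[i])
    }
  }
  structure(list(k = k, postings = postings,
                 accessions = records$full_accession),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d k-mers over %d records\n",
              x$k, length(ls(x$postings)), length(x$accessions)))
  invisible(x)
}

.empty_hits <- function() {
  data.frame(query = character(), full_accession = character(),
             canonical_accession = character(), gene_symbol = character(),
             entrez_id = character(), similarity_percent = numeric(),
             coverage = numeric(), alignment_length = integer(),
             reference_sequence = character(), stage = character(),
             stringsAsFactors = FALSE)
}

#' Best gapless window match of a query against each record
#'
#' For every record at least as long as the query, slides the query across
#' all same-length windows and reports the best per-position identity
#' fraction as a similarity percentage.  `X` matches nothing, including
#' another `X`.  Coverage is 1 whenever a valid window exists; alignment
#' length equals the query length.  Records shorter than the query yield no
#' hit.
#'
#' @param query An amino-acid string (normalized internally).
#' @param records A sequence-record data frame.
#' @return A hits data frame (stage `"window_scan"`), one row per record
#'   with a valid window, unsorted.
#' @export
substring_window_scan <- function(query, records) {
  query <- normalize_query(query)
  stopifnot(nzchar(query))
  m <- nchar(query)
  q_int <- utf8ToInt(query)
  x_code <- utf8ToInt("X")
  q_ok <- q_int != x_code
  hits <- .empty_hits()
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    L <- nchar(s)
    if (L < m) next
    s_int <- utf8ToInt(s)
    # embed() rows are windows with elements in reverse order
    W <- embed(s_int, m)
    Q <- matrix(rev(q_int), nrow(W), m, byrow = TRUE)
    OK <- matrix(rev(q_ok), nrow(W), m, byrow = TRUE)
    matches <- rowSums((W == Q) & OK)
    best <- max(matches)
    hits <- rbind(hits, data.frame(
      query = query, full_accession = records$full_accession[i],
      canonical_accession = records$canonical_accession[i],
      gene_symbol = records$gene_symbol[i],
      entrez_id = records$entrez_id[i],
      similarity_percent = 100 * best / m,
      coverage = 1, alignment_length = m,
      reference_sequence = s, stage = "window_scan",
      stringsAsFactors = FALSE))
  }
  hits
}

#' Approximate k-mer search against a prebuilt index
#'
#' The query is split into overlapping k-mers (set semantics) and each
#' candidate accession is scored by shared k-mers relative to the total
#' query k-mers.  The ratio defines both the similarity percentage and a
#' heuristic coverage estimate; alignment length is the ratio scaled by the
#' query length (rounded).  Candidates are ranked by shared k-mers and
#' trimmed to `max_candidates`.
#'
#' @param query An amino-acid string.
#' @param records The sequence-record data frame the index was built from.
#' @param index A `kmer_index`.
#' @param max_candidates Candidate list cap before merging (default 50).
#' @return A hits data frame (stage `"kmer"`).  A query shorter than
#'   `index$k` yields an empty result with a warning.
#' @export
kmer_search <- function(query, records, index, max_candidates = 50L) {
  stopifnot(inherits(index, "kmer_index"))
  query <- normalize_query(query)
  qk <- .as_kmers(query, index$k)
  if (!length(qk)) {
    warning("query shorter than k; no k-mer search possible")
    return(.empty_hits())
  }
  found <- unlist(lapply(qk, function(km) index$postings[[km]]),
                  use.names = FALSE)
  if (!length(found)) return(.empty_hits())
  shared <- table(found)
  acc <- names(shared)
  ratio <- as.numeric(shared) / length(qk)
  idx <- match(acc, records$full_accession)
  hits <- data.frame(
    query = query, full_accession = acc,
    canonical_accession = records$canonical_accession[idx],
    gene_symbol = records$gene_symbol[idx],
    entrez_id = records$entrez_id[idx],
    similarity_percent = 100 * ratio,
    coverage = ratio,
    alignment_length = as.integer(round(ratio * nchar(query))),
    reference_sequence = records$sequence[idx], stage = "kmer",
    stringsAsFactors = FALSE)
  ord <- order(-hits$similarity_percent,
               !(!is.na(hits$gene_symbol) & nzchar_na(hits$gene_symbol)),
               hits$canonical_accession, hits$full_accession)
  hits <- hits[ord, , drop = FALSE]
  hits <- utils::head(hits, max_candidates)
  rownames(hits) <- NULL
  hits
}

# nzchar that treats NA as empty
nzchar_na <- function(x) !is.na(x) & nzchar(x)

#' Merge, threshold, de-duplicate and rank hits from both stages
#'
#' Hits below the similarity threshold are dropped; for each (gene symbol,
#' accession) pair only the highest-scoring hit survives.  The merged list
#' is sorted to prefer records with a gene symbol, then by decreasing
#' similarity, canonical accession, and full accession, and trimmed to
#' `per_query_limit` entries.
#'
#' @param stage1,stage2 Hits data frames for the same query (either may be
#'   empty).
#' @param min_similarity_percent Inclusive threshold (default 80).
#' @param per_query_limit Maximum retained hits (default 5).
#' @return A hits data frame in final order.
#' @export
merge_and_rank <- function(stage1, stage2, min_similarity_percent = 80,
                           per_query_limit = 5L) {
  hits <- rbind(stage1, stage2)
  if (!nrow(hits)) return(.empty_hits())
  hits <- hits[hits$similarity_percent >= min_similarity_percent, ,
               drop = FALSE]
  if (!nrow(hits)) return(.empty_hits())
  key <- paste(ifelse(is.na(hits$gene_symbol), "", hits$gene_symbol),
               hits$full_accession, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(hits)), key), function(idx) {
    idx[which.max(hits$similarity_percent[idx])]
  }), use.names = FALSE)
  hits <- hits[keep, , drop = FALSE]
  ord <- order(!nzchar_na(hits$gene_symbol), -hits$similarity_percent,
               hits$canonical_accession, hits$full_accession)
  hits <- utils::head(hits[ord, , drop = FALSE], per_query_limit)
  rownames(hits) <- NULL
  hits
}

#' Resolve amino-acid queries to gene entities
#'
#' Runs both resolution stages for each query, merges and ranks the hits,
#' compiles the unique gene symbols with at least one retained hit, and
#' either reuses an existing gene entity with the same symbol or creates a
#' new one initialized with the accession and any Entrez ID.  Hits without
#' a gene symbol may remain in hit lists but contribute no entity.
#'
#' @param queries Character vector of query sequences.
#' @param records Sequence-record data frame.
#' @param index Optional prebuilt `kmer_index` (built on the fly if `NULL`).
#' @param existing_genes Data frame of existing gene entities with columns
#'   `symbol`, `accession`, `entrez_id` (or `NULL`).
#' @param min_similarity_percent,per_query_limit Passed to
#'   [merge_and_rank()].
#' @return A list with `genes` (updated entity data frame), `hits` (named
#'   list of per-query hit data frames) and `unresolved` (queries with no
#'   retained hit).
#' @export
resolve_to_gene_entities <- function(queries, records, index = NULL,
                                     existing_genes = NULL,
                                     min_similarity_percent = 80,
                                     per_query_limit = 5L) {
  if (is.null(index)) index <- build_kmer_index(records)
  if (is.null(existing_genes))
    existing_genes <- data.frame(symbol = character(),
                                 accession = character(),
                                 entrez_id = character(),
                                 stringsAsFactors = FALSE)
  hits_by_query <- list()
  unresolved <- character()
  genes <- existing_genes
  for (q in queries) {
    qn <- normalize_query(q)
    s1 <- substring_window_scan(qn, records)
    s2 <- if (nchar(qn) >= index$k)
      suppressWarnings(kmer_search(qn, records, index)) else .empty_hits()
    merged <- merge_and_rank(s1, s2, min_similarity_percent, per_query_limit)
    hits_by_query[[qn]] <- merged
    symbols <- unique(merged$gene_symbol[nzchar_na(merged$gene_symbol)])
    if (!length(symbols)) {
      unresolved <- c(unresolved, qn)
      next
    }
    for (sym in symbols) {
      if (sym %in% genes$symbol) next
      row <- merged[nzchar_na(merged$gene_symbol) &
                      merged$gene_symbol == sym, , drop = FALSE][1, ]
      genes <- rbind(genes, data.frame(
        symbol = sym, accession = row$canonical_accession,
        entrez_id = row$entrez_id, stringsAsFactors = FALSE))
    }
  }
  list(genes = genes, hits = hits_by_query, unresolved = unresolved)
}

#' Read a sequence database from FASTA plus sidecar TSV
#'
#' The FASTA headers carry full accessions; the sidecar TSV maps
#' `full_accession` to `canonical_accession`, `gene_symbol` and
#' `entrez_id`.  Uses Biostrings when available, else a plain-text reader.
#'
#' @param fasta Path to an uncompressed amino-acid FASTA file.
#' @param sidecar Path to the TSV sidecar.
#' @return A sequence-record data frame.
#' @export
read_sequence_db <- function(fasta, sidecar) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(fasta)
    seqs <- as.character(aa)
    accs <- sub("\\s.*$", "", names(aa))
  } else {
    lines <- readLines(fasta)
    hdr <- grepl("^>", lines)
    grp <- cumsum(hdr)
    accs <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  }
  side <- utils::read.delim(sidecar, stringsAsFactors = FALSE,
                            colClasses = "character")
  idx <- match(accs, side$full_accession)
  sequence_records(accs, side$canonical_accession[idx], seqs,
                   side$gene_symbol[idx], side$entrez_id[idx])
}

#' Write a sequence database as FASTA plus sidecar TSV
#'
#' @param records Sequence-record data frame.
#' @param fasta,sidecar Output paths.
#' @return Invisibly, the two paths.
#' @export
write_sequence_db <- function(records, fasta, sidecar) {
  wrapped <- vapply(records$sequence, function(s) {
    n <- nchar(s)
    paste(substring(s, seq(1, n, 60), pmin(seq(60, n + 59, 60), n)),
          collapse = "\n")
  }, "")
  writeLines(paste0(">", records$full_accession, "\n", wrapped), fasta)
  utils::write.table(
    records[, c("full_accession", "canonical_accession", "gene_symbol",
                "entrez_id")],
    sidecar, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(c(fasta, sidecar))
}
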