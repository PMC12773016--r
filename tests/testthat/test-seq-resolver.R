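make_recs <- function(seqs, symbols = NULL) {
  n <- length(seqs)
  if (is.null(symbols)) symbols <- sprintf("G%d", seq_len(n))
  sequence_records(sprintf("A%d-1", seq_len(n)), sprintf("A%d", seq_len(n)),
                   seqs, symbols, as.character(seq_len(n)))
}

test_that("k-mer index posts all overlapping k-mers with set semantics", {
  idx <- build_kmer_index(make_recs("MKVLA"), k = 5)
  expect_equal(ls(idx$postings), "MKVLA")
  # record shorter than k contributes nothing
  idx2 <- build_kmer_index(make_recs(c("MKV", "MKVLAG")), k = 5)
  expect_setequal(ls(idx2$postings), c("MKVLA", "KVLAG"))
  expect_equal(idx2$postings[["MKVLA"]], "A2-1")
  # repeats collapse to one posting
  idx3 <- build_kmer_index(make_recs("AAAAAA"), k = 5)
  expect_equal(idx3$postings[["AAAAA"]], "A1-1")
  expect_error(build_kmer_index(make_recs("MKVLA"), k = 0),
               "k")
})

test_that("window scan matches examples and skips short records", {
  recs <- make_recs(c("MMMKVLAGWWW", "SHORT"))
  h <- substring_window_scan("KVLAG", recs)
  expect_equal(h$similarity_percent[h$full_accession == "A1-1"], 100)
  expect_equal(h$coverage, rep(1, nrow(h)))
  expect_equal(h$alignment_length, rep(5L, nrow(h)))
  # query longer than every record
  expect_equal(nrow(substring_window_scan(strrep("M", 50), recs)), 0L)
  # one mismatch in a length-10 query
  recs2 <- make_recs("AAAACDEFGHIKAAAA")
  h2 <- substring_window_scan("CDEFGHIKWA", recs2)  # best window has 2 mism.
  expect_equal(h2$similarity_percent, oracle_window_similarity(
    "CDEFGHIKWA", recs2$sequence[1]))
})

test_that("window-scan similarity equals the brute-force all-windows oracle", {
  set.seed(101)
  for (trial in 1:25) {
    recs <- make_recs(vapply(sample(20:60, 5, replace = TRUE), function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), ""))
    q <- paste(sample(c(AA_ALPHABET, "X"), sample(6:15, 1), replace = TRUE),
               collapse = "")
    h <- substring_window_scan(q, recs)
    for (i in seq_len(nrow(h))) {
      seq_i <- recs$sequence[recs$full_accession == h$full_accession[i]]
      expect_equal(h$similarity_percent[i],
                   oracle_window_similarity(normalize_query(q), seq_i))
    }
  }
})

test_that("k-mer similarity equals the set-intersection oracle", {
  set.seed(202)
  for (trial in 1:25) {
    recs <- make_recs(vapply(sample(20:60, 5, replace = TRUE), function(L)
      paste(sample(AA_ALPHABET[1:6], L, replace = TRUE), collapse = ""), ""))
    idx <- build_kmer_index(recs, k = 5)
    q <- paste(sample(AA_ALPHABET[1:6], sample(8:20, 1), replace = TRUE),
               collapse = "")
    h <- kmer_search(q, recs, idx)
    oracle <- vapply(recs$sequence, function(s)
      oracle_kmer_similarity(q, s, 5L), 0)
    for (i in seq_len(nrow(h))) {
      seq_i <- recs$sequence[recs$full_accession == h$full_accession[i]]
      expect_equal(h$similarity_percent[i], oracle_kmer_similarity(q, seq_i))
    }
    # records sharing no k-mer are absent from the hit list
    absent <- setdiff(recs$full_accession, h$full_accession)
    expect_true(all(oracle[match(absent, recs$full_accession)] == 0))
  }
})

test_that("k-mer search warns and returns empty for queries shorter than k", {
  recs <- make_recs("MKVLAGWKT")
  idx <- build_kmer_index(recs)
  expect_warning(h <- kmer_search("MKV", recs, idx), "shorter than k")
  expect_equal(nrow(h), 0L)
})

test_that("merging thresholds at 80, dedupes pairs and ranks totally", {
  h <- function(acc, sym, sim, stage) data.frame(
    query = "Q", full_accession = acc, canonical_accession = sub("-1", "", acc),
    gene_symbol = sym, entrez_id = "1", similarity_percent = sim,
    coverage = 1, alignment_length = 10L, reference_sequence = "X",
    stage = stage, stringsAsFactors = FALSE)
  # 79.9 is excluded, 80 retained
  m <- merge_and_rank(h("A1-1", "G1", 79.9, "window_scan"),
                      h("A2-1", "G2", 80, "kmer"))
  expect_equal(m$full_accession, "A2-1")
  # same (gene, accession) pair keeps the higher score
  m2 <- merge_and_rank(h("A1-1", "G1", 85, "window_scan"),
                       h("A1-1", "G1", 92, "kmer"))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$similarity_percent, 92)
  expect_equal(m2$stage, "kmer")
  # 7 passing hits trimmed to 5, symbol-bearing first, then similarity
  s1 <- do.call(rbind, lapply(1:7, function(i)
    h(sprintf("A%d-1", i), if (i <= 6) sprintf("G%d", i) else NA_character_,
      80 + i, "kmer")))
  m3 <- merge_and_rank(s1, s1[0, ])
  expect_equal(nrow(m3), 5L)
  expect_true(all(!is.na(m3$gene_symbol)))
  expect_false(is.unsorted(rev(m3$similarity_percent)))
  # rerun gives identical ordering (total order)
  expect_identical(m3, merge_and_rank(s1, s1[0, ]))
})

test_that("exact substring queries resolve at rank 1 with similarity 100", {
  set.seed(303)
  db <- make_sequence_db(20, c(80, 150),
                         data.frame(identity = 1, query_length = 40L),
                         seed = 9)
  res <- resolve_to_gene_entities(db$queries$query, db$records)
  top <- res$hits[[normalize_query(db$queries$query)]][1, ]
  expect_equal(top$full_accession, db$queries$source_accession)
  expect_equal(top$similarity_percent, 100)
})

test_that("gene entities are reused, created and unresolved queries reported", {
  db <- make_sequence_db(15, c(80, 150),
                         data.frame(identity = c(1, 1),
                                    query_length = c(40L, 40L)),
                         seed = 21)
  existing <- data.frame(symbol = db$queries$source_gene[1],
                         accession = "KEEP", entrez_id = "0",
                         stringsAsFactors = FALSE)
  res <- resolve_to_gene_entities(
    c(db$queries$query, strrep("W", 30)), db$records,
    existing_genes = existing)
  # reused entity keeps its original accession
  expect_equal(res$genes$accession[res$genes$symbol ==
                                     db$queries$source_gene[1]], "KEEP")
  expect_true(db$queries$source_gene[2] %in% res$genes$symbol)
  expect_equal(res$unresolved, strrep("W", 30))
})

test_that("FASTA + sidecar round trip preserves the record table", {
  db <- make_sequence_db(6, c(50, 90), seed = 5)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_sequence_db(db$records, fa, tsv)
  back <- read_sequence_db(fa, tsv)
  expect_equal(back$sequence, db$records$sequence)
  expect_equal(back$gene_symbol, db$records$gene_symbol)
  expect_equal(back$canonical_accession, db$records$canonical_accession)
})
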