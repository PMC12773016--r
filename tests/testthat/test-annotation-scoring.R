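mk_terms <- function(labels, prefix = "BP") {
  data.frame(term_id = sprintf("GO:%07d", seq_along(labels)),
             label = paste0(prefix, ": ", labels),
             stringsAsFactors = FALSE)
}

test_that("term embeddings are deterministic means of token vectors", {
  emb_fun <- hashed_embedder(dim = 16)
  terms <- mk_terms(c("kinase", "kinase activity", "kinase"))
  emb <- embed_terms(terms, emb_fun)
  # single-token term equals its token vector
  expect_equal(unname(emb[1, ]), emb_fun("kinase"))
  # two-token term is the midpoint
  expect_equal(unname(emb[2, ]),
               (emb_fun("kinase") + emb_fun("activity")) / 2)
  # identical labels give identical vectors
  expect_equal(unname(emb[3, ]), unname(emb[1, ]))
  expect_error(embed_terms(mk_terms(" ")), "tokens")
})

test_that("FPS selection equals the exhaustive greedy max-min oracle", {
  # all terms returned when the group is at most k
  small <- mk_terms(c("alpha one", "beta two", "gamma three", "delta four"))
  emb <- embed_terms(small)
  expect_setequal(fps_select(emb, small, k = 6), small$term_id)

  # namespace groups are sampled independently and combined
  mixed <- rbind(mk_terms(sprintf("process %d word%d", 1:8, 1:8), "BP"),
                 mk_terms(sprintf("function %d item%d", 1:8, 5:12), "MF"))
  mixed$term_id <- sprintf("GO:%07d", seq_len(nrow(mixed)))
  embm <- embed_terms(mixed)
  sel <- fps_select(embm, mixed, k = 3)
  expect_length(sel, 6L)
  pref <- sub(":.*$", "", mixed$label[match(sel, mixed$term_id)])
  expect_equal(as.integer(table(pref)[c("BP", "MF")]), c(3L, 3L))
  for (grp in c("BP", "MF")) {
    ids <- mixed$term_id[startsWith(mixed$label, grp)]
    expect_equal(intersect(sel, ids),
                 oracle_fps(embm[ids, , drop = FALSE], 3))
  }

  # randomized oracle equivalence without grouping
  set.seed(19)
  vocab <- c("cell", "cycle", "repair", "binding", "transport", "signal",
             "kinase", "membrane", "nuclear", "histone", "lipid", "rna")
  for (trial in 1:20) {
    n <- sample(5:12, 1)
    labs <- vapply(1:n, function(i)
      paste(sample(vocab, sample(1:3, 1)), collapse = " "), "")
    terms <- mk_terms(labs)
    emb <- embed_terms(terms)
    k <- sample(2:4, 1)
    expect_equal(fps_select(emb, terms, k, separate_sampling = FALSE),
                 oracle_fps(emb, k))
  }
})

test_that("Fisher enrichment matches the hypergeometric tail oracle", {
  # the worked 2x2 table: 5 of 10 set genes vs 10 of 990 others
  bg <- sprintf("g%04d", 1:1000)
  set_genes <- bg[1:10]
  term_genes <- c(bg[1:5], bg[101:110])
  ann <- data.frame(gene = term_genes, term_id = "T1", label = "BP: x",
                    namespace = "BP", stringsAsFactors = FALSE)
  res <- fisher_enrichment(set_genes, ann, bg)
  expect_equal(res$p_value, oracle_fisher_p(5, 5, 10, 980),
               tolerance = 1e-10)
  expect_equal(res$in_set_count, 5L)
  expect_equal(res$in_background_count, 15L)

  # randomized tables, background <= 2000
  set.seed(23)
  for (trial in 1:30) {
    N <- sample(50:400, 1)
    bg <- sprintf("g%04d", 1:N)
    s <- sample(5:20, 1)
    set_genes <- sample(bg, s)
    K <- sample(3:30, 1)
    term_genes <- sample(bg, K)
    a <- length(intersect(set_genes, term_genes))
    if (a == 0) next
    ann <- data.frame(gene = term_genes, term_id = "T", label = "BP: y",
                      namespace = "BP", stringsAsFactors = FALSE)
    res <- fisher_enrichment(set_genes, ann, bg)
    oracle <- oracle_fisher_p(a, s - a, K - a, N - s - K + a)
    expect_equal(res$p_value, oracle, tolerance = 1e-10 * oracle)
  }
})

test_that("BH correction selects exactly the largest-prefix set", {
  bg <- sprintf("g%03d", 1:300)
  set_genes <- bg[1:15]
  set.seed(29)
  ann <- do.call(rbind, lapply(1:12, function(t) {
    enriched <- t <= 4
    genes <- if (enriched) c(sample(set_genes, 6), sample(bg[16:300], 4))
             else sample(bg, 15)
    data.frame(gene = genes, term_id = sprintf("T%02d", t),
               label = sprintf("BP: term %d", t), namespace = "BP",
               stringsAsFactors = FALSE)
  }))
  res <- fisher_enrichment(set_genes, ann, bg)
  p <- sort(res$p_value)
  m <- length(p)
  crit <- which(p <= 0.05 * seq_len(m) / m)
  expected_sig <- if (length(crit)) p <= p[max(crit)] else rep(FALSE, m)
  expect_equal(sum(res$significant), sum(expected_sig))
  # q-values are monotone in p-rank and never below p
  ord <- order(res$p_value)
  expect_false(is.unsorted(res$q_value[ord]))
  expect_true(all(res$q_value >= res$p_value))
  # terms with no set genes are not tested
  expect_true(all(res$in_set_count >= 1L))
  expect_error(fisher_enrichment("g001", ann, character()), "empty")
})

test_that("potency summaries keep the strongest value per type with pChEMBL", {
  recs <- data.frame(
    assay_type = c("IC50", "IC50", "Ki", "EC50", "IC50"),
    value = c(38, 120, 1000, 55, -5),
    compound_id = c("CHEMBL601757", "C2", "C3", "C4", "C5"),
    stringsAsFactors = FALSE)
  s <- summarize_potency(recs)
  ic50 <- s[s$assay_type == "IC50", ]
  expect_equal(ic50$strongest_nM, 38)
  expect_equal(ic50$compound_id, "CHEMBL601757")
  expect_equal(ic50$pchembl_2dp, 7.42)
  expect_equal(s$pchembl_2dp[s$assay_type == "Ki"], 6.00)
  # nonpositive values never survive
  expect_false("C5" %in% s$compound_id)
  expect_equal(round(pchembl(39), 2), 7.41)
  # singleton passthrough
  one <- summarize_potency(data.frame(assay_type = "Ki", value = 7,
                                      compound_id = "X"))
  expect_equal(one$strongest_nM, 7)
  expect_equal(nrow(summarize_potency(NULL)), 0L)
})

test_that("drug-target scoring filters species, sums counts and keeps top 5", {
  rows <- do.call(rbind, c(
    lapply(1:3, function(i) data.frame(
      drug = "drugA", gene_symbol = "ABL1", accession = "P00519",
      is_moa = i == 1, species = "human", stringsAsFactors = FALSE)),
    list(data.frame(drug = "drugA",
                    gene_symbol = sprintf("T%d", 1:7),
                    accession = sprintf("P%05d", 1:7),
                    is_moa = FALSE, species = "human",
                    stringsAsFactors = FALSE)),
    list(data.frame(drug = "drugA", gene_symbol = "MouseOnly",
                    accession = "Q1", is_moa = TRUE, species = "mouse",
                    stringsAsFactors = FALSE))))
  sc <- score_drug_targets(rows)
  expect_false("MouseOnly" %in% sc$gene_symbol)
  abl <- sc[sc$gene_symbol == "ABL1", ]
  expect_equal(abl$activity_count, 3L)
  expect_equal(abl$moa_count, 1L)
  expect_equal(abl$score, 4L)
  expect_equal(nrow(sc), 5L)          # 8 scored genes trimmed to 5
  expect_equal(sc$gene_symbol[1], "ABL1")
  # deterministic total order: ties break lexicographically
  expect_identical(sc, score_drug_targets(rows))
  expect_equal(sc$gene_symbol[2:5], c("T1", "T2", "T3", "T4"))
})
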