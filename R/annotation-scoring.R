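# Gene-annotation summarization and drug-evidence scoring.
#
# GO-term summarization embeds each term as the mean of its token vectors
# and picks a diverse subset with greedy farthest-point sampling in cosine
# space, independently within each namespace group.  Enrichment uses a
# one-sided Fisher test with Benjamini-Hochberg correction.  Drug evidence
# is normalized to nM potencies with pChEMBL, and target evidence is the
# sum of activity and mechanism-of-action counts.

# Deterministic token hash (polynomial, modulus < 2^31 so doubles are
# exact), used to seed a Lehmer stream per token.
.token_hash <- function(token) {
  codes <- utf8ToInt(token)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483629
  h
}

#' Deterministic hashed-projection token embedder
#'
#' Returns an embedder function mapping a token to a fixed pseudo-random
#' vector in `[-1, 1]^dim`, derived from a Lehmer stream seeded by a hash
#' of the token (and the embedder seed).  Identical tokens always map to
#' identical vectors with no RNG state involved, so embeddings are
#' reproducible without a training corpus.  A trained skip-gram embedder
#' can be plugged in through the same interface.
#'
#' @param dim Embedding dimension (default 64).
#' @param seed Integer mixed into the token hash.
#' @return A function `token -> numeric(dim)`.
#' @export
hashed_embedder <- function(dim = 64L, seed = 1L) {
  m <- 2147483647  # Lehmer modulus 2^31 - 1
  force(dim); force(seed)
  function(token) {
    x <- (.token_hash(tolower(token)) + seed * 7919) %% (m - 1) + 1
    out <- numeric(dim)
    for (j in seq_len(dim)) {
      x <- (48271 * x) %% m
      out[j] <- 2 * x / (m - 1) - 1
    }
    out
  }
}

.tokenize_label <- function(label) {
  toks <- tolower(unlist(regmatches(
    label, gregexpr("[A-Za-z0-9]+", label, perl = TRUE))))
  toks[nzchar(toks)]
}

#' Embed GO terms as mean token vectors
#'
#' Each term label is tokenized and embedded as the arithmetic mean of its
#' token vectors.  Identical labels yield identical vectors.
#'
#' @param terms Data frame with columns `term_id` and `label` (labels
#'   carry a namespace prefix before a colon, e.g. `"BP: histone
#'   acetylation"`).
#' @param embedder Token-vector function, default [hashed_embedder()].
#' @return A numeric matrix, one row per term, rownames = `term_id`.
#' @export
embed_terms <- function(terms, embedder = hashed_embedder()) {
  stopifnot(nrow(terms) > 0)
  vecs <- lapply(terms$label, function(lab) {
    toks <- .tokenize_label(sub("^[^:]*:", "", lab))
    if (!length(toks)) stop("term label has no tokens: ", lab)
    rowMeans(vapply(toks, embedder, embedder(toks[1])))
  })
  mat <- do.call(rbind, vecs)
  rownames(mat) <- terms$term_id
  mat
}

.cosine_dist <- function(a, B) {
  # distance from vector a to each row of B; per-pair scalar products keep
  # the summation order stable so equal inputs give bit-equal distances
  na <- sqrt(sum(a^2))
  sim <- vapply(seq_len(nrow(B)), function(i) {
    b <- B[i, ]
    sum(a * b) / (na * sqrt(sum(b^2)))
  }, 0)
  sim[!is.finite(sim)] <- 0
  1 - sim
}

.fps_group <- function(emb, k) {
  ids <- rownames(emb)
  n <- nrow(emb)
  if (n <= k) return(sort(ids))
  centroid <- colMeans(emb)
  d0 <- .cosine_dist(centroid, emb)
  start <- order(-d0, ids)[1]
  selected <- start
  mind <- .cosine_dist(emb[start, ], emb)
  while (length(selected) < k) {
    cand <- setdiff(seq_len(n), selected)
    best <- cand[order(-mind[cand], ids[cand])[1]]
    selected <- c(selected, best)
    mind <- pmin(mind, .cosine_dist(emb[best, ], emb))
  }
  ids[selected]
}

#' Farthest-point sampling of diverse terms
#'
#' Greedy max-min selection under cosine distance.  The start point is the
#' term farthest from the group centroid (ties broken by lexicographic
#' term ID); each subsequent pick maximizes the minimum cosine distance to
#' the already-selected set.  With `separate_sampling`, terms are first
#' grouped by the label prefix before the colon, FPS runs independently
#' per group, and the selections are combined.  Groups with at most `k`
#' terms are returned whole.
#'
#' @param embeddings Matrix from [embed_terms()] (rownames = term IDs).
#' @param terms The term data frame the embeddings came from.
#' @param k Number of terms per group (default 6).
#' @param separate_sampling Group by namespace prefix first (default TRUE).
#' @return Character vector of selected term IDs (selection order within
#'   group).
#' @export
fps_select <- function(embeddings, terms, k = 6L, separate_sampling = TRUE) {
  stopifnot(k >= 1)
  if (separate_sampling) {
    prefix <- sub(":.*$", "", terms$label)
    groups <- split(terms$term_id, prefix)
    out <- lapply(groups[order(names(groups))], function(ids)
      .fps_group(embeddings[ids, , drop = FALSE], k))
    unlist(out, use.names = FALSE)
  } else {
    .fps_group(embeddings, k)
  }
}

#' Fisher enrichment of terms in a gene set
#'
#' For every term with at least one gene in the set, a one-sided
#' (enrichment) Fisher exact test on the 2x2 table of set membership
#' versus term annotation over the background, run separately per
#' namespace with Benjamini-Hochberg correction within each namespace.
#'
#' @param gene_set Character vector of genes (must lie in `background`).
#' @param annotations Data frame with columns `gene`, `term_id`, `label`,
#'   `namespace`.
#' @param background Character vector of background genes.
#' @param fdr Significance cutoff on the BH q-value (default 0.05).
#' @return Data frame of enrichment results: `term_id`, `label`,
#'   `namespace`, `in_set_count`, `set_size`, `in_background_count`,
#'   `background_size`, `p_value`, `q_value`, `significant`.
#' @export
fisher_enrichment <- function(gene_set, annotations, background,
                              fdr = 0.05) {
  if (!length(background)) stop("background gene set is empty")
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of background")
  gene_set <- unique(gene_set)
  background <- unique(background)
  annotations <- annotations[annotations$gene %in% background, , drop = FALSE]
  out <- lapply(split(annotations, annotations$namespace), function(ann) {
    terms <- unique(ann[, c("term_id", "label", "namespace")])
    rows <- lapply(seq_len(nrow(terms)), function(i) {
      genes_t <- unique(ann$gene[ann$term_id == terms$term_id[i]])
      a <- length(intersect(gene_set, genes_t))
      if (a == 0L) return(NULL)
      b <- length(gene_set) - a
      c_ <- length(genes_t) - a
      d <- length(background) - a - b - c_
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                     byrow = TRUE),
                              alternative = "greater")$p.value
      data.frame(term_id = terms$term_id[i], label = terms$label[i],
                 namespace = terms$namespace[i], in_set_count = a,
                 set_size = length(gene_set), in_background_count = a + c_,
                 background_size = length(background), p_value = p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    if (is.null(res)) return(NULL)
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$q_value <= fdr
    res[order(res$p_value, res$term_id), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(term_id = character(), label = character(),
                      namespace = character(), in_set_count = integer(),
                      set_size = integer(), in_background_count = integer(),
                      background_size = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' pChEMBL from a potency in nM
#'
#' Negative log10 of the molar potency: 38 nM gives 7.42 (at two
#' decimals).
#'
#' @param value_nM Positive potency values in nM.
#' @return Numeric pChEMBL values (full precision).
#' @export
pchembl <- function(value_nM) {
  stopifnot(all(value_nM > 0))
  -log10(value_nM * 1e-9)
}

#' Summarize assay potencies per type
#'
#' Restricted to positive IC50, Ki and EC50 values in nM; per assay type
#' the strongest (lowest) potency is retained and accompanied by its
#' pChEMBL (reported at two decimals, full precision retained).
#'
#' @param records Data frame with columns `assay_type` (one of `IC50`,
#'   `Ki`, `EC50`), `value` (nM) and `compound_id`.
#' @return Data frame with one row per assay type present: `assay_type`,
#'   `strongest_nM`, `compound_id`, `pchembl`, `pchembl_2dp`.
#' @export
summarize_potency <- function(records) {
  empty <- data.frame(assay_type = character(), strongest_nM = numeric(),
                      compound_id = character(), pchembl = numeric(),
                      pchembl_2dp = numeric(), stringsAsFactors = FALSE)
  if (is.null(records) || !nrow(records)) return(empty)
  records <- records[records$assay_type %in% c("IC50", "Ki", "EC50") &
                       !is.na(records$value) & records$value > 0, ,
                     drop = FALSE]
  if (!nrow(records)) return(empty)
  out <- lapply(split(records, records$assay_type, drop = TRUE),
                function(grp) {
    i <- which.min(grp$value)
    data.frame(assay_type = grp$assay_type[i], strongest_nM = grp$value[i],
               compound_id = grp$compound_id[i],
               pchembl = pchembl(grp$value[i]),
               pchembl_2dp = round(pchembl(grp$value[i]), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score and rank drug targets by activity evidence
#'
#' Only human rows are retained; rows referring to the same gene-protein
#' pair are aggregated, counting total activities and those labeled as
#' mechanism-of-action.  The evidence score is the sum of the two counts.
#' Targets are ranked per drug by score descending (ties by gene symbol)
#' and the top `top_n` are retained.
#'
#' @param rows Data frame with columns `drug`, `gene_symbol`, `accession`,
#'   `is_moa` (logical), `species`.
#' @param top_n Retained targets per drug (default 5).
#' @return Data frame: `drug`, `gene_symbol`, `accession`,
#'   `activity_count`, `moa_count`, `score`, in final rank order.
#' @export
score_drug_targets <- function(rows, top_n = 5L) {
  empty <- data.frame(drug = character(), gene_symbol = character(),
                      accession = character(), activity_count = integer(),
                      moa_count = integer(), score = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(rows) || !nrow(rows)) return(empty)
  human <- tolower(rows$species) %in% c("human", "homo sapiens")
  rows <- rows[human, , drop = FALSE]
  if (!nrow(rows)) return(empty)
  key <- paste(rows$drug, rows$gene_symbol, rows$accession, sep = "\r")
  agg <- lapply(split(seq_len(nrow(rows)), key), function(idx) {
    data.frame(drug = rows$drug[idx[1]],
               gene_symbol = rows$gene_symbol[idx[1]],
               accession = rows$accession[idx[1]],
               activity_count = length(idx),
               moa_count = sum(rows$is_moa[idx] %in% TRUE),
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, agg)
  agg$score <- agg$activity_count + agg$moa_count
  out <- lapply(split(agg, agg$drug), function(grp) {
    grp <- grp[order(-grp$score, grp$gene_symbol), , drop = FALSE]
    utils::head(grp, top_n)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}
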