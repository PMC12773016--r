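# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

# best gapless window identity (percent) of query against one sequence;
# X matches nothing, including another X
oracle_window_similarity <- function(query, seq) {
  m <- nchar(query); L <- nchar(seq)
  if (L < m) return(NA_real_)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  best <- 0
  for (off in 0:(L - m)) {
    hits <- 0
    for (j in 1:m) {
      a <- qc[j]; b <- sc[off + j]
      if (a == b && a != "X") hits <- hits + 1
    }
    if (hits > best) best <- hits
  }
  100 * best / m
}

# shared-k-mer ratio (percent) between query and one sequence, set semantics
oracle_kmer_similarity <- function(query, seq, k = 5L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    out <- character(0)
    for (i in 1:(n - k + 1)) out <- c(out, substr(s, i, i + k - 1))
    unique(out)
  }
  qk <- kmers(query)
  if (!length(qk)) return(NA_real_)
  100 * length(intersect(qk, kmers(seq))) / length(qk)
}

# exhaustive greedy max-min FPS in cosine space with the centroid-farthest
# start rule and lexicographic tie-breaks
oracle_fps <- function(emb, k) {
  ids <- rownames(emb)
  n <- nrow(emb)
  if (n <= k) return(sort(ids))
  cosd <- function(a, b) {
    s <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    if (!is.finite(s)) s <- 0
    1 - s
  }
  centroid <- colMeans(emb)
  d0 <- numeric(n)
  for (i in 1:n) d0[i] <- cosd(centroid, emb[i, ])
  ord <- order(-d0, ids)
  sel <- ord[1]
  while (length(sel) < k) {
    best_i <- NA; best_d <- -Inf
    for (i in setdiff(1:n, sel)) {
      mind <- Inf
      for (s in sel) mind <- min(mind, cosd(emb[i, ], emb[s, ]))
      if (mind > best_d ||
          (mind == best_d && ids[i] < ids[best_i])) {
        best_d <- mind; best_i <- i
      }
    }
    sel <- c(sel, best_i)
  }
  ids[sel]
}

# one-sided (enrichment) Fisher p-value by explicit hypergeometric tail sum
oracle_fisher_p <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  K <- a + c_       # annotated genes
  s <- a + b        # set size
  p <- 0
  for (x in a:min(K, s)) {
    p <- p + choose(K, x) * choose(n - K, s - x) / choose(n, s)
  }
  p
}

# exhaustive run scan for segment metrics
oracle_segment_metrics <- function(track, threshold = 0.5, min_len = 5L) {
  n <- length(track)
  runs <- integer(0)
  cur <- 0L
  for (i in 1:n) {
    if (track[i] >= threshold) cur <- cur + 1L
    else { if (cur > 0L) runs <- c(runs, cur); cur <- 0L }
  }
  if (cur > 0L) runs <- c(runs, cur)
  qual <- runs[runs >= min_len]
  list(min = min(track), max = max(track), mean = mean(track),
       fraction_above = sum(track >= threshold) / n,
       n_segments = length(qual),
       longest_segment = if (length(qual)) max(qual) else 0L)
}

# small drug library used across entity tests
test_drug_library <- function() {
  drug_library(data.frame(
    name = c("imatinib", "dasatinib", "vemurafenib", "aspirin"),
    synonyms = c("gleevec|STI-571", "", "PLX4032", "acetylsalicylic acid"),
    chembl_id = c("CHEMBL941", "CHEMBL1421", "CHEMBL1229517", "CHEMBL25"),
    drugcentral_id = c("1344", "783", "2806", "74"),
    cas = c("152459-95-5", "302962-49-8", "918504-65-1", "50-78-2"),
    stringsAsFactors = FALSE))
}
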