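# Pattern-based extraction of biomedical entity mentions.
#
# These are the deterministic members of an entity-recognition ensemble:
# regular expressions for dbSNP rsIDs, genomic coordinate variants
# (chr:pos ref>alt), Ensembl gene/transcript/protein IDs and miRNA names,
# plus a fuzzy scanner over a drug-name library with explicit external-ID
# parsing.  Spans are 0-based, half-open, relative to the input text.

#' Built-in entity mention patterns
#'
#' @details Pattern dialects follow public conventions:
#' * rsID: `rs` followed by 1--12 digits.
#' * Genomic coordinate: optional `chr` prefix, chromosome 1--22/X/Y/MT,
#'   `:`, a 1-based position, a separator, then `REF>ALT` with alleles over
#'   `ACGT`.
#' * Ensembl: `ENSG`/`ENST`/`ENSP` followed by 11 digits.
#' * miRNA: optional three-letter species prefix, `miR`/`let`/`lin` stem
#'   (case-insensitive), a hyphenated number with optional letter suffix,
#'   and an optional `-3p`/`-5p` arm.
#' @keywords internal
.entity_patterns <- function() {
  list(
    variant_coord = list(
      regex = "(?:chr)?(2[0-2]|1[0-9]|[1-9]|X|Y|MT):(\\d+)[ _:]?([ACGT]+)>([ACGT]+)",
      entity_kind = "variant", id_system = "coordinate",
      case_insensitive = FALSE),
    rsid = list(
      regex = "\\brs\\d{1,12}\\b",
      entity_kind = "variant", id_system = "rsid",
      case_insensitive = FALSE),
    ensembl = list(
      regex = "\\bENS(?:G|T|P)\\d{11}\\b",
      entity_kind = "gene", id_system = "ensembl",
      case_insensitive = FALSE),
    mirna = list(
      regex = "\\b(?:[a-z]{3}-)?(?:miR|let|lin)-\\d+[a-z]*(?:-[35]p)?\\b",
      entity_kind = "mirna", id_system = "mirna_name",
      case_insensitive = TRUE)
  )
}

.empty_mentions <- function() {
  data.frame(surface_text = character(), start = integer(), end = integer(),
             entity_kind = character(), normalized_id = character(),
             id_system = character(), stringsAsFactors = FALSE)
}

#' Extract pattern-based entity mentions from text
#'
#' Scans plain text for rsIDs, genomic coordinate variants, Ensembl IDs and
#' miRNA names.  Matches are returned exactly once, non-overlapping and
#' sorted by span start; where two patterns would overlap, the longer match
#' wins (then the earlier start).
#'
#' @param text A single character string (may be empty).
#' @return A data frame of mentions with columns `surface_text`, `start`,
#'   `end` (0-based, half-open), `entity_kind`, `normalized_id`,
#'   `id_system`, and for coordinate variants `chrom`, `pos`, `ref`, `alt`.
#'   Positions in coordinate mentions are 1-based as printed in the text.
#' @examples
#' extract_pattern_entities("rs334 causes sickle cell")
#' extract_pattern_entities("variant chr7:117559590 G>A")
#' @export
extract_pattern_entities <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- .empty_mentions()
  out$chrom <- character(); out$pos <- numeric()
  out$ref <- character(); out$alt <- character()
  if (is.na(text) || !nzchar(text)) return(out)

  rows <- list()
  for (pname in names(.entity_patterns())) {
    p <- .entity_patterns()[[pname]]
    m <- gregexpr(p$regex, text, perl = TRUE,
                  ignore.case = p$case_insensitive)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      surface <- substr(text, m[i], m[i] + lens[i] - 1L)
      row <- list(surface_text = surface,
                  start = m[i] - 1L, end = m[i] + lens[i] - 1L,
                  entity_kind = p$entity_kind,
                  normalized_id = surface, id_system = p$id_system,
                  chrom = NA_character_, pos = NA_real_,
                  ref = NA_character_, alt = NA_character_)
      if (pname == "mirna") row$normalized_id <- .canonical_mirna_case(surface)
      if (pname == "variant_coord") {
        g <- regmatches(surface, regexec(p$regex, surface, perl = TRUE))[[1]]
        row$chrom <- g[2]; row$pos <- as.numeric(g[3])
        row$ref <- g[4]; row$alt <- g[5]
        row$normalized_id <- sprintf("chr%s:%s %s>%s", g[2], g[3], g[4], g[5])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) return(out)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  # resolve overlaps: prefer longer matches, then earlier start
  df <- df[order(df$start, -(df$end - df$start)), , drop = FALSE]
  keep <- logical(nrow(df)); last_end <- -1L
  prio <- order(-(df$end - df$start), df$start)
  taken <- rep(FALSE, nrow(df))
  for (i in prio) {
    ok <- TRUE
    for (j in which(taken)) {
      if (df$start[i] < df$end[j] && df$end[i] > df$start[j]) { ok <- FALSE; break }
    }
    taken[i] <- ok
  }
  df <- df[taken, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Normalizes stem capitalization: "mir" stems become "miR" while preserving
# species prefix and suffixes; "let"/"lin" stay lower-case.
.canonical_mirna_case <- function(name) {
  sub("(?i)\\bmir(?=-)", "miR", sub("(?i)\\blet(?=-)", "let",
      sub("(?i)\\blin(?=-)", "lin", name, perl = TRUE), perl = TRUE),
      perl = TRUE)
}

#' Test whether a name looks like a miRNA
#'
#' A name is classified as a miRNA when it contains any of the substrings
#' `mir`, `let` or `lin`, compared case-insensitively.
#'
#' @param name Character vector of entity names.
#' @return Logical vector.
#' @examples
#' is_mirna_name(c("hsa-let-7a", "TP53", "lin-4"))
#' @export
is_mirna_name <- function(name) {
  stopifnot(is.character(name))
  grepl("mir|let|lin", tolower(name), fixed = FALSE)
}

# miRNA grouping key: species prefix and arm suffix stripped, case folded,
# so "miR-21", "hsa-miR-21" and "hsa-miR-21-5p" share one key.
.mirna_group_key <- function(name) {
  x <- tolower(name)
  x <- sub("^[a-z]{3}-(?=(mir|let|lin)-)", "", x, perl = TRUE)
  x <- sub("-[35]p$", "", x)
  x
}

# Specificity score used to pick the canonical miRNA alias.
.mirna_specificity <- function(name) {
  has_prefix <- grepl("^[a-z]{3}-(miR|mir|let|lin)-", name, perl = TRUE)
  has_arm <- grepl("-[35]p$", name)
  as.integer(has_prefix) + as.integer(has_arm)
}

#' Consolidate entity mentions from multiple extractors
#'
#' Combines, normalizes and de-duplicates mentions so that each distinct
#' biological object appears once.  Among miRNA aliases referring to the
#' same molecule, the most specific name (species prefix and arm suffix
#' present) is retained as canonical.
#'
#' @param mentions A mentions data frame (as from
#'   [extract_pattern_entities()] or [scan_drug_library()]), possibly
#'   concatenated across extractors.
#' @return A data frame with one row per entity: `entity_kind`,
#'   `canonical_name`, `normalized_id`, `id_system`, `n_mentions`.
#' @export
consolidate_mentions <- function(mentions) {
  empty <- data.frame(entity_kind = character(), canonical_name = character(),
                      normalized_id = character(), id_system = character(),
                      n_mentions = integer(), stringsAsFactors = FALSE)
  if (is.null(mentions) || !nrow(mentions)) return(empty)
  key <- ifelse(mentions$entity_kind == "mirna",
                paste0("mirna|", .mirna_group_key(mentions$normalized_id)),
                paste0(mentions$entity_kind, "|",
                       tolower(mentions$normalized_id)))
  out <- lapply(split(seq_len(nrow(mentions)), key), function(idx) {
    grp <- mentions[idx, , drop = FALSE]
    if (grp$entity_kind[1] == "mirna") {
      sc <- .mirna_specificity(grp$normalized_id)
      best <- order(-sc, -nchar(grp$normalized_id), grp$normalized_id)[1]
    } else {
      best <- order(-nchar(grp$normalized_id), grp$normalized_id)[1]
    }
    data.frame(entity_kind = grp$entity_kind[1],
               canonical_name = grp$normalized_id[best],
               normalized_id = grp$normalized_id[best],
               id_system = grp$id_system[best],
               n_mentions = nrow(grp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$entity_kind, out$canonical_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a drug library from TSV
#'
#' Expected columns: `name`, `synonyms` (pipe-separated, may be empty),
#' `chembl_id`, `drugcentral_id`, `cas`.  Lookup downstream is
#' case-insensitive.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `drug_library` object.
#' @export
read_drug_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  drug_library(df)
}

#' Construct a drug library
#'
#' @param entries Data frame with columns `name`, `synonyms`
#'   (pipe-separated), `chembl_id`, `drugcentral_id`, `cas`.
#' @return A `drug_library` object: one row per searchable name (primary
#'   names and synonyms expanded) plus the external-ID columns.
#' @export
drug_library <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) > 0, all(nzchar(entries$name)))
  for (col in c("synonyms", "chembl_id", "drugcentral_id", "cas"))
    if (is.null(entries[[col]])) entries[[col]] <- ""
  expanded <- lapply(seq_len(nrow(entries)), function(i) {
    syn <- entries$synonyms[i]
    nm <- c(entries$name[i],
            if (nzchar(syn)) strsplit(syn, "|", fixed = TRUE)[[1]])
    nm <- nm[nzchar(nm)]
    data.frame(search_name = nm, primary_name = entries$name[i],
               chembl_id = entries$chembl_id[i],
               drugcentral_id = entries$drugcentral_id[i],
               cas = entries$cas[i], stringsAsFactors = FALSE)
  })
  lib <- do.call(rbind, expanded)
  structure(list(names = lib, entries = entries), class = "drug_library")
}

#' Normalized indel similarity between two strings
#'
#' `1 - d / (nchar(a) + nchar(b))` where `d` is the insertion/deletion edit
#' distance (substitutions cost 2, i.e. are not allowed as single edits).
#' Comparison is case-insensitive.
#'
#' @param a,b Character vectors (recycled).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
indel_similarity <- function(a, b) {
  a <- tolower(a); b <- tolower(b)
  n <- max(length(a), length(b))
  ia <- rep_len(seq_along(a), n); ib <- rep_len(seq_along(b), n)
  D <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))
  d <- D[cbind(ia, ib)]
  tot <- nchar(a)[ia] + nchar(b)[ib]
  ifelse(tot == 0, 1, 1 - d / tot)
}

#' Scan text for drug-library mentions
#'
#' Finds fuzzy matches of library names in the text scoring at least
#' `min_similarity` under normalized indel similarity, plus all exact
#' external-ID matches (`CHEMBL` IDs always; DrugCentral IDs and CAS
#' numbers listed in the library).  When several library entries match a
#' token equally well, the longer matched name wins, then the
#' lexicographically smaller.
#'
#' @param text A character string.
#' @param library A `drug_library`.
#' @param min_similarity Minimum normalized indel similarity for fuzzy name
#'   matches (default 0.9, recall-biased).
#' @return A mentions data frame (columns as in
#'   [extract_pattern_entities()]) plus `matched_entry` (the primary
#'   library name, or `NA` for IDs not in the library) and `similarity`.
#' @export
scan_drug_library <- function(text, library, min_similarity = 0.9) {
  stopifnot(inherits(library, "drug_library"), length(text) == 1L)
  out <- .empty_mentions()
  out$matched_entry <- character(); out$similarity <- numeric()
  if (is.na(text) || !nzchar(text)) return(out)

  rows <- list()
  # explicit external-ID parsing
  m <- gregexpr("\\bCHEMBL\\d+\\b", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      id <- substr(text, m[i], m[i] + lens[i] - 1L)
      hit <- library$names$primary_name[
        toupper(library$names$chembl_id) == toupper(id)]
      rows[[length(rows) + 1L]] <- list(
        surface_text = id, start = m[i] - 1L, end = m[i] + lens[i] - 1L,
        entity_kind = "drug", normalized_id = id, id_system = "chembl",
        matched_entry = if (length(hit)) hit[1] else NA_character_,
        similarity = 1)
    }
  }
  for (col in c("drugcentral_id", "cas")) {
    ids <- unique(library$names[[col]])
    ids <- ids[nzchar(ids)]
    for (id in ids) {
      m <- gregexpr(paste0("\\b", gsub("([][{}()+*^$|\\\\?.-])",
                                       "\\\\\\1", id), "\\b"),
                    text, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      lens <- attr(m, "match.length")
      hit <- library$names$primary_name[library$names[[col]] == id][1]
      for (i in seq_along(m)) {
        rows[[length(rows) + 1L]] <- list(
          surface_text = id, start = m[i] - 1L, end = m[i] + lens[i] - 1L,
          entity_kind = "drug", normalized_id = id,
          id_system = if (col == "cas") "drugcentral" else "drugcentral",
          matched_entry = hit, similarity = 1)
      }
    }
  }

  # fuzzy name scan over word tokens and short phrases
  toks <- gregexpr("[A-Za-z][A-Za-z0-9'-]*", text, perl = TRUE)[[1]]
  if (toks[1] != -1L) {
    tlens <- attr(toks, "match.length")
    max_words <- max(lengths(strsplit(library$names$search_name, "\\s+")))
    n_tok <- length(toks)
    for (i in seq_len(n_tok)) {
      for (w in seq_len(min(max_words, n_tok - i + 1L))) {
        s0 <- toks[i]; e0 <- toks[i + w - 1L] + tlens[i + w - 1L] - 1L
        cand <- substr(text, s0, e0)
        if (grepl("\n", cand, fixed = TRUE)) next
        sims <- indel_similarity(cand, library$names$search_name)
        best <- max(sims)
        if (best >= min_similarity) {
          ties <- which(sims == best)
          nm <- library$names$search_name[ties]
          pick <- ties[order(-nchar(nm), nm)[1]]
          rows[[length(rows) + 1L]] <- list(
            surface_text = cand, start = s0 - 1L, end = e0,
            entity_kind = "drug",
            normalized_id = library$names$primary_name[pick],
            id_system = "symbol",
            matched_entry = library$names$primary_name[pick],
            similarity = best)
        }
      }
    }
  }
  if (!length(rows)) return(out)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  # non-overlapping: prefer higher similarity, then longer span
  prio <- order(-df$similarity, -(df$end - df$start), df$start)
  taken <- rep(FALSE, nrow(df))
  for (i in prio) {
    ok <- TRUE
    for (j in which(taken))
      if (df$start[i] < df$end[j] && df$end[i] > df$start[j]) { ok <- FALSE; break }
    taken[i] <- ok
  }
  df <- df[taken, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
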