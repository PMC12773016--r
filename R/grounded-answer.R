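# Entity-to-document serialization, budgeted context truncation, and
# reconstruction of statement-level proofs from inline citation markers.
#
# Documents are indexed 0..n-1; a manifest maps titles to indices both
# ways.  Citation markers use a neutral inline syntax,
#   [[doc=<index> start=<s> end=<e>]]  or  [[doc=<index> text="..."]]
# with 0-based half-open character spans, so any answer generator (human,
# template, or model) can emit verifiable citations.

#' Elision sentinel inserted where document middles are condensed
#'
#' A fixed line so downstream consumers can detect truncation and never
#' treat elided text as evidence.
#' @export
ELISION_MARKER <- "\n<<ELIDED>>\n"

#' Construct an entity for serialization
#'
#' @param title Unique display title (e.g. a gene symbol).
#' @param kind Entity kind string.
#' @param ids Named character vector of identifiers.
#' @param annotations Character vector of free-text tool annotations.
#' @return A `gg_entity` list.
#' @export
gg_entity <- function(title, kind, ids = character(), annotations = character()) {
  stopifnot(nzchar(title))
  structure(list(title = title, kind = kind, ids = ids,
                 annotations = annotations), class = "gg_entity")
}

#' Serialize entities into documents plus a citation manifest
#'
#' Produces exactly one document per entity: the core fields and
#' identifiers are rendered as text (IDs listed explicitly) and every tool
#' annotation is appended verbatim.  The manifest is a bijection between
#' document titles and dense 0-based indices.
#'
#' @param entities A list of [gg_entity()] objects with unique titles.
#' @return A list with `documents` (data frame: `index`, `title`, `text`)
#'   and `manifest` (named integer vector, title -> index).
#' @export
serialize_entities <- function(entities) {
  stopifnot(is.list(entities))
  titles <- vapply(entities, function(e) e$title, "")
  if (anyDuplicated(titles)) stop("entity titles must be unique")
  texts <- vapply(entities, function(e) {
    id_txt <- if (length(e$ids))
      paste(sprintf("%s=%s", names(e$ids), e$ids), collapse = "; ")
    else "none"
    paste(c(sprintf("Entity: %s", e$title),
            sprintf("Kind: %s", e$kind),
            sprintf("IDs: %s", id_txt),
            if (length(e$annotations)) c("", e$annotations)),
          collapse = "\n")
  }, "")
  documents <- data.frame(index = seq_along(entities) - 1L,
                          title = titles, text = texts,
                          stringsAsFactors = FALSE)
  manifest <- stats::setNames(documents$index, documents$title)
  list(documents = documents, manifest = manifest)
}

.shrink_one <- function(text, target) {
  marker <- ELISION_MARKER
  target <- max(0L, as.integer(target))
  if (nchar(text) <= target) return(text)
  head_len <- floor(0.7 * target)
  tail_len <- target - head_len
  paste0(substr(text, 1L, head_len), marker,
         if (tail_len > 0) substr(text, nchar(text) - tail_len + 1L,
                                  nchar(text)) else "")
}

#' Shorten documents to recover a required amount of context
#'
#' On attempt 1 only the longest document is shortened: the leading 70% and
#' trailing 30% of the target length are kept verbatim with an elision
#' marker between.  On attempt 2 the two longest documents are targeted
#' with an enlarged reduction margin (1.5 times the attempt-1 target).
#' At most two attempts are permitted.
#'
#' @param documents A documents data frame (`index`, `title`, `text`).
#' @param required_reduction Characters that must be removed in total; 0 or
#'   less is a no-op.
#' @param attempt 1 or 2.
#' @return The documents data frame with shortened text.
#' @export
shrink_context <- function(documents, required_reduction, attempt = 1L) {
  if (!attempt %in% c(1L, 2L))
    stop("maximum of 2 shrink attempts; attempt must be 1 or 2")
  if (required_reduction <= 0) return(documents)
  marker_len <- nchar(ELISION_MARKER)
  lens <- nchar(documents$text)
  if (attempt == 1L) {
    i <- which.max(lens)
    target <- lens[i] - required_reduction - marker_len
    documents$text[i] <- .shrink_one(documents$text[i], target)
  } else {
    goal <- ceiling(1.5 * required_reduction)
    ord <- order(-lens)[seq_len(min(2L, nrow(documents)))]
    share <- lens[ord] / sum(lens[ord])
    for (j in seq_along(ord)) {
      i <- ord[j]
      cut <- ceiling(goal * share[j])
      target <- lens[i] - cut - marker_len
      documents$text[i] <- .shrink_one(documents$text[i], target)
    }
  }
  documents
}

#' Fit documents under a total character budget
#'
#' Applies [shrink_context()] up to twice; if the total still exceeds the
#' budget after the second attempt, fails hard rather than truncating
#' silently a third time.
#'
#' @param documents Documents data frame.
#' @param budget Total character budget across document texts.
#' @return Documents data frame within budget.
#' @export
enforce_context_budget <- function(documents, budget) {
  for (attempt in 1:2) {
    total <- sum(nchar(documents$text))
    if (total <= budget) return(documents)
    documents <- shrink_context(documents, total - budget, attempt)
  }
  if (sum(nchar(documents$text)) > budget)
    stop("context still over budget after 2 shrink attempts")
  documents
}

.citation_marker_re <-
  "\\[\\[doc=(\\d+)(?:\\s+start=(\\d+)\\s+end=(\\d+))?(?:\\s+text=\"([^\"]*)\")?\\]\\]"

#' Reconstruct statement-level proofs from an annotated response
#'
#' The raw response contains one statement per line with inline citation
#' markers.  Each marker's span is sliced out of the named document; when
#' the span is missing or invalid the marker's own `text` attribute is used
#' as a fallback and the proof is flagged.  A marker naming a document
#' index outside the manifest is flagged invalid (and consumed downstream
#' by the verifier).
#'
#' @param raw_response Character string with embedded citation markers.
#' @param documents Documents data frame.
#' @param manifest Named integer vector (title -> index).
#' @return A `cited_answer`: list with `statements` (each a list of `text`
#'   and `proofs`) and `plain_text` (statements joined with newlines).
#' @export
reconstruct_citations <- function(raw_response, documents, manifest) {
  lines <- strsplit(raw_response, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  statements <- lapply(lines, function(line) {
    m <- gregexpr(.citation_marker_re, line, perl = TRUE)[[1]]
    proofs <- list()
    if (m[1] != -1L) {
      marks <- regmatches(line, list(m))[[1]]
      for (mk in marks) {
        g <- regmatches(mk, regexec(.citation_marker_re, mk, perl = TRUE))[[1]]
        doc <- as.integer(g[2])
        start <- if (nzchar(g[3])) as.integer(g[3]) else NA_integer_
        end <- if (nzchar(g[4])) as.integer(g[4]) else NA_integer_
        cited_text <- if (nzchar(g[5])) g[5] else NA_character_
        valid_doc <- doc %in% documents$index
        text <- NA_character_; fallback <- FALSE
        title <- if (valid_doc)
          documents$title[documents$index == doc] else NA_character_
        if (valid_doc && !is.na(start) && !is.na(end)) {
          dtext <- documents$text[documents$index == doc]
          if (start >= 0 && end <= nchar(dtext) && start < end) {
            text <- substr(dtext, start + 1L, end)  # 0-based half-open
          }
        }
        if (is.na(text) && !is.na(cited_text)) {
          text <- cited_text
          fallback <- TRUE
        }
        proofs[[length(proofs) + 1L]] <- list(
          doc = doc, start = start, end = end, cited_text = cited_text,
          text = text, title = title, valid = valid_doc,
          fallback = fallback)
      }
    }
    stmt_text <- trimws(gsub(.citation_marker_re, "", line, perl = TRUE))
    stmt_text <- gsub("\\s+", " ", stmt_text)
    list(text = stmt_text, proofs = proofs)
  })
  plain_text <- paste(vapply(statements, `[[`, "", "text"), collapse = "\n")
  structure(list(statements = statements, plain_text = plain_text),
            class = "cited_answer")
}

#' @export
print.cited_answer <- function(x, ...) {
  cat(sprintf("<cited_answer> %d statement(s), %d proof(s)\n",
              length(x$statements),
              sum(vapply(x$statements, function(s) length(s$proofs), 0L))))
  invisible(x)
}

#' Write an evidence bundle to JSON
#'
#' The bundle carries documents, the manifest, and the cited answer in the
#' schema consumed by [read_evidence_bundle()] and the verifier.
#'
#' @param documents Documents data frame.
#' @param manifest Named integer vector.
#' @param answer A `cited_answer` (or `NULL`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evidence_bundle <- function(documents, manifest, answer, path) {
  stmts <- if (is.null(answer)) list() else lapply(answer$statements,
    function(s) list(
      text = s$text,
      proofs = lapply(s$proofs, function(p) list(
        doc = p$doc, start = p$start, end = p$end,
        cited_text = p$cited_text))))
  obj <- list(
    documents = lapply(seq_len(nrow(documents)), function(i) list(
      index = documents$index[i], title = documents$title[i],
      text = documents$text[i])),
    manifest = as.list(manifest),
    answer = list(statements = stmts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an evidence bundle from JSON
#'
#' @param path Path to a bundle written by [write_evidence_bundle()].
#' @return A list with `documents`, `manifest` and `answer` (a
#'   `cited_answer`).
#' @export
read_evidence_bundle <- function(path) {
  obj <- jsonlite::read_json(path)
  documents <- do.call(rbind, lapply(obj$documents, function(d)
    data.frame(index = as.integer(d$index), title = d$title, text = d$text,
               stringsAsFactors = FALSE)))
  if (is.null(documents))
    documents <- data.frame(index = integer(), title = character(),
                            text = character(), stringsAsFactors = FALSE)
  manifest <- stats::setNames(as.integer(unlist(obj$manifest)),
                              names(obj$manifest))
  statements <- lapply(obj$answer$statements, function(s) {
    proofs <- lapply(s$proofs, function(p) {
      doc <- as.integer(p$doc)
      start <- if (is.null(p$start)) NA_integer_ else as.integer(p$start)
      end <- if (is.null(p$end)) NA_integer_ else as.integer(p$end)
      cited_text <- if (is.null(p$cited_text)) NA_character_ else p$cited_text
      valid_doc <- doc %in% documents$index
      text <- NA_character_; fallback <- FALSE
      if (valid_doc && !is.na(start) && !is.na(end)) {
        dtext <- documents$text[documents$index == doc]
        if (start >= 0 && end <= nchar(dtext) && start < end)
          text <- substr(dtext, start + 1L, end)
      }
      if (is.na(text) && !is.na(cited_text)) { text <- cited_text; fallback <- TRUE }
      list(doc = doc, start = start, end = end, cited_text = cited_text,
           text = text,
           title = if (valid_doc) documents$title[documents$index == doc]
                   else NA_character_,
           valid = valid_doc, fallback = fallback)
    })
    list(text = s$text, proofs = proofs)
  })
  answer <- structure(
    list(statements = statements,
         plain_text = paste(vapply(statements, `[[`, "", "text"),
                            collapse = "\n")),
    class = "cited_answer")
  list(documents = documents, manifest = manifest, answer = answer)
}
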