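# Statement-level verification of a cited answer against its evidence.
#
# Two ensemble members judge every statement: a deterministic check
# (citation validity plus identifier grounding in the cited proof text) and
# a pluggable qualitative reviewer (the bundled default is rule-based
# lexical overlap plus numeric grounding).  Only one member needs to fail
# for a statement to be downgraded.  An answer fails outright when 30% or
# more of its statements are unsupported, regardless of the overall
# judgment.

.verdict_labels <- c("supported", "speculation_ok", "partial",
                     "speculation_overreach", "unsupported")

# severity order: supported < speculation_ok < partial <
# speculation_overreach ~ unsupported (the last two tie)
.label_rank <- c(supported = 1, speculation_ok = 2, partial = 3,
                 speculation_overreach = 4, unsupported = 4)

.identifier_patterns <- function(pathway_registry = "R-HSA-\\d+") {
  c(rsid = "\\brs\\d{1,12}\\b",
    ensembl = "\\bENS(?:G|T|P)\\d{11}\\b",
    pathway = pathway_registry,
    hgnc = "\\bHGNC:\\d+\\b",
    mgi = "\\bMGI:\\d+\\b",
    rgd = "\\bRGD:\\d+\\b")
}

#' Extract typed identifiers from text
#'
#' Finds rsIDs, Ensembl IDs, pathway IDs (Reactome `R-HSA-` by default; the
#' registry is extensible) and HGNC/MGI/RGD IDs, typed and de-duplicated.
#'
#' @param text Character string.
#' @param pathway_registry Regex alternation for recognized pathway ID
#'   schemes.
#' @return Data frame with columns `id` and `type`.
#' @export
extract_identifiers <- function(text, pathway_registry = "R-HSA-\\d+") {
  pats <- .identifier_patterns(pathway_registry)
  rows <- lapply(names(pats), function(ty) {
    m <- gregexpr(pats[[ty]], text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(id = regmatches(text, list(m))[[1]], type = ty,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(id = character(), type = character(),
                      stringsAsFactors = FALSE))
  out <- out[!duplicated(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.proof_texts <- function(proofs) {
  txt <- vapply(proofs, function(p)
    if (is.null(p$text) || is.na(p$text)) "" else p$text, "")
  txt[nzchar(txt)]
}

#' Deterministic statement check
#'
#' Flags bad or missing document indices and detects identifiers referenced
#' in the statement that are absent from the concatenated proof texts.
#' All identifiers present with valid citations gives `supported`; a mix of
#' present and absent identifiers gives `partial`; no proofs, no valid
#' citations, or all referenced identifiers absent gives `unsupported`.
#'
#' @param statement Statement text.
#' @param proofs List of proofs (as in a `cited_answer`).
#' @param documents Documents data frame (used to validate indices when
#'   proofs carry raw indices).
#' @return A `statement_verdict`: list with `label` and `issues` (each
#'   issue a list with `type` and optional detail fields).
#' @export
deterministic_check <- function(statement, proofs, documents) {
  issues <- list()
  if (!length(proofs)) {
    issues[[1]] <- list(type = "missing_proofs")
    return(structure(list(label = "unsupported", issues = issues),
                     class = "statement_verdict"))
  }
  valid <- vapply(proofs, function(p) {
    v <- if (!is.null(p$valid)) isTRUE(p$valid) else
      as.integer(p$doc) %in% documents$index
    v
  }, TRUE)
  for (i in which(!valid))
    issues[[length(issues) + 1L]] <- list(type = "bad_doc_index",
                                          doc = proofs[[i]]$doc)
  evidence <- paste(.proof_texts(proofs[valid]), collapse = "\n")
  ids <- extract_identifiers(statement)
  label <-
    if (!any(valid)) "unsupported"
    else if (!nrow(ids)) { if (all(valid)) "supported" else "partial" }
    else {
      present <- vapply(ids$id, function(id)
        grepl(id, evidence, fixed = TRUE), TRUE)
      for (id in ids$id[!present])
        issues[[length(issues) + 1L]] <- list(type = "identifier_absent",
                                              id = id)
      if (all(present) && all(valid)) "supported"
      else if (any(present)) "partial"
      else "unsupported"
    }
  structure(list(label = label, issues = issues),
            class = "statement_verdict")
}

#' Combine the two ensemble verdicts for one statement
#'
#' The final label is the worse of the two on the severity order
#' supported < speculation_ok < partial < speculation_overreach ~
#' unsupported; issues are unioned.  When the two labels tie at the worst
#' level but differ, `unsupported` is returned (commutative).
#'
#' @param deterministic,qualitative `statement_verdict` objects.
#' @return A `statement_verdict` with the final label.
#' @export
combine_ensemble <- function(deterministic, qualitative) {
  rd <- .label_rank[[deterministic$label]]
  rq <- .label_rank[[qualitative$label]]
  label <- if (rd > rq) deterministic$label
           else if (rq > rd) qualitative$label
           else if (deterministic$label == qualitative$label)
             deterministic$label
           else "unsupported"
  structure(list(label = label,
                 issues = c(deterministic$issues, qualitative$issues)),
            class = "statement_verdict")
}

#' Judge the whole answer
#'
#' The unsupported fraction is the number of `unsupported` statement labels
#' over the number of statements, compared with 30% in exact integer
#' arithmetic (`10 * n_unsupported >= 3 * n` fails, so 3 of 10 fails).
#' `speculation_ok` and `speculation_overreach` do not count as
#' unsupported.  An answer passes only when the overall quality judgment is
#' a pass and the fraction is below the threshold.  An empty statement list
#' fails with concern `"no content"`.
#'
#' @param labels Character vector of final statement labels.
#' @param overall_pass Logical overall judgment from the reviewer.
#' @param concerns Character vector of reviewer concerns to retain.
#' @return An `answer_verdict`: list with `passed`, `unsupported_fraction`,
#'   `labels`, `concerns`.
#' @export
judge_answer <- function(labels, overall_pass = TRUE,
                         concerns = character()) {
  n <- length(labels)
  if (!n) {
    return(structure(list(passed = FALSE, unsupported_fraction = NA_real_,
                          labels = labels,
                          concerns = c(concerns, "no content")),
                     class = "answer_verdict"))
  }
  n_uns <- sum(labels == "unsupported")
  over_threshold <- (10L * n_uns) >= (3L * n)
  structure(list(passed = isTRUE(overall_pass) && !over_threshold,
                 unsupported_fraction = n_uns / n,
                 labels = labels, concerns = concerns),
            class = "answer_verdict")
}

.stopwords <- c("the", "a", "an", "and", "or", "of", "in", "on", "to",
                "is", "are", "was", "were", "with", "for", "by", "as",
                "that", "this", "it", "its", "at", "from", "be")

.content_tokens <- function(text) {
  toks <- tolower(unlist(regmatches(
    text, gregexpr("[A-Za-z][A-Za-z0-9-]{2,}", text, perl = TRUE))))
  setdiff(toks, .stopwords)
}

.numbers_in <- function(text) {
  unlist(regmatches(text,
    gregexpr("(?<![A-Za-z0-9.])\\d+(?:\\.\\d+)?(?![A-Za-z0-9])", text,
             perl = TRUE)))
}

#' Speculative-language markers
#'
#' Word stems treated as hedging; configurable wherever they are consumed.
#' @export
SPECULATIVE_MARKERS <- c("may", "might", "could", "possibly", "suggests",
                         "potentially", "hypothes")

.is_speculative <- function(text) {
  any(vapply(SPECULATIVE_MARKERS, function(m)
    grepl(paste0("\\b", m), tolower(text), perl = TRUE), TRUE))
}

#' Bundled rule-based qualitative reviewer
#'
#' Scores each statement by lexical overlap of its content words with the
#' union of its proof texts and additionally requires every number in the
#' statement to appear in the proofs.  Hedged statements with some support
#' are labeled `speculation_ok`.  Returns the structured review contract:
#' per-statement labels, an ordinal `support_quality` (high/medium/low) and
#' concerns.
#'
#' @param answer A `cited_answer`.
#' @param documents Documents data frame (unused by the lexical rules but
#'   part of the reviewer contract).
#' @return A review list: `statements` (list of `statement_verdict`),
#'   `support_quality`, `overall_pass`, `concerns`.
#' @export
rule_based_reviewer <- function(answer, documents) {
  verdicts <- lapply(answer$statements, function(s) {
    ev <- paste(.proof_texts(s$proofs), collapse = "\n")
    toks <- .content_tokens(s$text)
    overlap <- if (!length(toks)) 1 else {
      ev_toks <- .content_tokens(ev)
      mean(toks %in% ev_toks)
    }
    nums <- .numbers_in(s$text)
    nums_ok <- !length(nums) ||
      all(vapply(nums, function(x) grepl(x, ev, fixed = TRUE), TRUE))
    issues <- list()
    if (!nums_ok)
      issues[[1]] <- list(type = "qualitative",
                          reason = "number not found in proofs")
    spec <- .is_speculative(s$text)
    label <-
      if (overlap >= 0.7 && nums_ok) { if (spec) "speculation_ok" else "supported" }
      else if (overlap > 0.2 || (length(nums) && nums_ok))
        { if (spec) "speculation_ok" else "partial" }
      else "unsupported"
    if (label %in% c("partial", "unsupported") && !length(issues))
      issues[[1]] <- list(type = "qualitative",
                          reason = sprintf("content overlap %.2f", overlap))
    structure(list(label = label, issues = issues),
              class = "statement_verdict")
  })
  labels <- vapply(verdicts, `[[`, "", "label")
  quality <- if (all(labels %in% c("supported", "speculation_ok"))) "high"
             else if (any(labels == "unsupported")) "low" else "medium"
  list(statements = verdicts, support_quality = quality,
       overall_pass = quality != "low",
       concerns = character())
}

#' No-context reviewer (document-access ablation)
#'
#' Judges statements without any access to documents or proofs: it can
#' only flag explicit negations and universal quantifiers as potential
#' overreach.  Numeric and identifier corruption is invisible to it, which
#' is the point of the ablation.
#'
#' @param answer A `cited_answer`.
#' @param documents Ignored.
#' @return A review list in the reviewer contract.
#' @export
no_context_reviewer <- function(answer, documents = NULL) {
  cues <- c("\\ball\\b", "\\balways\\b", "\\bnever\\b", "\\bevery\\b",
            "\\bcompletely\\b", "\\buniversally\\b", "\\bnot\\b",
            "\\bno\\b")
  verdicts <- lapply(answer$statements, function(s) {
    hit <- any(vapply(cues, function(p) grepl(p, tolower(s$text), perl = TRUE),
                      TRUE))
    structure(list(
      label = if (hit) "speculation_overreach" else "supported",
      issues = if (hit) list(list(type = "qualitative",
                                  reason = "absolute or negated claim"))
               else list()),
      class = "statement_verdict")
  })
  labels <- vapply(verdicts, `[[`, "", "label")
  list(statements = verdicts,
       support_quality = if (any(labels != "supported")) "medium" else "high",
       overall_pass = TRUE, concerns = character())
}

.validate_review <- function(review, n_statements) {
  ok <- is.list(review) && length(review$statements) == n_statements &&
    all(vapply(review$statements, function(v)
      is.list(v) && v$label %in% .verdict_labels, TRUE)) &&
    review$support_quality %in% c("high", "medium", "low") &&
    is.logical(review$overall_pass)
  if (!ok) stop("reviewer output violates the review schema")
  review
}

#' Run the qualitative review through a pluggable reviewer
#'
#' @param answer A `cited_answer`.
#' @param documents Documents data frame.
#' @param reviewer A function `(answer, documents) -> review list`; the
#'   bundled default is [rule_based_reviewer()].  Output is validated
#'   against the review schema.
#' @return The validated review.
#' @export
qualitative_review <- function(answer, documents,
                               reviewer = rule_based_reviewer) {
  .validate_review(reviewer(answer, documents), length(answer$statements))
}

#' Verify a cited answer against its evidence
#'
#' Runs the deterministic check and the qualitative reviewer on every
#' statement, combines them with [combine_ensemble()] and judges the
#' answer with [judge_answer()].  With `context_aware = FALSE` the
#' deterministic evidence checks are disabled and the
#' [no_context_reviewer()] is used, emulating a verifier with no document
#' access.
#'
#' @param answer A `cited_answer`.
#' @param documents Documents data frame.
#' @param reviewer Qualitative reviewer function (default rule-based).
#' @param context_aware Whether the verifier may read documents and proofs.
#' @return An `answer_verdict` with per-statement details in
#'   `$statement_verdicts`.
#' @export
verify_answer <- function(answer, documents,
                          reviewer = rule_based_reviewer,
                          context_aware = TRUE) {
  if (!context_aware) {
    review <- qualitative_review(answer, NULL, no_context_reviewer)
    finals <- review$statements
  } else {
    review <- qualitative_review(answer, documents, reviewer)
    finals <- lapply(seq_along(answer$statements), function(i) {
      s <- answer$statements[[i]]
      det <- deterministic_check(s$text, s$proofs, documents)
      combine_ensemble(det, review$statements[[i]])
    })
  }
  labels <- vapply(finals, `[[`, "", "label")
  verdict <- judge_answer(labels, review$overall_pass, review$concerns)
  verdict$statement_verdicts <- finals
  verdict$support_quality <- review$support_quality
  verdict
}

#' Verify an evidence bundle file
#'
#' @param path Path to an evidence-bundle JSON file.
#' @param reviewer `"rule"`, `"none"` (deterministic only, qualitative
#'   member always passes), or a reviewer function.
#' @return An `answer_verdict`.
#' @export
verify_bundle <- function(path, reviewer = "rule") {
  bundle <- read_evidence_bundle(path)
  rev_fun <- if (is.function(reviewer)) reviewer
    else switch(reviewer,
      rule = rule_based_reviewer,
      none = function(answer, documents) {
        n <- length(answer$statements)
        list(statements = replicate(n, structure(
               list(label = "supported", issues = list()),
               class = "statement_verdict"), simplify = FALSE),
             support_quality = "high", overall_pass = TRUE,
             concerns = character())
      },
      stop("unknown reviewer: ", reviewer))
  verify_answer(bundle$answer, bundle$documents, rev_fun)
}

#' @export
print.answer_verdict <- function(x, ...) {
  cat(sprintf("<answer_verdict> %s; unsupported %.0f%% of %d statement(s)\n",
              if (isTRUE(x$passed)) "PASS" else "FAIL",
              100 * x$unsupported_fraction, length(x$labels)))
  invisible(x)
}
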