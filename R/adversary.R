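# Controlled corruption of grounded answers to stress-test the verifier.
#
# Candidate statements are filtered (non-empty proofs, non-speculative
# language, minimum length, mode-specific content), up to three candidate
# indices are sampled, and a pluggable generator produces the corrupted
# statement; the default generator is rule-based so the whole evaluation
# is deterministic and model-free.  Every perturbation is logged with
# enough detail to reverse it.

.perturbation_modes <- c("contradiction", "overstatement", "numeric",
                         "alphanumeric")

# mixed alphanumeric tokens (identifier-like): letters and digits in one
# token, e.g. rs334, ENSG00000141510, R-HSA-109582
.alnum_token_re <- "\\b(?=[A-Za-z0-9:-]*[A-Za-z])(?=[A-Za-z0-9:-]*\\d)[A-Za-z][A-Za-z0-9:-]*\\b"

.mask_identifiers <- function(text) {
  toks <- gregexpr(.alnum_token_re, text, perl = TRUE)[[1]]
  if (toks[1] == -1L) return(text)
  lens <- attr(toks, "match.length")
  for (i in seq_along(toks)) {
    substr(text, toks[i], toks[i] + lens[i] - 1L) <-
      strrep("#", lens[i])
  }
  text
}

#' Filter statements eligible for perturbation
#'
#' Keeps statements with at least one proof, without speculative markers
#' (see [SPECULATIVE_MARKERS]) and at least `min_length` characters long.
#' Numeric mode additionally requires a digit outside identifier-like
#' tokens; alphanumeric mode requires a mixed alphanumeric token.
#'
#' @param answer A `cited_answer`.
#' @param mode One of `"contradiction"`, `"overstatement"`, `"numeric"`,
#'   `"alphanumeric"`, or `NULL` for the base filter only.
#' @param min_length Minimum statement length in characters (default 40).
#' @return Integer vector of eligible statement indices.
#' @export
filter_candidates <- function(answer, mode = NULL, min_length = 40L) {
  if (!is.null(mode)) mode <- match.arg(mode, .perturbation_modes)
  ok <- vapply(answer$statements, function(s) {
    if (!length(s$proofs)) return(FALSE)
    if (.is_speculative(s$text)) return(FALSE)
    if (nchar(s$text) < min_length) return(FALSE)
    if (identical(mode, "numeric")) {
      masked <- .mask_identifiers(s$text)
      if (!grepl("\\d", masked)) return(FALSE)
    }
    if (identical(mode, "alphanumeric")) {
      if (!grepl(.alnum_token_re, s$text, perl = TRUE)) return(FALSE)
    }
    TRUE
  }, TRUE)
  which(ok)
}

.mutate_digit <- function(token, rng_digit) {
  # replace one digit with a different digit at a pseudo-random position
  digits <- gregexpr("\\d", token, perl = TRUE)[[1]]
  pos <- digits[1 + (rng_digit %% length(digits))]
  old <- substr(token, pos, pos)
  new <- as.character((as.integer(old) + 1 + (rng_digit %% 9)) %% 10)
  if (new == old) new <- as.character((as.integer(old) + 1) %% 10)
  substr(token, pos, pos) <- new
  token
}

#' Default rule-based perturbation generator
#'
#' Contract: stay on topic, introduce no new entities, return only the
#' modified statement (or `NULL` when the mode does not apply).
#' * numeric: one number outside identifier tokens gets a digit changed.
#' * alphanumeric: one digit inside an identifier-like token changes.
#' * contradiction: the main claim verb is negated.
#' * overstatement: a hedged quantifier is escalated to a universal.
#'
#' @param statement Statement text.
#' @param mode Perturbation mode.
#' @param draw Integer used to vary pseudo-random choices.
#' @return Modified statement or `NULL`.
#' @export
rule_based_generator <- function(statement, mode, draw = 0L) {
  mode <- match.arg(mode, .perturbation_modes)
  if (mode == "numeric") {
    masked <- .mask_identifiers(statement)
    m <- gregexpr("\\d+(?:\\.\\d+)?", masked, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    lens <- attr(m, "match.length")
    i <- 1 + (draw %% length(m))
    tok <- substr(statement, m[i], m[i] + lens[i] - 1L)
    new_tok <- .mutate_digit(tok, draw)
    out <- statement
    substr(out, m[i], m[i] + lens[i] - 1L) <- new_tok
    return(out)
  }
  if (mode == "alphanumeric") {
    m <- gregexpr(.alnum_token_re, statement, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    lens <- attr(m, "match.length")
    i <- 1 + (draw %% length(m))
    tok <- substr(statement, m[i], m[i] + lens[i] - 1L)
    new_tok <- .mutate_digit(tok, draw)
    out <- statement
    substr(out, m[i], m[i] + lens[i] - 1L) <- new_tok
    return(out)
  }
  if (mode == "contradiction") {
    subs <- list(c("\\bis\\b", "is not"), c("\\bare\\b", "are not"),
                 c("\\bincreases\\b", "decreases"),
                 c("\\bactivates\\b", "inhibits"),
                 c("\\bcontains\\b", "lacks"),
                 c("\\bhas\\b", "lacks"))
    for (s in subs) {
      if (grepl(s[1], statement, perl = TRUE))
        return(sub(s[1], s[2], statement, perl = TRUE))
    }
    return(paste0("It is not the case that ",
                  tolower(substr(statement, 1, 1)),
                  substr(statement, 2, nchar(statement))))
  }
  # overstatement
  subs <- list(c("\\bsome\\b", "all"), c("\\bmany\\b", "all"),
               c("\\bmost\\b", "all"), c("\\boften\\b", "always"),
               c("\\bpartially\\b", "completely"),
               c("\\bcan\\b", "always will"))
  for (s in subs) {
    if (grepl(s[1], statement, perl = TRUE))
      return(sub(s[1], s[2], statement, perl = TRUE))
  }
  paste0(statement, " This holds in every case and in all conditions.")
}

#' Perturb one statement of a grounded answer
#'
#' Samples up to `max_candidates` eligible statement indices with the
#' given seed and iterates (bounded at `max_attempts`) until the generator
#' returns a modified statement different from the original.  The chosen
#' statement is replaced in place; its proofs are left untouched.
#'
#' @param answer A `cited_answer`.
#' @param mode Perturbation mode.
#' @param generator Generator function `(statement, mode, draw)`;
#'   default [rule_based_generator()].
#' @param seed Integer seed for candidate sampling.
#' @param max_candidates Candidate indices sampled (default 3).
#' @param min_length Passed to [filter_candidates()].
#' @param max_attempts Bound on generation attempts (default 10).
#' @return `NULL` when no candidate is eligible (mode skip); otherwise a
#'   list with `answer` (modified), `log` (a perturbation record with
#'   `original`, `modified`, `mode`, `index`, `candidates`, `attempts`,
#'   `proofs`).
#' @export
perturb_answer <- function(answer, mode, generator = rule_based_generator,
                           seed = 1L, max_candidates = 3L,
                           min_length = 40L, max_attempts = 10L) {
  mode <- match.arg(mode, .perturbation_modes)
  eligible <- filter_candidates(answer, mode, min_length)
  if (!length(eligible)) return(NULL)
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(as.integer(seed))
  cand <- sample(eligible, min(max_candidates, length(eligible)))
  attempts <- 0L
  for (idx in cand) {
    original <- answer$statements[[idx]]$text
    for (a in seq_len(max_attempts)) {
      attempts <- attempts + 1L
      modified <- generator(original, mode, draw = attempts - 1L)
      if (!is.null(modified) && !identical(modified, original)) {
        answer$statements[[idx]]$text <- modified
        answer$plain_text <- paste(
          vapply(answer$statements, `[[`, "", "text"), collapse = "\n")
        log <- list(original = original, modified = modified, mode = mode,
                    index = idx, candidates = cand, attempts = attempts,
                    proofs = answer$statements[[idx]]$proofs)
        return(list(answer = answer, log = log))
      }
    }
  }
  NULL
}

#' Evaluate verifier detection of adversarial perturbations
#'
#' A perturbation counts as detected when the perturbed statement's final
#' label is not `"supported"`.  Rates are reported per mode, with and
#' without document access (the context ablation).
#'
#' @param bundles List of bundles, each a list with `answer` (perturbed
#'   `cited_answer`), `documents`, `mode` and `perturbed_index`.
#' @param reviewer Reviewer passed to [verify_answer()] for the
#'   context-aware arm.
#' @return Data frame: `mode`, `context_aware`, `n`, `detected`, `rate`.
#' @export
evaluate_detection <- function(bundles, reviewer = rule_based_reviewer) {
  rows <- list()
  for (ctx in c(TRUE, FALSE)) {
    det <- vapply(bundles, function(b) {
      v <- verify_answer(b$answer, b$documents, reviewer = reviewer,
                         context_aware = ctx)
      v$statement_verdicts[[b$perturbed_index]]$label != "supported"
    }, TRUE)
    modes <- vapply(bundles, `[[`, "", "mode")
    for (m in unique(modes)) {
      sel <- modes == m
      rows[[length(rows) + 1L]] <- data.frame(
        mode = m, context_aware = ctx, n = sum(sel),
        detected = sum(det[sel]), rate = mean(det[sel]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
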