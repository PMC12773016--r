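# Multiple-choice benchmark harness: question generation from fixture
# tables, answer parsing, accuracy scoring with bootstrap confidence
# intervals, and tool-selection matrices.
#
# The default configuration emits 8 categories x 90 questions = 720
# questions; templates are data (JSON under inst/extdata) so new
# categories need no code change.

#' Load the bundled question templates
#'
#' One template per category: a stem with `{entity}` and `{value}`
#' placeholders, the expected primary tool, and whether the template
#' requires naming the source database (deterministic setup).
#'
#' @param path Optional path to a template JSON file; defaults to the
#'   bundled set.
#' @return Named list of templates.
#' @export
benchmark_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "benchmark_templates.json",
                        package = "genoground", mustWork = TRUE)
  jsonlite::read_json(path)
}

#' Default benchmark configuration
#'
#' Eight categories at 90 questions each (720 total); all counts
#' configurable.
#'
#' @param questions_per_category Questions per category (default 90).
#' @param templates Template list (default bundled).
#' @return A config list mapping category to count and template.
#' @export
benchmark_config <- function(questions_per_category = 90L,
                             templates = benchmark_templates()) {
  lapply(templates, function(tpl)
    list(n = questions_per_category, template = tpl))
}

#' Generate seeded multiple-choice questions
#'
#' For each category, entities are sampled from its fixture table; the key
#' answer is the sampled row's value and three distractors are sampled
#' from the remaining distinct values of the same table; the correct
#' answer is positioned at a seeded-uniform letter A--D.  A pure function
#' of (tables, config, seed).
#'
#' @param tables Named list of data frames (one per category) with columns
#'   `entity` and `value`.
#' @param config From [benchmark_config()].
#' @param seed Integer seed.
#' @return Data frame of questions: `id`, `category`, `stem`, `option_a`
#'   .. `option_d`, `key`, `expected_tool`, `source_row`.
#' @export
generate_questions <- function(tables, config, seed) {
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(as.integer(seed))
  out <- list()
  for (cat in names(config)) {
    tbl <- tables[[cat]]
    if (is.null(tbl)) stop("no fixture table for category: ", cat)
    tpl <- config[[cat]]$template
    n <- config[[cat]]$n
    values <- unique(tbl$value)
    if (length(values) < 4L)
      stop("fixture table for ", cat,
           " too small for one key and three distinct distractors")
    for (i in seq_len(n)) {
      row <- sample.int(nrow(tbl), 1L)
      key_val <- tbl$value[row]
      distractors <- sample(setdiff(values, key_val), 3L)
      key_letter <- sample(c("A", "B", "C", "D"), 1L)
      opts <- character(4)
      opts[match(key_letter, c("A", "B", "C", "D"))] <- key_val
      opts[opts == ""] <- distractors
      stem <- gsub("{entity}", tbl$entity[row], tpl$stem, fixed = TRUE)
      if (isTRUE(tpl$deterministic_setup))
        stem <- paste0("According to ", tpl$database, ": ", stem)
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("%s_%04d", cat, i), category = cat, stem = stem,
        option_a = opts[1], option_b = opts[2], option_c = opts[3],
        option_d = opts[4], key = key_letter,
        expected_tool = tpl$expected_tool, source_row = row,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

#' Parse a multiple-choice answer letter from response text
#'
#' Precedence: the content of the first `<answer>` tag containing a letter
#' A--D; else the first such `<solution>` tag; else the last standalone
#' (word-boundary, uppercase) A--D letter in the text; else `NA`.
#'
#' @param response_text Character vector of responses.
#' @return Character vector of letters or `NA`.
#' @examples
#' parse_answer("<answer>B</answer>")
#' parse_answer("Options A and C are close; I choose C.")
#' @export
parse_answer <- function(response_text) {
  vapply(response_text, function(txt) {
    if (is.na(txt)) return(NA_character_)
    for (tag in c("answer", "solution")) {
      re <- sprintf("(?is)<%s>(.*?)</%s>", tag, tag)
      m <- regmatches(txt, gregexpr(re, txt, perl = TRUE))[[1]]
      for (mk in m) {
        inner <- gsub(sprintf("(?is)</?%s>", tag), "", mk, perl = TRUE)
        lt <- regmatches(inner, regexpr("[A-D]", inner))
        if (length(lt)) return(lt)
      }
    }
    hits <- regmatches(txt, gregexpr("\\b[A-D]\\b", txt, perl = TRUE))[[1]]
    if (length(hits)) hits[length(hits)] else NA_character_
  }, "", USE.NAMES = FALSE)
}

#' Score a benchmark run with a bootstrap confidence interval
#'
#' Accuracy counts unparsed responses as incorrect.  The confidence
#' interval comes from a seeded nonparametric bootstrap over the answer
#' records (default 1,000 resamples) using the 2.5th and 97.5th
#' percentiles of the resampled accuracies.
#'
#' @param records Data frame with a logical `correct` column (`NA` =
#'   unparsed).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List with `accuracy`, `ci_low`, `ci_high`, `n`.
#' @export
score_run <- function(records, n_boot = 1000L, seed = 1L) {
  if (is.null(records) || !nrow(records)) stop("no answer records to score")
  correct <- records$correct %in% TRUE
  n <- length(correct)
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(i)
    mean(correct[sample.int(n, n, replace = TRUE)]), 0)
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  list(accuracy = mean(correct), ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Tool-selection matrix
#'
#' Rows are the expected primary tool from question metadata; columns are
#' the tools actually called.  Diagonal entries reflect correct primary
#' tool selection; off-diagonal entries count supplementary tools.
#'
#' @param records Data frame with columns `expected_tool` and
#'   `tools_called` (list column of character vectors).
#' @param vocabulary Optional fixed tool vocabulary for the axes.
#' @return List with `counts` (matrix) and `row_normalized`.
#' @export
tool_selection_matrix <- function(records, vocabulary = NULL) {
  if (is.null(vocabulary))
    vocabulary <- sort(unique(c(records$expected_tool,
                                unlist(records$tools_called))))
  if (!length(vocabulary)) vocabulary <- character()
  counts <- matrix(0L, length(vocabulary), length(vocabulary),
                   dimnames = list(expected = vocabulary,
                                   called = vocabulary))
  if (!is.null(records) && nrow(records)) {
    for (i in seq_len(nrow(records))) {
      exp_t <- records$expected_tool[i]
      for (called in records$tools_called[[i]]) {
        if (exp_t %in% vocabulary && called %in% vocabulary)
          counts[exp_t, called] <- counts[exp_t, called] + 1L
      }
    }
  }
  rn <- counts
  rs <- rowSums(counts)
  nz <- rs > 0
  rn[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  list(counts = counts, row_normalized = rn)
}
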