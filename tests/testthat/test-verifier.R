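mk_proof <- function(text, doc = 0L, valid = TRUE) {
  list(doc = doc, start = NA_integer_, end = NA_integer_,
       cited_text = text, text = text, title = "T", valid = valid,
       fallback = FALSE)
}
docs1 <- data.frame(index = 0:4, title = paste0("D", 0:4), text = "x",
                    stringsAsFactors = FALSE)

test_that("typed identifiers are extracted and deduplicated", {
  ids <- extract_identifiers("rs334 maps to ENSG00000141510 in R-HSA-109582")
  expect_setequal(ids$type, c("rsid", "ensembl", "pathway"))
  ids2 <- extract_identifiers("HGNC:11998, MGI:95479, RGD:2004")
  expect_setequal(ids2$type, c("hgnc", "mgi", "rgd"))
  expect_equal(nrow(extract_identifiers("plain prose only")), 0L)
  expect_equal(nrow(extract_identifiers("rs1 rs1 rs1")), 1L)
})

test_that("deterministic check labels supported, partial and unsupported", {
  sup <- deterministic_check("rs334 is pathogenic here",
                             list(mk_proof("record for rs334")), docs1)
  expect_equal(sup$label, "supported")
  expect_length(sup$issues, 0L)

  uns <- deterministic_check("rs334 is pathogenic here",
                             list(mk_proof("no identifiers at all")), docs1)
  expect_equal(uns$label, "unsupported")
  expect_true(any(vapply(uns$issues, function(i)
    i$type == "identifier_absent" && i$id == "rs334", TRUE)))

  mix <- deterministic_check(
    "rs334 and ENSG00000141510 act together",
    list(mk_proof("only rs334 appears")), docs1)
  expect_equal(mix$label, "partial")

  bad <- deterministic_check("claim", list(mk_proof("x", doc = 12L,
                                                    valid = FALSE)), docs1)
  expect_true(any(vapply(bad$issues, function(i)
    i$type == "bad_doc_index", TRUE)))
  expect_equal(bad$label, "unsupported")

  nop <- deterministic_check("claim", list(), docs1)
  expect_equal(nop$label, "unsupported")
  expect_equal(nop$issues[[1]]$type, "missing_proofs")
})

test_that("ensemble combination takes the worse label and unions issues", {
  v <- function(label) structure(list(label = label, issues = list()),
                                 class = "statement_verdict")
  expect_equal(combine_ensemble(v("supported"), v("unsupported"))$label,
               "unsupported")
  expect_equal(combine_ensemble(v("unsupported"), v("supported"))$label,
               "unsupported")
  expect_equal(combine_ensemble(v("partial"), v("supported"))$label,
               "partial")
  expect_equal(combine_ensemble(v("supported"), v("supported"))$label,
               "supported")
  # commutative at the tied worst level
  expect_equal(
    combine_ensemble(v("speculation_overreach"), v("unsupported"))$label,
    combine_ensemble(v("unsupported"), v("speculation_overreach"))$label)
})

test_that("the 30% unsupported rule uses exact arithmetic at the boundary", {
  labs <- function(k, n) c(rep("unsupported", k), rep("supported", n - k))
  expect_false(judge_answer(labs(3, 10), overall_pass = TRUE)$passed)
  expect_true(judge_answer(labs(2, 10), overall_pass = TRUE)$passed)
  # overall fail always fails
  expect_false(judge_answer(labs(0, 10), overall_pass = FALSE)$passed)
  # speculation labels do not count toward the fraction
  sp <- judge_answer(c(rep("speculation_ok", 5), rep("supported", 5)))
  expect_true(sp$passed)
  expect_equal(sp$unsupported_fraction, 0)
  # degenerate: no statements
  empty <- judge_answer(character())
  expect_false(empty$passed)
  expect_true("no content" %in% empty$concerns)
})

test_that("adding an unsupported statement never flips failed to passed", {
  set.seed(77)
  for (trial in 1:30) {
    n <- sample(3:12, 1)
    labs <- sample(c("supported", "partial", "unsupported"), n,
                   replace = TRUE)
    before <- judge_answer(labs)$passed
    after <- judge_answer(c(labs, "unsupported"))$passed
    expect_false(!before && after)
  }
})

test_that("the rule-based reviewer follows the review contract", {
  corp <- make_grounded_corpus(3, 6, seed = 12)
  rev <- qualitative_review(corp$answer, corp$documents)
  expect_length(rev$statements, 6L)
  expect_true(all(vapply(rev$statements, `[[`, "", "label") == "supported"))
  expect_equal(rev$support_quality, "high")

  # zero-overlap statement is unsupported
  ans <- corp$answer
  ans$statements[[1]]$text <- "zebras gallop through quantum meadows nightly"
  rev2 <- qualitative_review(ans, corp$documents)
  expect_equal(rev2$statements[[1]]$label, "unsupported")

  # mock reviewer passes through unchanged; schema violations error
  mock <- function(answer, documents) {
    n <- length(answer$statements)
    list(statements = replicate(n, structure(
           list(label = "partial", issues = list()),
           class = "statement_verdict"), simplify = FALSE),
         support_quality = "medium", overall_pass = TRUE,
         concerns = character())
  }
  expect_equal(vapply(qualitative_review(corp$answer, corp$documents,
                                         mock)$statements,
                      `[[`, "", "label"),
               rep("partial", 6))
  broken <- function(answer, documents) list(statements = list())
  expect_error(qualitative_review(corp$answer, corp$documents, broken),
               "schema")
})

test_that("clean synthetic corpora verify with zero deterministic flags", {
  for (seed in 1:5) {
    corp <- make_grounded_corpus(4, 8, seed = seed)
    for (s in corp$answer$statements) {
      det <- deterministic_check(s$text, s$proofs, corp$documents)
      expect_equal(det$label, "supported")
      expect_length(det$issues, 0L)
    }
    v <- verify_answer(corp$answer, corp$documents)
    expect_true(v$passed)
    expect_equal(v$unsupported_fraction, 0)
  }
})

test_that("corrupting an identifier absent from proofs is always detected", {
  corp <- make_grounded_corpus(4, 8, seed = 33)
  for (i in seq_along(corp$answer$statements)) {
    ans <- corp$answer
    txt <- ans$statements[[i]]$text
    # replace the first digit of the identifier with a different digit
    pos <- regexpr("[0-9]", txt)
    corrupted <- txt
    substr(corrupted, pos, pos) <-
      as.character((as.integer(substr(txt, pos, pos)) + 1) %% 10)
    stopifnot(corrupted != txt)
    ans$statements[[i]]$text <- corrupted
    det <- deterministic_check(corrupted, ans$statements[[i]]$proofs,
                               corp$documents)
    expect_true(det$label != "supported")
  }
})
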