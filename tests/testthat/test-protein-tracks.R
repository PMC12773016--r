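test_that("polarity index matches its defining formula and forced zeros", {
  expect_equal(polarity_index(30, 10), 0.5)
  expect_equal(polarity_index(0, 0), 0)    # buried residue
  expect_equal(polarity_index(0, 25), -1)  # fully apolar bound
  expect_equal(polarity_index(NA, 25), 0)  # missing component
  expect_error(polarity_index(c(1, 2), 1), "length")
})

test_that("polarity index is bounded and antisymmetric", {
  set.seed(11)
  for (trial in 1:20) {
    p <- stats::runif(50, 0, 100); a <- stats::runif(50, 0, 100)
    z <- sample(50, 5); p[z] <- 0; a[z] <- 0
    d <- polarity_index(p, a)
    expect_true(all(d >= -1 & d <= 1))
    expect_equal(polarity_index(a, p), -d)  # forced zeros negate to zero
  }
})

test_that("pocket tracks average overlaps, zero-fill gaps and normalize", {
  tr <- pocket_residue_track(list(
    list(member_residues = 1:5, druggability = 0.4),
    list(member_residues = 3:8, druggability = 0.8)), length = 10)
  expect_equal(tr$raw[3], 0.6)   # mean of both pockets
  expect_equal(tr$raw[1], 0.4)
  expect_equal(tr$raw[10], 0)    # no pocket: neutral zero
  expect_equal(tr$raw_min, 0)
  expect_equal(tr$raw_max, 0.8)
  # min-max normalization attains 0 and 1
  expect_equal(min(tr$normalized), 0)
  expect_equal(max(tr$normalized), 1)
  # explicit min-max check
  tr2 <- pocket_residue_track(list(
    list(member_residues = 2L, druggability = 0.3),
    list(member_residues = 3L, druggability = 0.6)), length = 3)
  expect_equal(tr2$raw, c(0, 0.3, 0.6))
  expect_equal(tr2$normalized, c(0, 0.5, 1))
  expect_equal(tr2$raw_max, 0.6)
  # constant raw track: all-zero normalized view
  tr3 <- pocket_residue_track(list(), length = 4)
  expect_equal(tr3$normalized, rep(0, 4))
  expect_error(pocket_residue_track(list(list(member_residues = 99L,
                                              druggability = 1)), 10),
               "outside")
})

test_that("pLDDT summary bands and the low-mean flag behave as documented", {
  s <- plddt_summary(rep(65, 10))
  expect_true(s$low_mean_plddt)
  expect_equal(s$n_low, 10L)
  s2 <- plddt_summary(rep(85, 10))
  expect_false(s2$low_mean_plddt)
  expect_equal(s2$n_confident, 10L)
  # mean exactly 70 does not raise the flag (strictly below)
  expect_false(plddt_summary(rep(70, 5))$low_mean_plddt)
  s3 <- plddt_summary(c(95, 91, 90, 70, 69))
  expect_equal(s3$n_very_high, 2L)
  expect_equal(s3$n_confident, 2L)
  expect_equal(s3$n_low, 1L)
})

test_that("curated disorder regions merge on overlap and propagate ambiguity", {
  r <- function(s, e, amb) data.frame(start = s, end = e, term_name = "t",
                                      namespace = "ns", evidence = "manual",
                                      ambiguous = amb,
                                      stringsAsFactors = FALSE)
  m <- merge_disprot(rbind(r(10, 30, FALSE), r(25, 50, FALSE)), 60)
  expect_equal(nrow(m$regions), 1L)
  expect_equal(c(m$regions$start, m$regions$end), c(10, 50))
  expect_true(all(m$mask[10:50] == 1.0))
  expect_true(all(m$mask[-(10:50)] == 0))

  m2 <- merge_disprot(rbind(r(10, 30, FALSE), r(25, 50, TRUE)), 60)
  expect_true(m2$regions$ambiguous)
  expect_true(all(m2$mask[10:50] == 0.5))

  # adjacent but not overlapping regions stay separate
  m3 <- merge_disprot(rbind(r(10, 20, FALSE), r(21, 30, FALSE)), 60)
  expect_equal(nrow(m3$regions), 2L)

  m4 <- merge_disprot(NULL, 20)
  expect_equal(m4$mask, rep(0, 20))
  # mask values are always in {0, 0.5, 1}; merged regions disjoint
  set.seed(6)
  regs <- r(sort(sample(1:40, 4)), 0, sample(c(TRUE, FALSE), 4, TRUE))
  regs$end <- regs$start + sample(5:15, 4)
  regs$end <- pmin(regs$end, 60)
  m5 <- merge_disprot(regs, 60)
  expect_true(all(m5$mask %in% c(0, 0.5, 1)))
  if (nrow(m5$regions) > 1)
    expect_true(all(utils::head(m5$regions$end, -1) <
                      utils::tail(m5$regions$start, -1)))
})

test_that("consensus disorder averages available contributors and clips", {
  expect_equal(consensus_disorder(0.6, 0.8, 1.0), 0.8)
  expect_equal(consensus_disorder(0.4, NULL, NULL), 0.4)
  expect_equal(consensus_disorder(NA_real_, NA_real_, 0), 0)
  # disprot vote contributes its mask value only where the mask is positive
  expect_equal(consensus_disorder(0.5, NULL, 0.5), 0.5)
  expect_equal(consensus_disorder(0.5, NULL, 0), 0.5)
  # monotone nondecreasing in each contributor
  set.seed(13)
  for (trial in 1:20) {
    s <- stats::runif(30); l <- stats::runif(30)
    mask <- sample(c(0, 0.5, 1), 30, replace = TRUE)
    base <- consensus_disorder(s, l, mask)
    bump <- pmin(s + 0.1, 1)
    expect_true(all(consensus_disorder(bump, l, mask) >= base - 1e-12))
    expect_true(all(base >= 0 & base <= 1))
  }
})

test_that("MoRF propensity is the per-residue maximum with 0 default", {
  expect_equal(morf_track(0.3, 0.7), 0.7)
  expect_equal(morf_track(c(0.4, NA), NULL), c(0.4, 0))
  expect_equal(morf_track(NULL, c(0.2, 0.9)), c(0.2, 0.9))
  expect_error(morf_track(NULL, NULL), "missing")
})

test_that("segment metrics match the exhaustive run-scan oracle", {
  m <- segment_metrics(rep(0.6, 5))
  expect_equal(m$n_segments, 1L)
  expect_equal(m$longest_segment, 5L)
  expect_equal(m$fraction_above, 1)
  # runs of 4 and 1 do not qualify at min_len 5
  m2 <- segment_metrics(c(0.6, 0.6, 0.6, 0.6, 0.1, 0.6))
  expect_equal(m2$n_segments, 0L)
  expect_equal(m2$longest_segment, 0L)
  set.seed(17)
  for (trial in 1:50) {
    tr <- stats::runif(200)
    expect_equal(segment_metrics(tr), oracle_segment_metrics(tr))
  }
})

test_that("cysteine flag aggregation counts, labels and surfaces neighbors", {
  flags <- data.frame(position = c(74L, 81L, 123L),
                      detected = c(TRUE, TRUE, TRUE),
                      hyperreactive = c(FALSE, TRUE, FALSE),
                      ligandable = c(TRUE, TRUE, TRUE),
                      active_site = FALSE, near_active_site = FALSE,
                      binding_site = FALSE,
                      near_binding_site = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  flags$neighbors <- list("SMAD anchor", "SMAD anchor", character())
  agg <- aggregate_cysdb(flags, "P12345", length = 200L)
  expect_equal(unname(agg$counts["ligandable"]), 3L)
  expect_equal(unname(agg$counts["near_binding_site"]), 2L)
  expect_true("P12345_C123" %in% agg$labels)
  expect_equal(agg$neighbors[["P12345_C74"]], "SMAD anchor")
  expect_true(any(grepl("near: SMAD anchor", agg$summary)))
  expect_equal(sum(agg$tracks$ligandable), 3)
  expect_equal(agg$tracks$near_binding_site[c(74, 81)], c(1, 1))

  none <- aggregate_cysdb(NULL, "P1")
  expect_true(all(none$counts == 0L))
  expect_length(none$labels, 0L)
})
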