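# Residue-level protein feature tracks for druggability assessment.
#
# All tracks are numeric vectors indexed by 1-based UniProt residue
# numbering over one protein fragment.  Normalized views live in [0, 1];
# raw extrema are preserved alongside for interpretation.

#' SASA polarity index
#'
#' For residue i with polar SASA `Ap` and apolar SASA `Aa` (both in
#' square Angstroms), the polarity index is `(Ap - Aa) / (Ap + Aa)`,
#' unitless and bounded in `[-1, 1]`.  Values near -1 indicate
#' predominantly apolar exposure, near +1 predominantly polar exposure.
#' Wherever the denominator is zero (buried residues) or either component
#' is missing, the index is set to 0 so the track stays continuous.
#'
#' @param polar,apolar Numeric vectors of per-residue polar and apolar
#'   SASA contributions (same length, values >= 0; `NA` = missing).
#' @return Numeric track in `[-1, 1]`.
#' @examples
#' polarity_index(c(30, 0, 0), c(10, 0, 25))  # 0.5, 0, -1
#' @export
polarity_index <- function(polar, apolar) {
  if (length(polar) != length(apolar))
    stop("polar and apolar tracks must have the same length")
  tot <- polar + apolar
  delta <- (polar - apolar) / tot
  delta[is.na(polar) | is.na(apolar) | tot == 0] <- 0
  delta
}

#' Per-residue pocket druggability track
#'
#' Each residue receives the mean druggability of all pockets that include
#' it; residues in no pocket get a neutral zero so the track stays
#' continuous.  A normalized view is min-max scaled to `[0, 1]` within the
#' fragment, with the raw extrema preserved.  When the raw track is
#' constant the normalized view is all zeros.
#'
#' @param pockets List of pockets, each a list with `member_residues`
#'   (integer positions) and `druggability` (number).
#' @param length Fragment length in residues.
#' @return List with `raw`, `normalized`, `raw_min`, `raw_max`.
#' @export
pocket_residue_track <- function(pockets, length) {
  acc <- numeric(length)
  cnt <- integer(length)
  for (p in pockets) {
    pos <- as.integer(p$member_residues)
    if (any(pos < 1L | pos > length))
      stop("pocket members outside 1..length")
    acc[pos] <- acc[pos] + p$druggability
    cnt[pos] <- cnt[pos] + 1L
  }
  raw <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), 0)
  rmin <- min(raw); rmax <- max(raw)
  normalized <- if (rmax > rmin) (raw - rmin) / (rmax - rmin)
                else numeric(length)
  list(raw = raw, normalized = normalized, raw_min = rmin, raw_max = rmax)
}

#' Summarize a pLDDT confidence track
#'
#' Bands follow the usual AlphaFold reading: above 90 very reliable, 70 to
#' 90 usually a correct backbone, below 70 often flexible or disordered.
#' The `low_mean_plddt` flag is raised only when the mean falls strictly
#' below 70.
#'
#' @param plddt Numeric vector with values in `[0, 100]`.
#' @return List with `min`, `max`, `mean`, band counts `n_very_high`
#'   (> 90), `n_confident` (70--90), `n_low` (< 70), and `low_mean_plddt`.
#' @export
plddt_summary <- function(plddt) {
  stopifnot(all(plddt >= 0 & plddt <= 100, na.rm = TRUE))
  m <- mean(plddt, na.rm = TRUE)
  list(min = min(plddt, na.rm = TRUE), max = max(plddt, na.rm = TRUE),
       mean = m,
       n_very_high = sum(plddt > 90, na.rm = TRUE),
       n_confident = sum(plddt >= 70 & plddt <= 90, na.rm = TRUE),
       n_low = sum(plddt < 70, na.rm = TRUE),
       low_mean_plddt = m < 70)
}

#' Merge curated disorder regions and build the residue mask
#'
#' Overlapping regions are merged (adjacent-but-not-overlapping regions
#' are not) and ambiguity is propagated: a merged region is ambiguous when
#' any constituent is.  The mask is 1.0 inside unambiguous regions, 0.5
#' inside ambiguous ones, and 0 outside.
#'
#' @param regions Data frame with columns `start`, `end` (1-based,
#'   inclusive), `term_name`, `namespace`, `evidence`, `ambiguous`.
#' @param length Fragment length.
#' @return List with `regions` (merged data frame) and `mask` (numeric
#'   track over `{0, 0.5, 1}`).
#' @export
merge_disprot <- function(regions, length) {
  mask <- numeric(length)
  empty <- data.frame(start = integer(), end = integer(),
                      term_name = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(regions) || !nrow(regions))
    return(list(regions = empty, mask = mask))
  stopifnot(all(regions$start <= regions$end),
            all(regions$start >= 1L), all(regions$end <= length))
  regions <- regions[order(regions$start, regions$end), , drop = FALSE]
  merged <- list()
  cur <- list(start = regions$start[1], end = regions$end[1],
              term_name = regions$term_name[1],
              ambiguous = isTRUE(regions$ambiguous[1]))
  for (i in seq_len(nrow(regions))[-1]) {
    if (regions$start[i] <= cur$end) {   # strict overlap only
      cur$end <- max(cur$end, regions$end[i])
      cur$ambiguous <- cur$ambiguous || isTRUE(regions$ambiguous[i])
      cur$term_name <- paste(unique(c(cur$term_name, regions$term_name[i])),
                             collapse = "; ")
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- list(start = regions$start[i], end = regions$end[i],
                  term_name = regions$term_name[i],
                  ambiguous = isTRUE(regions$ambiguous[i]))
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, lapply(merged, function(r)
    data.frame(start = r$start, end = r$end, term_name = r$term_name,
               ambiguous = r$ambiguous, stringsAsFactors = FALSE)))
  for (i in seq_len(nrow(out)))
    mask[out$start[i]:out$end[i]] <- if (out$ambiguous[i]) 0.5 else 1.0
  list(regions = out, mask = mask)
}

#' Consensus disorder profile
#'
#' Per residue, the average over available contributors: the IUPred short
#' and long scores where present and the curated-region vote (the mask
#' value, 1.0 or 0.5) where the mask is positive.  The average is clipped
#' to `[0, 1]`; residues with no contributors are 0.
#'
#' @param iupred_short,iupred_long Numeric tracks or `NULL`; `NA` marks a
#'   missing residue.
#' @param disprot_mask Numeric track over `{0, 0.5, 1}` or `NULL`.
#' @return Numeric track in `[0, 1]`.
#' @export
consensus_disorder <- function(iupred_short = NULL, iupred_long = NULL,
                               disprot_mask = NULL) {
  tracks <- Filter(Negate(is.null),
                   list(iupred_short, iupred_long, disprot_mask))
  if (!length(tracks)) stop("at least one contributor track required")
  n <- unique(lengths(tracks))
  if (length(n) != 1L) stop("contributor tracks must share length")
  total <- numeric(n); count <- numeric(n)
  add <- function(v, active) {
    act <- active & !is.na(v)
    total[act] <<- total[act] + v[act]
    count[act] <<- count[act] + 1
  }
  if (!is.null(iupred_short)) add(iupred_short, rep(TRUE, n))
  if (!is.null(iupred_long)) add(iupred_long, rep(TRUE, n))
  if (!is.null(disprot_mask)) add(disprot_mask, disprot_mask > 0)
  out <- ifelse(count > 0, total / count, 0)
  pmin(pmax(out, 0), 1)
}

#' MoRF propensity track
#'
#' Per-residue maximum of the ANCHOR-style short and long scores,
#' defaulting to 0 where both are missing.
#'
#' @param anchor_short,anchor_long Numeric tracks or `NULL`.
#' @return Numeric track.
#' @export
morf_track <- function(anchor_short = NULL, anchor_long = NULL) {
  if (is.null(anchor_short) && is.null(anchor_long))
    stop("track length unknown: both inputs missing; supply at least one")
  if (is.null(anchor_short)) anchor_short <- rep(NA_real_, length(anchor_long))
  if (is.null(anchor_long)) anchor_long <- rep(NA_real_, length(anchor_short))
  stopifnot(length(anchor_short) == length(anchor_long))
  out <- pmax(anchor_short, anchor_long, na.rm = TRUE)
  out[is.na(out)] <- 0
  out
}

#' Segment metrics over a residue track
#'
#' Reports the minimum, maximum and mean of the track, the fraction of
#' residues at or above the threshold, the number of maximal runs at or
#' above the threshold with length at least `min_len`, and the longest
#' such qualifying run (0 when none qualifies).
#'
#' @param track Numeric vector.
#' @param threshold Score threshold (default 0.5).
#' @param min_len Minimum qualifying run length (default 5).
#' @return List with `min`, `max`, `mean`, `fraction_above`, `n_segments`,
#'   `longest_segment`.
#' @export
segment_metrics <- function(track, threshold = 0.5, min_len = 5L) {
  if (!length(track))
    return(list(min = NA_real_, max = NA_real_, mean = NA_real_,
                fraction_above = NA_real_, n_segments = 0L,
                longest_segment = 0L))
  above <- track >= threshold
  r <- rle(above)
  runs <- r$lengths[r$values]
  qualifying <- runs[runs >= min_len]
  list(min = min(track), max = max(track), mean = mean(track),
       fraction_above = mean(above),
       n_segments = length(qualifying),
       longest_segment = if (length(qualifying)) max(qualifying) else 0L)
}

.cys_categories <- c("detected", "hyperreactive", "ligandable",
                     "active_site", "near_active_site", "binding_site",
                     "near_binding_site")

#' Aggregate cysteine chemoproteomics flags for one protein
#'
#' Counts how many cysteines fall into each category, generates stable
#' labels of the form `<accession>_C<position>` for every flagged
#' cysteine, surfaces neighbor lists for near-site cysteines, and emits
#' binary per-category visualization tracks when the fragment length is
#' supplied.
#'
#' @param flags Data frame with column `position` plus logical columns
#'   `detected`, `hyperreactive`, `ligandable`, `active_site`,
#'   `near_active_site`, `binding_site`, `near_binding_site`, and
#'   optionally a list column `neighbors` of site labels.
#' @param accession UniProt accession used in labels.
#' @param length Optional fragment length for binary tracks.
#' @return List with `counts` (named integer vector), `labels`,
#'   `neighbors` (named list for near-site cysteines), `tracks` (list of
#'   0/1 vectors, or `NULL`), and `summary` (one text line per flagged
#'   cysteine).
#' @export
aggregate_cysdb <- function(flags, accession, length = NULL) {
  empty_counts <- stats::setNames(integer(base::length(.cys_categories)),
                                  .cys_categories)
  if (is.null(flags) || !nrow(flags))
    return(list(counts = empty_counts, labels = character(),
                neighbors = list(), tracks = NULL, summary = character()))
  stopifnot(!anyDuplicated(flags$position))
  for (cat in .cys_categories)
    if (is.null(flags[[cat]])) flags[[cat]] <- FALSE
  counts <- vapply(.cys_categories, function(cat)
    sum(flags[[cat]], na.rm = TRUE), 0L)
  flagged <- Reduce(`|`, lapply(.cys_categories, function(cat)
    flags[[cat]] %in% TRUE))
  labels <- sprintf("%s_C%d", accession, flags$position[flagged])
  near <- flags$near_active_site %in% TRUE | flags$near_binding_site %in% TRUE
  neighbors <- list()
  if (!is.null(flags$neighbors)) {
    for (i in which(near)) {
      nb <- flags$neighbors[[i]]
      if (base::length(nb))
        neighbors[[sprintf("%s_C%d", accession, flags$position[i])]] <- nb
    }
  }
  tracks <- NULL
  if (!is.null(length)) {
    tracks <- lapply(.cys_categories, function(cat) {
      v <- numeric(length)
      v[flags$position[flags[[cat]] %in% TRUE]] <- 1
      v
    })
    names(tracks) <- .cys_categories
  }
  summary_lines <- vapply(which(flagged), function(i) {
    cats <- .cys_categories[vapply(.cys_categories, function(cat)
      isTRUE(flags[[cat]][i]), TRUE)]
    lab <- sprintf("%s_C%d", accession, flags$position[i])
    line <- sprintf("%s: %s", lab, paste(cats, collapse = ", "))
    nb <- neighbors[[lab]]
    if (!is.null(nb))
      line <- sprintf("%s (near: %s)", line, paste(nb, collapse = ", "))
    line
  }, "")
  list(counts = counts, labels = labels, neighbors = neighbors,
       tracks = tracks, summary = summary_lines)
}
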