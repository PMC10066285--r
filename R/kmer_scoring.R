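# Probe-intensity normalization and per-7-mer trimmed-mean scores / Z-scores,
# per probe subset (Set A, Set B, or merged).

#' Intensity profile constructor
#'
#' One experiment's probe-level fluorescence measurements. `flag` follows the
#' spot-flagging convention: 0 = usable, 1 = excluded.
#'
#' @param probe_id character vector.
#' @param intensity nonnegative numeric vector.
#' @param flag integer vector (0/1), recycled.
#' @return data.frame of class `IntensityProfile`.
#' @export
intensity_profile <- function(probe_id, intensity, flag = 0L) {
  stopifnot(length(probe_id) == length(intensity))
  flag <- rep_len(as.integer(flag), length(probe_id))
  usable <- flag == 0L
  if (any(usable & (!is.finite(intensity) | intensity < 0)))
    stop("usable probes must have finite nonnegative intensities")
  structure(data.frame(probe_id = as.character(probe_id),
                       intensity = as.numeric(intensity),
                       flag = flag, stringsAsFactors = FALSE),
            class = c("IntensityProfile", "data.frame"))
}

#' Normalize probe intensities
#'
#' Drops flagged (excluded) spots, log-transforms (`log1p`, rank-preserving
#' on nonnegative input), and median-centers, so the output is on a log
#' scale with median exactly 0.
#'
#' @param profile `IntensityProfile` (or data.frame with the same columns).
#' @return normalized `IntensityProfile` (all flags 0, attribute
#'   `normalized = TRUE`).
#' @export
normalize_intensities <- function(profile) {
  usable <- profile$flag == 0L
  if (!any(usable)) stop("all probes are excluded; nothing to normalize")
  v <- log1p(profile$intensity[usable])
  v <- v - median(v)
  out <- data.frame(probe_id = as.character(profile$probe_id[usable]),
                    intensity = v, flag = 0L, stringsAsFactors = FALSE)
  structure(out, normalized = TRUE,
            class = c("IntensityProfile", "data.frame"))
}

#' Precomputed k-mer -> probe incidence index
#'
#' Unique (k-mer, probe) presence pairs for every universe member, reusable
#' across many experiments on the same pool (the expensive part of scoring).
#'
#' @param pool `ProbePool`.
#' @param universe `KmerUniverse`.
#' @return object of class `KmerIndex`.
#' @export
kmer_probe_index <- function(pool, universe = kmer_universe()) {
  stopifnot(inherits(pool, "ProbePool"), inherits(universe, "KmerUniverse"))
  pr <- kmer_seq_pairs_cpp(pool$probes$sequence, as.integer(universe$k))
  keep_code <- match(universe$members, all_kmers(universe$k))
  code_map <- integer(4^universe$k)
  code_map[keep_code] <- seq_along(keep_code)  # 0 for excluded k-mers
  member_id <- code_map[pr$kmer_code]
  keep <- member_id > 0L
  structure(list(member_id = member_id[keep],
                 probe_idx = pr$seq_index[keep],
                 probe_id = pool$probes$probe_id,
                 set_label = pool$probes$set_label,
                 universe = universe),
            class = "KmerIndex")
}

#' Compute per-k-mer trimmed-mean scores and Z-scores
#'
#' For each universe k-mer w, score(w) is the trimmed mean (default 2.5% per
#' tail) of the normalized intensities of subset probes containing w, each
#' probe counted once regardless of how many times w occurs in it. Z-scores
#' standardize the score vector by its median and MAD (x 1.4826); if the MAD
#' is zero the standard deviation is used, and if that is also zero all
#' Z-scores are 0.
#'
#' @param profile `IntensityProfile`; normalized internally unless already
#'   marked `normalized`.
#' @param pool `ProbePool` with set labels.
#' @param subset `"A"`, `"B"`, or `"merged"`.
#' @param universe `KmerUniverse`.
#' @param trim_fraction fraction trimmed from each tail (default 0.025).
#' @param index optional precomputed [kmer_probe_index()] for this pool.
#' @return data.frame of class `KmerTable` with columns `kmer`, `score`,
#'   `z`, ordered lexicographically by k-mer; attributes `subset`,
#'   `universe`, `trim_fraction`.
#' @export
compute_kmer_zscores <- function(profile, pool, subset = c("merged", "A", "B"),
                                 universe = kmer_universe(),
                                 trim_fraction = 0.025, index = NULL) {
  subset <- match.arg(subset)
  if (is.null(index)) index <- kmer_probe_index(pool, universe)
  stopifnot(inherits(index, "KmerIndex"))
  universe <- index$universe
  if (!isTRUE(attr(profile, "normalized")))
    profile <- normalize_intensities(profile)

  value <- rep(NA_real_, length(index$probe_id))
  m <- match(profile$probe_id, index$probe_id)
  value[m[!is.na(m)]] <- profile$intensity[!is.na(m)]
  in_subset <- if (subset == "merged") rep(TRUE, length(index$probe_id))
               else index$set_label %in% subset
  ok_probe <- in_subset & !is.na(value)
  if (!any(ok_probe)) stop("no usable probes in subset ", subset)

  keep <- ok_probe[index$probe_idx]
  dt <- data.table::data.table(id = index$member_id[keep],
                               v = value[index$probe_idx[keep]])
  nm <- length(universe$members)
  sizes <- tabulate(dt$id, nbins = nm)
  missing <- which(sizes == 0L)
  if (length(missing))
    stop(sprintf("universe %d-mer %s has no supporting probe in subset %s (pool/universe mismatch)",
                 universe$k, universe$members[missing[1]], subset))
  if (floor(max(sizes) * trim_fraction) == 0L) {
    agg <- dt[, list(score = mean(v)), keyby = "id"]
  } else {
    tf <- trim_fraction
    agg <- dt[, list(score = trimmed_mean(v, tf)), keyby = "id"]
  }
  score <- agg$score
  med <- median(score)
  scale <- 1.4826 * mad(score, constant = 1)
  if (scale == 0) scale <- sd(score)
  z <- if (is.na(scale) || scale == 0) rep(0, nm) else (score - med) / scale
  structure(data.frame(kmer = universe$members, score = score, z = z,
                       stringsAsFactors = FALSE),
            subset = subset, universe = universe,
            trim_fraction = trim_fraction,
            class = c("KmerTable", "data.frame"))
}

#' Top-n k-mers of a KmerTable
#'
#' Sorted by Z descending with lexicographic tie-break on the k-mer.
#'
#' @param table `KmerTable`.
#' @param n how many (default 10).
#' @return data.frame slice (columns `kmer`, `score`, `z`).
#' @export
top_kmers <- function(table, n = 10) {
  ord <- order(-table$z, table$kmer)
  table[head(ord, n), , drop = FALSE]
}

#' Bonferroni-corrected upper-tail normal probability
#'
#' The multiple-testing-corrected P value attached to a k-mer Z-score under
#' a standard-normal null: `n_tests` one-sided tests, capped at 1. At the
#' default 16,382-test universe, Z > 5 gives P < 0.005.
#'
#' @param z Z-score(s).
#' @param n_tests number of tests (default 16,382 scored 7-mers).
#' @return corrected p value(s) in \[0, 1\].
#' @export
bonferroni_tail <- function(z, n_tests = 16382) {
  stopifnot(n_tests >= 1)
  pmin(1, n_tests * pnorm(z, lower.tail = FALSE))
}

#' Set A vs Set B reproducibility diagnostics
#'
#' @param tableA,tableB `KmerTable`s over the same universe.
#' @return list with `pearson_r` (correlation of Z-scores over all universe
#'   k-mers) and `top10_overlap` (size of the intersection of the two top-10
#'   lists, deterministic lexicographic tie-breaking).
#' @export
ab_diagnostics <- function(tableA, tableB) {
  if (!identical(tableA$kmer, tableB$kmer))
    stop("universe mismatch between Set A and Set B tables")
  list(pearson_r = cor(tableA$z, tableB$z),
       top10_overlap = length(intersect(top_kmers(tableA, 10)$kmer,
                                        top_kmers(tableB, 10)$kmer)))
}

#' Write a combined Z-score table (TSV)
#'
#' Columns `kmer, scoreA, zA, scoreB, zB, zMerged`, sorted by `zMerged`
#' descending.
#'
#' @param tableA,tableB,tableMerged per-subset `KmerTable`s.
#' @param file output path.
#' @export
write_zscores <- function(tableA, tableB, tableMerged, file) {
  stopifnot(identical(tableA$kmer, tableB$kmer),
            identical(tableA$kmer, tableMerged$kmer))
  out <- data.frame(kmer = tableA$kmer,
                    scoreA = tableA$score, zA = tableA$z,
                    scoreB = tableB$score, zB = tableB$z,
                    zMerged = tableMerged$z)
  out <- out[order(-out$zMerged, out$kmer), ]
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an intensity TSV (probe_id, intensity, flag)
#'
#' @param file path to a tab-delimited table with a header.
#' @return `IntensityProfile`.
#' @export
read_intensities <- function(file) {
  tab <- read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (is.null(tab$flag)) tab$flag <- 0L
  intensity_profile(tab$probe_id, tab$intensity, tab$flag)
}

#' Write an intensity TSV
#'
#' @param profile `IntensityProfile`.
#' @param file output path.
#' @export
write_intensities <- function(profile, file) {
  write.table(profile, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
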