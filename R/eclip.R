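# eCLIP-side analysis: peak preparation for motif discovery input, 5-mer
# frequency profiles, correlation clustering, and IUPAC-motif k-mer rank.

#' Read a BED6 file of merged peaks into a GRanges
#'
#' BED is 0-based half-open; the returned GRanges is 1-based closed per
#' Bioconductor convention.
#'
#' @param file BED6 path (chrom, start, end, name, score, strand).
#' @return `GRanges` with `name` and `score` metadata columns.
#' @export
read_peaks_bed <- function(file) {
  tab <- read.table(file, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("expected BED6 (6 columns)")
  names(tab)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for strand-specific eCLIP peaks")
  GenomicRanges::GRanges(tab$chrom,
                         IRanges::IRanges(tab$start + 1L, tab$end),
                         strand = tab$strand,
                         name = tab$name, score = tab$score)
}

# strand-aware sequence extraction from a named DNAStringSet genome;
# returns the sense-strand sequence of each range
extract_genome_seq <- function(genome, gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  out <- character(length(gr))
  for (i in seq_along(gr)) {
    s <- Biostrings::subseq(genome[[chrom[i]]],
                            GenomicRanges::start(gr)[i],
                            GenomicRanges::end(gr)[i])
    if (as.character(GenomicRanges::strand(gr)[i]) == "-")
      s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  out
}

#' Prepare positive/negative sequence sets for motif-discovery input
#'
#' Each peak is extended by `upstream_ext` bases upstream (strand-aware: the
#' 5' direction of the annotated strand) to capture the full binding site;
#' the matched negative is a same-size window whose extended start lies
#' `neg_offset` bases upstream of the extended peak; `flank` context bases
#' are added on both sides of core and negative alike (context is for RNA
#' folding and is meant to be stripped before motif identification). Minus-
#' strand sequences are reverse-complemented, so output is always the sense
#' strand. Sequences are emitted as DNA (T, not U). Windows falling outside
#' chromosome bounds are dropped and counted.
#'
#' @param peaks `GRanges` (e.g. from [read_peaks_bed()]).
#' @param genome named `DNAStringSet` covering all peak chromosomes.
#' @param upstream_ext upstream core extension (default 20).
#' @param neg_offset distance upstream for the negative window (default 300).
#' @param flank context bases each side (default 50).
#' @return list with data.frames `positive` and `negative` (columns `name`,
#'   `chrom`, `start`, `end`, `strand`, `core`, `context`; coordinates
#'   1-based closed, core window) and `dropped` (count).
#' @export
prepare_priesstess_inputs <- function(peaks, genome, upstream_ext = 20,
                                      neg_offset = 300, flank = 50) {
  stopifnot(methods::is(peaks, "GRanges"))
  chroms <- unique(as.character(GenomicRanges::seqnames(peaks)))
  missing <- setdiff(chroms, names(genome))
  if (length(missing))
    stop("genome is missing chromosome(s): ", paste(missing, collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))

  minus <- as.character(GenomicRanges::strand(peaks)) == "-"
  core <- GenomicRanges::resize(peaks,
                                GenomicRanges::width(peaks) + upstream_ext,
                                fix = "end")
  neg <- GenomicRanges::shift(core, ifelse(minus, neg_offset, -neg_offset))

  in_bounds <- function(gr, pad) {
    st <- GenomicRanges::start(gr) - pad
    en <- GenomicRanges::end(gr) + pad
    st >= 1 & en <= lens[as.character(GenomicRanges::seqnames(gr))]
  }
  ok <- in_bounds(core, flank) & in_bounds(neg, flank)
  dropped <- sum(!ok)
  if (dropped)
    warning(sprintf("%d peak(s) dropped: extended/negative window out of chromosome bounds",
                    dropped))
  core <- core[ok]
  neg <- neg[ok]
  if (!length(core)) stop("no peaks survive the bounds check")

  ctx <- function(gr) {
    g2 <- gr
    GenomicRanges::start(g2) <- GenomicRanges::start(gr) - flank
    GenomicRanges::end(g2) <- GenomicRanges::end(gr) + flank
    g2
  }
  record <- function(gr, tag) {
    nm <- if (!is.null(gr$name)) gr$name else sprintf("peak_%d", seq_along(gr))
    data.frame(name = paste0(nm, tag),
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               core = extract_genome_seq(genome, gr),
               context = extract_genome_seq(genome, ctx(gr)),
               stringsAsFactors = FALSE)
  }
  list(positive = record(core, "_pos"),
       negative = record(neg, "_neg"),
       dropped = dropped)
}

#' Write positive/negative FASTA pair for motif-discovery input
#'
#' Writes `positive.fa` and `negative.fa` (context sequences, i.e. including
#' flanks) plus a `manifest.tsv` recording the preparation settings.
#'
#' @param prep output of [prepare_priesstess_inputs()].
#' @param dir output directory.
#' @param settings named list recorded in the manifest.
#' @export
write_priesstess_inputs <- function(prep, dir,
                                    settings = list(upstream_ext = 20,
                                                    neg_offset = 300,
                                                    flank = 50)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (side in c("positive", "negative")) {
    ss <- Biostrings::DNAStringSet(prep[[side]]$context)
    names(ss) <- prep[[side]]$name
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(side, ".fa")))
  }
  man <- data.frame(key = names(settings),
                    value = vapply(settings, as.character, character(1)))
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Count k-mer frequencies in a set of sequences
#'
#' All overlapping windows; windows containing a non-ACGT/U character are
#' skipped. Frequencies sum to 1.
#'
#' @param sequences character vector (DNA or RNA).
#' @param k word length (default 5).
#' @param as_frequency divide by the total window count (default TRUE).
#' @param alphabet `"DNA"` (names use T) or `"RNA"` (names use U).
#' @return named numeric vector of length `4^k`.
#' @export
count_kmer_freq <- function(sequences, k = 5, as_frequency = TRUE,
                            alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  counts <- as.numeric(count_kmers_cpp(sequences, as.integer(k)))
  total <- sum(counts)
  if (total == 0) stop("no countable ", k, "-mer windows in the input")
  names(counts) <- if (alphabet == "RNA") all_kmers(k)
                   else rna_to_dna(all_kmers(k))
  if (as_frequency) counts / total else counts
}

#' Correlate and cluster k-mer profiles across experiments
#'
#' Pairwise Pearson correlation of per-experiment k-mer profiles, then
#' hierarchical agglomerative clustering with centroid linkage on the
#' distance `1 - r`. Experiments with fewer than `min_peaks` peaks are
#' excluded before correlating and reported.
#'
#' @param profiles numeric matrix (experiments x k-mers, rownames =
#'   experiment ids) or list of named vectors.
#' @param peak_counts per-experiment peak counts (for the filter); NULL
#'   skips filtering.
#' @param min_peaks filter threshold (default 1000).
#' @param k if not NULL, also cut the tree into `k` cluster labels.
#' @return list with `correlation` (symmetric, unit diagonal), `hclust`,
#'   `labels` (or NULL), `excluded` (character vector of experiment ids).
#' @export
correlate_and_cluster <- function(profiles, peak_counts = NULL,
                                  min_peaks = 1000, k = NULL) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("exp_%d", seq_len(nrow(profiles)))
  excluded <- character(0)
  if (!is.null(peak_counts)) {
    stopifnot(length(peak_counts) == nrow(profiles))
    drop <- peak_counts < min_peaks
    excluded <- rownames(profiles)[drop]
    profiles <- profiles[!drop, , drop = FALSE]
  }
  if (nrow(profiles) < 2)
    stop(sprintf("need >= 2 profiles after the %d-peak filter (have %d)",
                 min_peaks, nrow(profiles)))
  r <- cor(t(profiles))
  hc <- hclust(as.dist(1 - r), method = "centroid")
  list(correlation = r, hclust = hc,
       labels = if (!is.null(k)) cutree(hc, k = k) else NULL,
       excluded = excluded)
}

#' Write clustering outputs (correlation TSV + Newick dendrogram)
#'
#' @param res result of [correlate_and_cluster()].
#' @param dir output directory; writes `correlation.tsv` and
#'   `dendrogram.nwk`.
#' @export
write_cluster_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(experiment = rownames(res$correlation),
                         res$correlation, check.names = FALSE),
              file.path(dir, "correlation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(ape::as.phylo(res$hclust), file.path(dir, "dendrogram.nwk"))
  invisible(dir)
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

#' Rank of the first k-mer matching an IUPAC motif
#'
#' k-mers are ranked by frequency (descending; ties broken lexicographically)
#' and the rank of the most frequent k-mer matching any contiguous length-k
#' window of the IUPAC pattern is returned (1-based). `NA` if no k-mer
#' matches ("absent").
#'
#' @param profile named frequency vector over all k-mers (from
#'   [count_kmer_freq()]).
#' @param iupac IUPAC string, length >= k.
#' @return integer rank or `NA_integer_`.
#' @export
iupac_rank <- function(profile, iupac) {
  kmers <- names(profile)
  k <- nchar(kmers[1])
  iupac <- toupper(iupac)
  sym <- strsplit(iupac, "")[[1]]
  if (!all(sym %in% names(IUPAC_SETS)))
    stop("invalid IUPAC symbol(s): ",
         paste(setdiff(sym, names(IUPAC_SETS)), collapse = ", "))
  if (length(sym) < k) stop("IUPAC motif must have length >= ", k)
  sets <- lapply(sym, function(s) IUPAC_SETS[[s]])
  kd <- chartr("Uu", "Tt", kmers)
  matches_window <- function(kmer) {
    b <- strsplit(kmer, "")[[1]]
    for (o in 0:(length(sets) - k)) {
      if (all(mapply(function(bb, st) bb %in% st, b, sets[o + seq_len(k)])))
        return(TRUE)
    }
    FALSE
  }
  # only observed k-mers participate in the ranking; "absent" means no
  # observed k-mer matches the motif
  ord <- order(-profile, kmers)
  ord <- ord[profile[ord] > 0]
  for (r in seq_along(ord)) {
    if (matches_window(kd[ord[r]])) return(r)
  }
  NA_integer_
}
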