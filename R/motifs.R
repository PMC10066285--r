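# Position frequency matrices from top-scoring 7-mers, information content,
# and a column-correlation motif comparison metric.

#' Position frequency matrix constructor
#'
#' @param mat 4 x L numeric matrix of base probabilities, rows A, C, G, U;
#'   each column must sum to 1.
#' @param name motif name.
#' @param support number of weighted k-mers aggregated (or NA).
#' @return matrix of class `PFM`.
#' @export
pfm <- function(mat, name = "", support = NA_integer_) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PFM must have 4 rows (A, C, G, U)")
  if (any(mat < 0)) stop("PFM entries must be nonnegative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) stop("PFM columns must sum to 1")
  rownames(mat) <- RNA_BASES
  structure(mat, name = name, support = support, class = "PFM")
}

#' @export
print.PFM <- function(x, ...) {
  cat(sprintf("PFM '%s': %d columns, consensus %s, %.2f bits\n",
              attr(x, "name"), ncol(x), consensus_string(x),
              information_content(x)$total))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Point-mass-like PFM from a consensus k-mer
#'
#' Each column puts `1 - 3 * mismatch` on the consensus base and `mismatch`
#' on each other base.
#'
#' @param consensus RNA string over A/C/G/U.
#' @param mismatch per-base off-consensus probability (default 0.05).
#' @return `PFM`.
#' @export
consensus_pfm <- function(consensus, mismatch = 0.05) {
  consensus <- toupper(dna_to_rna(consensus))
  stopifnot(mismatch >= 0, mismatch < 1 / 3)
  b <- strsplit(consensus, "")[[1]]
  if (!all(b %in% RNA_BASES)) stop("consensus must be RNA over {A,C,G,U}")
  mat <- matrix(mismatch, nrow = 4, ncol = length(b),
                dimnames = list(RNA_BASES, NULL))
  mat[cbind(match(b, RNA_BASES), seq_along(b))] <- 1 - 3 * mismatch
  pfm(mat, name = consensus)
}

#' Consensus string of a PFM (majority base per column)
#'
#' @param p `PFM`.
#' @return character scalar.
#' @export
consensus_string <- function(p) {
  paste(RNA_BASES[apply(unclass(p), 2, which.max)], collapse = "")
}

# number of identical bases when `kmer` is laid at `offset` relative to `ref`
# (offset > 0 shifts kmer rightward); positions outside the overlap ignored
offset_identity <- function(ref, kmer, offset) {
  rb <- strsplit(ref, "")[[1]]
  kb <- strsplit(kmer, "")[[1]]
  ri <- seq_along(rb)
  ki <- ri - offset
  ok <- ki >= 1 & ki <= length(kb)
  sum(rb[ok] == kb[ki[ok]])
}

#' Build a motif from the top-scoring k-mers
#'
#' Takes the `n_top` highest-Z k-mers (lexicographic tie-break), aligns each
#' ungapped to the top k-mer at the offset in `-offset_range..offset_range`
#' maximizing position-wise identity (ties: smallest `|offset|`, negative
#' first), stacks them weighted by `max(Z, 0)`, adds a pseudocount per cell,
#' trims flanking columns whose information content is below `ic_trim` bits,
#' and column-normalizes.
#'
#' @param table `KmerTable`.
#' @param n_top number of k-mers to stack (default 10).
#' @param offset_range maximum absolute alignment offset (default 3).
#' @param pseudocount added to every cell before normalization (default 0.01).
#' @param ic_trim flank-trimming threshold in bits (default 0.1).
#' @return `PFM` with `support = n_top`.
#' @export
build_motif <- function(table, n_top = 10, offset_range = 3,
                        pseudocount = 0.01, ic_trim = 0.1) {
  finite <- is.finite(table$z)
  if (sum(finite) < n_top)
    stop(sprintf("need at least %d k-mers with finite Z (have %d)",
                 n_top, sum(finite)))
  top <- top_kmers(table[finite, , drop = FALSE], n_top)
  ref <- top$kmer[1]
  k <- nchar(ref)
  offsets <- vapply(seq_len(n_top), function(i) {
    cand <- (-offset_range):offset_range
    ident <- vapply(cand, function(o) offset_identity(ref, top$kmer[i], o),
                    numeric(1))
    cand[order(-ident, abs(cand), cand)][1]
  }, numeric(1))

  ncol_full <- 2 * offset_range + k
  counts <- matrix(0, nrow = 4, ncol = ncol_full,
                   dimnames = list(RNA_BASES, NULL))
  w <- pmax(top$z, 0)
  for (i in seq_len(n_top)) {
    b <- strsplit(top$kmer[i], "")[[1]]
    cols <- offsets[i] + offset_range + seq_len(k)
    counts[cbind(match(b, RNA_BASES), cols)] <-
      counts[cbind(match(b, RNA_BASES), cols)] + w[i]
  }
  counts <- counts + pseudocount
  probs <- sweep(counts, 2, colSums(counts), "/")
  ic <- apply(probs, 2, column_ic)
  keep <- which(ic >= ic_trim)
  if (!length(keep)) {
    # fully uninformative stack (all weights zero): keep the core k columns
    keep <- offset_range + seq_len(k)
  } else keep <- keep[1]:keep[length(keep)]
  pfm(probs[, keep, drop = FALSE], name = ref, support = n_top)
}

column_ic <- function(p) {
  p <- p[p > 0]
  2 + sum(p * log2(p))
}

#' Information content of a PFM
#'
#' Per column, `IC = 2 + sum(p * log2 p)` bits against a uniform background
#' (`0 * log 0 = 0`); the total is the sum over columns.
#'
#' @param p `PFM`.
#' @return list with `total` and `per_column`.
#' @export
information_content <- function(p) {
  per <- apply(unclass(p), 2, column_ic)
  list(total = sum(per), per_column = per)
}

# Pearson correlation of two probability 4-vectors; columns with zero
# variance (uniform) contribute 0
column_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

align_score <- function(p, q, offset, min_overlap) {
  # offset: columns of q shifted rightward relative to p
  pi <- seq_len(ncol(p))
  qi <- pi - offset
  ok <- qi >= 1 & qi <= ncol(q)
  if (sum(ok) < min_overlap) return(NA_real_)
  mean(vapply(which(ok), function(i) column_cor(p[, i], q[, i - offset]),
              numeric(1)))
}

best_alignment <- function(p, q, min_overlap) {
  offs <- (-(ncol(q) - min_overlap)):(ncol(p) - min_overlap)
  sc <- vapply(offs, function(o) align_score(p, q, o, min_overlap),
               numeric(1))
  if (all(is.na(sc))) return(NULL)
  ord <- order(-sc, abs(offs), offs, na.last = TRUE)
  list(score = sc[ord[1]], offset = offs[ord[1]])
}

#' Compare two motifs by mean column correlation
#'
#' Over all ungapped offsets with at least `min_overlap` overlapping
#' columns, the similarity is the mean per-column Pearson correlation of the
#' base-probability vectors at the best-scoring offset. The empirical p is
#' the fraction of column-shuffled nulls scoring at least as high, averaged
#' over shuffling `q` against `p` and `p` against `q` (making it symmetric).
#'
#' @param p,q `PFM`s.
#' @param min_overlap minimum overlapping columns (default 4).
#' @param n_null shuffled nulls per orientation (default 1000; 0 skips the
#'   p-value).
#' @param seed integer seed for the shuffles.
#' @return list with `score`, `offset`, `p_value` (NA when `n_null = 0`).
#' @export
compare_motifs <- function(p, q, min_overlap = 4, n_null = 1000, seed = 0) {
  stopifnot(inherits(p, "PFM"), inherits(q, "PFM"))
  if (min(ncol(p), ncol(q)) < min_overlap)
    stop(sprintf("motifs too short: need >= %d columns for any alignment",
                 min_overlap))
  best <- best_alignment(unclass(p), unclass(q), min_overlap)
  if (is.null(best)) stop("no alignment with sufficient overlap")
  p_value <- NA_real_
  if (n_null > 0) {
    null_one <- function(a, b) {
      vapply(seq_len(n_null), function(i) {
        perm <- sample.int(ncol(b))
        best_alignment(a, b[, perm, drop = FALSE], min_overlap)$score
      }, numeric(1))
    }
    p_value <- with_seed(seed, {
      nulls <- c(null_one(unclass(p), unclass(q)),
                 null_one(unclass(q), unclass(p)))
      mean(nulls >= best$score - 1e-12)
    })
  }
  list(score = best$score, offset = best$offset, p_value = p_value)
}

#' Write motifs in minimal MEME format
#'
#' @param pfms a `PFM` or list of `PFM`s.
#' @param file output path.
#' @param background background frequencies (default uniform).
#' @export
write_meme <- function(pfms, file, background = rep(0.25, 4)) {
  if (inherits(pfms, "PFM")) pfms <- list(pfms)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", RNA_BASES, background),
                     collapse = " "), ""), con)
  for (i in seq_along(pfms)) {
    p <- pfms[[i]]
    nm <- attr(p, "name")
    if (is.null(nm) || !nzchar(nm)) nm <- sprintf("motif_%d", i)
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(p), max(1L, as.integer(attr(p, "support")), na.rm = TRUE)), con)
    writeLines(apply(unclass(p), 2, function(col)
      paste(sprintf("%.6f", col), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(file)
}

#' Write / read a PFM as plain TSV
#'
#' Columns `position`, `A`, `C`, `G`, `U`.
#'
#' @param p `PFM`.
#' @param file path.
#' @export
write_pfm_tsv <- function(p, file) {
  tab <- data.frame(position = seq_len(ncol(p)), t(unclass(p)))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pfm_tsv
#' @param name motif name for the read PFM.
#' @export
read_pfm_tsv <- function(file, name = "") {
  tab <- read.table(file, sep = "\t", header = TRUE)
  pfm(t(as.matrix(tab[, c("A", "C", "G", "U")])), name = name)
}

#' Set A vs Set B Z-score scatter
#'
#' The standard reproducibility diagnostic: every scored 7-mer plotted by
#' its Set A and Set B Z-scores, shared top-10 7-mers highlighted.
#'
#' @param tableA,tableB per-set `KmerTable`s.
#' @param main title (default reports Pearson r).
#' @export
plot_ab_scatter <- function(tableA, tableB, main = NULL) {
  d <- ab_diagnostics(tableA, tableB)
  if (is.null(main))
    main <- sprintf("Set A vs Set B (r = %.2f, top-10 overlap %d)",
                    d$pearson_r, d$top10_overlap)
  shared <- intersect(top_kmers(tableA, 10)$kmer, top_kmers(tableB, 10)$kmer)
  hi <- tableA$kmer %in% shared
  graphics::plot(tableA$z, tableB$z, pch = 16, cex = 0.4,
                 col = ifelse(hi, "#D62839", "#00000044"),
                 xlab = "Set A Z-score", ylab = "Set B Z-score", main = main)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(d)
}

#' Schematic sequence logo
#'
#' Base-graphics rendering with letter heights proportional to each base's
#' share of the column information content (a schematic, not a typographic
#' logo).
#'
#' @param p `PFM`.
#' @param main plot title.
#' @export
plot_logo <- function(p, main = attr(p, "name")) {
  ic <- information_content(p)$per_column
  L <- ncol(p)
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, 2),
                 xlab = "position", ylab = "bits", main = main, xaxt = "n")
  graphics::axis(1, at = seq_len(L))
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", U = "#D62839")
  for (j in seq_len(L)) {
    h <- unclass(p)[, j] * ic[j]
    ord <- order(h)
    y0 <- 0
    for (b in ord) {
      if (h[b] > 0.01)
        graphics::text(j, y0 + h[b] / 2, RNA_BASES[b], col = cols[b],
                       cex = 0.8 + 2.2 * h[b] / 2, font = 2)
      y0 <- y0 + h[b]
    }
  }
  invisible(p)
}
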