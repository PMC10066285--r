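# Shared helpers: seeding, robust statistics, k-mer string utilities.

RNA_BASES <- c("A", "C", "G", "U")

# the grouped-scoring code uses data.table syntax internally
.datatable.aware <- TRUE

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' All k-mers over an alphabet, in lexicographic order
#'
#' Order matches the internal integer k-mer encoding (A=0 < C=1 < G=2 < U=3),
#' so `all_kmers(k)[code + 1]` decodes a k-mer code.
#'
#' @param k word length.
#' @param alphabet character vector of single letters (default RNA).
#' @return character vector of length `length(alphabet)^k`.
#' @export
all_kmers <- function(k, alphabet = RNA_BASES) {
  stopifnot(k >= 1, k <= 12)
  g <- do.call(expand.grid,
               c(rep(list(alphabet), k), stringsAsFactors = FALSE))
  do.call(paste0, g[, k:1, drop = FALSE])
}

# mean of x after dropping floor(n * trim) observations from each tail
trimmed_mean <- function(x, trim = 0) {
  n <- length(x)
  if (n == 0L) return(NaN)
  drop <- floor(n * trim)
  if (drop == 0L) return(mean(x))
  x <- sort(x)
  mean(x[(drop + 1L):(n - drop)])
}

# moment-based sample skewness g1 = m3 / m2^(3/2)
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# excess kurtosis g2 = m4 / m2^2 - 3
kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}

#' AUROC by the rank (Wilcoxon-Mann-Whitney) statistic
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 vector, TRUE/1 = positive class.
#' @return scalar in \[0, 1\]; ties receive mean ranks.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("auroc needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Transliterate between RNA and DNA alphabets
#'
#' @param x character vector of sequences.
#' @return `x` with U<->T swapped (case preserved).
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# fast string assembly from 0-based symbol codes
codes_to_string <- function(codes, alphabet = RNA_BASES) {
  pts <- vapply(alphabet, utf8ToInt, integer(1))
  intToUtf8(pts[codes + 1L])
}
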