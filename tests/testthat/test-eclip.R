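# eCLIP peak preparation, 5-mer profiles, clustering, IUPAC rank.

make_genome <- function(seed = 5, lens = c(chr1 = 5000, chr2 = 2000)) {
  withr::with_seed(seed, Biostrings::DNAStringSet(setNames(
    vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
      character(1)),
    names(lens))))
}

write_bed <- function(df) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  f
}

test_that("peak preparation follows the 20/300/50 coordinate rules on + strand", {
  genome <- make_genome()
  f <- write_bed(data.frame("chr1", 1000, 1010, "p1", 0, "+"))
  prep <- prepare_priesstess_inputs(read_peaks_bed(f), genome)
  pos <- prep$positive
  # BED [1000,1010) + 20 nt upstream -> core [980,1010) (1-based 981..1010)
  expect_equal(pos$start, 981)
  expect_equal(pos$end, 1010)
  expect_equal(nchar(pos$core), 30)
  expect_equal(nchar(pos$context), 130)            # core + 2x50 flanks
  g <- as.character(genome[["chr1"]])
  expect_equal(pos$core, substr(g, 981, 1010))
  expect_equal(pos$context, substr(g, 931, 1060))  # [930,1060) 0-based
  # negative: same size, 300 upstream of the extended peak
  neg <- prep$negative
  expect_equal(neg$start, 981 - 300)
  expect_equal(nchar(neg$core), nchar(pos$core))   # L + 20
  expect_equal(prep$dropped, 0)
})

test_that("minus-strand peaks extend upstream on the high-coordinate side and revcomp", {
  genome <- make_genome()
  f <- write_bed(data.frame("chr1", 2000, 2050, "m1", 0, "-"))
  prep <- prepare_priesstess_inputs(read_peaks_bed(f), genome)
  pos <- prep$positive
  expect_equal(pos$start, 2001)
  expect_equal(pos$end, 2070)                      # +20 on the 5' (high) side
  plus_seq <- substr(as.character(genome[["chr1"]]), 2001, 2070)
  expect_equal(pos$core, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_seq))))
  expect_equal(prep$negative$start, 2001 + 300)    # upstream = +300 on minus
})

test_that("out-of-bounds windows are dropped with a count; missing chrom errors", {
  genome <- make_genome()
  f <- write_bed(data.frame(c("chr1", "chr2"), c(1000, 50), c(1010, 80),
                            c("ok", "edge"), 0, "+"))
  expect_warning(prep <- prepare_priesstess_inputs(read_peaks_bed(f), genome),
                 "dropped")
  expect_equal(prep$dropped, 1)
  expect_equal(nrow(prep$positive), 1)
  f2 <- write_bed(data.frame("chrX", 100, 200, "x", 0, "+"))
  expect_error(prepare_priesstess_inputs(read_peaks_bed(f2), genome),
               "missing chromosome")
})

test_that("FASTA pair and manifest are written for downstream motif discovery", {
  genome <- make_genome()
  f <- write_bed(data.frame("chr1", c(1000, 3000), c(1040, 3030),
                            c("p1", "p2"), 0, "+"))
  prep <- prepare_priesstess_inputs(read_peaks_bed(f), genome)
  d <- withr::local_tempdir()
  write_priesstess_inputs(prep, d)
  pos <- Biostrings::readDNAStringSet(file.path(d, "positive.fa"))
  neg <- Biostrings::readDNAStringSet(file.path(d, "negative.fa"))
  expect_equal(length(pos), 2)
  expect_equal(length(neg), 2)
  expect_equal(unname(Biostrings::width(pos)), unname(Biostrings::width(neg)))
  man <- read.table(file.path(d, "manifest.tsv"), header = TRUE, sep = "\t")
  expect_true(all(c("upstream_ext", "neg_offset", "flank") %in% man$key))
})

test_that("5-mer counting: hand counts, concatenation invariance, N handling", {
  f1 <- count_kmer_freq("AAAAAA", 5, as_frequency = FALSE)
  expect_equal(unname(f1["AAAAA"]), 2)
  expect_equal(sum(f1), 2)
  f2 <- count_kmer_freq("ACGTACGTA", 5, as_frequency = FALSE)
  expect_equal(sum(f2), 5)                        # 5 windows
  expect_equal(unname(f2["ACGTA"]), 2)
  # counting sequences separately sums counts (no cross-boundary windows)
  joint <- count_kmer_freq(c("ACGTACGTA", "AAAAAA"), 5, as_frequency = FALSE)
  expect_equal(joint, f1 + f2)
  # windows containing N are skipped
  fn <- count_kmer_freq("AAAANAAAAA", 5, as_frequency = FALSE)
  expect_equal(unname(fn["AAAAA"]), 1)
  expect_equal(sum(fn), 1)
  expect_error(count_kmer_freq("NNNNNN", 5), "no countable")
  # frequencies sum to 1
  expect_equal(sum(count_kmer_freq(c("ACGTACGTA", "GGGCC"), 5)), 1)
})

test_that("correlation clustering matches a brute-force centroid-linkage oracle", {
  withr::with_seed(23, {
    for (rep in 1:4) {
      n <- sample(4:6, 1)
      profs <- matrix(runif(n * 64), n,
                      dimnames = list(sprintf("e%d", 1:n), NULL))
      res <- correlate_and_cluster(profs, min_peaks = 0)
      oracle <- naive_centroid_linkage(1 - res$correlation)
      expect_equal(res$hclust$height, oracle$heights, tolerance = 1e-12)
      expect_identical(hclust_merge_sets(res$hclust), oracle$sets)
    }
  })
})

test_that("duplicate profiles merge first; correlation matrix is well-formed", {
  base <- count_kmer_freq("ACGTACGTAGGCCATGCA", 3, as_frequency = TRUE)
  other <- count_kmer_freq("GGGGGGGGCCCCCCCC", 3, as_frequency = TRUE)
  profs <- rbind(a = base, b = base, c = other)
  res <- correlate_and_cluster(profs, min_peaks = 0)
  expect_equal(unname(diag(res$correlation)), rep(1, 3))
  expect_equal(res$correlation, t(res$correlation))
  expect_equal(res$correlation["a", "b"], 1)
  expect_identical(sort(res$hclust$merge[1, ]), c(-2L, -1L))  # a,b first
})

test_that("the min_peaks filter excludes and reports shallow experiments", {
  profs <- matrix(runif(4 * 64), 4,
                  dimnames = list(c("deep1", "deep2", "shallow", "deep3"), NULL))
  res <- correlate_and_cluster(profs, peak_counts = c(2000, 1500, 400, 1200),
                               min_peaks = 1000)
  expect_identical(res$excluded, "shallow")
  expect_equal(nrow(res$correlation), 3)
  expect_error(correlate_and_cluster(profs, peak_counts = c(2000, 10, 10, 10),
                                     min_peaks = 1000), ">= 2 profiles")
})

test_that("cluster outputs: correlation TSV and Newick tree round-trip", {
  profs <- withr::with_seed(44, matrix(runif(4 * 64), 4,
                                       dimnames = list(letters[1:4], NULL)))
  res <- correlate_and_cluster(profs, min_peaks = 0)
  d <- withr::local_tempdir()
  write_cluster_outputs(res, d)
  tab <- read.table(file.path(d, "correlation.tsv"), header = TRUE,
                    sep = "\t", check.names = FALSE)
  expect_equal(as.matrix(tab[, letters[1:4]]),
               unname(res$correlation), ignore_attr = TRUE)
  tree <- ape::read.tree(file.path(d, "dendrogram.nwk"))
  expect_setequal(tree$tip.label, letters[1:4])
})

test_that("IUPAC rank: universal match, explicit pattern, ranked position, absent", {
  p <- count_kmer_freq(c("GGGGGTTTTTT"), 5, as_frequency = TRUE)
  expect_equal(iupac_rank(p, "NNNNN"), 1)
  # construct a profile with known ranking: TTTTT (2 windows) > GGGGG (1) > mixed
  counts <- count_kmer_freq("GGGGG", 5, as_frequency = FALSE) +
            2 * count_kmer_freq("TTTTT", 5, as_frequency = FALSE) +
            3 * count_kmer_freq("ACGTA", 5, as_frequency = FALSE)
  expect_equal(iupac_rank(counts, "ACGTA"), 1)
  expect_equal(iupac_rank(counts, "TTTTT"), 2)
  expect_equal(iupac_rank(counts, "GGGGG"), 3)
  # GU-rich IUPAC window matching: KKKKK = G/T runs
  expect_equal(iupac_rank(counts, "KKKKK"), 2)    # TTTTT is the top K-run
  # longer IUPAC: any 5-window may match
  expect_equal(iupac_rank(counts, "AACGTAA"), 1)  # window ACGTA matches
  expect_true(is.na(iupac_rank(counts, "CCCCC")))
  expect_error(iupac_rank(counts, "XYZZY"), "invalid IUPAC")
})
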