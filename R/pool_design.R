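# Pool design: de Bruijn cycle generation, chopping into probes, and the
# balanced Set A / Set B split with per-7-mer coverage guarantees.

#' Scored k-mer universe
#'
#' The set of k-mers over which probe intensities are summarized. For the
#' standard 7-mer analysis the two SapI/BspQI restriction-site 7-mers
#' (GCUCUUC and its complement-derived CGAGAAG) are excluded from scoring
#' (they are removed from the counted set, not from probe sequences),
#' leaving 4^7 - 2 = 16,382 members.
#'
#' @param k word length (default 7).
#' @param excluded RNA k-mers dropped from the scored set.
#' @return object of class `KmerUniverse` with fields `k`, `excluded`,
#'   `members` (lexicographically sorted).
#' @export
kmer_universe <- function(k = 7, excluded = c("GCUCUUC", "CGAGAAG")) {
  stopifnot(k >= 1, k <= 12)
  excluded <- toupper(dna_to_rna(excluded))
  if (length(excluded) && any(nchar(excluded) != k))
    stop("excluded k-mers must have length k")
  members <- all_kmers(k)
  u <- list(k = k, excluded = excluded,
            members = setdiff(members, excluded))
  class(u) <- "KmerUniverse"
  u
}

#' @export
print.KmerUniverse <- function(x, ...) {
  cat(sprintf("KmerUniverse: k=%d, %d members (%d excluded: %s)\n",
              x$k, length(x$members), length(x$excluded),
              paste(x$excluded, collapse = ", ")))
  invisible(x)
}

#' Generate a de Bruijn sequence
#'
#' Constructs a cyclic sequence of length `|alphabet|^order` containing every
#' length-`order` word exactly once when read cyclically, via a Hierholzer
#' Eulerian circuit on the (order-1)-mer graph with seeded edge ordering.
#' Deterministic given `(order, seed)`.
#'
#' @param order de Bruijn order (word length guaranteed unique coverage).
#' @param alphabet four single-character symbols.
#' @param seed integer seed controlling the edge ordering.
#' @param max_order capacity bound; `4^order` cycles above it are refused.
#' @return character scalar (the cycle, linearized) with attributes `order`,
#'   `alphabet`, `seed`.
#' @examples
#' nchar(generate_debruijn(2))  # 16
#' @export
generate_debruijn <- function(order, alphabet = RNA_BASES, seed = 0,
                              max_order = 12) {
  stopifnot(order >= 1)
  if (length(alphabet) != 4L || any(nchar(alphabet) != 1L))
    stop("alphabet must be four single characters")
  if (order > max_order)
    stop(sprintf("capacity error: order %d exceeds the configured bound %d (4^%d symbols)",
                 order, max_order, order))
  n_nodes <- 4^(order - 1)
  perm <- with_seed(seed, {
    key <- runif(4L * n_nodes)
    grp <- rep.int(seq_len(n_nodes), rep.int(4L, n_nodes))
    sym <- rep.int(0:3, n_nodes)
    sym[order(grp, key)]
  })
  codes <- debruijn_cycle_cpp(as.integer(order), as.integer(perm))
  cyc <- codes_to_string(codes, alphabet)
  structure(cyc, order = order, alphabet = alphabet, seed = seed)
}

#' Default probe window schedule
#'
#' Draws probe lengths uniformly from `lengths` with steps equal to
#' `length - preserve_m + 1` (the largest step under which consecutive
#' windows still cover every `preserve_m`-window of the cycle), and emits
#' enough windows for `n_wraps` complete passes around the cycle. Successive
#' passes start at phase-shifted positions, giving interleaved tilings.
#'
#' @param cycle_length length of the cycle being chopped.
#' @param lengths candidate probe lengths (default 30:41).
#' @param preserve_m word length whose cyclic occurrences must all be
#'   retained in at least one probe (default 11).
#' @param n_wraps complete passes around the cycle (default 2).
#' @param seed integer seed.
#' @return data.frame with columns `length`, `step`.
#' @export
default_window_schedule <- function(cycle_length, lengths = 30:41,
                                    preserve_m = 11, n_wraps = 2, seed = 0) {
  stopifnot(cycle_length >= max(lengths), all(lengths >= preserve_m))
  need <- n_wraps * cycle_length
  mean_step <- mean(lengths) - preserve_m + 1
  n_guess <- ceiling(need / mean_step) + 64L
  with_seed(seed, {
    len <- sample(lengths, n_guess, replace = TRUE)
    step <- len - preserve_m + 1L
    while (sum(step) < need) {
      extra <- sample(lengths, 64L, replace = TRUE)
      len <- c(len, extra)
      step <- c(step, extra - preserve_m + 1L)
    }
    keep <- seq_len(which(cumsum(step) >= need)[1])
    data.frame(length = len[keep], step = step[keep])
  })
}

#' Chop a cycle into a probe pool
#'
#' Extracts consecutive windows from the circular sequence following
#' `window_schedule` (window i+1 starts `step[i]` after window i, wrapping),
#' truncated to exactly `target_count` probes. Requires every step to be at
#' most `length - preserve_m + 1`, so that, as long as at least one complete
#' wrap of the cycle survives truncation, every `preserve_m`-window of the
#' cycle is contained in some probe.
#'
#' @param cycle character scalar (from [generate_debruijn()]) or any string
#'   treated as circular.
#' @param target_count exact number of probes to emit.
#' @param window_schedule data.frame(length, step); default built by
#'   [default_window_schedule()].
#' @param preserve_m coverage word length (default 11).
#' @param seed seed forwarded to the default schedule.
#' @return `ProbePool` without set labels (`set_label` all `NA`).
#' @export
chop_pool <- function(cycle, target_count, window_schedule = NULL,
                      preserve_m = 11, seed = 0) {
  n <- nchar(cycle)
  if (is.null(window_schedule)) {
    wraps <- 2
    repeat {
      window_schedule <- default_window_schedule(n, preserve_m = preserve_m,
                                                 n_wraps = wraps, seed = seed)
      if (nrow(window_schedule) >= target_count || wraps > 64) break
      wraps <- wraps + 1
    }
  }
  stopifnot(is.data.frame(window_schedule),
            all(c("length", "step") %in% names(window_schedule)))
  len <- as.integer(window_schedule$length)
  step <- as.integer(window_schedule$step)
  if (any(step > len - preserve_m + 1L))
    stop(sprintf("precondition violation: every step must be <= length - %d + 1 to preserve %d-mer coverage",
                 preserve_m, preserve_m))
  if (any(step < 1L) || any(len < 1L)) stop("lengths and steps must be positive")
  if (nrow(window_schedule) < target_count)
    stop(sprintf("design error: schedule yields only %d windows, cannot reach target_count %d",
                 nrow(window_schedule), target_count))
  len <- len[seq_len(target_count)]
  step <- step[seq_len(target_count)]
  if (sum(step) < n)
    stop(sprintf("design error: truncation to %d probes leaves the first wrap incomplete (%d of %d positions); %d-mer coverage would be lost",
                 target_count, sum(step), n, preserve_m))
  starts <- 1 + c(0, cumsum(as.numeric(step))[-target_count]) %% n
  ext <- paste0(cycle, substr(cycle, 1, max(len) - 1L))
  seqs <- substring(ext, starts, starts + len - 1L)
  probes <- data.frame(
    probe_id = sprintf("probe_%07d", seq_len(target_count)),
    sequence = seqs,
    set_label = NA_character_,
    stringsAsFactors = FALSE
  )
  probe_pool(probes, design_meta = list(
    debruijn_order = attr(cycle, "order"),
    seed = seed,
    preserve_m = preserve_m,
    window_schedule = window_schedule[seq_len(target_count), ]
  ))
}

#' ProbePool constructor
#'
#' @param probes data.frame with columns `probe_id`, `sequence` (RNA over
#'   A/C/G/U), `set_label` (`"A"`, `"B"`, or `NA` before the split).
#' @param design_meta free-form list recording how the pool was built.
#' @return object of class `ProbePool`.
#' @export
probe_pool <- function(probes, design_meta = list()) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "sequence") %in% names(probes)))
  if (is.null(probes$set_label)) probes$set_label <- NA_character_
  if (anyDuplicated(probes$probe_id)) stop("probe_ids must be unique")
  if (any(grepl("[^ACGU]", probes$sequence)))
    stop("probe sequences must be RNA over {A,C,G,U}")
  bad <- !probes$set_label %in% c("A", "B", NA)
  if (any(bad)) stop("set_label must be 'A', 'B', or NA")
  structure(list(probes = probes, design_meta = design_meta),
            class = "ProbePool")
}

#' @export
print.ProbePool <- function(x, ...) {
  lens <- nchar(x$probes$sequence)
  tab <- table(factor(x$probes$set_label, levels = c("A", "B")), useNA = "ifany")
  cat(sprintf("ProbePool: %d probes, lengths %d-%d\n",
              nrow(x$probes), min(lens), max(lens)))
  cat(sprintf("  Set A: %d  Set B: %d  unassigned: %d\n",
              tab[["A"]], tab[["B"]],
              sum(is.na(x$probes$set_label))))
  if (!is.null(x$design_meta$debruijn_order))
    cat(sprintf("  de Bruijn order %d, seed %s\n",
                x$design_meta$debruijn_order,
                format(x$design_meta$seed)))
  invisible(x)
}

# total k-mer occurrence counts (with multiplicity) across a character
# vector of sequences, named by k-mer
pool_kmer_counts <- function(sequences, k) {
  counts <- count_kmers_cpp(sequences, as.integer(k))
  names(counts) <- all_kmers(k)
  counts
}

#' Split a pool into balanced Set A and Set B
#'
#' Initial assignment alternates probes between the sets (probes are
#' interleaved tilings of the cycle, so alternation spreads every k-mer's
#' occurrences roughly evenly); greedy repair then moves probes from the
#' richer set to the poorer one for any universe k-mer whose per-set
#' occurrence count falls below `min_per_set`.
#'
#' @param pool `ProbePool`.
#' @param universe `KmerUniverse` (default: 7-mers minus restriction sites).
#' @param min_per_set minimum occurrences required in each set for every
#'   universe member (default 155).
#' @param seed integer seed (tie-breaking in repair).
#' @param max_repair bound on repair sweeps.
#' @return the pool with `set_label` filled in.
#' @export
split_sets <- function(pool, universe = kmer_universe(), min_per_set = 155,
                       seed = 0, max_repair = 25) {
  stopifnot(inherits(pool, "ProbePool"), inherits(universe, "KmerUniverse"))
  seqs <- pool$probes$sequence
  np <- length(seqs)
  if (np < 2L) stop("need at least 2 probes to split")
  k <- universe$k
  member_idx <- match(universe$members, all_kmers(k))

  total <- count_kmers_cpp(seqs, as.integer(k))[member_idx]
  short <- total < 2L * min_per_set
  if (any(short))
    stop(sprintf("unsatisfiable split: %d universe %d-mers have pool totals below 2*min_per_set (e.g. %s: %d)",
                 sum(short), k, universe$members[which(short)[1]],
                 total[which(short)[1]]))

  in_a <- seq_len(np) %% 2L == 1L
  count_a <- count_kmers_cpp(seqs[in_a], as.integer(k))[member_idx]
  count_b <- total - count_a

  it <- 0L
  with_seed(seed, {
    repeat {
      def_a <- min_per_set - count_a
      def_b <- min_per_set - count_b
      bad <- which(def_a > 0L | def_b > 0L)
      if (!length(bad) || it >= max_repair) break
      it <- it + 1L
      for (j in bad) {
        kmer <- universe$members[j]
        deficit_in_a <- (min_per_set - count_a[j]) > 0L
        donor <- if (deficit_in_a) !in_a else in_a
        cand <- which(donor & grepl(kmer, seqs, fixed = TRUE))
        if (!length(cand)) next
        # probes with the most copies of the deficient k-mer move first
        copies <- vapply(cand, function(i)
          count_kmers_cpp(seqs[i], as.integer(k))[member_idx[j]], integer(1))
        cand <- cand[order(-copies, runif(length(cand)))]
        need <- abs(if (deficit_in_a) min_per_set - count_a[j]
                    else min_per_set - count_b[j])
        moved <- 0L
        for (i in cand) {
          if (moved >= need) break
          delta <- count_kmers_cpp(seqs[i], as.integer(k))[member_idx]
          # refuse moves that would create a new violation on the donor side
          if (deficit_in_a) {
            if (any((count_b - delta) < min_per_set & delta > 0L)) next
            in_a[i] <- TRUE
            count_a <- count_a + delta
            count_b <- count_b - delta
          } else {
            if (any((count_a - delta) < min_per_set & delta > 0L)) next
            in_a[i] <- FALSE
            count_a <- count_a - delta
            count_b <- count_b + delta
          }
          moved <- moved + delta[j]
        }
      }
    }
  })
  def_a <- min_per_set - count_a
  def_b <- min_per_set - count_b
  bad <- which(def_a > 0L | def_b > 0L)
  if (length(bad)) {
    show <- head(bad, 5)
    stop(sprintf("split constraint unsatisfied after %d repair sweeps for %d k-mers: %s",
                 it, length(bad),
                 paste(sprintf("%s (A=%d, B=%d)", universe$members[show],
                               count_a[show], count_b[show]), collapse = "; ")))
  }
  pool$probes$set_label <- ifelse(in_a, "A", "B")
  pool$design_meta$split <- list(min_per_set = min_per_set, seed = seed,
                                 repair_sweeps = it, universe_k = k)
  pool
}

#' Add the T7 phi2.5 promoter prefix (DNA template pool)
#'
#' Each DNA template is the phi2.5 bacteriophage T7 promoter followed by an
#' AGA or AGG transcription initiator and the U->T transliteration of the
#' probe. RNA-side analyses never see the prefix.
#'
#' @param pool `ProbePool`.
#' @param initiator `"AGA"` or `"AGG"`.
#' @param promoter promoter constant (DNA).
#' @return data.frame(probe_id, template) with attributes `promoter`,
#'   `initiator`.
#' @export
add_t7_prefix <- function(pool, initiator = c("AGA", "AGG"),
                          promoter = "TAATACGACTCACTATTA") {
  initiator <- match.arg(initiator)
  stopifnot(inherits(pool, "ProbePool"))
  templates <- paste0(promoter, initiator, rna_to_dna(pool$probes$sequence))
  structure(data.frame(probe_id = pool$probes$probe_id,
                       template = templates, stringsAsFactors = FALSE),
            promoter = promoter, initiator = initiator)
}

#' @rdname add_t7_prefix
#' @param templates data.frame from `add_t7_prefix`.
#' @return for `strip_t7_prefix`: the RNA probe sequences.
#' @export
strip_t7_prefix <- function(templates) {
  pre <- paste0(attr(templates, "promoter"), attr(templates, "initiator"))
  dna_to_rna(substring(templates$template, nchar(pre) + 1L))
}

#' Build the default designed pool
#'
#' The standard design: an order-11 de Bruijn cycle chopped with the default
#' window schedule (lengths 30-41, overlap >= 10, two interleaved wraps,
#' truncated to 241,399 probes) and split into Set A / Set B with at least
#' 155 occurrences of every scored 7-mer per set.
#'
#' @param order de Bruijn order.
#' @param target_count number of probes.
#' @param min_per_set per-set 7-mer floor for the split.
#' @param universe scored k-mer universe.
#' @param seed master seed; cycle, schedule, and split seeds derive from it.
#' @return labeled `ProbePool`.
#' @export
build_pool <- function(order = 11, target_count = 241399, min_per_set = 155,
                       universe = kmer_universe(), seed = 1) {
  cyc <- generate_debruijn(order, seed = seed)
  pool <- chop_pool(cyc, target_count, preserve_m = min(11, order),
                    seed = seed + 1L)
  pool$design_meta$debruijn_order <- order
  pool$design_meta$seed <- seed
  split_sets(pool, universe = universe, min_per_set = min_per_set,
             seed = seed + 2L)
}

#' Build the reduced benchmarking pool
#'
#' A scaled-down design for simulation studies: order-9 cycle, ~15,000
#' probes, per-set floor of 5 occurrences per scored 7-mer. Every 7-mer
#' still appears in both sets, at roughly 1/16 the depth of the full design.
#'
#' @inheritParams build_pool
#' @export
build_reduced_pool <- function(order = 9, target_count = 15000,
                               min_per_set = 5, universe = kmer_universe(),
                               seed = 1) {
  build_pool(order = order, target_count = target_count,
             min_per_set = min_per_set, universe = universe, seed = seed)
}

#' Write / read a probe pool (FASTA + set-assignment TSV)
#'
#' @param pool `ProbePool`.
#' @param dir output directory (created if needed); writes `pool.fa` and
#'   `pool_sets.tsv`.
#' @return `write_pool`: the directory, invisibly. `read_pool`: a
#'   `ProbePool`.
#' @export
write_pool <- function(pool, dir) {
  stopifnot(inherits(pool, "ProbePool"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rs <- Biostrings::RNAStringSet(pool$probes$sequence)
  names(rs) <- pool$probes$probe_id
  Biostrings::writeXStringSet(rs, file.path(dir, "pool.fa"))
  tab <- data.frame(probe_id = pool$probes$probe_id,
                    set_label = pool$probes$set_label,
                    length = nchar(pool$probes$sequence))
  write.table(tab, file.path(dir, "pool_sets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_pool
#' @export
read_pool <- function(dir) {
  rs <- Biostrings::readRNAStringSet(file.path(dir, "pool.fa"))
  tab <- read.table(file.path(dir, "pool_sets.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = names(rs),
                       sequence = as.character(rs),
                       stringsAsFactors = FALSE)
  m <- match(probes$probe_id, tab$probe_id)
  probes$set_label <- tab$set_label[m]
  probe_pool(probes, design_meta = list(source = normalizePath(dir)))
}
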