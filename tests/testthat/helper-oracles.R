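# Independent oracles and tiny fixture builders, deliberately naive:
# plain-R substring scans and hand-rolled linkage, no package internals.

# all cyclic k-windows of a circular string
cyclic_windows <- function(s, k) {
  n <- nchar(s)
  ext <- paste0(s, substr(s, 1, k - 1))
  substring(ext, seq_len(n), seq_len(n) + k - 1)
}

# naive per-k-mer trimmed-mean scores and Z-scores by substring scan
naive_kmer_scores <- function(profile, pool, subset, universe,
                              trim_fraction = 0.025) {
  keep <- profile$flag == 0
  v <- log1p(profile$intensity[keep])
  v <- v - median(v)
  ids <- profile$probe_id[keep]
  probes <- pool$probes
  if (subset != "merged") probes <- probes[probes$set_label == subset, ]
  m <- match(probes$probe_id, ids)
  probes <- probes[!is.na(m), ]
  vals <- v[m[!is.na(m)]]
  score <- vapply(universe$members, function(w) {
    x <- vals[grepl(w, probes$sequence, fixed = TRUE)]
    n <- length(x)
    drop <- floor(n * trim_fraction)
    x <- sort(x)
    mean(x[(drop + 1):(n - drop)])
  }, numeric(1))
  med <- median(score)
  s <- 1.4826 * median(abs(score - med))
  if (s == 0) s <- sd(score)
  z <- if (is.na(s) || s == 0) rep(0, length(score)) else (score - med) / s
  data.frame(kmer = universe$members, score = unname(score), z = unname(z),
             stringsAsFactors = FALSE)
}

# naive sum-over-windows PWM occupancy
naive_occupancy <- function(seq, mat) {
  b <- strsplit(seq, "")[[1]]
  L <- ncol(mat)
  idx <- match(b, c("A", "C", "G", "U"))
  total <- 0
  for (s in seq_len(length(b) - L + 1)) {
    total <- total + prod(mat[cbind(idx[s:(s + L - 1)], seq_len(L))])
  }
  total
}

# brute-force centroid-linkage agglomeration (Lance-Williams update) on a
# dissimilarity matrix; returns merge heights and member sets per step
naive_centroid_linkage <- function(d) {
  n <- nrow(d)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  heights <- numeric(0)
  merged_sets <- list()
  dm <- d
  diag(dm) <- Inf
  while (length(active) > 1) {
    sub <- dm[active, active, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[min(ij)]; j <- active[max(ij)]
    heights <- c(heights, dm[i, j])
    new_members <- sort(c(members[[i]], members[[j]]))
    merged_sets[[length(merged_sets) + 1]] <- new_members
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      dnew <- (ni * dm[i, k] + nj * dm[j, k]) / (ni + nj) -
        ni * nj * dm[i, j] / (ni + nj)^2
      dm[i, k] <- dm[k, i] <- dnew
    }
    members[[i]] <- new_members
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = heights, sets = merged_sets)
}

# member sets in merge order from an hclust object
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  sets
}

# trapezoidal AUROC from an explicit ROC curve
trapezoid_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!labels] >= t), numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small labeled pool used across tests: order-o de Bruijn chopped and split
make_test_pool <- function(order = 7, count = 3000, min_per_set = 1,
                           seed = 101) {
  k <- min(7L, order)
  u <- if (k == 7) kmer_universe() else kmer_universe(k, excluded = character(0))
  build_pool(order = order, target_count = count, min_per_set = min_per_set,
             universe = u, seed = seed)
}

# fake KmerTable whose top-10 are all G-runs (every one contains GGGG),
# plus an accompanying motif; used for artifact-count construction tests
fake_tab_for_artifacts <- function() {
  gk <- c("GGGGGGG", "AGGGGGG", "CGGGGGG", "UGGGGGG", "GGGGGGA",
          "GGGGGGC", "GGGGGGU", "AGGGGGA", "CGGGGGC", "UGGGGGU")
  filler <- c("AUCGAUC", "UCUCUCU", "AGAGAGA", "CUCUCUC", "AAACCCA",
              "CCCAAAC", "AUAUAUA", "UAUAUAU", "CAGUCAG", "AAAGAAA")
  tab <- structure(data.frame(kmer = c(gk, filler),
                              score = c(seq(20, 11), seq(5, 0.5, length.out = 10)),
                              z = c(seq(20, 11), seq(5, 0.5, length.out = 10)),
                              stringsAsFactors = FALSE),
                   class = c("KmerTable", "data.frame"))
  list(tab = tab, motif = build_motif(tab))
}

# random toy pool of unconstrained sequences (not de Bruijn based)
make_random_pool <- function(n = 20, len = 30, seed = 1, labeled = TRUE) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = ""),
      character(1))
    probe_pool(data.frame(
      probe_id = sprintf("t%03d", seq_len(n)),
      sequence = seqs,
      set_label = if (labeled) rep(c("A", "B"), length.out = n)
                  else NA_character_,
      stringsAsFactors = FALSE))
  })
}
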