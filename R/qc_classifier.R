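# Experiment-level feature extraction and the L1 logistic pass/fail
# classifier with the 0.35/0.65 triage band.

#' Default artifact k-mer list (placeholder, non-canonical)
#'
#' Twenty-six k-mers of lengths 4-7 standing in for the recurrently enriched
#' technical artifact signatures seen across unrelated experiments. The
#' published list is not public; this stand-in covers G-rich, poly-U/A/C,
#' purine-rich and dinucleotide-repeat families plus restriction-site-derived
#' words, and is clearly non-canonical: supply your own via the `artifacts`
#' argument wherever it is accepted.
#'
#' @return character vector of 26 RNA k-mers.
#' @export
default_artifact_kmers <- function() {
  c("GGGG", "GGGGG", "GGGGGG", "GGGGGGG",
    "UUUU", "UUUUU", "UUUUUU", "UUUUUUU",
    "AAAA", "AAAAAAA", "CCCC", "CCCCCCC",
    "UGUG", "UGUGUGU", "GUGUGUG",
    "ACAC", "ACACACA", "CACACAC",
    "UAUAUAU", "AUAUAUA",
    "GCUCUUC", "CGAGAAG", "GAAGAGC", "GCUCUU", "CUCUUC",
    "AGGAGG")
}

#' Extract the experiment-level classifier feature vector
#'
#' Statistics of the Set A / Set B 7-mer Z-score tables, the artifact
#' content of the two top-10 lists, and motif-level summaries. With the
#' default 26 artifact k-mers the vector has 83 entries: A/B Pearson r,
#' top-10 overlap, the ten top Z-scores of each set, skewness and kurtosis
#' of each Z distribution, the highest merged-set Z, one count per artifact
#' and set (top-10 7-mers containing the artifact as a substring), the
#' artifact count sum, each motif's information content, and the motif
#' similarity score.
#'
#' @param tableA,tableB,tableMerged per-subset `KmerTable`s (same universe).
#' @param motifA,motifB `PFM`s built from the two sets.
#' @param artifacts artifact k-mers, lengths 4-7.
#' @return named numeric vector of class `ExperimentFeatures`.
#' @export
extract_features <- function(tableA, tableB, tableMerged,
                             motifA = build_motif(tableA),
                             motifB = build_motif(tableB),
                             artifacts = default_artifact_kmers()) {
  if (!identical(tableA$kmer, tableB$kmer) ||
      !identical(tableA$kmer, tableMerged$kmer))
    stop("k-mer tables must share one universe")
  artifacts <- toupper(dna_to_rna(artifacts))
  if (any(nchar(artifacts) > 7) || any(nchar(artifacts) < 4))
    stop("artifact k-mers must have lengths 4-7")

  diag <- ab_diagnostics(tableA, tableB)
  topA <- top_kmers(tableA, 10)
  topB <- top_kmers(tableB, 10)
  artA <- vapply(artifacts, function(a)
    sum(grepl(a, topA$kmer, fixed = TRUE)), numeric(1))
  artB <- vapply(artifacts, function(a)
    sum(grepl(a, topB$kmer, fixed = TRUE)), numeric(1))
  sim <- compare_motifs(motifA, motifB, n_null = 0)$score

  f <- c(ab_pearson = diag$pearson_r,
         top10_overlap = diag$top10_overlap,
         setNames(topA$z, sprintf("top10_z_A_%02d", 1:10)),
         setNames(topB$z, sprintf("top10_z_B_%02d", 1:10)),
         skew_A = skewness(tableA$z), skew_B = skewness(tableB$z),
         kurt_A = kurtosis(tableA$z), kurt_B = kurtosis(tableB$z),
         max_merged_z = max(tableMerged$z),
         setNames(artA, sprintf("artifact_%s_A", artifacts)),
         setNames(artB, sprintf("artifact_%s_B", artifacts)),
         artifact_sum = sum(artA) + sum(artB),
         ic_A = information_content(motifA)$total,
         ic_B = information_content(motifB)$total,
         motif_similarity = sim)
  class(f) <- "ExperimentFeatures"
  f
}

#' Score one intensity profile end to end
#'
#' Convenience wrapper: normalize, compute Set A / Set B / merged Z-score
#' tables, build both motifs, and extract the classifier features.
#'
#' @param profile `IntensityProfile`.
#' @param pool labeled `ProbePool`.
#' @param universe `KmerUniverse`.
#' @param artifacts artifact k-mers.
#' @param index optional [kmer_probe_index()] (reuse across experiments).
#' @return list with `tables` (A, B, merged), `motifs` (A, B), `features`.
#' @export
profile_features <- function(profile, pool, universe = kmer_universe(),
                             artifacts = default_artifact_kmers(),
                             index = NULL) {
  if (is.null(index)) index <- kmer_probe_index(pool, universe)
  norm <- normalize_intensities(profile)
  tA <- compute_kmer_zscores(norm, pool, "A", index = index)
  tB <- compute_kmer_zscores(norm, pool, "B", index = index)
  tM <- compute_kmer_zscores(norm, pool, "merged", index = index)
  mA <- build_motif(tA)
  mB <- build_motif(tB)
  list(tables = list(A = tA, B = tB, merged = tM),
       motifs = list(A = mA, B = mB),
       features = extract_features(tA, tB, tM, mA, mB, artifacts))
}

# stratified fold ids, preserving class balance; called under the caller's RNG
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the L1 logistic pass/fail classifier
#'
#' Features are standardized with training-set statistics (constant features
#' dropped with a warning); the L1 regularization strength is chosen by a
#' seeded stratified k-fold grid search maximizing validation AUROC over a
#' log-spaced grid; a stratified holdout (default 20 passes and 20 fails)
#' never touches training or selection and yields the reported AUROC via
#' the rank statistic.
#'
#' @param collection list of `LabeledExperiment`-like elements carrying
#'   `$features` (named numeric) and `$label` (`"pass"`/`"fail"`), or a list
#'   with `$x` (matrix) and `$y`.
#' @param holdout either a fraction in (0, 1) or a length-2 vector
#'   `c(pass = , fail = )` of holdout counts (default 20/20).
#' @param seed integer seed (holdout draw, folds).
#' @param lambda_grid log-spaced L1 strengths searched.
#' @param n_folds CV folds (default 5).
#' @return list with `model` (class `rbp_classifier`) and `holdout_auroc`.
#' @export
train_classifier <- function(collection, holdout = c(pass = 20, fail = 20),
                             seed = 1,
                             lambda_grid = 10^seq(-0.5, -4, length.out = 25),
                             n_folds = 5) {
  if (!is.null(collection$x)) {
    x <- collection$x
    y <- collection$y
  } else {
    x <- do.call(rbind, lapply(collection, function(e) unclass(e$features)))
    y <- vapply(collection, function(e) e$label, character(1))
  }
  y <- as.character(y)
  if (!all(y %in% c("pass", "fail"))) stop("labels must be 'pass'/'fail'")
  if (length(unique(y)) < 2L) stop("both classes must be present")

  with_seed(seed, {
    if (length(holdout) == 1 && holdout > 0 && holdout < 1) {
      n_hp <- round(sum(y == "pass") * holdout)
      n_hf <- round(sum(y == "fail") * holdout)
    } else {
      n_hp <- holdout[["pass"]]
      n_hf <- holdout[["fail"]]
    }
    hold <- c(sample(which(y == "pass"), n_hp),
              sample(which(y == "fail"), n_hf))
    xt <- x[-hold, , drop = FALSE]
    yt <- as.integer(y[-hold] == "pass")

    mu <- colMeans(xt)
    sdv <- apply(xt, 2, sd)
    const <- sdv == 0 | !is.finite(sdv)
    if (any(const)) {
      warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                      paste(colnames(xt)[const], collapse = ", ")))
      sdv[const] <- 1
    }
    xs <- sweep(sweep(xt, 2, mu), 2, sdv, "/")
    xs[, const] <- 0

    fold <- stratified_folds(yt, n_folds)
    cv_auc <- matrix(NA_real_, n_folds, length(lambda_grid))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(xs[tr, , drop = FALSE], yt[tr],
                            family = "binomial", alpha = 1,
                            lambda = lambda_grid, standardize = FALSE)
      pred <- predict(fit, xs[!tr, , drop = FALSE], type = "response",
                      s = lambda_grid, exact = FALSE)
      cv_auc[f, ] <- apply(pred, 2, auroc, labels = yt[!tr])
    }
    mean_auc <- colMeans(cv_auc)
    # ties toward the larger lambda (sparser model)
    best <- which(mean_auc >= max(mean_auc) - 1e-12)[1]
    lambda <- lambda_grid[best]

    fit <- glmnet::glmnet(xs, yt, family = "binomial", alpha = 1,
                          lambda = lambda_grid, standardize = FALSE)
    w <- as.numeric(predict(fit, type = "coefficients", s = lambda))
    model <- structure(list(
      weights = setNames(w[-1], colnames(x)),
      intercept = w[1],
      l1_strength = lambda,
      triage_band = c(fail_max = 0.35, pass_min = 0.65),
      feature_names = colnames(x),
      scaler = list(mean = mu, sd = sdv, dropped = colnames(x)[const]),
      cv = data.frame(lambda = lambda_grid, mean_auroc = mean_auc),
      training_meta = list(n_pass = sum(yt == 1), n_fail = sum(yt == 0),
                           n_holdout = length(hold), seed = seed,
                           similarity_metric = "mean column Pearson (in-package)"),
      version = "1.0"), class = "rbp_classifier")

    ho_p <- vapply(hold, function(i)
      classify(model, x[i, ])$probability, numeric(1))
    list(model = model, holdout_auroc = auroc(ho_p, y[hold] == "pass"))
  })
}

#' Classify one experiment
#'
#' Probability is `logistic(w . x_standardized + b)`; calls follow the
#' triage band: `p <= 0.35` fail, `p >= 0.65` pass, otherwise uncertain
#' (routed to manual review).
#'
#' @param model `rbp_classifier`.
#' @param features named numeric vector (names must match the model's).
#' @return list of class `triage_result`: `probability`, `label`.
#' @export
classify <- function(model, features) {
  features <- unclass(features)
  if (is.null(names(features)) ||
      !identical(sort(names(features)), sort(model$feature_names)))
    stop("feature names do not match the trained model")
  x <- features[model$feature_names]
  xs <- (x - model$scaler$mean) / model$scaler$sd
  xs[model$feature_names %in% model$scaler$dropped] <- 0
  p <- plogis(sum(model$weights * xs) + model$intercept)
  triage_result(p, model$triage_band)
}

triage_result <- function(p, band = c(fail_max = 0.35, pass_min = 0.65)) {
  label <- if (p <= band[["fail_max"]]) "fail"
           else if (p >= band[["pass_min"]]) "pass"
           else "uncertain"
  structure(list(probability = unname(p), label = label),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("triage: %s (p = %.3f)\n", x$label, x$probability))
  invisible(x)
}

#' Resolve replicate triage calls for one protein
#'
#' Unanimous automatic calls stand; any disagreement, or any uncertain
#' replicate, is flagged for manual review rather than silently resolved.
#'
#' @param results list of `triage_result`s (or their labels).
#' @return `"pass"`, `"fail"`, or `"manual_review"`.
#' @export
resolve_replicates <- function(results) {
  if (!length(results)) stop("need at least one result")
  labels <- vapply(results, function(r)
    if (inherits(r, "triage_result")) r$label else as.character(r),
    character(1))
  if (any(labels == "uncertain")) return("manual_review")
  u <- unique(labels)
  if (length(u) == 1L) u else "manual_review"
}

#' Serialize / load a trained classifier (versioned JSON)
#'
#' @param model `rbp_classifier`.
#' @param file path.
#' @export
write_classifier <- function(model, file) {
  payload <- list(version = model$version,
                  weights = as.list(model$weights),
                  intercept = model$intercept,
                  l1_strength = model$l1_strength,
                  triage_band = as.list(model$triage_band),
                  feature_names = model$feature_names,
                  scaler = list(mean = as.list(model$scaler$mean),
                                sd = as.list(model$scaler$sd),
                                dropped = model$scaler$dropped),
                  training_meta = model$training_meta)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(weights = unlist(p$weights),
                 intercept = p$intercept,
                 l1_strength = p$l1_strength,
                 triage_band = unlist(p$triage_band),
                 feature_names = p$feature_names,
                 scaler = list(mean = unlist(p$scaler$mean),
                               sd = unlist(p$scaler$sd),
                               dropped = as.character(unlist(p$scaler$dropped))),
                 training_meta = p$training_meta,
                 version = p$version),
            class = "rbp_classifier")
}
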