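# Feature extraction, L1 logistic training, triage, replicate resolution.

make_tables <- function(seed = 1) {
  pool <- make_test_pool(order = 7, count = 2500, min_per_set = 1, seed = 51)
  idx <- kmer_probe_index(pool, kmer_universe())
  cfg <- sim_config(planted_motif = "UGCAUGU", seed = seed)
  prof <- simulate_experiment(pool, cfg)
  list(A = compute_kmer_zscores(prof, pool, "A", index = idx),
       B = compute_kmer_zscores(prof, pool, "B", index = idx),
       M = compute_kmer_zscores(prof, pool, "merged", index = idx))
}

test_that("feature vector has the documented 83 dimensions and identity behavior", {
  tabs <- make_tables()
  f <- extract_features(tabs$A, tabs$A, tabs$M,
                        build_motif(tabs$A), build_motif(tabs$A))
  expect_length(f, 83)
  expect_equal(unname(f["ab_pearson"]), 1)
  expect_equal(unname(f["top10_overlap"]), 10)
  expect_equal(unname(f["ic_A"]), unname(f["ic_B"]))
  expect_equal(unname(f["motif_similarity"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["artifact_sum"]),
               unname(sum(f[grepl("^artifact_.*_[AB]$", names(f))])))
})

test_that("artifact counts follow substring matching on the top-10 lists", {
  g7 <- fake_tab_for_artifacts()
  f <- extract_features(g7$tab, g7$tab, g7$tab, g7$motif, g7$motif,
                        artifacts = c("GGGG", "UUUU", "ACAC"))
  expect_equal(unname(f["artifact_GGGG_A"]), 10)  # all top-10 are G-runs
  expect_equal(unname(f["artifact_GGGG_B"]), 10)
  expect_equal(unname(f["artifact_UUUU_A"]), 0)
  expect_equal(unname(f["artifact_sum"]), 20)
  expect_error(
    extract_features(g7$tab, g7$tab, g7$tab, g7$motif, g7$motif,
                     artifacts = "GGGGGGGG"), "lengths 4-7")
})

test_that("pass and fail simulations separate on A/B correlation alone", {
  pool <- make_test_pool(order = 7, count = 2500, min_per_set = 1, seed = 51)
  idx <- kmer_probe_index(pool, kmer_universe())
  r_of <- function(cfg) {
    prof <- simulate_experiment(pool, cfg)
    ab_diagnostics(compute_kmer_zscores(prof, pool, "A", index = idx),
                   compute_kmer_zscores(prof, pool, "B", index = idx))$pearson_r
  }
  r_pass <- vapply(1:4, function(s)
    r_of(sim_config(planted_motif = "UGCAUGU", seed = 810 + s)), numeric(1))
  r_fail <- vapply(1:4, function(s)
    r_of(sim_config(mode = "nonspecific", seed = 820 + s)), numeric(1))
  expect_gt(min(r_pass), max(r_fail))
})

test_that("a linearly separable collection trains to holdout AUROC 1", {
  withr::with_seed(31, {
    n <- 60
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c("pass", "fail"), each = n / 2)
    x[, 1] <- ifelse(y == "pass", 5, -5) + rnorm(n, 0, 0.1)
    res <- train_classifier(list(x = x, y = y), holdout = c(pass = 8, fail = 8),
                            seed = 3)
    expect_equal(res$holdout_auroc, 1.0)
  })
})

test_that("permutation-null training gives chance-level holdout AUROC", {
  withr::with_seed(77, {
    n <- 160
    x <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    base_y <- rep(c("pass", "fail"), each = n / 2)
    aucs <- vapply(1:20, function(r) {
      y <- sample(base_y)   # labels carry no signal
      train_classifier(list(x = x, y = y), holdout = c(pass = 20, fail = 20),
                       seed = r)$holdout_auroc
    }, numeric(1))
    expect_gte(median(aucs), 0.35)
    expect_lte(median(aucs), 0.65)
    expect_true(all(aucs >= 0.1 & aucs <= 0.9))
  })
})

test_that("train_classifier rejects single-class input", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(train_classifier(list(x = x, y = rep("pass", 10))),
               "both classes")
})

test_that("triage band: <=0.35 fail, >=0.65 pass, between uncertain, ties included", {
  band_label <- function(p) rbpscreen:::triage_result(p)$label
  expect_equal(band_label(0.20), "fail")
  expect_equal(band_label(0.50), "uncertain")
  expect_equal(band_label(0.90), "pass")
  expect_equal(band_label(0.35), "fail")       # tie maps to fail  ("<=")
  expect_equal(band_label(0.65), "pass")       # tie maps to pass  (">=")
  # partition of [0,1] is exhaustive and exclusive
  for (p in seq(0, 1, by = 0.01))
    expect_true(band_label(p) %in% c("fail", "uncertain", "pass"))
})

test_that("classify standardizes with stored scaler and checks feature names", {
  withr::with_seed(5, {
    n <- 80
    x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rep(c("pass", "fail"), each = n / 2)
    x[, 2] <- ifelse(y == "pass", 3, -3) + rnorm(n, 0, 0.3)
    res <- train_classifier(list(x = x, y = y), holdout = 0.2, seed = 2)
    r <- classify(res$model, x[1, ])
    expect_true(r$label %in% c("pass", "fail", "uncertain"))
    expect_true(r$probability >= 0 && r$probability <= 1)
    bad <- setNames(x[1, ], c("f1", "f2", "f3", "nope"))
    expect_error(classify(res$model, bad), "feature names")
    # affine rescaling of a raw feature + retraining leaves probabilities intact
    x2 <- x; x2[, 2] <- 10 * x[, 2] + 7
    res2 <- train_classifier(list(x = x2, y = y), holdout = 0.2, seed = 2)
    p1 <- vapply(1:10, function(i) classify(res$model, x[i, ])$probability,
                 numeric(1))
    p2 <- vapply(1:10, function(i) classify(res2$model, x2[i, ])$probability,
                 numeric(1))
    expect_equal(p1, p2, tolerance = 1e-6)
  })
})

test_that("rank-statistic AUROC equals trapezoidal ROC integration (n <= 20)", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(6:20, 1)
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
      scores <- round(rnorm(n), sample(c(1, 5), 1))  # include ties
      expect_equal(auroc(scores, labels), trapezoid_auroc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("replicate resolution: unanimity stands, anything else is manual", {
  tr <- function(p) rbpscreen:::triage_result(p)
  expect_equal(resolve_replicates(list(tr(0.9), tr(0.8))), "pass")
  expect_equal(resolve_replicates(list(tr(0.1), tr(0.2))), "fail")
  expect_equal(resolve_replicates(list(tr(0.9), tr(0.1))), "manual_review")
  expect_equal(resolve_replicates(list(tr(0.5))), "manual_review")
  expect_error(resolve_replicates(list()), "at least one")
})

test_that("classifier JSON serialization round-trips classification", {
  withr::with_seed(13, {
    n <- 60
    x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rep(c("pass", "fail"), each = n / 2)
    x[, 1] <- ifelse(y == "pass", 4, -4) + rnorm(n)
    res <- train_classifier(list(x = x, y = y), holdout = 0.2, seed = 4)
    f <- withr::local_tempfile(fileext = ".json")
    write_classifier(res$model, f)
    back <- read_classifier(f)
    for (i in 1:5) {
      expect_equal(classify(back, x[i, ])$probability,
                   classify(res$model, x[i, ])$probability, tolerance = 1e-9)
    }
  })
})
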