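# Synthetic probe-intensity simulator: planted sequence specificity, log-normal
# noise, non-specific background, artifact contamination, and discordant
# Set A/B failure modes. Stands in for real microarray data in every test.

#' Simulation configuration
#'
#' Intensities follow
#' `exp(N(background_mu, background_sigma)) + gain * occupancy * exp(N(0, noise_sigma))`
#' where occupancy is the sum over probe windows of the product of planted-PFM
#' base probabilities (linear in site count: equilibrium binding far from
#' saturation). The default "strong signal" regime puts a perfect site's
#' contribution at roughly 10x the median background with 0.3 log-units of
#' multiplicative noise; nothing in real-array terms pins these, they are
#' declared defaults.
#'
#' @param planted_motif a `PFM`, or a consensus RNA k-mer (converted with
#'   [consensus_pfm()] using `mismatch`).
#' @param mismatch per-base mismatch probability when `planted_motif` is a
#'   consensus string (default 0.05).
#' @param gain intensity units per unit occupancy.
#' @param background_mu,background_sigma log-scale background parameters.
#' @param noise_sigma multiplicative log-normal noise scale.
#' @param mode one of `"specific"`, `"nonspecific"`, `"artifact"`,
#'   `"split_discordant"`.
#' @param artifact_kmer contaminating k-mer (mode `"artifact"`).
#' @param planted_motif_b second motif planted in Set B probes
#'   (mode `"split_discordant"`; Set A gets `planted_motif`).
#' @param exclude_fraction fraction of spots randomly flagged excluded.
#' @param seed integer seed.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(planted_motif = "UGCAUGU", mismatch = 0.05,
                       gain = 3000, background_mu = log(100),
                       background_sigma = 0.25, noise_sigma = 0.3,
                       mode = c("specific", "nonspecific", "artifact",
                                "split_discordant"),
                       artifact_kmer = "GGGG", planted_motif_b = NULL,
                       exclude_fraction = 0, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(gain >= 0, background_sigma >= 0, noise_sigma >= 0,
            exclude_fraction >= 0, exclude_fraction < 1)
  cfg <- list(planted_motif = planted_motif, mismatch = mismatch, gain = gain,
              background_mu = background_mu, background_sigma = background_sigma,
              noise_sigma = noise_sigma, mode = mode,
              artifact_kmer = toupper(dna_to_rna(artifact_kmer)),
              planted_motif_b = planted_motif_b,
              exclude_fraction = exclude_fraction, seed = seed)
  class(cfg) <- "SimConfig"
  cfg
}

as_sim_pfm <- function(motif, mismatch) {
  if (inherits(motif, "PFM")) return(motif)
  consensus_pfm(motif, mismatch = mismatch)
}

#' Simulate one probe-intensity experiment
#'
#' @param pool `ProbePool` (set labels required for mode
#'   `"split_discordant"`).
#' @param cfg `SimConfig`.
#' @return `IntensityProfile`, deterministic given `cfg$seed`.
#' @export
simulate_experiment <- function(pool, cfg) {
  stopifnot(inherits(pool, "ProbePool"), inherits(cfg, "SimConfig"))
  seqs <- pool$probes$sequence
  n <- length(seqs)
  if (n == 0L) stop("pool is empty")

  occ <- switch(cfg$mode,
    nonspecific = numeric(n),
    artifact = as.numeric(grepl(cfg$artifact_kmer, seqs, fixed = TRUE)),
    specific = {
      pfm <- as_sim_pfm(cfg$planted_motif, cfg$mismatch)
      if (ncol(pfm) > min(nchar(seqs)))
        stop("planted motif is longer than the shortest probe")
      pwm_occupancy_cpp(seqs, unclass(pfm))
    },
    split_discordant = {
      if (is.null(cfg$planted_motif_b))
        stop("mode 'split_discordant' needs planted_motif_b")
      if (anyNA(pool$probes$set_label))
        stop("mode 'split_discordant' needs a set-labeled pool")
      pa <- as_sim_pfm(cfg$planted_motif, cfg$mismatch)
      pb <- as_sim_pfm(cfg$planted_motif_b, cfg$mismatch)
      if (max(ncol(pa), ncol(pb)) > min(nchar(seqs)))
        stop("planted motif is longer than the shortest probe")
      o <- numeric(n)
      a <- pool$probes$set_label == "A"
      o[a] <- pwm_occupancy_cpp(seqs[a], unclass(pa))
      o[!a] <- pwm_occupancy_cpp(seqs[!a], unclass(pb))
      o
    })
  gain <- if (cfg$mode == "nonspecific") 0 else cfg$gain

  with_seed(cfg$seed, {
    bg <- exp(rnorm(n, cfg$background_mu, cfg$background_sigma))
    noise <- exp(rnorm(n, 0, cfg$noise_sigma))
    flag <- if (cfg$exclude_fraction > 0)
      as.integer(runif(n) < cfg$exclude_fraction) else rep(0L, n)
    intensity_profile(pool$probes$probe_id, bg + gain * occ * noise, flag)
  })
}

# seeded sampler of planted-motif settings for "pass" experiments: consensus
# length 4-8, variable sharpness and gain, all within the strong-signal regime
sample_sim_motif <- function() {
  len <- sample(4:8, 1)
  consensus <- paste(sample(RNA_BASES, len, replace = TRUE), collapse = "")
  list(consensus = consensus,
       mismatch = runif(1, 0.02, 0.08),
       gain = exp(runif(1, log(2000), log(8000))))
}

#' Generate a labeled experiment collection for classifier training
#'
#' `n_pass` experiments carry a planted motif (mode `"specific"`, labels
#' `"pass"`); `n_fail` experiments cycle through the failure modes
#' (`nonspecific`, `artifact`, `split_discordant`) and are labeled `"fail"`.
#' Ground truth is by construction. The default 229/242 split mirrors the
#' size of a curated training corpus.
#'
#' @param pool `ProbePool` with set labels.
#' @param n_pass,n_fail experiment counts.
#' @param artifact_kmers pool of contaminating k-mers for artifact mode.
#' @param seed master seed; per-experiment seeds derive from it.
#' @return list of `LabeledExperiment` (fields `intensities`, `label`,
#'   `provenance`).
#' @export
generate_training_collection <- function(pool, n_pass = 229, n_fail = 242,
                                         artifact_kmers = default_artifact_kmers(),
                                         seed = 1) {
  stopifnot(n_pass >= 0, n_fail >= 0)
  fail_modes <- c("nonspecific", "artifact", "split_discordant")
  with_seed(seed, {
    exp_seeds <- sample.int(2^30, n_pass + n_fail)
    out <- vector("list", n_pass + n_fail)
    for (i in seq_len(n_pass)) {
      m <- sample_sim_motif()
      cfg <- sim_config(planted_motif = m$consensus, mismatch = m$mismatch,
                        gain = m$gain, mode = "specific", seed = exp_seeds[i])
      out[[i]] <- structure(list(intensities = simulate_experiment(pool, cfg),
                                 label = "pass", provenance = cfg),
                            class = "LabeledExperiment")
    }
    for (j in seq_len(n_fail)) {
      i <- n_pass + j
      mode <- fail_modes[(j - 1L) %% 3L + 1L]
      m <- sample_sim_motif()
      cfg <- switch(mode,
        nonspecific = sim_config(mode = "nonspecific", seed = exp_seeds[i]),
        artifact = sim_config(mode = "artifact",
                              artifact_kmer = sample(artifact_kmers, 1),
                              gain = m$gain, seed = exp_seeds[i]),
        split_discordant = {
          m2 <- sample_sim_motif()
          sim_config(planted_motif = m$consensus, mismatch = m$mismatch,
                     planted_motif_b = m2$consensus, gain = m$gain,
                     mode = "split_discordant", seed = exp_seeds[i])
        })
      out[[i]] <- structure(list(intensities = simulate_experiment(pool, cfg),
                                 label = "fail", provenance = cfg),
                            class = "LabeledExperiment")
    }
    out
  })
}
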