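# Figure-level experiment drivers: bias curves across theta, heterogeneous
# theta mixtures, structured models across divergence times, predictive
# pi_RAD distributions, and the on-disk fixture generator. Every driver is
# exactly reproducible from its arguments and master seed, and per-point
# replicates use independent substreams.

# the three heterogeneity mixtures of the study, plus the homogeneous model
heterogeneity_models <- function() {
  list(
    homogeneous = data.frame(proportion = 1, factor = 1),
    model1 = data.frame(proportion = c(0.7, 0.2, 0.1),
                        factor = c(1, 1 / 2, 1 / 10)),
    model2 = data.frame(proportion = c(0.7, 0.2, 0.1),
                        factor = c(1, 1 / 10, 1 / 100)),
    model3 = data.frame(proportion = c(0.5, 0.4, 0.1),
                        factor = c(1, 1 / 10, 1 / 100)))
}

#' Bias curve under the neutral panmictic model
#'
#' Runs the full pipeline over a theta grid and returns per-replicate
#' diversity summaries, the raw material of the pi_RAD-vs-pi_true bias
#' curve.
#'
#' @param theta_grid per-site theta values.
#' @param n_reps replicates per grid point.
#' @param n_loci,locus_len locus layout (defaults: reduced desk scale; the
#'   full study scale is 1000 x 10000).
#' @param n_motifs,motif_len,tag_len digestion parameters.
#' @param mode estimator normalisation.
#' @param seed master seed.
#' @return data frame, one row per (theta, replicate), with the
#'   \code{\link{rad_replicate}} columns plus \code{rep}.
#' @export
run_bias_sweep <- function(theta_grid, n_reps = 10L, n_loci = 200L,
                           locus_len = 2000L, n_motifs = 10L, motif_len = 8L,
                           tag_len = 100L, mode = "pair_mean", seed = 1L) {
  stopifnot(length(theta_grid) >= 1L, n_reps >= 1L)
  out <- list()
  for (gi in seq_along(theta_grid)) for (r in seq_len(n_reps)) {
    cfg <- model_config("panmictic", theta_site = theta_grid[gi],
                        n_loci = n_loci, locus_len = locus_len,
                        seed = mix_seed(seed, gi * 100000L + r))
    row <- rad_replicate(cfg, n_motifs, motif_len, tag_len, mode)
    row$rep <- r
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' Heterogeneous-theta sweep (selection models)
#'
#' Compares the drop-out bias across the three heterogeneity mixtures and
#' the homogeneous model at matched \eqn{\pi_{true}}: for each target
#' diversity, each model's reference theta is scaled so the
#' proportion-weighted mean theta equals the target, isolating the effect of
#' heterogeneity itself.
#'
#' @param pi_true_targets target weighted-mean theta values.
#' @param models subset of \code{c("homogeneous","model1","model2","model3")}.
#' @inheritParams run_bias_sweep
#' @return data frame with columns of \code{\link{rad_replicate}} plus
#'   \code{model_label}, \code{theta_ref} and \code{rep}.
#' @export
run_heterogeneous_sweep <- function(pi_true_targets, models = names(heterogeneity_models()),
                                    n_reps = 10L, n_loci = 200L,
                                    locus_len = 2000L, n_motifs = 10L,
                                    motif_len = 8L, tag_len = 100L,
                                    mode = "pair_mean", seed = 1L) {
  defs <- heterogeneity_models()
  models <- match.arg(models, names(defs), several.ok = TRUE)
  out <- list()
  for (mi in seq_along(models)) {
    def <- defs[[models[mi]]]
    wmean <- sum(def$proportion * def$factor)
    for (gi in seq_along(pi_true_targets)) for (r in seq_len(n_reps)) {
      theta_ref <- pi_true_targets[gi] / wmean
      s <- mix_seed(seed, (mi * 100L + gi) * 100000L + r)
      cfg <- if (identical(models[mi], "homogeneous"))
        model_config("panmictic", theta_site = theta_ref, n_loci = n_loci,
                     locus_len = locus_len, seed = s)
      else
        model_config("heterogeneous",
                     theta_classes = data.frame(proportion = def$proportion,
                                                theta = theta_ref * def$factor),
                     n_loci = n_loci, locus_len = locus_len, seed = s)
      row <- rad_replicate(cfg, n_motifs, motif_len, tag_len, mode)
      row$model_label <- models[mi]
      row$theta_ref <- theta_ref
      row$rep <- r
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Structured-model sweep over divergence times
#'
#' Runs the two-population split model over a grid of divergence times at
#' fixed theta. Since the split imposes a lower bound on cross-population
#' coalescence, drop-out bias weakens as \code{t} grows; at large \code{t}
#' RAD-based divergence between the populations is nearly unbiased.
#'
#' @param theta_site per-site theta.
#' @param t_grid divergence times in units of \eqn{4 N_e} generations
#'   (0 = panmixia).
#' @inheritParams run_bias_sweep
#' @return data frame with \code{\link{rad_replicate}} columns plus
#'   \code{divergence_t} and \code{rep}.
#' @export
run_structured_sweep <- function(theta_site, t_grid, n_reps = 10L,
                                 n_loci = 200L, locus_len = 2000L,
                                 n_motifs = 10L, motif_len = 8L,
                                 tag_len = 100L, mode = "pair_mean",
                                 seed = 1L) {
  out <- list()
  for (gi in seq_along(t_grid)) for (r in seq_len(n_reps)) {
    cfg <- model_config("structured", theta_site = theta_site,
                        divergence_t = t_grid[gi], n_loci = n_loci,
                        locus_len = locus_len,
                        seed = mix_seed(seed, gi * 100000L + r))
    row <- rad_replicate(cfg, n_motifs, motif_len, tag_len, mode)
    row$divergence_t <- t_grid[gi]
    row$rep <- r
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' Predictive distribution of pi_RAD at a given theta
#'
#' Simulates the distribution of \eqn{\pi_{RAD}} expected under the neutral
#' panmictic model at a known true polymorphism level, as used to compare
#' highly polymorphic empirical populations with their model expectation
#' (400 simulations per distribution in the study).
#'
#' @param theta per-site theta (the population's true polymorphism).
#' @param n_sims number of simulations.
#' @inheritParams run_bias_sweep
#' @return numeric vector of \eqn{\pi_{RAD}} values (one per simulation),
#'   with the per-simulation \eqn{\pi_{true}} as attribute
#'   \code{"pi_true"}.
#' @export
run_predictive_distribution <- function(theta, n_sims = 400L, n_loci = 200L,
                                        locus_len = 2000L, n_motifs = 10L,
                                        motif_len = 8L, tag_len = 100L,
                                        mode = "pair_mean", seed = 1L) {
  pr <- pt <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    cfg <- model_config("panmictic", theta_site = theta, n_loci = n_loci,
                        locus_len = locus_len, seed = mix_seed(seed, i))
    row <- rad_replicate(cfg, n_motifs, motif_len, tag_len, mode)
    pr[i] <- row$pi_rad
    pt[i] <- row$pi_true
  }
  attr(pr, "pi_true") <- pt
  pr
}

#' Generate an on-disk fixture bundle
#'
#' Writes a deterministic set of small plain-text fixtures emulating
#' reference-aligned phased genomes: (1) four simulated haplotype FASTAs
#' (5 chromosomes x 2 kb, theta = 0.007) with a pairing table; (2) a
#' synthetic "planted" genome with two motif occurrences, hand-placed SNPs
#' and one destroyed restriction site, whose exact pi values are known by
#' construction; (3) a variant of the planted genome with an N run. Used by
#' the test-suite and as worked-example inputs for the empirical front-end.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed for the simulated component.
#' @return list of file paths plus the planted genome's expected values
#'   (\code{planted_expected}: pi_true, pi_rad, motif, tag_len).
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  haps <- paste0("hap", 1:4)
  # (1) simulated genomes, one FASTA per haplotype
  cfg <- model_config("panmictic", theta_site = 0.007, n_loci = 5L,
                      locus_len = 2000L, seed = seed)
  genome <- simulate_genome(cfg)
  sim_paths <- write_genome_fasta(genome, file.path(dir, "sim_"),
                                  per_haplotype = TRUE)
  names(sim_paths) <- haps
  pairing <- data.frame(individual_id = c("ind1", "ind2"),
                        haplotype_a = c("hap1", "hap3"),
                        haplotype_b = c("hap2", "hap4"),
                        population = "popA")
  pairing_path <- file.path(dir, "pairing.tsv")
  write.table(pairing, pairing_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  # (2) planted-ADO genome with hand-computed pi values
  planted <- planted_genome()
  planted_paths <- vapply(haps, function(h) {
    x <- Biostrings::DNAStringSet(planted$sequences[, h, drop = TRUE])
    names(x) <- rownames(planted$sequences)
    f <- file.path(dir, paste0("planted_", h, ".fasta"))
    Biostrings::writeXStringSet(x, f)
    f
  }, "")
  # (3) planted genome with an N run in hap1
  nrun <- planted$sequences
  substr(nrun[1L, "hap1"], 300L, 330L) <- paste(rep("N", 31L), collapse = "")
  nrun_paths <- vapply(haps, function(h) {
    x <- Biostrings::DNAStringSet(nrun[, h, drop = TRUE])
    names(x) <- rownames(nrun)
    f <- file.path(dir, paste0("nrun_", h, ".fasta"))
    Biostrings::writeXStringSet(x, f)
    f
  }, "")
  list(sim_fastas = sim_paths, pairing = pairing_path,
       planted_fastas = planted_paths, nrun_fastas = nrun_paths,
       planted_expected = planted$expected)
}

# Synthetic 1-chromosome genome with two occurrences of the motif
# TTTTCCCC and hand-placed SNPs; site 2 is destroyed in hap4. With
# tag_len = 20 the estimator values are exact by construction:
#   locus 1 (pos 51):  cross distances (1,3)=1 (1,4)=0 (2,3)=1 (2,4)=0
#                      -> pi_k = 2/4 = 0.5 (all intact)
#   locus 2 (pos 201): cross distances (1,3)=0 (1,4)=1 (2,3)=1 (2,4)=2
#                      -> pi_k true = 4/4 = 1; RAD: hap4 dropped,
#                      h1=2, h2=1, distances (1,3)=0 (2,3)=1
#                      -> pi_k = 1/2 (pair_mean) or 1/3 (as_printed)
#   pi_true = (0.5 + 1) / 40 = 0.0375
#   pi_rad  = (0.5 + 1/2) / 40 = 0.025 (pair_mean)
#           = (0.5 + 1/3) / 40 = 0.0208333... (as_printed)
planted_genome <- function() {
  motif <- "TTTTCCCC"
  tag_len <- 20L
  len <- 400L
  base <- paste(rep("A", len), collapse = "")
  seqs <- matrix(base, 1L, 4L,
                 dimnames = list("chr1", paste0("hap", 1:4)))
  for (h in 1:4) {
    substr(seqs[1L, h], 51L, 58L) <- motif   # locus 1 site
    substr(seqs[1L, h], 201L, 208L) <- motif # locus 2 site
  }
  substr(seqs[1L, "hap3"], 61L, 61L) <- "G"  # locus 1 tag SNP (hap3)
  substr(seqs[1L, "hap2"], 214L, 214L) <- "C" # locus 2 tag SNP (hap2)
  substr(seqs[1L, "hap4"], 216L, 216L) <- "T" # locus 2 tag SNP (hap4)
  substr(seqs[1L, "hap4"], 201L, 201L) <- "G" # destroy locus 2 site in hap4
  list(sequences = seqs,
       expected = list(pi_true = 1.5 / 40,
                       pi_rad = (0.5 + 1 / 2) / 40,
                       pi_rad_as_printed = (0.5 + 1 / 3) / 40,
                       motif = motif, tag_len = tag_len,
                       n_catalog = 2L, n_shared = 2L))
}
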