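# End-to-end simulated RAD experiment: genome -> motifs -> diploids ->
# catalog -> diversity summary, fully determined by the config seed.

#' Run one simulated RAD experiment
#'
#' Simulates a genome under \code{config}, draws random restriction motifs,
#' merges the haplotypes into two diploids, digests in silico and computes
#' the diversity summary. All randomness is derived from \code{config$seed}
#' (motifs and pairing use reserved substreams, loci use per-locus
#' substreams), so a replicate is exactly reproducible.
#'
#' @param config a \code{\link{model_config}}.
#' @param n_motifs,motif_len random motif set size/length (ignored when
#'   \code{motifs} is supplied).
#' @param tag_len tag length in bp.
#' @param mode normalisation mode, see \code{\link{pi_locus}}.
#' @param motifs optional fixed \code{motif_set} (otherwise drawn from the
#'   config's motif substream).
#' @param return_catalog also return the catalog (as attribute
#'   \code{"catalog"}).
#' @return one-row data frame: \code{theta_true}, \code{model}, the columns
#'   of \code{\link{diversity_result}}, and \code{seed}.
#' @examples
#' rad_replicate(model_config("panmictic", theta_site = 0.01,
#'                            n_loci = 100, locus_len = 2000, seed = 3))
#' @export
rad_replicate <- function(config, n_motifs = 10L, motif_len = 8L,
                          tag_len = 100L, mode = "pair_mean",
                          motifs = NULL, return_catalog = FALSE) {
  stopifnot(inherits(config, "rad_model_config"))
  genome <- simulate_genome(config)
  if (is.null(motifs))
    motifs <- draw_motifs(n_motifs, motif_len,
                          seed = mix_seed(config$seed, .STREAM_MOTIFS))
  pair <- pair_into_diploids(config$model_kind,
                             seed = mix_seed(config$seed, .STREAM_PAIRING))
  catalog <- build_catalog(genome, motifs, pair, tag_len)
  res <- suppressWarnings(diversity_result(catalog, mode))
  out <- cbind(data.frame(theta_true = config$theta_true,
                          model = config$model_kind), res,
               data.frame(seed = config$seed))
  if (return_catalog) attr(out, "catalog") <- catalog
  out
}
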