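# Coalescent simulation of unlinked loci in a small haplotype sample, with
# finite-site Jukes-Cantor sequence evolution. Time is measured in units of
# 4*Ne generations (ms convention), so the coalescence rate for k lineages is
# k*(k-1) and the expected TMRCA of a pair is 0.5.

.BASE_CODES <- c(65L, 67L, 71L, 84L) # utf8 codes of A, C, G, T

#' Simulation model configuration
#'
#' Describes one multi-locus simulation: the demographic/selection model, the
#' per-site population mutation rate \eqn{\theta = 4 N_e \mu}, and the locus
#' layout. Three models are supported: \code{"panmictic"} (homogeneous
#' \eqn{\theta}, no structure), \code{"heterogeneous"} (loci fall into
#' \eqn{\theta} classes in fixed proportions, emulating linked selection
#' reducing diversity in parts of the genome), and \code{"structured"} (two
#' demes that split \code{divergence_t} time units ago with no subsequent
#' migration; haplotypes 1-2 are sampled in deme 1 and haplotypes 3-4 in
#' deme 2).
#'
#' @param model_kind one of \code{"panmictic"}, \code{"heterogeneous"},
#'   \code{"structured"}.
#' @param theta_site per-site \eqn{\theta} (panmictic and structured models).
#' @param theta_classes for the heterogeneous model, a data frame (or list of
#'   \code{c(proportion, theta)} pairs) with columns \code{proportion} and
#'   \code{theta}; proportions must sum to 1.
#' @param divergence_t split time in units of \eqn{4 N_e} generations
#'   (structured model only).
#' @param n_loci number of unlinked loci.
#' @param locus_len locus length in bp.
#' @param n_haplotypes sampled haploid sequences per locus; the study design
#'   uses 4 (two diploids). Values 2..8 are accepted for testing; the
#'   structured model requires an even count (half per deme).
#' @param seed master seed; every locus derives an independent substream from
#'   it, so results for locus i do not depend on \code{n_loci}.
#' @return an object of class \code{rad_model_config}. Its \code{theta_true}
#'   field is the proportion-weighted mean \eqn{\theta}, the quantity that
#'   genome-wide \eqn{\pi_{true}} estimates.
#' @examples
#' cfg <- model_config("panmictic", theta_site = 0.007,
#'                     n_loci = 20, locus_len = 1000, seed = 1)
#' cfg$theta_true
#' @export
model_config <- function(model_kind = c("panmictic", "heterogeneous", "structured"),
                         theta_site = NULL, theta_classes = NULL,
                         divergence_t = NULL, n_loci = 1000L,
                         locus_len = 10000L, n_haplotypes = 4L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  n_loci <- as.integer(n_loci)
  locus_len <- as.integer(locus_len)
  n_haplotypes <- as.integer(n_haplotypes)
  stopifnot(n_loci >= 1L, locus_len >= 1L,
            n_haplotypes >= 2L, n_haplotypes <= 8L)
  if (model_kind == "heterogeneous") {
    if (is.null(theta_classes)) stop("heterogeneous model requires theta_classes")
    if (is.list(theta_classes) && !is.data.frame(theta_classes))
      theta_classes <- data.frame(
        proportion = vapply(theta_classes, `[`, 0, 1),
        theta = vapply(theta_classes, `[`, 0, 2))
    stopifnot(all(c("proportion", "theta") %in% names(theta_classes)))
    if (abs(sum(theta_classes$proportion) - 1) > 1e-8)
      stop("theta_classes proportions must sum to 1")
    if (any(theta_classes$theta < 0)) stop("theta values must be >= 0")
    theta_true <- sum(theta_classes$proportion * theta_classes$theta)
  } else {
    if (is.null(theta_site)) stop(model_kind, " model requires theta_site")
    stopifnot(theta_site >= 0)
    theta_true <- theta_site
  }
  if (model_kind == "structured") {
    if (is.null(divergence_t) || divergence_t < 0)
      stop("structured model requires divergence_t >= 0")
    if (n_haplotypes %% 2L != 0L)
      stop("structured model requires an even number of haplotypes")
  } else divergence_t <- NULL
  structure(list(model_kind = model_kind, theta_site = theta_site,
                 theta_classes = theta_classes, divergence_t = divergence_t,
                 n_loci = n_loci, locus_len = locus_len,
                 n_haplotypes = n_haplotypes, seed = as.integer(seed),
                 theta_true = theta_true),
            class = "rad_model_config")
}

#' @export
print.rad_model_config <- function(x, ...) {
  cat("RAD simulation config:", x$model_kind, "model\n")
  cat("  loci:", x$n_loci, "x", x$locus_len, "bp,",
      x$n_haplotypes, "haplotypes, seed", x$seed, "\n")
  if (x$model_kind == "heterogeneous") {
    cls <- paste0(format(x$theta_classes$proportion), " @ theta=",
                  format(x$theta_classes$theta), collapse = "; ")
    cat("  theta classes:", cls, "\n")
  } else cat("  theta/site:", x$theta_site, "\n")
  if (!is.null(x$divergence_t)) cat("  divergence t:", x$divergence_t, "(4Ne units)\n")
  cat("  weighted-mean theta (theta_true):", x$theta_true, "\n")
  invisible(x)
}

# theta assigned to each locus; heterogeneous classes are filled by
# deterministic counts (round of cumulative proportions) so the realised
# class fractions match the model exactly.
theta_by_locus <- function(config) {
  if (config$model_kind != "heterogeneous")
    return(rep(config$theta_site, config$n_loci))
  counts <- diff(c(0L, round(cumsum(config$theta_classes$proportion) * config$n_loci)))
  rep(config$theta_classes$theta, counts)
}

# n-coalescent genealogy under the current RNG stream. Structured model:
# within-deme coalescence only until divergence_t (backwards in time), then
# the demes merge into one ancestral population.
coalescent_tree <- function(n_tips, model_kind = "panmictic", divergence_t = 0) {
  stopifnot(n_tips >= 2L)
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n_tips)
  nxt <- n_tips + 1L
  t_now <- 0
  tip_deme <- NULL
  if (identical(model_kind, "structured")) {
    tip_deme <- rep(1:2, each = n_tips %/% 2L)
    lin_deme <- tip_deme
    repeat {
      k <- tabulate(lin_deme, 2L)
      rates <- k * (k - 1)
      total <- sum(rates)
      if (total == 0) break
      w <- rexp(1L, total)
      if (t_now + w >= divergence_t) break
      t_now <- t_now + w
      d <- sample.int(2L, 1L, prob = rates)
      idx <- active[lin_deme == d]
      pick <- sample(idx, 2L)
      parent[pick] <- nxt
      node_time[nxt] <- t_now
      keep <- !(active %in% pick)
      lin_deme <- c(lin_deme[keep], d)
      active <- c(active[keep], nxt)
      nxt <- nxt + 1L
    }
    t_now <- divergence_t
  }
  while (length(active) > 1L) {
    k <- length(active)
    t_now <- t_now + rexp(1L, k * (k - 1))
    pick <- sample(active, 2L)
    parent[pick] <- nxt
    node_time[nxt] <- t_now
    active <- c(active[!(active %in% pick)], nxt)
    nxt <- nxt + 1L
  }
  structure(list(n_tips = n_tips, parent = parent, node_time = node_time,
                 model_kind = model_kind,
                 divergence_t = if (identical(model_kind, "structured")) divergence_t else NULL,
                 tip_deme = tip_deme),
            class = "rad_genealogy")
}

#' Simulate one locus genealogy
#'
#' Draws the coalescent genealogy of one locus under the configured model,
#' using the locus's own reproducible RNG substream (derived from
#' \code{config$seed} and \code{locus_index}); this is the same genealogy
#' \code{\link{simulate_genome}} uses for that locus.
#'
#' @param config a \code{\link{model_config}}.
#' @param locus_index 1-based locus index selecting the RNG substream.
#' @return an object of class \code{rad_genealogy}: ultrametric topology with
#'   node times in units of \eqn{4 N_e} generations (tips at time 0, root =
#'   node \code{2 * n_tips - 1}).
#' @export
simulate_genealogy <- function(config, locus_index = 1L) {
  stopifnot(inherits(config, "rad_model_config"), locus_index >= 1L)
  with_seed(mix_seed(config$seed, locus_index),
            coalescent_tree(config$n_haplotypes, config$model_kind,
                            config$divergence_t %||% 0))
}

# time of the MRCA of tips i and j
pair_tmrca <- function(gen, i, j) {
  anc <- function(v) {
    out <- v
    while (gen$parent[v] != 0L) { v <- gen$parent[v]; out <- c(out, v) }
    out
  }
  common <- intersect(anc(i), anc(j))
  min(gen$node_time[common])
}

tree_height <- function(gen) gen$node_time[2L * gen$n_tips - 1L]

# JC sequence evolution along a genealogy under the current RNG stream.
# Substitutions arise at rate theta_site per site per unit (4Ne) branch
# length; per branch the exact JC transition is sampled directly: a site
# differs from its parent with probability 3/4 * (1 - exp(-4 r b / 3)) and
# the new base is uniform among the other three.
mutate_tree <- function(gen, theta_site, locus_len) {
  n_nodes <- 2L * gen$n_tips - 1L
  root <- n_nodes
  seqs <- vector("list", n_nodes)
  seqs[[root]] <- sample.int(4L, locus_len, replace = TRUE)
  for (v in order(gen$node_time, decreasing = TRUE)) {
    if (v == root) next
    s <- seqs[[gen$parent[v]]]
    bl <- gen$node_time[gen$parent[v]] - gen$node_time[v]
    p_diff <- 0.75 * (1 - exp(-4 * theta_site * bl / 3))
    k <- rbinom(1L, locus_len, p_diff)
    if (k > 0L) {
      pos <- sample.int(locus_len, k)
      s[pos] <- ((s[pos] - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L
    }
    seqs[[v]] <- s
  }
  vapply(seqs[seq_len(gen$n_tips)],
         function(v) intToUtf8(.BASE_CODES[v]), "")
}

#' Evolve sequences along a genealogy
#'
#' Places Jukes-Cantor substitutions on the branches of a genealogy, starting
#' from a uniform random root sequence, calibrated so that the expected
#' per-site diversity of two random haplotypes equals \code{theta_site} in
#' the low-\eqn{\theta} limit (finite-site saturation lowers it slightly at
#' high \eqn{\theta}).
#'
#' @param genealogy a \code{rad_genealogy}.
#' @param theta_site per-site \eqn{\theta}.
#' @param locus_len sequence length (bp).
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @param locus_id identifier stored in the result.
#' @return a \code{locus_alignment}: list with \code{locus_id},
#'   \code{sequences} (named character vector, one equal-length ACGT string
#'   per haplotype) and \code{theta_used}.
#' @export
mutate_alignment <- function(genealogy, theta_site, locus_len,
                             seed = NULL, locus_id = 1L) {
  stopifnot(inherits(genealogy, "rad_genealogy"),
            theta_site >= 0, locus_len >= 1L)
  seqs <- with_seed(seed, mutate_tree(genealogy, theta_site, as.integer(locus_len)))
  names(seqs) <- paste0("hap", seq_along(seqs))
  structure(list(locus_id = locus_id, sequences = seqs,
                 theta_used = theta_site),
            class = "locus_alignment")
}

#' Simulate a multi-locus genome sample
#'
#' Simulates \code{n_loci} unlinked loci (complete linkage within each
#' locus): one coalescent genealogy and one Jukes-Cantor alignment per
#' locus. In the heterogeneous model, loci are assigned to \eqn{\theta}
#' classes deterministically in the configured proportions.
#'
#' @param config a \code{\link{model_config}}.
#' @return an object of class \code{rad_genome}: list with the config, the
#'   per-locus \eqn{\theta} vector, \code{theta_true} (weighted-mean
#'   \eqn{\theta}) and \code{sequences}, a character matrix with one row per
#'   locus and one column per haplotype.
#' @examples
#' g <- simulate_genome(model_config("panmictic", theta_site = 0.01,
#'                                   n_loci = 5, locus_len = 500, seed = 42))
#' dim(g$sequences)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "rad_model_config"))
  th <- theta_by_locus(config)
  nh <- config$n_haplotypes
  seqs <- matrix("", config$n_loci, nh,
                 dimnames = list(NULL, paste0("hap", seq_len(nh))))
  for (i in seq_len(config$n_loci)) {
    seqs[i, ] <- with_seed(mix_seed(config$seed, i), {
      gen <- coalescent_tree(nh, config$model_kind, config$divergence_t %||% 0)
      mutate_tree(gen, th[i], config$locus_len)
    })
  }
  structure(list(config = config, theta_by_locus = th,
                 theta_true = config$theta_true, sequences = seqs),
            class = "rad_genome")
}

#' @export
print.rad_genome <- function(x, ...) {
  cat("Simulated RAD genome:", nrow(x$sequences), "loci x",
      x$config$locus_len, "bp,", ncol(x$sequences), "haplotypes (",
      x$config$model_kind, "model, theta_true =", x$theta_true, ")\n")
  invisible(x)
}

#' Write simulated loci to FASTA
#'
#' @param genome a \code{rad_genome} (or character matrix of sequences,
#'   loci in rows, haplotypes in columns).
#' @param path output file. With \code{per_haplotype = FALSE} (default) one
#'   multi-FASTA is written with headers \code{locus<i>|hap<j>}; with
#'   \code{per_haplotype = TRUE}, \code{path} is treated as a filename prefix
#'   and one file \code{<path><hapname>.fasta} per haplotype is written with
#'   loci as records (the layout \code{\link{load_aligned_genomes}} reads).
#' @param per_haplotype write one FASTA per haplotype instead of one
#'   combined file.
#' @return invisibly, the written file path(s).
#' @export
write_genome_fasta <- function(genome, path, per_haplotype = FALSE) {
  seqs <- if (inherits(genome, "rad_genome")) genome$sequences else genome
  stopifnot(is.matrix(seqs))
  haps <- colnames(seqs) %||% paste0("hap", seq_len(ncol(seqs)))
  if (per_haplotype) {
    paths <- character(0)
    for (j in seq_along(haps)) {
      x <- Biostrings::DNAStringSet(seqs[, j])
      names(x) <- paste0("locus", seq_len(nrow(seqs)))
      f <- paste0(path, haps[j], ".fasta")
      Biostrings::writeXStringSet(x, f)
      paths <- c(paths, f)
    }
    return(invisible(paths))
  }
  ids <- as.vector(outer(seq_len(nrow(seqs)), haps,
                         function(i, h) paste0("locus", i, "|", h)))
  x <- Biostrings::DNAStringSet(as.vector(seqs))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
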