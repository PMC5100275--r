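# In silico RAD digestion of real (or fixture) reference-aligned phased
# genomes: load per-haplotype FASTA files, pair haploid genomes into diploid
# individuals within populations, digest every chromosome and aggregate the
# diversity estimators genome-wide.

#' Load reference-aligned phased haploid genomes
#'
#' Reads one FASTA per haplotype (records = chromosomes, identical names and
#' lengths across haplotypes; the genomes must already be reference-aligned,
#' no alignment is performed). N runs are allowed and reported.
#'
#' @param fasta_paths named character vector of FASTA paths; names are the
#'   haplotype ids.
#' @param population_map named character vector mapping every haplotype id
#'   to its population label.
#' @return object of class \code{aligned_genome_set}: list with
#'   \code{sequences} (character matrix, chromosomes x haplotypes),
#'   \code{populations}, and \code{n_fraction} (per-haplotype fraction of
#'   non-ACGT sites).
#' @export
load_aligned_genomes <- function(fasta_paths, population_map) {
  stopifnot(length(fasta_paths) >= 2L)
  if (is.null(names(fasta_paths))) stop("fasta_paths must be named by haplotype")
  haps <- names(fasta_paths)
  if (anyDuplicated(haps)) stop("haplotype names must be unique")
  missing_pop <- setdiff(haps, names(population_map))
  if (length(missing_pop) > 0L)
    stop("no population label for haplotype(s): ",
         paste(missing_pop, collapse = ", "))
  sets <- lapply(fasta_paths, Biostrings::readDNAStringSet)
  chroms <- names(sets[[1L]])
  for (j in seq_along(sets)) {
    if (!identical(sort(names(sets[[j]])), sort(chroms)))
      stop("haplotype ", haps[j], " has a different chromosome set")
    sets[[j]] <- sets[[j]][chroms]
  }
  lens <- vapply(sets, function(s) Biostrings::width(s), integer(length(chroms)))
  lens <- matrix(lens, nrow = length(chroms))
  bad <- which(apply(lens, 1L, function(v) length(unique(v)) > 1L))
  if (length(bad) > 0L)
    stop("length mismatch on chromosome ", chroms[bad[1L]],
         " between haplotypes ", paste(haps, collapse = ", "))
  seqs <- vapply(sets, as.character, character(length(chroms)))
  seqs <- matrix(seqs, nrow = length(chroms),
                 dimnames = list(chroms, haps))
  n_frac <- vapply(seq_along(haps), function(j) {
    x <- paste(seqs[, j], collapse = "")
    r <- charToRaw(x)
    sum(!(r %in% .ACGT_RAW)) / length(r)
  }, 0)
  names(n_frac) <- haps
  message("loaded ", length(haps), " haplotypes x ", length(chroms),
          " chromosomes; non-ACGT fraction: ",
          paste(sprintf("%s=%.3g", haps, n_frac), collapse = ", "))
  structure(list(sequences = seqs,
                 populations = population_map[haps],
                 n_fraction = n_frac),
            class = "aligned_genome_set")
}

#' Read a diploid pairing table
#'
#' TSV with columns \code{individual_id}, \code{haplotype_a},
#' \code{haplotype_b}, \code{population}: which haploid genomes are merged
#' into which diploid individual. Haplotypes must be paired within one
#' population and used at most once.
#'
#' @param path TSV path.
#' @return validated data frame.
#' @export
read_pairing_table <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  need <- c("individual_id", "haplotype_a", "haplotype_b", "population")
  if (!all(need %in% names(tab)))
    stop("pairing table needs columns: ", paste(need, collapse = ", "))
  used <- c(tab$haplotype_a, tab$haplotype_b)
  if (anyDuplicated(used)) stop("each haplotype may be used at most once")
  tab
}

#' Digest real genomes and estimate diversity per diploid pair
#'
#' For every pair of diploid individuals from the same population, digests
#' all chromosomes of the four underlying haplotypes and computes the
#' genome-wide diversity summary (tags aggregated across chromosomes via
#' \eqn{\sum_k \pi_k / \sum_k L_k}). Tags overlapping non-ACGT symbols are
#' excluded symmetrically from \eqn{\pi_{RAD}} and \eqn{\pi_{true}} (see
#' \code{\link{build_catalog}}).
#'
#' @param genomes an \code{\link{load_aligned_genomes}} result.
#' @param pairing a pairing table (see \code{\link{read_pairing_table}}) or
#'   data frame with the same columns.
#' @param motifs a \code{motif_set} or character vector of motifs (e.g. a
#'   named enzyme recognition site).
#' @param tag_len tag length in bp.
#' @param mode estimator normalisation, see \code{\link{pi_locus}}.
#' @param search_revcomp also search motif reverse complements, see
#'   \code{\link{build_catalog}}.
#' @return data frame with one row per within-population pair of
#'   individuals: ids, population and the \code{\link{diversity_result}}
#'   columns. Attribute \code{"snp_counts"} holds the per-tag SNP counts of
#'   each pair (for \code{\link{snp_dispersion_test}}), attribute
#'   \code{"catalogs"} the catalogs.
#' @export
digest_and_estimate <- function(genomes, pairing, motifs, tag_len = 100L,
                                mode = "pair_mean", search_revcomp = FALSE) {
  stopifnot(inherits(genomes, "aligned_genome_set"))
  haps <- colnames(genomes$sequences)
  for (col in c("haplotype_a", "haplotype_b")) {
    unknown <- setdiff(pairing[[col]], haps)
    if (length(unknown) > 0L)
      stop("pairing table references unknown haplotype(s): ",
           paste(unknown, collapse = ", "))
  }
  pops <- genomes$populations
  wrong <- pairing$population != pops[pairing$haplotype_a] |
    pairing$population != pops[pairing$haplotype_b]
  if (any(wrong))
    stop("individual(s) pair haplotypes across populations: ",
         paste(pairing$individual_id[wrong], collapse = ", "))
  rows <- list(); snp_counts <- list(); catalogs <- list()
  for (pop in unique(pairing$population)) {
    inds <- pairing[pairing$population == pop, , drop = FALSE]
    if (nrow(inds) < 2L) next
    combos <- utils::combn(nrow(inds), 2L)
    for (k in seq_len(ncol(combos))) {
      i1 <- inds[combos[1L, k], ]; i2 <- inds[combos[2L, k], ]
      four <- c(i1$haplotype_a, i1$haplotype_b, i2$haplotype_a, i2$haplotype_b)
      pair <- structure(list(individual_1 = c(1L, 2L),
                             individual_2 = c(3L, 4L)),
                        class = "diploid_pair")
      cat_ <- build_catalog(genomes$sequences[, four, drop = FALSE],
                            motifs, pair, tag_len, search_revcomp)
      if (nrow(cat_$loci) == 0L) {
        warning("no RAD loci for pair ", i1$individual_id, " / ",
                i2$individual_id)
        next
      }
      res <- suppressWarnings(diversity_result(cat_, mode))
      id <- paste0(i1$individual_id, ":", i2$individual_id)
      rows[[id]] <- cbind(data.frame(individual_1 = i1$individual_id,
                                     individual_2 = i2$individual_id,
                                     population = pop), res)
      snp_counts[[id]] <- tag_snp_counts(cat_)
      catalogs[[id]] <- cat_
    }
  }
  if (length(rows) == 0L) stop("no within-population pair of individuals")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "snp_counts") <- snp_counts
  attr(out, "catalogs") <- catalogs
  out
}
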