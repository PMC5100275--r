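# Nucleotide diversity estimators for RAD catalogs:
# pi = sum_k pi_k / sum_k L_k over RAD loci, where pi_k aggregates the
# cross-individual Hamming distances d_ij over the h1, h2 haplotypes
# present, normalised by h1*h2 (mean pairwise distance, default) or by
# h1+h2 (the published formula; both agree when h1 = h2 = 2). pi_true uses
# all haplotypes (h1 = h2 = 2); pi_RAD uses intact haplotypes at loci
# shared by both individuals.

#' Hamming distance between two tags
#'
#' Counts differing sites between two equal-length tags. Positions where
#' either tag carries a non-ACGT symbol are skipped (the effective length is
#' reduced accordingly).
#'
#' @param tag_i,tag_j equal-length sequence strings.
#' @return integer count of differing (comparable) sites.
#' @examples
#' tag_distance("ACGT", "TGCA")
#' @export
tag_distance <- function(tag_i, tag_j) {
  a <- charToRaw(tag_i)
  b <- charToRaw(tag_j)
  if (length(a) != length(b)) stop("tags must have equal length")
  valid <- (a %in% .ACGT_RAW) & (b %in% .ACGT_RAW)
  sum(a[valid] != b[valid])
}

#' Per-locus genetic distance between two individuals
#'
#' Evaluates \eqn{\pi_k} for one locus from the tags present in each
#' individual. The printed-formula normalisation divides the sum of
#' cross-individual distances by \eqn{h_1 + h_2}; the conventional
#' mean-pairwise normalisation divides by \eqn{h_1 h_2}. The two agree when
#' \eqn{h_1 = h_2 = 2} (no drop-out) and differ when haplotypes have dropped
#' out.
#'
#' @param tags_1,tags_2 character vectors of tags present in individuals 1
#'   and 2 (length = number of haplotypes present, at least 1).
#' @param mode \code{"pair_mean"} (default, \eqn{1/(h_1 h_2)}: the mean
#'   pairwise distance, which is also what genotype-level RAD data yields,
#'   since an apparent homozygote duplicates its intact haplotype) or
#'   \code{"as_printed"} (\eqn{1/(h_1 + h_2)}, the published formula).
#'   \code{pair_mean} is the default because only it reproduces the study's
#'   structured-model limit (no bias between long-isolated populations) and
#'   its predictive distributions for highly polymorphic genomes.
#' @return numeric \eqn{\pi_k} (distance units, not per site).
#' @examples
#' pi_locus(c("AAAA", "AACA"), c("AAAA", "TACA")) # = (1+2+0+1)/4
#' @export
pi_locus <- function(tags_1, tags_2, mode = c("pair_mean", "as_printed")) {
  mode <- match.arg(mode)
  h1 <- length(tags_1); h2 <- length(tags_2)
  if (h1 < 1L || h2 < 1L) stop("each individual needs at least one tag")
  total <- 0
  for (i in seq_len(h1)) for (j in seq_len(h2))
    total <- total + tag_distance(tags_1[i], tags_2[j])
  total / if (mode == "as_printed") (h1 + h2) else (h1 * h2)
}

# per-locus Hamming distances for the 4 cross-individual haplotype pairs;
# rows (a1,b1), (a1,b2), (a2,b1), (a2,b2), columns = catalog loci
cross_pair_distances <- function(catalog) {
  a <- catalog$pair$individual_1
  b <- catalog$pair$individual_2
  tr <- catalog$tags_raw
  n <- nrow(catalog$loci)
  out <- matrix(0L, 4L, n)
  k <- 0L
  for (i in a) for (j in b) {
    k <- k + 1L
    out[k, ] <- colSums(matrix(tr[[i]] != tr[[j]], catalog$tag_len, n))
  }
  out
}

check_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "rad_catalog"))
  if (nrow(catalog$loci) == 0L) stop("empty catalog: no RAD loci")
  invisible(catalog)
}

#' True nucleotide diversity at RAD loci
#'
#' \eqn{\pi_{true}}: per-site diversity between the two individuals computed
#' from all haplotypes (\eqn{h_1 = h_2 = 2}) at every catalog locus,
#' regardless of restriction-site state. This is the unbiased benchmark the
#' RAD estimate is compared with.
#'
#' @param catalog a \code{\link{build_catalog}} result.
#' @return numeric per-site diversity.
#' @export
pi_true <- function(catalog) {
  check_catalog(catalog)
  d <- cross_pair_distances(catalog)
  sum(d) / 4 / (nrow(catalog$loci) * catalog$tag_len)
}

# per-locus intact masks for the two individuals
intact_masks <- function(catalog) {
  a <- catalog$pair$individual_1
  b <- catalog$pair$individual_2
  list(a1 = catalog$intact[, a[1L]], a2 = catalog$intact[, a[2L]],
       b1 = catalog$intact[, b[1L]], b2 = catalog$intact[, b[2L]])
}

#' RAD-observed nucleotide diversity
#'
#' \eqn{\pi_{RAD}}: per-site diversity between the two individuals computed
#' only from haplotypes whose restriction site is intact, at loci present
#' in both individuals (at least one intact haplotype each). This is what a
#' RAD experiment would actually measure; allele drop-out makes it an
#' underestimate of \eqn{\pi_{true}}.
#'
#' @inheritParams pi_locus
#' @param catalog a \code{\link{build_catalog}} result.
#' @return numeric per-site diversity, or \code{NA} (with a warning) when no
#'   locus is shared by the two individuals.
#' @export
pi_rad <- function(catalog, mode = c("pair_mean", "as_printed")) {
  mode <- match.arg(mode)
  check_catalog(catalog)
  m <- intact_masks(catalog)
  h1 <- m$a1 + m$a2
  h2 <- m$b1 + m$b2
  shared <- h1 > 0L & h2 > 0L
  if (!any(shared)) {
    warning("no RAD locus shared by the two individuals; pi_RAD undefined")
    return(NA_real_)
  }
  d <- cross_pair_distances(catalog)
  num <- d[1L, ] * (m$a1 & m$b1) + d[2L, ] * (m$a1 & m$b2) +
    d[3L, ] * (m$a2 & m$b1) + d[4L, ] * (m$a2 & m$b2)
  denom <- if (mode == "as_printed") h1 + h2 else h1 * h2
  sum(num[shared] / denom[shared]) / (sum(shared) * catalog$tag_len)
}

#' Per-individual locus sharing proportions
#'
#' For individual i, the proportion of its RAD loci (those with at least one
#' intact haplotype in i) that are also present in the other individual.
#' Drop-out lowers these proportions as \eqn{\theta} grows.
#'
#' @param catalog a \code{\link{build_catalog}} result.
#' @return named numeric vector \code{c(share_1, share_2)}; \code{NA} with a
#'   warning for an individual with no loci.
#' @export
sharing_proportions <- function(catalog) {
  check_catalog(catalog)
  m <- intact_masks(catalog)
  in1 <- m$a1 | m$a2
  in2 <- m$b1 | m$b2
  both <- sum(in1 & in2)
  if (sum(in1) == 0L || sum(in2) == 0L) {
    warning("an individual has no RAD loci; sharing proportions undefined")
    return(c(share_1 = NA_real_, share_2 = NA_real_))
  }
  c(share_1 = both / sum(in1), share_2 = both / sum(in2))
}

#' SNPs per tag
#'
#' Number of segregating sites among the (up to 4) haplotype tags at each
#' catalog locus, the raw counts for \code{\link{snp_dispersion_test}}.
#'
#' @param catalog a \code{\link{build_catalog}} result.
#' @return integer vector, one count per catalog locus.
#' @export
tag_snp_counts <- function(catalog) {
  check_catalog(catalog)
  n <- nrow(catalog$loci)
  tr <- catalog$tags_raw
  diff_any <- matrix(FALSE, catalog$tag_len, n)
  for (j in seq_along(tr)[-1L])
    diff_any <- diff_any | (tr[[1L]] != tr[[j]])
  as.integer(colSums(diff_any))
}

#' Dispersion test for SNP-per-tag counts
#'
#' Chi-square index-of-dispersion test of Poisson equidispersion. Under a
#' homogeneous Poisson process the statistic \eqn{D = (n-1) s^2 / \bar x} is
#' approximately \eqn{\chi^2_{n-1}}; the one-sided upper tail tests for
#' overdispersion (SNPs more heterogeneous across tags than Poisson, as
#' expected when \eqn{\theta} varies along the genome or genealogies differ
#' between loci).
#'
#' @param per_tag_snp_counts integer vector of SNP counts, one per tag
#'   (length >= 2).
#' @return list with \code{dispersion_index} (\eqn{D}), \code{p_value}
#'   (one-sided, overdispersion), \code{df} and \code{ratio}
#'   (variance/mean). All-\code{NA} with a warning when the mean is 0.
#' @examples
#' snp_dispersion_test(c(0, 1, 0, 2, 12, 0, 9, 1))
#' @export
snp_dispersion_test <- function(per_tag_snp_counts) {
  x <- per_tag_snp_counts
  n <- length(x)
  stopifnot(n >= 2L)
  m <- mean(x)
  if (m == 0) {
    warning("all SNP counts are zero; dispersion undefined")
    return(list(dispersion_index = NA_real_, p_value = NA_real_,
                df = n - 1L, ratio = NA_real_))
  }
  D <- (n - 1) * var(x) / m
  list(dispersion_index = D,
       p_value = pchisq(D, df = n - 1L, lower.tail = FALSE),
       df = n - 1L, ratio = var(x) / m)
}

#' Full diversity summary for one catalog
#'
#' Computes \eqn{\pi_{true}}, \eqn{\pi_{RAD}}, their ratio (the drop-out
#' bias), catalog/shared locus counts and sharing proportions for the
#' diploid pair the catalog was built for.
#'
#' @inheritParams pi_rad
#' @return one-row data frame: \code{pi_true}, \code{pi_rad}, \code{ratio},
#'   \code{n_catalog}, \code{n_shared}, \code{share_1}, \code{share_2},
#'   \code{normalization_mode}.
#' @export
diversity_result <- function(catalog, mode = c("pair_mean", "as_printed")) {
  mode <- match.arg(mode)
  check_catalog(catalog)
  pt <- pi_true(catalog)
  pr <- pi_rad(catalog, mode)
  m <- intact_masks(catalog)
  shared <- (m$a1 | m$a2) & (m$b1 | m$b2)
  sh <- sharing_proportions(catalog)
  data.frame(pi_true = pt, pi_rad = pr,
             ratio = if (pt > 0) pr / pt else NA_real_,
             n_catalog = nrow(catalog$loci), n_shared = sum(shared),
             share_1 = unname(sh[1L]), share_2 = unname(sh[2L]),
             normalization_mode = mode)
}
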