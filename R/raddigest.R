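# In silico RAD digestion: restriction motifs, diploid pairing, and tag
# catalogs with per-haplotype intactness (allele drop-out bookkeeping).

.ACGT_RAW <- charToRaw("ACGT")

#' Draw a random restriction motif set
#'
#' Draws \code{k} distinct uniform random DNA words of length
#' \code{motif_len}, emulating the recognition sites of \code{k} restriction
#' enzymes. Searching several motifs in the same alignment increases the
#' number of RAD loci without enlarging the simulated genome.
#'
#' @param k number of motifs (10 in the study design).
#' @param motif_len motif length in bp (8 in the study design).
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return an object of class \code{motif_set}: list with \code{motifs}
#'   (character vector), \code{motif_len} and \code{seed}.
#' @examples
#' draw_motifs(3, 8, seed = 1)
#' @export
draw_motifs <- function(k = 10L, motif_len = 8L, seed = NULL) {
  k <- as.integer(k); motif_len <- as.integer(motif_len)
  stopifnot(k >= 1L, motif_len >= 1L)
  if (4^motif_len < k)
    stop("cannot draw ", k, " distinct motifs of length ", motif_len)
  motifs <- with_seed(seed, {
    if (4^motif_len <= 65536) {
      all_words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")),
                                                   motif_len),
                                               stringsAsFactors = FALSE))
      sample(all_words, k)
    } else {
      out <- character(0)
      while (length(out) < k) {
        new <- vapply(seq_len(k - length(out)), function(i)
          intToUtf8(.BASE_CODES[sample.int(4L, motif_len, replace = TRUE)]), "")
        out <- unique(c(out, new))
      }
      out
    }
  })
  structure(list(motifs = motifs, motif_len = motif_len, seed = seed),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(length(x$motifs), "restriction motifs of", x$motif_len, "bp:\n ",
      paste(x$motifs, collapse = " "), "\n")
  invisible(x)
}

# accept a motif_set, or a plain character vector (e.g. a named enzyme
# recognition site such as SbfI "CCTGCAGG")
as_motif_set <- function(motifs) {
  if (inherits(motifs, "motif_set")) return(motifs)
  stopifnot(is.character(motifs), length(motifs) >= 1L)
  motifs <- toupper(motifs)
  len <- unique(nchar(motifs))
  if (length(len) != 1L) stop("all motifs must have the same length")
  if (any(grepl("[^ACGT]", motifs))) stop("motifs must be over {A,C,G,T}")
  if (anyDuplicated(motifs)) stop("motifs must be distinct")
  structure(list(motifs = motifs, motif_len = len, seed = NULL),
            class = "motif_set")
}

#' Merge haplotypes into two diploid individuals
#'
#' Randomly partitions the four sampled haplotypes into two diploids. In the
#' structured model each individual is formed within one deme (haplotypes
#' 1+2 = individual 1, haplotypes 3+4 = individual 2), matching sampling one
#' diploid per population.
#'
#' @param model_kind model the haplotypes were simulated under.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return an object of class \code{diploid_pair}: list with
#'   \code{individual_1} and \code{individual_2}, each a pair of haplotype
#'   indices.
#' @export
pair_into_diploids <- function(model_kind = c("panmictic", "heterogeneous", "structured"),
                               seed = NULL) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "structured") {
    pair <- list(individual_1 = c(1L, 2L), individual_2 = c(3L, 4L))
  } else {
    partner <- with_seed(seed, sample.int(3L, 1L)) + 1L
    pair <- list(individual_1 = c(1L, partner),
                 individual_2 = setdiff(2:4, partner))
  }
  structure(pair, class = "diploid_pair")
}

#' @export
print.diploid_pair <- function(x, ...) {
  cat("Diploid pairing: individual 1 = haplotypes (",
      paste(x$individual_1, collapse = ","), "), individual 2 = (",
      paste(x$individual_2, collapse = ","), ")\n")
  invisible(x)
}

# forward-strand exact-match positions of all motifs in one haplotype's
# loci; returns data.frame(locus, pos, motif_index), 1-based positions.
# Loci are concatenated with a single "N" spacer so one overlapping fixed
# search scans the whole haplotype; motifs are ACGT-only, so no match can
# span the spacer.
scan_haplotype <- function(locus_seqs, motifs, offsets) {
  big <- paste(locus_seqs, collapse = "N")
  hits <- stringi::stri_locate_all_fixed(big, motifs, overlap = TRUE)
  st <- lapply(hits, function(m) m[!is.na(m[, 1L]), 1L])
  starts <- unlist(st, use.names = FALSE)
  if (length(starts) == 0L)
    return(data.frame(locus = integer(0), pos = integer(0),
                      motif_index = integer(0)))
  motif_index <- rep(seq_along(st), lengths(st))
  locus <- findInterval(starts, offsets + 1L)
  data.frame(locus = locus, pos = starts - offsets[locus],
             motif_index = motif_index)
}

#' Build a RAD tag catalog
#'
#' Scans every haplotype of every locus for exact forward-strand occurrences
#' of the restriction motifs and emits one RAD locus per position where at
#' least one haplotype carries an intact motif. For each RAD locus the
#' catalog records, per haplotype, whether the restriction site is intact
#' (the window exactly equals the motif) and the \code{tag_len}-bp tag
#' immediately 3' of the motif. Tags exist for every haplotype whether or
#' not its site is intact: \eqn{\pi_{true}} uses all of them,
#' \eqn{\pi_{RAD}} only those with intact sites. Occurrences whose tag would
#' run past the locus end are skipped; overlapping occurrences are
#' independent loci. Loci where any haplotype's tag contains a non-ACGT
#' symbol (possible for empirical genomes with N runs) are excluded
#' symmetrically from the catalog and counted in \code{n_excluded_n}.
#'
#' @param genome a \code{rad_genome}, or a character matrix of aligned
#'   sequences (loci/chromosomes in rows, haplotypes in columns; row lengths
#'   may differ between rows but not within a row).
#' @param motifs a \code{\link{draw_motifs}} result or character vector of
#'   distinct equal-length ACGT motifs.
#' @param pair a \code{\link{pair_into_diploids}} result; default pairs
#'   haplotypes (1,2) and (3,4).
#' @param tag_len tag length in bp (100 in the study design).
#' @param search_revcomp also search the reverse complements of the motifs
#'   (both-strand recognition for empirical enzymes); tags are still taken
#'   3' of the matched word on the forward strand.
#' @return an object of class \code{rad_catalog}; see Details. Main fields:
#'   \code{loci} (data frame: locus_id, position, motif_index, motif),
#'   \code{intact} (locus x haplotype logical matrix), \code{tags} (locus x
#'   haplotype character matrix), \code{pair}, \code{tag_len}.
#' @examples
#' g <- simulate_genome(model_config("panmictic", theta_site = 0.005,
#'                                   n_loci = 50, locus_len = 2000, seed = 7))
#' cat <- build_catalog(g, draw_motifs(10, 8, seed = 8),
#'                      pair_into_diploids("panmictic", seed = 9))
#' cat
#' @export
build_catalog <- function(genome, motifs, pair = NULL, tag_len = 100L,
                          search_revcomp = FALSE) {
  seqs <- if (inherits(genome, "rad_genome")) genome$sequences else genome
  stopifnot(is.matrix(seqs), is.character(seqs))
  motifs <- as_motif_set(motifs)
  tag_len <- as.integer(tag_len)
  stopifnot(tag_len >= 1L)
  nh <- ncol(seqs)
  if (is.null(pair))
    pair <- structure(list(individual_1 = c(1L, 2L), individual_2 = c(3L, 4L)),
                      class = "diploid_pair")
  search <- motifs$motifs
  if (search_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(search)))
    search <- unique(c(search, rc))
  }
  mlen <- motifs$motif_len
  locus_len <- nchar(seqs[, 1L])
  if (min(locus_len) < mlen + tag_len)
    stop("motif_len + tag_len must fit within every locus")
  offsets <- cumsum(c(0L, head(locus_len + 1L, -1L)))
  hits <- do.call(rbind, lapply(seq_len(nh), function(j)
    scan_haplotype(seqs[, j], search, offsets)))
  hits <- unique(hits)
  hits <- hits[hits$pos + mlen + tag_len - 1L <= locus_len[hits$locus], ,
               drop = FALSE]
  hits <- hits[order(hits$locus, hits$pos, hits$motif_index), , drop = FALSE]
  n <- nrow(hits)
  intact <- matrix(FALSE, n, nh)
  tags <- matrix("", n, nh, dimnames = list(NULL, colnames(seqs)))
  if (n > 0L) for (j in seq_len(nh)) {
    s <- unname(seqs[cbind(hits$locus, j)])
    intact[, j] <- substring(s, hits$pos, hits$pos + mlen - 1L) ==
      search[hits$motif_index]
    tags[, j] <- substring(s, hits$pos + mlen, hits$pos + mlen + tag_len - 1L)
  }
  tags_raw <- lapply(seq_len(nh), function(j)
    matrix(charToRaw(paste(tags[, j], collapse = "")), tag_len, n))
  ok <- rep(TRUE, n)
  for (j in seq_len(nh))
    ok <- ok & (colSums(matrix(!(tags_raw[[j]] %in% .ACGT_RAW), tag_len, n)) == 0L)
  n_excluded_n <- sum(!ok)
  if (n_excluded_n > 0L) {
    hits <- hits[ok, , drop = FALSE]
    intact <- intact[ok, , drop = FALSE]
    tags <- tags[ok, , drop = FALSE]
    tags_raw <- lapply(tags_raw, function(m) m[, ok, drop = FALSE])
    n <- nrow(hits)
  }
  structure(list(
    loci = data.frame(locus_id = hits$locus, position = hits$pos,
                      motif_index = hits$motif_index,
                      motif = search[hits$motif_index]),
    intact = intact, tags = tags, tags_raw = tags_raw,
    tag_len = tag_len, motif_len = mlen, n_haplotypes = nh,
    pair = pair, n_excluded_n = n_excluded_n),
    class = "rad_catalog")
}

#' @export
print.rad_catalog <- function(x, ...) {
  n <- nrow(x$loci)
  cat("RAD catalog:", n, "loci,", x$tag_len, "bp tags,",
      x$n_haplotypes, "haplotypes\n")
  if (n > 0L) {
    ado <- sum(rowSums(!x$intact) > 0L)
    cat("  loci with >=1 dropped haplotype:", ado,
        sprintf("(%.1f%%)\n", 100 * ado / n))
  }
  if (x$n_excluded_n > 0L)
    cat("  loci excluded for non-ACGT tags:", x$n_excluded_n, "\n")
  invisible(x)
}

#' Export a catalog as TSV (and optionally tags as FASTA)
#'
#' @param catalog a \code{rad_catalog}.
#' @param path TSV output path (locus_id, position, motif, per-haplotype
#'   intact flags).
#' @param tags_fasta optional FASTA path for the tags (headers
#'   \code{locus<id>_<pos>|<hap>|intact=<0/1>}).
#' @return invisibly, \code{path}.
#' @export
write_catalog_tsv <- function(catalog, path, tags_fasta = NULL) {
  stopifnot(inherits(catalog, "rad_catalog"))
  df <- catalog$loci
  flags <- as.data.frame(catalog$intact)
  names(flags) <- paste0("intact_hap", seq_len(catalog$n_haplotypes))
  write.table(cbind(df, flags), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(tags_fasta)) {
    nh <- catalog$n_haplotypes
    ids <- as.vector(outer(seq_len(nrow(df)), seq_len(nh), function(i, j)
      paste0("locus", df$locus_id[i], "_", df$position[i], "|hap", j,
             "|intact=", as.integer(catalog$intact[cbind(i, j)]))))
    x <- Biostrings::DNAStringSet(as.vector(catalog$tags))
    names(x) <- ids
    Biostrings::writeXStringSet(x, tags_fasta)
  }
  invisible(path)
}
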