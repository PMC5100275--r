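# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorised code paths: plain double loops over
# characters, so estimator results can be checked exactly.

# naive forward-strand scanner: every window of every haplotype
naive_scan <- function(seqs, motifs, tag_len) {
  motif_len <- nchar(motifs[1])
  hits <- list()
  for (loc in seq_len(nrow(seqs))) {
    L <- nchar(seqs[loc, 1])
    for (pos in seq_len(L - motif_len - tag_len + 1)) {
      for (mi in seq_along(motifs)) {
        any_hit <- FALSE
        for (h in seq_len(ncol(seqs))) {
          if (substr(seqs[loc, h], pos, pos + motif_len - 1) == motifs[mi]) {
            any_hit <- TRUE
            break
          }
        }
        if (any_hit)
          hits[[length(hits) + 1]] <- data.frame(
            locus = loc, pos = pos, motif_index = mi)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(locus = integer(0), pos = integer(0),
                      motif_index = integer(0)))
  do.call(rbind, hits)
}

# character-by-character Hamming distance (ACGT-only positions)
naive_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  d <- 0L
  for (i in seq_along(ca))
    if (ca[i] %in% c("A", "C", "G", "T") && cb[i] %in% c("A", "C", "G", "T") &&
        ca[i] != cb[i]) d <- d + 1L
  d
}

# naive reimplementation of all estimators by direct double loops
naive_divstats <- function(catalog, mode = "as_printed") {
  a <- catalog$pair$individual_1
  b <- catalog$pair$individual_2
  n <- nrow(catalog$loci)
  pt_num <- 0; pr_num <- 0
  n_shared <- 0L; n_in1 <- 0L; n_in2 <- 0L; n_both <- 0L
  for (k in seq_len(n)) {
    d_all <- 0
    for (i in a) for (j in b)
      d_all <- d_all + naive_distance(catalog$tags[k, i], catalog$tags[k, j])
    pt_num <- pt_num + d_all / 4
    in1 <- any(catalog$intact[k, a])
    in2 <- any(catalog$intact[k, b])
    if (in1) n_in1 <- n_in1 + 1L
    if (in2) n_in2 <- n_in2 + 1L
    if (in1 && in2) {
      n_both <- n_both + 1L
      n_shared <- n_shared + 1L
      t1 <- catalog$tags[k, a[catalog$intact[k, a]]]
      t2 <- catalog$tags[k, b[catalog$intact[k, b]]]
      h1 <- length(t1); h2 <- length(t2)
      d <- 0
      for (x in t1) for (y in t2) d <- d + naive_distance(x, y)
      pr_num <- pr_num + d / (if (mode == "as_printed") h1 + h2 else h1 * h2)
    }
  }
  list(pi_true = pt_num / (n * catalog$tag_len),
       pi_rad = if (n_shared > 0) pr_num / (n_shared * catalog$tag_len) else NA_real_,
       share_1 = n_both / n_in1, share_2 = n_both / n_in2,
       n_shared = n_shared)
}

# build a rad_catalog object directly from tags and intact flags
make_catalog <- function(tags, intact, tag_len,
                         pair = list(individual_1 = c(1L, 2L),
                                     individual_2 = c(3L, 4L))) {
  n <- nrow(tags)
  nh <- ncol(tags)
  structure(list(
    loci = data.frame(locus_id = seq_len(n), position = 1L,
                      motif_index = 1L, motif = "NNNNNNNN"),
    intact = intact, tags = tags,
    tags_raw = lapply(seq_len(nh), function(j)
      matrix(charToRaw(paste(tags[, j], collapse = "")), tag_len, n)),
    tag_len = tag_len, motif_len = 8L, n_haplotypes = nh,
    pair = structure(pair, class = "diploid_pair"), n_excluded_n = 0L),
    class = "rad_catalog")
}

# random small catalog with guaranteed >=1 intact per locus and >=1 shared
random_catalog <- function(seed, n_loci = 8L, tag_len = 12L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  tags <- matrix("", n_loci, 4L)
  intact <- matrix(FALSE, n_loci, 4L)
  ref <- replicate(n_loci, paste(sample(bases, tag_len, TRUE), collapse = ""))
  for (k in seq_len(n_loci)) {
    for (h in 1:4) {
      t <- ref[k]
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        pos <- sample(tag_len, nmut)
        for (p in pos) substr(t, p, p) <- sample(bases, 1)
      }
      tags[k, h] <- t
    }
    repeat {
      intact[k, ] <- runif(4) < 0.75
      if (any(intact[k, ])) break
    }
  }
  # force at least one shared locus
  intact[1L, ] <- TRUE
  make_catalog(tags, intact, tag_len)
}
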