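# Empirical front-end: FASTA round-trips, validation errors, N handling and
# the planted-ADO fixture with hand-computed pi values.

fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "radbias-fixtures")
      generate_fixtures(dir, seed = 5)
    }
    dir
  }
})

pops4 <- setNames(rep("popA", 4), paste0("hap", 1:4))

test_that("FASTA round-trip reproduces the in-memory pipeline bit-for-bit", {
  dir <- fixture_dir()
  cfg <- model_config("panmictic", theta_site = 0.007, n_loci = 5,
                      locus_len = 2000, seed = 5)
  genome <- simulate_genome(cfg)
  paths <- setNames(file.path(dir, paste0("sim_hap", 1:4, ".fasta")),
                    paste0("hap", 1:4))
  genomes <- suppressMessages(load_aligned_genomes(paths, pops4))
  expect_identical(unname(genomes$sequences), unname(genome$sequences))
  motifs <- draw_motifs(10, 6, seed = 55)
  pairing <- read_pairing_table(file.path(dir, "pairing.tsv"))
  res <- digest_and_estimate(genomes, pairing, motifs, tag_len = 60)
  cat_mem <- build_catalog(genome, motifs, tag_len = 60)
  mem <- diversity_result(cat_mem)
  expect_identical(res$pi_true, mem$pi_true)
  expect_identical(res$pi_rad, mem$pi_rad)
  expect_identical(res$n_catalog, mem$n_catalog)
})

test_that("planted-ADO fixture reproduces hand-computed pi values", {
  dir <- fixture_dir()
  exp_ <- generate_fixtures(dir, seed = 5)$planted_expected
  paths <- setNames(file.path(dir, paste0("planted_hap", 1:4, ".fasta")),
                    paste0("hap", 1:4))
  genomes <- suppressMessages(load_aligned_genomes(paths, pops4))
  pairing <- read_pairing_table(file.path(dir, "pairing.tsv"))
  res <- digest_and_estimate(genomes, pairing, exp_$motif,
                             tag_len = exp_$tag_len)
  expect_identical(res$n_catalog, exp_$n_catalog)
  expect_identical(res$n_shared, exp_$n_shared)
  expect_equal(res$pi_true, exp_$pi_true)
  expect_equal(res$pi_rad, exp_$pi_rad)
  expect_lt(res$pi_rad, res$pi_true)
  res_ap <- digest_and_estimate(genomes, pairing, exp_$motif,
                                tag_len = exp_$tag_len, mode = "as_printed")
  expect_equal(res_ap$pi_rad, exp_$pi_rad_as_printed)
})

test_that("N-run genomes load with reported N fraction and digest unchanged", {
  dir <- fixture_dir()
  exp_ <- generate_fixtures(dir, seed = 5)$planted_expected
  paths <- setNames(file.path(dir, paste0("nrun_hap", 1:4, ".fasta")),
                    paste0("hap", 1:4))
  msg <- capture.output(
    genomes <- load_aligned_genomes(paths, pops4), type = "message")
  expect_match(paste(msg, collapse = " "), "non-ACGT fraction")
  expect_gt(genomes$n_fraction[["hap1"]], 0)
  expect_identical(genomes$n_fraction[["hap2"]], 0)
  # the N run lies outside both tags: estimates unchanged
  pairing <- read_pairing_table(file.path(dir, "pairing.tsv"))
  res <- digest_and_estimate(genomes, pairing, exp_$motif,
                             tag_len = exp_$tag_len)
  expect_equal(res$pi_true, exp_$pi_true)
})

test_that("tags overlapping N are excluded symmetrically from both estimators", {
  planted <- radbias:::planted_genome()
  seqs <- planted$sequences
  # blank part of locus 2's tag in hap1: the locus must drop from catalog
  substr(seqs[1, "hap1"], 210, 212) <- "NNN"
  cat_ <- build_catalog(seqs, planted$expected$motif,
                        tag_len = planted$expected$tag_len)
  expect_identical(nrow(cat_$loci), 1L)
  expect_identical(cat_$n_excluded_n, 1L)
  expect_equal(pi_true(cat_), 0.5 / 20)
})

test_that("malformed genome sets are rejected with informative errors", {
  dir <- tempdir()
  a <- file.path(dir, "a.fasta"); b <- file.path(dir, "b.fasta")
  writeLines(c(">chr1", "ACGTACGTAC"), a)
  writeLines(c(">chr1", "ACGTACG"), b)
  expect_error(
    suppressMessages(load_aligned_genomes(c(h1 = a, h2 = b),
                                          c(h1 = "p", h2 = "p"))),
    "length mismatch")
  writeLines(c(">chr2", "ACGTACGTAC"), b)
  expect_error(
    suppressMessages(load_aligned_genomes(c(h1 = a, h2 = b),
                                          c(h1 = "p", h2 = "p"))),
    "chromosome set")
  writeLines(c(">chr1", "ACGTACGTAC"), b)
  expect_error(
    suppressMessages(load_aligned_genomes(c(h1 = a, h2 = b), c(h1 = "p"))),
    "population")
})

test_that("pairing across populations or reused haplotypes is rejected", {
  dir <- fixture_dir()
  paths <- setNames(file.path(dir, paste0("planted_hap", 1:4, ".fasta")),
                    paste0("hap", 1:4))
  pops <- setNames(c("popA", "popA", "popB", "popB"), paste0("hap", 1:4))
  genomes <- suppressMessages(load_aligned_genomes(paths, pops))
  bad <- data.frame(individual_id = c("i1", "i2"),
                    haplotype_a = c("hap1", "hap3"),
                    haplotype_b = c("hap2", "hap4"),
                    population = c("popA", "popA"))
  expect_error(digest_and_estimate(genomes, bad, "TTTTCCCC", tag_len = 20),
               "across populations")
  dup <- data.frame(individual_id = c("i1", "i2"),
                    haplotype_a = c("hap1", "hap1"),
                    haplotype_b = c("hap2", "hap2"),
                    population = "popA")
  f <- tempfile(fileext = ".tsv")
  write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_pairing_table(f), "at most once")
})

test_that("results are independent of chromosome order", {
  cfg <- model_config("panmictic", theta_site = 0.02, n_loci = 6,
                      locus_len = 1500, seed = 61)
  g <- simulate_genome(cfg)
  motifs <- draw_motifs(6, 5, seed = 62)
  r1 <- diversity_result(build_catalog(g$sequences, motifs, tag_len = 40))
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  r2 <- diversity_result(build_catalog(g$sequences[perm, , drop = FALSE],
                                       motifs, tag_len = 40))
  expect_equal(r1$pi_true, r2$pi_true)
  expect_equal(r1$pi_rad, r2$pi_rad)
  expect_identical(r1$n_catalog, r2$n_catalog)
})

test_that("reverse-complement search finds sites on either strand record", {
  seqs <- matrix(paste(rep("A", 60), collapse = ""), 1, 4)
  for (h in 1:4) substr(seqs[1, h], 11, 16) <- "GGATCC" # palindromic (BamHI)
  cat1 <- build_catalog(seqs, "GGATCC", tag_len = 10, search_revcomp = TRUE)
  expect_identical(nrow(cat1$loci), 1L) # revcomp identical -> deduplicated
  seqs2 <- matrix(paste(rep("A", 60), collapse = ""), 1, 4)
  for (h in 1:4) substr(seqs2[1, h], 11, 16) <- "GAATTG"
  cat2 <- build_catalog(seqs2, "CAATTC", tag_len = 10, search_revcomp = FALSE)
  expect_identical(nrow(cat2$loci), 0L)
  cat3 <- build_catalog(seqs2, "CAATTC", tag_len = 10, search_revcomp = TRUE)
  expect_identical(nrow(cat3$loci), 1L)
})
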