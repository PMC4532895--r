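# Seed signatures, per-locus classification, overlap resolution, and the
# transcriptome-wide census.

test_that("seed signatures follow the site-type definitions", {
  sig <- seed_signatures("GGAAUGU")
  expect_equal(unname(sig), c("ACAUUCCA", "ACAUUCC", "CAUUCCA", "CAUUCC",
                              "ACAUUC"))
  expect_equal(seed_signatures("AAAAAAA")[["8mer"]], "UUUUUUUA")
  # structural invariants of the signature set
  expect_equal(sig[["8mer"]], paste0(sig[["7mer-m8"]], "A"))
  expect_equal(sig[["7mer-A1"]], paste0(sig[["6mer"]], "A"))
  expect_true(endsWith(sig[["7mer-m8"]], sig[["6mer"]]))
  expect_equal(sig[["offset-6mer"]], rc_rna(substr("GGAAUGU", 2, 7)))
  expect_error(seed_signatures("GGANUGU"), "non-nucleotide")
})

test_that("each locus is classified into exactly one type by the hierarchy", {
  fam <- example_family()
  s <- find_sites("GGACAUUCCAGG", fam)
  expect_equal(nrow(s), 1L)
  expect_equal(s$site_type, "8mer")
  expect_equal(c(s$start, s$end), c(2L, 10L))

  s <- find_sites("GGACAUUCCGGG", fam)      # m8 match, no A1
  expect_equal(s$site_type, "7mer-m8")
  s <- find_sites("GGGCAUUCCAGG", fam)      # A1 present, no m8 pair
  expect_equal(s$site_type, "7mer-A1")
  s <- find_sites("GGGCAUUCCGGG", fam)      # neither
  expect_equal(s$site_type, "6mer")
  s <- find_sites("GGGACAUUCGGG", fam)      # match to nt 3-8 only
  expect_equal(s$site_type, "offset-6mer")
  expect_equal(nrow(find_sites("GGGGGGGGGGGG", fam)), 0L)
  expect_equal(nrow(find_sites("GGACANUCCAGG", fam)), 0L)  # N never matches
  expect_error(find_sites("", fam), "nonempty")
})

test_that("classification partitions seed matches on random UTRs", {
  fam <- example_family()
  sig <- seed_signatures(fam)
  count_occ <- function(utr, pat) {   # overlapping occurrences
    k <- nchar(pat)
    sum(vapply(seq_len(nchar(utr) - k + 1L),
               function(i) substr(utr, i, i + k - 1L) == pat, logical(1)))
  }
  set.seed(42)
  for (r in 1:25) {
    utr <- rand_rna(400, gc = 0.3)
    s <- find_sites(utr, fam, resolve_overlaps = FALSE)
    n_m8_string <- count_occ(utr, sig[["7mer-m8"]])
    n_core <- count_occ(utr, sig[["6mer"]])
    counts <- table(factor(s$site_type,
                           levels = c("8mer", "7mer-m8", "7mer-A1", "6mer",
                                      "offset-6mer")))
    expect_equal(unname(counts[["8mer"]] + counts[["7mer-m8"]]),
                 n_m8_string)
    expect_equal(unname(sum(counts[c("8mer", "7mer-m8", "7mer-A1",
                                     "6mer")])), n_core)
  }
})

test_that("planted signatures are recovered at their exact offsets", {
  fam <- example_family()
  sig <- seed_signatures(fam)
  set.seed(7)
  for (st in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    utr <- paste0(rand_rna(40, gc = 1), sig[[st]], rand_rna(40, gc = 1))
    s <- find_sites(utr, fam)
    expect_equal(s$site_type, st)
    expect_equal(s$start, 40L)
    expect_false(s$in_ribosome_shadow)
  }
  # within the first 15 nt the site is flagged as in the ribosome path
  utr <- paste0(rand_rna(5, gc = 1), sig[["8mer"]], rand_rna(40, gc = 1))
  expect_true(find_sites(utr, fam)$in_ribosome_shadow)
})

test_that("overlapping distinct loci resolve by priority then 5' position", {
  fam <- example_family()
  # two overlapping 6mer cores: CAUUCCAUUCC has cores at 0 and 4
  utr <- paste0("GG", "CAUUCCAUUCC", "GG")
  s <- find_sites(utr, fam)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 2L)                   # 5'-most wins at equal priority
  s2 <- find_sites(utr, fam, resolve_overlaps = FALSE)
  expect_equal(nrow(s2), 2L)                  # both loci visible unresolved
})

test_that("ORF site counts follow the same hierarchy", {
  fam <- example_family()
  sig <- seed_signatures(fam)[["8mer"]]
  orf <- paste0(rand_rna(30, gc = 1), sig, rand_rna(30, gc = 1), sig,
                rand_rna(30, gc = 1))
  counts <- count_orf_sites(orf, fam)
  expect_equal(unname(counts[["8mer"]]), 2L)  # two disjoint 8mers
  expect_equal(unname(counts[["7mer-m8"]]), 0L)  # not double-counted
  expect_equal(sum(count_orf_sites(rand_rna(60, gc = 1), fam)), 0L)
})

test_that("census counts distinct seed-core offsets across the transcriptome", {
  fam <- example_family()
  core <- seed_signatures(fam)[["6mer"]]
  txs <- lapply(1:10, function(i)
    make_transcript(paste0(rand_rna(20, gc = 1), core, rand_rna(20, gc = 1)),
                    id = paste0("t", i)))
  names(txs) <- paste0("t", 1:10)
  expect_equal(target_site_census(txs, fam), 10L)
  # overlapping matches counted by distinct start offsets
  tx <- make_transcript(paste0("GG", "CAUUCCAUUCC", "GG"), id = "ov")
  expect_equal(target_site_census(list(ov = tx), fam), 2L)
  tx0 <- make_transcript(rand_rna(50, gc = 1), id = "none")
  expect_equal(target_site_census(list(none = tx0), fam), 0L)
  expect_error(target_site_census(list(), fam), "empty")
})
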