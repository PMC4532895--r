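# The fourteen model features: raw values, trimmed scaling, assembly.

test_that("target-site abundance is the log10 census", {
  expect_equal(target_site_abundance(1000), 3.0)
  expect_equal(target_site_abundance(1300), 3.1139, tolerance = 1e-4)
  expect_equal(target_site_abundance(1), 0.0)
  expect_error(target_site_abundance(0), "absent")
})

test_that("seed-pairing stability matches hand-summed stack energies", {
  # GC-rich seed more stable than AU-rich of the same span
  expect_lt(seed_pairing_stability("AGCGCGCGAAAAAAAAAA", "8mer"),
            seed_pairing_stability("AAUAUAUAAAAAAAAAAA", "8mer"))
  # independent hand summation for the example seed GGAAUGU (nt 2-8):
  # stacks GG, GA, AA, AU, UG, GU over the embedded table
  by_hand <- sum(c(-3.26, -2.35, -0.93, -1.10, -2.11, -2.24))
  expect_equal(seed_pairing_stability("UGGAAUGUAAAGAAGUAUGUAU", "8mer"),
               by_hand, tolerance = 1e-9)
  # the 8mer and 6mer spans differ only by the nt7:8 stack term (GU)
  d <- seed_pairing_stability("UGGAAUGUAAAGAAGUAUGUAU", "8mer") -
    seed_pairing_stability("UGGAAUGUAAAGAAGUAUGUAU", "6mer")
  expect_equal(d, -2.24, tolerance = 1e-9)
  # 7mer-m8 shares the nt 2-8 span with the 8mer
  expect_equal(seed_pairing_stability("UGGAAUGUAAAGAAGUAUGUAU", "7mer-m8"),
               by_hand, tolerance = 1e-9)
  expect_error(seed_pairing_stability("UGGANUGUAAAGAAGUAUGUAU", "8mer"),
               "non-nucleotide")
})

test_that("local AU content weights nucleotides by inverse distance", {
  site <- list(start = 40L, end = 48L)
  utr_au <- paste0(strrep("AU", 20), strrep("G", 8), strrep("UA", 20))
  expect_equal(local_au(utr_au, site), 1.0)
  utr_gc <- paste0(strrep("GC", 20), strrep("A", 8), strrep("CG", 20))
  expect_equal(local_au(utr_gc, site), 0.0)
  # truncated 4-nt upstream flank reading A,G,G,G outward from the edge,
  # UTR ending at the site: (1/1) / (1/1 + 1/2 + 1/3 + 1/4) = 0.48
  utr <- paste0("GGGA", "ACAUUCCA")
  expect_equal(local_au(utr, list(start = 4L, end = 12L)), 0.48)
  expect_true(is.na(local_au(paste0(strrep("G", 39), "N",
                                    strrep("G", 60)),
                             site)))
})

test_that("3'-supplementary pairing scores runs against the upstream region", {
  fam <- example_family()
  m <- fam$members[[1L]]                      # UGGAAUGUAAAGAAGUAUGUAU
  sig <- seed_signatures(fam)[["8mer"]]
  mk_site <- function(utr) find_sites(utr, fam)[1L, ]
  # all-G background: this member's 3' region (no C) cannot pair it
  utr0 <- paste0(strrep("G", 30), sig, strrep("G", 10))
  expect_equal(threep_score(m, utr0, mk_site(utr0)), 0.0)
  # perfect pairing of nt 13-16 at offset 0: rc(nt13-16) placed so that
  # miRNA nt m pairs target position p8 - (m - 8)
  p8 <- 30L
  up <- strrep("G", 30)
  frag <- rc_rna(substr(m, 13, 16))
  substr(up, p8 - 8L + 1L, p8 - 5L + 1L) <- frag
  utr1 <- paste0(up, sig, strrep("G", 10))
  expect_equal(threep_score(m, utr1, mk_site(utr1)), 4.0)
  # pairing nt 17-20 instead scores 4 x 0.5
  up2 <- strrep("G", 30)
  frag2 <- rc_rna(substr(m, 17, 20))
  substr(up2, p8 - 12L + 1L, p8 - 9L + 1L) <- frag2
  utr2 <- paste0(up2, sig, strrep("G", 10))
  expect_equal(threep_score(m, utr2, mk_site(utr2)), 2.0)
})

test_that("minimum distance uses the closest UTR terminus per isoform", {
  pr <- isoform_profile("t", 1000, 1)
  site <- list(transcript_id = "t", start = 100L, end = 107L,
               region = "utr3")
  expect_equal(min_dist(site, pr), 2.0)
  site0 <- list(transcript_id = "t", start = 0L, end = 7L, region = "utr3")
  expect_equal(min_dist(site0, pr), 0.0)      # clamped at distance 1
  # distal isoform end closer than the stop codon
  site2 <- list(transcript_id = "t", start = 900L, end = 907L,
                region = "utr3")
  expect_equal(min_dist(site2, pr), log10(1000 - 907))
  # isoform weighting: ends 300/1000 at 50:50, site near the stop
  pr2 <- isoform_profile("t", c(300, 1000), c(0.5, 0.5))
  site3 <- list(transcript_id = "t", start = 100L, end = 107L,
                region = "utr3")
  expect_equal(min_dist(site3, pr2), 0.5 * log10(100) + 0.5 * log10(100))
})

test_that("trimmed scaling is affine, unclipped, and table-driven", {
  tab <- default_scaling_table()
  expect_equal(scale_feature(-11.130, "SPS", "8mer", tab), 0.0)
  expect_equal(scale_feature(-5.520, "SPS", "8mer", tab), 1.0)
  expect_equal(scale_feature(-8.325, "SPS", "8mer", tab), 0.5)
  # not clipped beyond the percentile anchors
  expect_lt(scale_feature(-12, "SPS", "8mer", tab), 0)
  expect_gt(scale_feature(-5, "SPS", "8mer", tab), 1)
  # order preservation
  v <- sort(runif(10, -12, -5))
  expect_true(!is.unsorted(vapply(v, scale_feature, numeric(1),
                                  feature = "SPS", site_type = "8mer",
                                  table = tab)))
  # counts pass through unscaled
  expect_equal(scale_feature(3, "off6m", "8mer", tab), 3)
  expect_error(scale_feature(1, "nope", "8mer", tab), "no scaling entry")
})

test_that("feature vectors are complete, defaulted, and pure", {
  fam <- example_family()
  sig <- seed_signatures(fam)[["8mer"]]
  set.seed(3)
  utr3 <- paste0(rand_rna(60), sig, rand_rna(120))
  tx <- transcript_model("t1", "g1", rand_rna(50), rand_rna(300), utr3)
  site <- find_sites(tx, fam)
  site <- site[site$site_type == "8mer", ][1L, ]
  fv <- feature_vector(site, tx, fam, census = 1300L)
  expect_s3_class(fv, "FeatureVector")
  needed <- c("TA_3UTR", "SPS", "local_AU", "threep_score", "SA",
              "min_dist", "P_CT", "len_ORF", "len_3UTR", "off6m", "ORF8m",
              "sRNA1", "sRNA8", "site8")
  expect_true(all(needed %in% names(fv)))
  expect_false(isTRUE(attr(fv, "unscorable")))
  expect_equal(fv$P_CT, 0)                    # no lookup: defaults to zero
  expect_equal(attr(fv, "raw")$TA_3UTR, log10(1300))
  expect_lte(attr(fv, "raw")$SA, 0)           # log10 probability
  expect_equal(fv$sRNA1, "U")
  expect_equal(fv$site8, substr(utr3, site$start + 1L, site$start + 1L))
  # purity: recomputation is bit-identical
  fv2 <- feature_vector(site, tx, fam, census = 1300L)
  expect_identical(fv[names(fv)], fv2[names(fv2)])
  # supplied conservation scores are picked up for broadly conserved
  pct <- data.frame(transcript_id = "t1", family_id = "fam-ex",
                    start = site$start, p_ct = 0.6)
  fv3 <- feature_vector(site, tx, fam, census = 1300L, pct_lookup = pct)
  expect_equal(attr(fv3, "raw")$P_CT, 0.6)
  # expansion encodes categories as A/C/G indicators with U reference
  x <- expand_feature_vector(fv)
  expect_equal(unname(x["sRNA1_A"] + x["sRNA1_C"] + x["sRNA1_G"]), 0)
})
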