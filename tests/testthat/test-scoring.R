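# Linear scoring with caps, AIR weighting, the cumulative recursion, and
# prediction ranking.

fv_stub <- function(site_type = "8mer", values = list()) {
  fv <- list(site_type = site_type,
             TA_3UTR = 0, SPS = 0, local_AU = 0, threep_score = 0, SA = 0,
             min_dist = 0, P_CT = 0, len_ORF = 0, len_3UTR = 0,
             off6m = 0, ORF8m = 0, sRNA1 = "U", sRNA8 = "U", site8 = "U")
  fv[names(values)] <- values
  class(fv) <- "FeatureVector"
  fv
}

test_that("context scores are linear below the site-type cap", {
  m <- site_type_model("8mer", intercept = -0.5,
                       coefficients = c(local_AU = -0.4, min_dist = 0.3))
  expect_equal(context_score(fv_stub(), m), -0.5)   # all features zero
  # linearity in a single feature below the cap
  cs1 <- context_score(fv_stub(values = list(local_AU = 0.2)), m)
  cs2 <- context_score(fv_stub(values = list(local_AU = 0.7)), m)
  expect_equal((cs2 - cs1) / 0.5, -0.4, tolerance = 1e-12)
  # the cap binds for strongly repression-opposing features
  m2 <- site_type_model("8mer", intercept = 0.5,
                        coefficients = c(local_AU = -0.4))
  expect_equal(context_score(fv_stub(), m2), -0.03)
  expect_error(context_score(fv_stub(),
                             site_type_model("8mer", 0, c(absent = 1))),
               "missing")
  # default caps per site type
  expect_equal(unname(vapply(c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                             function(st) site_type_model(st, 0,
                                                          numeric(0))$cap,
                             numeric(1))),
               c(-0.03, -0.02, -0.01, 0))
})

test_that("AIR weighting interpolates between no effect and the full score", {
  expect_equal(site_weighted_score(-2, 1), -2)
  expect_equal(site_weighted_score(-2, 0), 0)
  expect_equal(site_weighted_score(-2, 0.5), log2(0.625))
  expect_equal(log2(0.625), -0.678, tolerance = 1e-3)
  expect_error(site_weighted_score(-2, 1.5), "AIR")
  # weighting can only attenuate predicted repression
  expect_gte(site_weighted_score(-1.3, 0.4), -1.3)
})

test_that("the cumulative recursion reproduces hand-computed cases", {
  expect_equal(cumulative_weighted_score(-1, 1), -1)
  expect_equal(cumulative_weighted_score(c(-1, -1), c(0.5, 1)),
               log2(0.375), tolerance = 1e-12)
  expect_equal(log2(0.375), -1.415, tolerance = 1e-3)
  expect_equal(cumulative_weighted_score(numeric(0), numeric(0)), 0)
  expect_error(cumulative_weighted_score(c(-1, -1), c(0.9, 0.4)),
               "nondecreasing")
})

test_that("the recursion equals the isoform-expectation oracle", {
  set.seed(101)
  worst <- 0
  for (r in 1:1000) {
    n <- sample(1:6, 1)
    cs <- -runif(n, 0, 3)
    airs <- sort(runif(n))
    got <- cumulative_weighted_score(cs, airs)
    want <- oracle_cwcs(cs, airs)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-12)
})

test_that("all-AIR-1 sites act independently and extra sites add repression", {
  set.seed(5)
  for (r in 1:20) {
    cs <- -runif(sample(1:5, 1), 0, 2)
    expect_equal(cumulative_weighted_score(cs, rep(1, length(cs))),
                 sum(cs), tolerance = 1e-12)
  }
  base <- cumulative_weighted_score(c(-0.5, -0.2), c(0.6, 1))
  more <- cumulative_weighted_score(c(-0.5, -0.2, -0.3), c(0.6, 1, 1))
  expect_lt(more, base)
  expect_lte(cumulative_weighted_score(c(-0.5), c(0.7)), 0)
})

test_that("family scores take the most repressive member and tag-rich transcript", {
  set.seed(9)
  fam2 <- mirna_family("fam2", "GGAAUGU",
                       c("UGGAAUGUAAAGAAGUAUGUAU",
                         "CGGAAUGUCCCGAAGUAUGCCC"),
                       conservation_class = "broadly_conserved")
  sig <- seed_signatures(fam2)[["8mer"]]
  utr3 <- paste0(rand_rna(60), sig, rand_rna(120))
  tx <- transcript_model("t1", "g1", rand_rna(50), rand_rna(300), utr3)
  model <- default_context_model()
  rec <- family_transcript_score(tx, fam2, model, census = 1000L)
  per_member <- vapply(fam2$members, function(mm) {
    f1 <- mirna_family("tmp", "GGAAUGU", mm)
    family_transcript_score(tx, f1, model, census = 1000L)$cwcs
  }, numeric(1))
  expect_equal(rec$cwcs, min(per_member))
  expect_equal(rec$member, fam2$members[[which.min(per_member)]])

  # the gene representative is the stop-codon isoform with most tags
  tx2 <- transcript_model("t2", "g1", rand_rna(50), rand_rna(300), utr3)
  profs <- list(t1 = isoform_profile("t1", nchar(utr3), 1, total_tags = 10),
                t2 = isoform_profile("t2", nchar(utr3), 1, total_tags = 100))
  recs <- score_transcriptome(list(t1 = tx, t2 = tx2), list(fam2 = fam2),
                              model, profiles = profs)
  expect_length(recs, 1L)
  expect_equal(recs[[1L]]$transcript_id, "t2")
})

test_that("ranking sorts by score, hides 6mer-only targets, tops at percentile 100", {
  mk_rec <- function(id, cwcs, types) {
    list(transcript_id = id, gene_id = id, family_id = "f", cwcs = cwcs,
         total_tags = 1,
         sites = data.frame(site_type = types))
  }
  recs <- list(mk_rec("a", -0.2, "7mer-m8"),
               mk_rec("b", -1.0, "8mer"),
               mk_rec("c", -0.05, "6mer"))
  tab <- rank_predictions(recs)
  expect_equal(tab$transcript_id, c("b", "a"))        # ascending score
  expect_false("c" %in% tab$transcript_id)            # 6mer-only hidden
  expect_equal(tab$percentile[tab$transcript_id == "b"], 100)
  tab_all <- rank_predictions(recs, only_7_8mer_listing = FALSE)
  expect_true("c" %in% tab_all$transcript_id)
})

test_that("model tables round-trip through TSV", {
  model <- default_context_model()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tsv")
  write_context_model(model, path)
  back <- read_context_model(path)
  for (st in names(model)) {
    expect_equal(back[[st]]$intercept, model[[st]]$intercept)
    expect_equal(back[[st]]$coefficients, model[[st]]$coefficients)
    expect_equal(back[[st]]$cap, model[[st]]$cap)
  }
})
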