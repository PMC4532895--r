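# Training-set selection, AIC, stepwise and bootstrap selection, OLS
# fitting, scaling estimation, and evaluation utilities.

test_that("training mRNAs need a dominant isoform and a single site", {
  fam <- example_family()
  sig <- seed_signatures(fam)[["8mer"]]
  mk <- function(id, n_sites) {
    utr <- paste0(rand_rna(30, gc = 1),
                  paste(rep(paste0(sig, rand_rna(20, gc = 1)), n_sites),
                        collapse = ""), rand_rna(30, gc = 1))
    make_transcript(utr, id = id)
  }
  set.seed(2)
  txs <- list(a = mk("a", 1), b = mk("b", 2), c = mk("c", 1), d = mk("d", 1))
  profs <- list(
    a = isoform_profile("a", nchar(txs$a$utr3), 1),                 # mono
    b = isoform_profile("b", nchar(txs$b$utr3), 1),
    c = isoform_profile("c", c(50, nchar(txs$c$utr3)), c(0.05, 0.95)),
    d = isoform_profile("d", c(50, nchar(txs$d$utr3)), c(0.4, 0.6)))
  sites <- do.call(rbind, lapply(txs, function(tx) find_sites(tx, fam)))
  picked <- select_training_mrnas(txs, profs, sites)
  expect_true(all(c("a", "c") %in% picked))
  expect_false("b" %in% picked)   # two sites
  expect_false("d" %in% picked)   # 60:40 isoforms
})

test_that("AIC matches its definition and the Gaussian closed form", {
  expect_equal(aic(0, 3), 6)
  expect_equal(aic(-10, 4) - aic(-10, 3), 2)
  set.seed(4)
  y <- rnorm(50); x <- rnorm(50)
  fit <- lm(y ~ x)
  # Gaussian log-likelihood from the RSS (ML variance), matching logLik
  n <- length(y); rss <- sum(resid(fit)^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  expect_equal(as.numeric(logLik(fit)), ll, tolerance = 1e-9)
  expect_equal(aic(ll, 3), AIC(fit), tolerance = 1e-9)  # slope+intercept+sigma
})

test_that("stepwise selection recovers planted features and drops aliases", {
  set.seed(6)
  n <- 400
  design <- as.data.frame(matrix(rnorm(n * 10), n,
                                 dimnames = list(NULL, paste0("f", 1:10))))
  y <- 2 * design$f3 - 1.5 * design$f7      # noiseless, 2 informative
  expect_setequal(suppressWarnings(stepwise_select(design, y)),
                  c("f3", "f7"))
  # perfectly collinear duplicate: exactly one representative survives
  design$dup <- design$f3
  sel <- suppressWarnings(stepwise_select(design, y))
  expect_equal(sum(c("f3", "dup") %in% sel), 1L)
  # pure-noise response: the per-candidate false-inclusion rate sits at
  # the AIC threshold, P(chisq_1 > 2) ~ 0.16
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    yn <- rnorm(n)
    length(stepwise_select(design[, 1:10], yn))
  }, numeric(1))
  rate <- mean(hits) / 10
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.35)
})

test_that("bootstrap selection is stratified and flags robust features", {
  set.seed(8)
  n <- 240
  design <- as.data.frame(matrix(rnorm(n * 6), n,
                                 dimnames = list(NULL, paste0("f", 1:6))))
  y <- -0.4 * design$f1 + 0.5 * design$f2 + rnorm(n, sd = 0.2)
  expt <- rep(sprintf("e%d", 1:4), each = n / 4)
  ts <- list("8mer" = list(design = design, response = y, experiment = expt),
             "7mer-m8" = list(design = design, response = y,
                              experiment = expt))
  rep_out <- bootstrap_selection(ts, B = 20, seed = 1)
  expect_true(all(rep_out$frequency[c("f1", "f2"), ] == 1))
  expect_setequal(rep_out$robust_set, c("f1", "f2"))
  expect_true(all(rep_out$heldout_r2 > 0.5, na.rm = TRUE))
  expect_error(bootstrap_selection(ts, B = 1), "B must be")
})

test_that("OLS fitting recovers noiseless coefficients and attaches caps", {
  set.seed(10)
  design <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- -0.3 + 0.7 * design$a - 0.2 * design$b
  m <- suppressWarnings(fit_site_model(design, y, site_type = "7mer-m8"))
  expect_equal(m$intercept, -0.3, tolerance = 1e-10)
  expect_equal(unname(m$coefficients[c("a", "b")]), c(0.7, -0.2),
               tolerance = 1e-10)
  expect_equal(m$cap, -0.02)
  expect_true(!is.null(attr(m, "ci")))
  m0 <- fit_site_model(design[, 0, drop = FALSE], y, site_type = "6mer")
  expect_equal(m0$intercept, mean(y))
  design$dup <- design$a
  expect_error(fit_site_model(design, y), "singular")
})

test_that("scaling estimation uses 5th/95th percentiles with interpolation", {
  raw <- data.frame(feature = "SPS", site_type = "8mer", value = 1:100)
  tab <- fit_scaling(raw)
  expect_equal(tab$p5, 5.95)
  expect_equal(tab$p95, 95.05)
  expect_error(fit_scaling(data.frame(feature = "SPS", site_type = "8mer",
                                      value = rep(1, 30))), "degenerate")
  expect_error(fit_scaling(raw[1:10, ]), "fewer than")
})

test_that("partial correlation residualizes on controls", {
  set.seed(14)
  n <- 5000
  c1 <- rnorm(n)
  x <- 0.5 * c1 + rnorm(n)
  y <- 0.5 * c1 + rnorm(n)
  expect_equal(partial_correlation(x, y, NULL), cor(x, y))
  expect_lt(abs(partial_correlation(x, y, cbind(c1))), 0.05)
  expect_warning(r <- partial_correlation(x, c1, cbind(c1)), "degenerate")
  expect_true(is.na(r))
  # planted partial correlation is recovered
  z <- rnorm(n)
  y2 <- 0.5 * c1 + 0.2 * scale(resid(lm(z ~ c1))) + rnorm(n) * sqrt(1 - 0.04)
  expect_lt(abs(partial_correlation(z, y2, cbind(c1)) - 0.2), 0.03)
})

test_that("r-squared evaluation and worst-score filling behave", {
  set.seed(16)
  x <- rnorm(100)
  expect_equal(evaluate_r2(x, x), 1)
  expect_equal(evaluate_r2(2 * x + 3, x), 1)            # affine invariance
  expect_lt(evaluate_r2(rnorm(10000), rnorm(10000)), 0.01)
  expect_error(evaluate_r2(rep(1, 5), rnorm(5)), "zero variance")
  pred <- c(a = -2, b = -0.5)
  filled <- with_worst_score(c("a", "b", "c"), pred)
  expect_equal(unname(filled["c"]), -0.5)               # worst score in range
})

test_that("top-N response counts thresholds and brackets the null", {
  set.seed(18)
  ids <- sprintf("m%04d", 1:2000)
  scores <- setNames(sort(rnorm(2000)), ids)            # best first
  fc <- setNames(rnorm(2000, sd = 0.4), ids)
  out <- top_n_response(scores, fc, thresholds = c(4, 16, 1000),
                        n_mirnas = 7, resamples = 200)
  expect_equal(out$n_selected, c(28, 112))              # 4x7 and 16x7
  expect_equal(nrow(out), 2L)                           # 1000x7 > available
  # random scores: medians sit inside the resampled 95% band
  expect_true(all(out$median >= out$null_lo & out$median <= out$null_hi))
})

test_that("added informative features raise held-out r2 over a reduced model", {
  set.seed(20)
  n <- 400
  design <- data.frame(local_AU = rnorm(n, sd = 0.2),
                       min_dist = rnorm(n, sd = 0.17),
                       len_3UTR = rnorm(n, sd = 0.15),
                       SA = rnorm(n, sd = 0.2))
  y <- -0.35 * design$local_AU + 0.3 * design$min_dist +
    0.3 * design$len_3UTR - 0.25 * design$SA + rnorm(n, sd = 0.15)
  reduced <- c("local_AU", "min_dist")          # context-only-style subset
  full <- colnames(design)
  r2_of <- function(cols, tr, te) {
    fit <- lm(y[tr] ~ ., data = design[tr, cols, drop = FALSE])
    cor(predict(fit, design[te, cols, drop = FALSE]), y[te])^2
  }
  diffs <- vapply(1:40, function(b) {
    tr <- sample(n, round(0.7 * n))
    te <- setdiff(seq_len(n), tr)
    r2_of(full, tr, te) - r2_of(reduced, tr, te)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.95)              # paired over samples
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 1e-6)
})

test_that("worked-example arithmetic reproduces the printed quantities", {
  expect_equal(site_information_bits("6mer"), 12)
  expect_equal(site_information_bits("7mer-m8"), 14)
  expect_equal(site_information_bits("7mer-A1"), 14)
  expect_equal(round(100 * information_captured(0.139, 0.126, 0.044)), 70)
  expect_equal(false_positive_bound(0.08), 0.16)
  expect_equal(top_prediction_count(16, 7), 112)
})
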