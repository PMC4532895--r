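# Training pipeline: training-set assembly, bootstrap stepwise-AIC feature
# selection, OLS fitting per site type, percentile scaling estimation, and
# prediction evaluation.

#' Select mRNAs eligible for regression modeling
#'
#' Keeps genes whose dominant 3'-UTR isoform carries at least
#' `dominant_frac` of the 3P-seq tags and whose 3' UTR contains exactly
#' one canonical site (8mer/7mer-m8/7mer-A1/6mer) to the perturbed small
#' RNA, so each fold change can be attributed to a single site in a
#' well-defined UTR.
#'
#' @param transcripts named list of transcript models.
#' @param profiles named list of isoform profiles (by transcript id).
#' @param sites site table from [find_sites()] for the cognate family.
#' @param dominant_frac dominance threshold (default 0.9).
#' @return Character vector of eligible transcript ids.
#' @export
select_training_mrnas <- function(transcripts, profiles, sites,
                                  dominant_frac = 0.9) {
  ids <- names(transcripts)
  ok <- vapply(ids, function(id) {
    pr <- profiles[[id]]
    if (is.null(pr) || max(pr$abundances) < dominant_frac) return(FALSE)
    s <- sites[sites$transcript_id == id &
                 sites$site_type %in% SITE_TYPES, , drop = FALSE]
    nrow(s) == 1L
  }, logical(1))
  ids[ok]
}

#' Akaike information criterion
#'
#' `-2 ln(L) + 2k`; smaller is better.
#'
#' @param loglik model log-likelihood.
#' @param k number of parameters.
#' @return AIC value.
#' @export
aic <- function(loglik, k) {
  if (k < 1) stop("k must be >= 1")
  -2 * loglik + 2 * k
}

#' Stepwise AIC feature selection
#'
#' Bidirectional stepwise search minimizing AIC, starting from the
#' intercept-only model (or the full model when `start = "full"`).
#' Perfectly collinear candidate columns are dropped (with a warning)
#' before the search, so the result is deterministic given the input
#' column order.
#'
#' @param design `data.frame` of candidate features.
#' @param response numeric response vector.
#' @param candidates candidate column names (default: all columns).
#' @param start `"intercept"` or `"full"`.
#' @return Character vector of selected feature names.
#' @export
stepwise_select <- function(design, response,
                            candidates = colnames(design),
                            start = c("intercept", "full")) {
  start <- match.arg(start)
  design <- design[, candidates, drop = FALSE]
  if (nrow(design) <= length(candidates))
    stop("need more rows than candidate features")
  # drop aliased columns
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    keep <- qr_$pivot[seq_len(qr_$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    warning("dropping aliased candidate(s): ",
            paste(dropped, collapse = ", "))
    candidates <- setdiff(candidates, dropped)
    design <- design[, candidates, drop = FALSE]
  }
  dat <- cbind(.response = response, design)
  full_fml <- as.formula(paste(".response ~",
                               paste(sprintf("`%s`", candidates),
                                     collapse = " + ")))
  init <- if (start == "intercept")
    lm(.response ~ 1, data = dat) else lm(full_fml, data = dat)
  fit <- step(init, scope = list(lower = ~1, upper = full_fml),
              direction = "both", trace = 0)
  sel <- gsub("`", "", attr(fit$terms, "term.labels"), fixed = TRUE)
  # in (near-)noiseless fits the log-likelihood diverges and AIC admits
  # features with no real contribution; prune any feature whose removal
  # leaves the residual sum of squares at the numerical-zero scale
  rss_of <- function(cols) {
    f <- if (length(cols) == 0L) .response ~ 1 else
      as.formula(paste(".response ~",
                       paste(sprintf("`%s`", cols), collapse = " + ")))
    sum(resid(lm(f, data = dat))^2)
  }
  rss_null <- rss_of(character(0))
  if (length(sel) > 0L && rss_of(sel) < 1e-10 * rss_null) {
    for (f in rev(sel)) {
      if (rss_of(setdiff(sel, f)) < 1e-10 * rss_null)
        sel <- setdiff(sel, f)
    }
  }
  sel
}

#' Bootstrap selection frequencies and robust feature set
#'
#' Repeats stepwise selection on `B` stratified subsamples, each holding
#' `train_frac` of the rows of every experiment (without replacement),
#' and records per-site-type selection frequencies and the held-out
#' r-squared of every subsample's model.  The robust set consists of
#' features selected with frequency >= `robust_freq` for at least
#' `robust_site_types` site types.
#'
#' @param training_set named list (per site type) of lists with elements
#'   `design` (data.frame), `response`, `experiment` (labels).
#' @param B number of bootstrap samples (default 1000; scaled-down runs
#'   use 100).
#' @param train_frac fraction of each experiment used for selection.
#' @param seed RNG seed.
#' @param robust_freq,robust_site_types robust-set thresholds (defaults
#'   0.99 and 2).
#' @return List of class `SelectionReport`: `frequency` (feature x site
#'   type), `robust_set`, `heldout_r2` (B x site type).
#' @export
bootstrap_selection <- function(training_set, B = 1000L, train_frac = 0.70,
                                seed = 1L, robust_freq = 0.99,
                                robust_site_types = 2L) {
  if (B < 2L) stop("B must be >= 2")
  set.seed(seed)
  feats <- sort(unique(unlist(lapply(training_set,
                                     function(ts) colnames(ts$design)))))
  freq <- matrix(0, length(feats), length(training_set),
                 dimnames = list(feats, names(training_set)))
  r2 <- matrix(NA_real_, B, length(training_set),
               dimnames = list(NULL, names(training_set)))
  for (st in names(training_set)) {
    ts <- training_set[[st]]
    strata <- split(seq_along(ts$response), ts$experiment)
    for (b in seq_len(B)) {
      tr <- unlist(lapply(strata, function(idx) {
        sample(idx, round(train_frac * length(idx)))
      }), use.names = FALSE)
      te <- setdiff(seq_along(ts$response), tr)
      sel <- suppressWarnings(
        stepwise_select(ts$design[tr, , drop = FALSE], ts$response[tr]))
      freq[sel, st] <- freq[sel, st] + 1
      if (length(te) > 1L) {
        dat <- cbind(.response = ts$response, ts$design)
        fml <- if (length(sel) == 0L) .response ~ 1 else
          as.formula(paste(".response ~",
                           paste(sprintf("`%s`", sel), collapse = " + ")))
        fit <- lm(fml, data = dat[tr, , drop = FALSE])
        pred <- predict(fit, newdata = dat[te, , drop = FALSE])
        if (sd(pred) > 0)
          r2[b, st] <- cor(pred, ts$response[te])^2
      }
    }
  }
  freq <- freq / B
  robust <- rownames(freq)[rowSums(freq >= robust_freq) >=
                             robust_site_types]
  structure(list(frequency = freq, robust_set = robust, heldout_r2 = r2),
            class = "SelectionReport")
}

#' Fit the per-site-type linear scoring model
#'
#' Ordinary least squares of the normalized fold changes on the selected
#' (scaled) features, with the site-type score cap attached; 95%
#' confidence intervals of the coefficients are stored in attribute
#' `"ci"`.
#'
#' @param design `data.frame` restricted to the selected features.
#' @param response numeric response.
#' @param site_type site type the model scores.
#' @param cap score ceiling (default the site type's published cap).
#' @return A [site_type_model()] with attributes `ci` and `fit`.
#' @export
fit_site_model <- function(design, response, site_type = "8mer",
                           cap = SITE_CAPS[[site_type]]) {
  dat <- cbind(.response = response, design)
  fml <- if (ncol(design) == 0L) .response ~ 1 else
    as.formula(paste(".response ~",
                     paste(sprintf("`%s`", colnames(design)),
                           collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit))) stop("singular design; drop aliased features")
  cf <- coef(fit)
  m <- site_type_model(site_type, cf[["(Intercept)"]],
                       setNames(unname(cf[-1L]),
                                gsub("`", "", names(cf)[-1L], fixed = TRUE)),
                       cap = cap)
  attr(m, "ci") <- confint(fit)
  attr(m, "fit") <- fit
  m
}

#' Estimate a percentile scaling table from raw feature values
#'
#' 5th/95th percentiles (linear interpolation) per (feature, site type).
#'
#' @param raw_table `data.frame` with columns `feature`, `site_type`,
#'   `value`.
#' @param min_n minimum observations per cell (default 20).
#' @return A `ScalingTable`.
#' @export
fit_scaling <- function(raw_table, min_n = 20L) {
  groups <- split(raw_table, list(raw_table$feature, raw_table$site_type),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (nrow(g) < min_n)
      stop(sprintf("fewer than %d values for (%s, %s)", min_n,
                   g$feature[1L], g$site_type[1L]))
    q <- quantile(g$value, c(0.05, 0.95), type = 7, names = FALSE)
    if (q[2L] <= q[1L])
      stop(sprintf("degenerate percentiles for (%s, %s)", g$feature[1L],
                   g$site_type[1L]))
    data.frame(feature = g$feature[1L], site_type = g$site_type[1L],
               p5 = q[1L], p95 = q[2L], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(tab) <- c("ScalingTable", "data.frame")
  tab
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the control matrix; with no controls this is the plain
#' Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param controls numeric matrix/data.frame of covariates (or `NULL`).
#' @return Correlation estimate; `NA` with a warning when a residual is
#'   degenerate.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0L) return(cor(x, y))
  C <- as.matrix(controls)
  rx <- resid(lm(x ~ C))
  ry <- resid(lm(y ~ C))
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    warning("degenerate residuals; partial correlation undefined")
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Explanatory power of predictions
#'
#' Squared Pearson correlation between scores and observed log2 fold
#' changes; mRNAs without a prediction should be assigned the worst score
#' in range before calling (see [with_worst_score()]).
#'
#' @param scores numeric prediction scores.
#' @param observed matching observed fold changes.
#' @return r-squared.
#' @export
evaluate_r2 <- function(scores, observed) {
  if (length(scores) != length(observed)) stop("length mismatch")
  if (sd(scores) == 0 || sd(observed) == 0)
    stop("zero variance; r-squared undefined")
  cor(scores, observed)^2
}

#' Fill unpredicted mRNAs with the worst score in range
#'
#' @param ids mRNA ids to evaluate.
#' @param predicted named score vector over a subset of `ids`.
#' @return Numeric vector over `ids`; missing entries receive
#'   `max(predicted)` (scores are repression-negative, so the maximum is
#'   the worst).
#' @export
with_worst_score <- function(ids, predicted) {
  out <- setNames(rep(max(predicted), length(ids)), ids)
  common <- intersect(ids, names(predicted))
  out[common] <- predicted[common]
  out
}

#' Median response of top-ranked predictions under sliding thresholds
#'
#' For each threshold t (an average number of predictions per miRNA), the
#' t x n_mirnas best-scored predictions are pooled across miRNAs and the
#' median (and mean) cognate fold change is reported together with a
#' resampled 95% null interval for the median of randomly chosen mRNAs.
#'
#' @param scores named numeric vector of prediction scores (ascending =
#'   better), pooled across miRNAs.
#' @param fold_changes named fold-change vector for the same ids; the
#'   resampling pool.
#' @param thresholds average per-miRNA prediction counts.
#' @param n_mirnas number of miRNAs pooled.
#' @param resamples null resamplings (default 1000).
#' @return `data.frame` with columns `threshold`, `n_selected`, `median`,
#'   `mean`, `null_lo`, `null_hi`; thresholds exceeding the number of
#'   predictions are omitted.
#' @export
top_n_response <- function(scores, fold_changes, thresholds, n_mirnas,
                           resamples = 1000L) {
  ord <- names(sort(scores))
  rows <- lapply(thresholds, function(t) {
    n_sel <- t * n_mirnas
    if (n_sel > length(scores)) return(NULL)
    sel <- fold_changes[ord[seq_len(n_sel)]]
    null_med <- replicate(resamples,
                          median(sample(fold_changes, n_sel)))
    data.frame(threshold = t, n_selected = n_sel, median = median(sel),
               mean = mean(sel),
               null_lo = quantile(null_med, 0.025, names = FALSE),
               null_hi = quantile(null_med, 0.975, names = FALSE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Information content of a canonical site motif
#'
#' Each fully specified nucleotide of the motif contributes 2 bits, so a
#' 6mer carries 12 bits and the 7mer sites carry 14.
#'
#' @param site_type canonical site type (or an integer motif length).
#' @return Bits.
#' @export
site_information_bits <- function(site_type) {
  if (is.numeric(site_type)) return(2 * site_type)
  2 * SITE_LEN[[match.arg(site_type, SITE_TYPES_ALL)]]
}

#' Fraction of a feature's information captured by the other features
#'
#' When removing a feature from the full model drops test-set r-squared
#' from `r2_full` to `r2_reduced`, while the feature alone achieves
#' `r2_alone`, the remaining molecular features capture
#' `(r2_alone - (r2_full - r2_reduced)) / r2_alone` of the information the
#' feature could impart.
#'
#' @param r2_full,r2_reduced,r2_alone r-squared values.
#' @return Fraction in \[0, 1\].
#' @export
information_captured <- function(r2_full, r2_reduced, r2_alone) {
  (r2_alone - (r2_full - r2_reduced)) / r2_alone
}

#' Upper bound on the false-positive fraction among top predictions
#'
#' If a fraction `frac_increased` of top predictions rise rather than
#' fall upon introducing the miRNA, and only half of false positives are
#' expected to rise, the bound is twice that fraction.
#'
#' @param frac_increased observed fraction with positive fold change.
#' @return Upper bound on the false-positive fraction.
#' @export
false_positive_bound <- function(frac_increased) 2 * frac_increased

#' Number of predictions selected at a per-miRNA threshold
#' @param threshold average predictions per miRNA.
#' @param n_mirnas number of miRNAs.
#' @return Total predictions selected.
#' @export
top_prediction_count <- function(threshold, n_mirnas) threshold * n_mirnas
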