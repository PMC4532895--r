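# Removal of small-RNA-independent structure from a fold-change compendium:
# per experiment, the shared component predictable from the other
# experiments is estimated by partial least squares and subtracted.  Site
# entries are masked out of the predictor matrix first, so that genuine
# repression measured twice is not removed as if it were batch structure.

#' Mask site-containing predictor entries
#'
#' Cells of `X` whose mask entry is 1 (the gene carries a canonical 7-8 nt
#' 3'-UTR site to the small RNA of that predictor experiment) are set
#' missing, so repression signal cannot leak into the batch estimate.
#'
#' @param X numeric matrix.
#' @param T_slice binary matrix of the same shape.
#' @return `X` with masked cells set to `NA`.
#' @export
mask_site_entries <- function(X, T_slice) {
  if (!all(dim(X) == dim(T_slice))) stop("X and mask differ in shape")
  X[T_slice == 1] <- NA_real_
  X
}

#' Select genes usable for one experiment's normalization
#'
#' Drops genes whose response is missing or that are missing in more than
#' 50% of predictor experiments (missing in exactly half is retained).
#'
#' @param y response vector (log2 fold changes of the experiment).
#' @param X predictor matrix (genes x other experiments).
#' @return Integer indices of retained genes.
#' @export
filter_genes <- function(y, X) {
  frac_missing <- rowMeans(is.na(X))
  which(!is.na(y) & frac_missing <= 0.5)
}

#' k-nearest-neighbor imputation of missing matrix cells
#'
#' Each missing cell is replaced by the mean of the cell's column over the
#' `k` genes nearest in Euclidean distance, computed over jointly observed
#' columns and rescaled by the square root of the fraction of columns
#' shared (so genes with few shared columns are not artificially close).
#' Only neighbor genes with the target column observed are eligible.
#'
#' @param X numeric matrix with missing cells; every row needs >= 1
#'   observed value.
#' @param k number of neighbors (default 20).
#' @return `X` with all missing cells imputed.
#' @export
knn_impute <- function(X, k = 20L) {
  if (!anyNA(X)) return(X)
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0L))
    stop("gene with no observed values; filter before imputing")
  m <- ncol(X)
  need <- which(rowSums(!obs) > 0L)
  Xf <- X; Xf[!obs] <- 0
  for (g in need) {
    xg <- Xf[g, ]; og <- obs[g, ]
    shared <- obs %*% og                    # columns jointly observed
    diff2 <- (Xf - matrix(xg, nrow(X), m, byrow = TRUE))^2
    diff2[!obs] <- 0
    diff2[, !og] <- 0
    ss <- rowSums(diff2)
    d <- sqrt(ss / pmax(shared, 1) * m)     # rescaled euclidean
    d[shared == 0] <- Inf
    d[g] <- Inf
    for (cc in which(!obs[g, ])) {
      cand <- which(obs[, cc])
      cand <- cand[cand != g]
      if (length(cand) == 0L)
        stop("column with a single observed gene cannot be imputed")
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      X[g, cc] <- mean(X[nb, cc])
    }
  }
  X
}

# NIPALS PLS1: returns function predicting y from new X for each ncomp
.pls1_fit <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  p <- ncol(X)
  Wmat <- matrix(0, p, ncomp); Pmat <- matrix(0, p, ncomp)
  qvec <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    pa <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pa)
    yc <- yc - qa * t
    Wmat[, a] <- w; Pmat[, a] <- pa; qvec[a] <- qa
  }
  list(xmean = xm, ymean = ym, W = Wmat, P = Pmat, q = qvec, ncomp = ncomp)
}

.pls1_predict <- function(fit, Xnew, ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  yhat <- rep(fit$ymean, nrow(Xnew))
  if (ncomp == 0L) return(yhat)
  Xc <- sweep(Xnew, 2L, fit$xmean)
  for (a in seq_len(ncomp)) {
    t <- Xc %*% fit$W[, a]
    yhat <- yhat + fit$q[a] * t
    Xc <- Xc - t %*% t(fit$P[, a])
  }
  yhat
}

#' Residualize a response on a predictor matrix by PLS regression
#'
#' Fits partial least squares (NIPALS) of `y` on `X`; the component count
#' is chosen by `cv_folds`-fold cross-validation as the smallest count
#' whose prediction error is within one standard error of the minimum
#' (0 components - no adjustment beyond the mean - is a candidate).
#' Returns `y - yhat`: what the other experiments cannot explain.
#'
#' @param y response vector.
#' @param X complete numeric predictor matrix, rows aligned with `y`.
#' @param max_components largest component count considered.
#' @param cv_folds folds for component selection (default 10).
#' @param seed optional seed controlling the fold assignment.
#' @return List with `residual`, `n_components`, `yhat`.
#' @export
plsr_residualize <- function(y, X, max_components = 10L, cv_folds = 10L,
                             seed = NULL) {
  n <- length(y)
  if (nrow(X) != n) stop("X rows must align with y")
  if (anyNA(X)) stop("X must be complete; impute first")
  if (n < 2L * cv_folds) stop("too few rows for cross-validation")
  max_components <- min(max_components, ncol(X), n - 2L)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  press <- matrix(NA_real_, cv_folds, max_components + 1L)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    fit <- .pls1_fit(X[tr, , drop = FALSE], y[tr], max_components)
    for (a in 0:max_components) {
      yh <- .pls1_predict(fit, X[!tr, , drop = FALSE], a)
      press[f, a + 1L] <- mean((y[!tr] - yh)^2)
    }
  }
  rmsep <- sqrt(colMeans(press))
  se <- apply(sqrt(press), 2L, sd) / sqrt(cv_folds)
  best <- which.min(rmsep)
  ncomp <- which(rmsep <= rmsep[best] + se[best])[1L] - 1L
  fit <- .pls1_fit(X, y, max(ncomp, 1L))
  yhat <- .pls1_predict(fit, X, ncomp)
  list(residual = y - yhat, n_components = ncomp, yhat = yhat)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Normalize a fold-change compendium
#'
#' For each experiment i: (i) site-containing cells are masked from the
#' predictor matrix of the remaining experiments, (ii) genes missing in
#' the response or in more than half of the predictors are dropped,
#' (iii) remaining predictor holes are imputed by k-nearest neighbors,
#' (iv) the response is residualized on the predictors by cross-validated
#' PLS.  Each normalized column is then centered by subtracting the
#' median of its no-site genes.  Pre/post inter-experiment Spearman
#' correlation matrices are returned as diagnostics.
#'
#' @param compendium a [fold_change_compendium()].
#' @param k neighbors for imputation.
#' @param max_components,cv_folds PLS settings per experiment.
#' @param seed seed controlling fold assignment.
#' @return List of class `NormalizationResult`: `Z_norm` (genes dropped
#'   for an experiment are `NA` in its column), `n_components`,
#'   `spearman_pre`, `spearman_post`.
#' @export
normalize_compendium <- function(compendium, k = 20L, max_components = 10L,
                                 cv_folds = 10L, seed = 1L) {
  Z <- compendium$Z; T <- compendium$T
  m <- ncol(Z)
  if (m < 3L) stop("compendium needs at least 3 experiments")
  Z_norm <- matrix(NA_real_, nrow(Z), m, dimnames = dimnames(Z))
  ncomps <- integer(m)
  for (i in seq_len(m)) {
    y <- Z[, i]
    X <- mask_site_entries(Z[, -i, drop = FALSE], T[, -i, drop = FALSE])
    keep <- filter_genes(y, X)
    Xk <- knn_impute(X[keep, , drop = FALSE], k = k)
    res <- plsr_residualize(y[keep], Xk, max_components = max_components,
                            cv_folds = cv_folds, seed = seed + i)
    ncomps[i] <- res$n_components
    no_site <- T[keep, i] == 0
    centered <- res$residual - median(res$residual[no_site])
    Z_norm[keep, i] <- centered
  }
  structure(list(Z_norm = Z_norm, n_components = ncomps,
                 spearman_pre = cor(Z, method = "spearman",
                                    use = "pairwise.complete.obs"),
                 spearman_post = cor(Z_norm, method = "spearman",
                                     use = "pairwise.complete.obs")),
            class = "NormalizationResult")
}
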