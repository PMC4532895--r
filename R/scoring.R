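# Per-site linear scoring with site-type caps, isoform weighting (AIR),
# the cumulative weighted score recursion, and prediction ranking.

#' Construct a per-site-type scoring model
#'
#' @param site_type one of the four canonical site types.
#' @param intercept regression intercept (log2 fold-change units).
#' @param coefficients named numeric vector over the expanded feature set
#'   (categories as `_A`/`_C`/`_G` indicators, U reference).
#' @param cap score ceiling; defaults to -0.03, -0.02, -0.01, 0 for 8mer,
#'   7mer-m8, 7mer-A1, 6mer.
#' @return An object of class `SiteTypeModel`.
#' @export
site_type_model <- function(site_type, intercept, coefficients,
                            cap = SITE_CAPS[[site_type]]) {
  site_type <- match.arg(site_type, SITE_TYPES)
  structure(list(site_type = site_type, intercept = intercept,
                 coefficients = coefficients, cap = cap),
            class = "SiteTypeModel")
}

#' Read a scoring model from a coefficient table
#'
#' TSV columns: `site_type`, `term`, `estimate`; one `(Intercept)` row per
#' site type plus one row per expanded feature.
#'
#' @param path coefficient table path.
#' @param label free-text provenance label attached to the model.
#' @return Named list of [site_type_model()]s (class `ContextModel`).
#' @export
read_context_model <- function(path, label = basename(path)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  models <- lapply(split(tab, tab$site_type), function(m) {
    ic <- m$estimate[m$term == "(Intercept)"]
    if (length(ic) != 1L)
      stop("model table needs exactly one (Intercept) per site type")
    co <- m[m$term != "(Intercept)", ]
    site_type_model(m$site_type[1L], ic, setNames(co$estimate, co$term))
  })
  models <- models[SITE_TYPES[SITE_TYPES %in% names(models)]]
  structure(models, class = "ContextModel", label = label)
}

#' Write a scoring model to a coefficient table
#' @param model a `ContextModel`.
#' @param path output TSV path.
#' @export
write_context_model <- function(model, path) {
  rows <- do.call(rbind, lapply(model, function(m) {
    data.frame(site_type = m$site_type,
               term = c("(Intercept)", names(m$coefficients)),
               estimate = c(m$intercept, unname(m$coefficients)),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Load the packaged default scoring model
#'
#' The shipped coefficients were trained by the package's own pipeline on
#' its synthetic compendium (there is no published coefficient table in
#' the package); they carry the label `"synthetic"` and are intended for
#' demonstration, testing and as a structural stand-in for a user-supplied
#' model.
#'
#' @return A `ContextModel`.
#' @export
default_context_model <- function() {
  read_context_model(
    system.file("extdata", "context_model_synthetic.tsv",
                package = "contextpp", mustWork = TRUE),
    label = "synthetic")
}

#' Per-site context score
#'
#' `CS = min(cap, intercept + sum(coef * feature))` over the scaled,
#' expanded feature vector; the site-type caps make the score a piece-wise
#' linear function bounded away from predicting enhancement.
#'
#' @param fv a [feature_vector()].
#' @param model a `SiteTypeModel` for `fv$site_type`, or a `ContextModel`
#'   from which it is selected.
#' @return Context score (log2 fold-change units, <= cap).
#' @export
context_score <- function(fv, model) {
  if (inherits(model, "ContextModel")) model <- model[[fv$site_type]]
  if (model$site_type != fv$site_type)
    stop("model site type does not match the feature vector")
  x <- expand_feature_vector(fv)
  need <- names(model$coefficients)
  if (!all(need %in% names(x)))
    stop("feature(s) missing from the vector: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  min(model$cap, model$intercept + sum(model$coefficients * x[need]))
}

#' AIR-weighted score of a single site
#'
#' `wCS = log2(1 - AIR * (1 - 2^CS))`: the predicted log2 fold change when
#' only the fraction AIR of the transcript's molecules carry the site.
#'
#' @param CS context score (<= 0).
#' @param AIR affected isoform ratio in \[0, 1\].
#' @return Weighted score (`CS` when AIR = 1, 0 when AIR = 0).
#' @export
site_weighted_score <- function(CS, AIR) {
  if (AIR < 0 || AIR > 1) stop("AIR must lie in [0, 1]")
  log2(1 - AIR * (1 - 2^CS))
}

#' Cumulative weighted score of all sites for one family
#'
#' Sites are processed from the distal end of the 3' UTR to the proximal
#' end (so AIR is nondecreasing); the cumulative predicted repression
#' follows `C_i = C_(i-1) + (1 - 2^CS_i) (AIR_i - C_(i-1))` with `C_0 = 0`,
#' and the returned score is `log2(1 - C_n)`: the log2 of the predicted
#' remaining mRNA fraction after the joint, isoform-weighted action of all
#' sites.
#'
#' @param cs numeric vector of per-site context scores, distal to
#'   proximal.
#' @param airs matching AIR values (nondecreasing in this order).
#' @return The cumulative weighted score (<= 0).
#' @export
cumulative_weighted_score <- function(cs, airs) {
  if (length(cs) != length(airs)) stop("cs and airs differ in length")
  if (length(cs) == 0L) return(0)
  if (any(diff(airs) < -1e-9))
    stop("AIR must be nondecreasing distal->proximal; sites are mis-sorted")
  C <- 0
  for (i in seq_along(cs)) {
    C <- C + (1 - 2^cs[i]) * (airs[i] - C)
    if (C < -1e-12 || C > airs[i] + 1e-12)
      stop("cumulative repression left [0, AIR_i]; invalid inputs")
  }
  log2(1 - C)
}

#' Score one transcript for one miRNA family
#'
#' Finds canonical sites, assembles feature vectors, applies the
#' per-site-type models and caps, weights by AIR, and combines sites into
#' the cumulative weighted score.  Scores are computed per family member
#' and the most repressive (minimum) member score represents the family.
#'
#' @param transcript a `TranscriptModel`.
#' @param family a `MirnaFamily`.
#' @param model a `ContextModel`.
#' @param profile an [isoform_profile()] (single annotated isoform when
#'   `NULL`).
#' @param census transcriptome-wide seed-match count for the family.
#' @param pct_lookup optional conservation-score table (see
#'   [feature_vector()]).
#' @param provider accessibility backend.
#' @param scaling percentile scaling table.
#' @param exclude_ribosome_shadow drop sites overlapping the first 15 nt
#'   of the 3' UTR (default TRUE).
#' @return `NULL` when the UTR has no canonical site; otherwise a list
#'   with the representative `cwcs`, the chosen `member`, the per-site
#'   table `sites` (1-based coordinates, per-site scores for the chosen
#'   member) and `total_tags` of the profile.
#' @export
family_transcript_score <- function(transcript, family, model,
                                    profile = NULL, census = 1000L,
                                    pct_lookup = NULL,
                                    provider = accessibility_provider(),
                                    scaling = default_scaling_table(),
                                    exclude_ribosome_shadow = TRUE) {
  utr3 <- transcript$utr3
  if (is.null(profile))
    profile <- isoform_profile(transcript$transcript_id, nchar(utr3), 1)
  sites_all <- find_sites(utr3, family, include_offset_6mer = TRUE,
                          transcript_id = transcript$transcript_id)
  sites <- sites_all[sites_all$site_type %in% SITE_TYPES, , drop = FALSE]
  if (exclude_ribosome_shadow)
    sites <- sites[!sites$in_ribosome_shadow, , drop = FALSE]
  if (nrow(sites) == 0L) return(NULL)
  # distal -> proximal processing order
  sites <- sites[order(-sites$end), , drop = FALSE]

  per_member <- lapply(family$members, function(member) {
    cs <- numeric(nrow(sites)); airs <- numeric(nrow(sites))
    wcs <- numeric(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      fv <- feature_vector(sites[i, ], transcript, family, member = member,
                           profile = profile, census = census,
                           pct_lookup = pct_lookup, provider = provider,
                           scaling = scaling, sites_all = sites_all)
      if (isTRUE(attr(fv, "unscorable")))
        return(NULL)
      cs[i] <- context_score(fv, model)
      airs[i] <- air(profile, sites[i, ])
      wcs[i] <- site_weighted_score(cs[i], airs[i])
    }
    list(cwcs = cumulative_weighted_score(cs, airs), cs = cs, airs = airs,
         wcs = wcs)
  })
  scored <- !vapply(per_member, is.null, logical(1))
  if (!any(scored)) return(NULL)
  cwcs <- vapply(per_member[scored], `[[`, numeric(1), "cwcs")
  best <- which(scored)[which.min(cwcs)]
  b <- per_member[[best]]
  list(transcript_id = transcript$transcript_id, gene_id = transcript$gene_id,
       family_id = family$family_id, member = family$members[[best]],
       cwcs = min(cwcs), total_tags = profile$total_tags,
       sites = data.frame(
         transcript_id = transcript$transcript_id,
         family_id = family$family_id,
         site_type = sites$site_type,
         start_1based = sites$start + 1L, end_1based = sites$end,
         context_score = b$cs, air = b$airs, weighted_score = b$wcs,
         stringsAsFactors = FALSE))
}

#' Score a transcriptome against a set of families
#'
#' Applies [family_transcript_score()] to every (transcript, family) pair;
#' for genes with several stop-codon isoforms the representative
#' transcript is the one with the most 3P-seq tag support.
#'
#' @param transcripts named list of transcript models.
#' @param families named list of miRNA families.
#' @param model a `ContextModel`.
#' @param profiles optional named list of isoform profiles (by transcript
#'   id).
#' @param censuses optional named integer vector of per-family censuses;
#'   computed from `transcripts` when `NULL`.
#' @param ... passed to [family_transcript_score()].
#' @return List of prediction records.
#' @export
score_transcriptome <- function(transcripts, families, model,
                                profiles = NULL, censuses = NULL, ...) {
  if (is.null(censuses))
    censuses <- vapply(families, function(f)
      target_site_census(transcripts, f), integer(1))
  records <- list()
  for (f in families) {
    for (tx in transcripts) {
      rec <- family_transcript_score(
        tx, f, model, profile = profiles[[tx$transcript_id]],
        census = max(1L, censuses[[f$family_id]]), ...)
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  }
  # representative transcript per (gene, family): most 3P-seq tags
  if (length(records) > 1L) {
    key <- vapply(records, function(r) paste(r$gene_id, r$family_id),
                  character(1))
    tags <- vapply(records, `[[`, numeric(1), "total_tags")
    keep <- unlist(lapply(split(seq_along(records), key), function(idx) {
      idx[which.max(tags[idx])]
    }), use.names = FALSE)
    records <- records[sort(keep)]
  }
  records
}

#' Rank prediction records
#'
#' Records are sorted by ascending cumulative weighted score (most
#' repressed first).  Although 6mer sites contribute to every cumulative
#' score, targets whose only canonical sites are 6mers are excluded from
#' the listing by default.  The score percentile of a record is 100 times
#' the fraction of same-family scores that are not more repressive
#' (higher percentile = better), so the best record of a family sits at
#' percentile 100.
#'
#' @param records list of records from [score_transcriptome()].
#' @param only_7_8mer_listing hide 6mer-only targets (default TRUE).
#' @return `data.frame` with columns `transcript_id`, `gene_id`,
#'   `family_id`, `n_sites`, `cwcs`, `percentile`, ordered by `cwcs` then
#'   lexicographically by transcript id.
#' @export
rank_predictions <- function(records, only_7_8mer_listing = TRUE) {
  if (length(records) == 0L)
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      family_id = character(0), n_sites = integer(0),
                      cwcs = numeric(0), percentile = numeric(0),
                      stringsAsFactors = FALSE))
  tab <- data.frame(
    transcript_id = vapply(records, `[[`, character(1), "transcript_id"),
    gene_id = vapply(records, `[[`, character(1), "gene_id"),
    family_id = vapply(records, `[[`, character(1), "family_id"),
    n_sites = vapply(records, function(r) nrow(r$sites), integer(1)),
    cwcs = vapply(records, `[[`, numeric(1), "cwcs"),
    stringsAsFactors = FALSE)
  only6 <- vapply(records, function(r) all(r$sites$site_type == "6mer"),
                  logical(1))
  tab$percentile <- NA_real_
  for (fam in unique(tab$family_id)) {
    idx <- tab$family_id == fam
    s <- tab$cwcs[idx]
    tab$percentile[idx] <- vapply(s, function(v) 100 * mean(s >= v),
                                  numeric(1))
  }
  if (only_7_8mer_listing) tab <- tab[!only6, , drop = FALSE]
  tab[order(tab$cwcs, tab$transcript_id), , drop = FALSE]
}
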