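# 3'-UTR tandem-isoform abundance profiles from 3P-seq clusters, the
# affected isoform ratio (AIR) of a site, and isoform-weighted features.

#' Construct an isoform profile
#'
#' @param transcript_id identifier.
#' @param ends ascending 1-based inclusive 3'-UTR end offsets (number of
#'   3'-UTR nucleotides retained by each tandem isoform); the last entry is
#'   the longest-annotation UTR length.
#' @param abundances matching nonnegative weights; normalized to sum to 1.
#' @param total_tags total (normalized) tag support.
#' @return An object of class `IsoformProfile`.
#' @export
isoform_profile <- function(transcript_id, ends, abundances,
                            total_tags = sum(abundances)) {
  if (length(ends) != length(abundances))
    stop("ends and abundances differ in length")
  if (is.unsorted(ends, strictly = TRUE))
    stop("isoform ends must be strictly increasing")
  if (any(abundances < 0)) stop("negative isoform abundance")
  s <- sum(abundances)
  if (s <= 0) stop("isoform profile has zero total abundance")
  structure(list(transcript_id = transcript_id, ends = as.numeric(ends),
                 abundances = abundances / s, total_tags = total_tags),
            class = "IsoformProfile")
}

#' @export
print.IsoformProfile <- function(x, ...) {
  cat(sprintf("IsoformProfile %s: %d isoform(s), ends [%s], tags %.1f\n",
              x$transcript_id, length(x$ends),
              paste(x$ends, collapse = ", "), x$total_tags))
  invisible(x)
}

# per-dataset upper-quartile scale factors: 75th percentile of per-
# transcript tag totals over transcripts with >= 1 tag, per dataset
.uq_factors <- function(clusters, quartile_type = 7) {
  totals <- tapply(clusters$tag_count,
                   list(clusters$transcript_id, clusters$dataset_id),
                   sum)
  f <- vapply(colnames(totals), function(ds) {
    v <- totals[, ds]
    v <- v[!is.na(v) & v >= 1]
    if (length(v) == 0L) return(1)
    as.numeric(quantile(v, 0.75, type = quartile_type, names = FALSE))
  }, numeric(1))
  # relative factors (geometric mean 1), so that a lone dataset is left on
  # its raw count scale and only between-dataset depth differences are
  # removed before pooling
  f / exp(mean(log(f)))
}

#' Build a 3'-UTR isoform profile from 3P-seq clusters
#'
#' Tag counts are upper-quartile normalized across datasets (per-dataset
#' scale factor = 75th percentile of per-transcript tag totals among
#' transcripts with at least one tag), summed per cluster position, then
#' pseudocounts are added: 0.1 tag on the longest tandem isoform and 5 tags
#' on the longest annotated (Gencode-style) isoform, so that a UTR with no
#' tag support still yields a profile.  Abundances are normalized to 1.
#'
#' @param transcript a `TranscriptModel`.
#' @param clusters a `ClusterSet` (possibly covering many transcripts and
#'   datasets); only rows for `transcript` are used.
#' @param pseudocount_longest_tandem pseudocount for the most distal
#'   cluster-supported isoform end (default 0.1).
#' @param pseudocount_gencode pseudocount for the longest annotated isoform
#'   (default 5).
#' @param datasets optional character vector restricting which datasets
#'   contribute (e.g. one developmental stage); default pools all.
#' @param quartile_type interpolation type passed to [stats::quantile()]
#'   for the 75th percentile (default 7, linear interpolation).
#' @return An [isoform_profile()]; its last end always equals the annotated
#'   3'-UTR length.
#' @export
build_profile <- function(transcript, clusters,
                          pseudocount_longest_tandem = 0.1,
                          pseudocount_gencode = 5.0,
                          datasets = NULL, quartile_type = 7) {
  len3 <- nchar(transcript$utr3)
  cl <- clusters[clusters$transcript_id == transcript$transcript_id, ,
                 drop = FALSE]
  if (!is.null(datasets))
    cl <- cl[cl$dataset_id %in% datasets, , drop = FALSE]
  if (nrow(cl) > 0L && any(cl$end_offset > len3))
    stop(sprintf("cluster beyond 3'-UTR end for %s",
                 transcript$transcript_id))
  if (nrow(cl) > 0L) {
    sub <- clusters
    if (!is.null(datasets))
      sub <- sub[sub$dataset_id %in% datasets, , drop = FALSE]
    factors <- .uq_factors(sub, quartile_type)
    norm <- cl$tag_count / factors[as.character(cl$dataset_id)]
    counts <- tapply(norm, cl$end_offset, sum)
    ends <- as.numeric(names(counts))
    counts <- as.numeric(counts)
    o <- order(ends); ends <- ends[o]; counts <- counts[o]
  } else {
    ends <- numeric(0); counts <- numeric(0)
  }
  # pseudocount on the longest tandem isoform (most distal supported end;
  # the annotated end when there is no tag support)
  if (length(ends) > 0L) {
    counts[length(counts)] <- counts[length(counts)] +
      pseudocount_longest_tandem
  } else {
    ends <- len3
    counts <- pseudocount_longest_tandem
  }
  # pseudocount on the longest annotated isoform
  if (ends[length(ends)] < len3) {
    ends <- c(ends, len3)
    counts <- c(counts, pseudocount_gencode)
  } else {
    counts[length(counts)] <- counts[length(counts)] + pseudocount_gencode
  }
  if (sum(counts) <= 0)
    stop(sprintf("profile for %s has zero support; enable pseudocounts",
                 transcript$transcript_id))
  isoform_profile(transcript$transcript_id, ends, counts,
                  total_tags = sum(counts))
}

#' Affected isoform ratio of a site
#'
#' The fraction of a gene's 3'-UTR isoform molecules that contain the site:
#' the summed abundance of isoforms whose end offset is >= the site end.  A
#' site is contained in an isoform only when the full site lies within it.
#' ORF sites are present in every isoform (AIR = 1).
#'
#' @param profile an [isoform_profile()].
#' @param site one row of a [find_sites()] table (list or data.frame row
#'   with `end`, 0-based half-open, and `region`).
#' @return AIR in \[0, 1\].
#' @export
air <- function(profile, site) {
  if (!is.null(site$region) && length(site$region) == 1L &&
      !is.na(site$region) && site$region == "orf") return(1)
  if (!is.null(site$transcript_id) && !is.na(site$transcript_id) &&
      site$transcript_id != profile$transcript_id)
    stop("site and profile refer to different transcripts")
  sum(profile$abundances[profile$ends >= site$end])
}

#' Isoform-weighted feature value
#'
#' Abundance-weighted mean of a per-isoform feature over the isoforms that
#' contain the site, with weights renormalized over those isoforms.  Used
#' for the minimum-distance, 3'-UTR-length and offset-6mer-count features,
#' which vary with the isoform end.
#'
#' @param profile an [isoform_profile()].
#' @param site a site row (uses its `end`).
#' @param per_isoform_feature function of the isoform end offset returning
#'   the feature value for that isoform.
#' @return Weighted mean feature value.
#' @export
weighted_feature <- function(profile, site, per_isoform_feature) {
  contains <- profile$ends >= site$end
  if (!any(contains))
    stop("no isoform contains the site; it cannot be scored on this profile")
  w <- profile$abundances[contains]
  w <- w / sum(w)
  vals <- vapply(profile$ends[contains], per_isoform_feature, numeric(1))
  sum(w * vals)
}
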