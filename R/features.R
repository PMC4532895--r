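# The fourteen regression features of the scoring model and their trimmed
# percentile scaling.
#
# Continuous features (scaled by the packaged percentile table):
#   TA_3UTR  log10 transcriptome-wide seed-match count (silencing-complex
#            titration)
#   SPS      seed-pairing stability, kcal/mol (thermo.R)
#   local_AU distance-weighted AU fraction flanking the site
#   threep_score  supplementary pairing at the miRNA 3' end
#   SA       log10 unpaired probability of the 14-nt segment over the
#            match to miRNA nt 7-8 (accessibility.R)
#   min_dist log10 distance from the closest 3'-UTR terminus
#            (isoform-weighted)
#   P_CT     probability of conserved targeting (consumed as input)
#   len_ORF, len_3UTR  log10 lengths (len_3UTR isoform-weighted)
# Count features (unscaled): off6m (isoform-weighted), ORF8m.
# Nucleotide categories (unscaled): sRNA1, sRNA8, site8.

CONTINUOUS_FEATURES <- c("TA_3UTR", "SPS", "local_AU", "threep_score",
                         "SA", "min_dist", "P_CT", "len_ORF", "len_3UTR")
COUNT_FEATURES <- c("off6m", "ORF8m")
CATEGORY_FEATURES <- c("sRNA1", "sRNA8", "site8")
MODEL_FEATURES <- c(CONTINUOUS_FEATURES, COUNT_FEATURES, CATEGORY_FEATURES)

#' Target-site abundance (TA)
#'
#' log10 of the transcriptome-wide count of a family's seed matches in
#' annotated 3' UTRs (see [target_site_census()]).
#'
#' @param census_count total seed-match count (>= 1).
#' @return log10 count.
#' @export
target_site_abundance <- function(census_count) {
  if (census_count < 1)
    stop("target-site census is 0: family absent from the transcriptome")
  log10(census_count)
}

#' Local AU content around a site
#'
#' Distance-weighted fraction of A/U nucleotides in the `window` nt
#' flanking each site boundary; the k-th nucleotide from the site edge has
#' weight 1/k, flanks truncated by the UTR ends are renormalized (absent
#' positions contribute no weight).
#'
#' @param utr3 3'-UTR RNA string.
#' @param site site row with `start`, `end` (0-based half-open).
#' @param window flank width in nt (default 30).
#' @return Value in \[0, 1\], or `NA` if a flank contains `N`.
#' @export
local_au <- function(utr3, site, window = 30L) {
  n <- nchar(utr3)
  chars <- strsplit(utr3, "", fixed = TRUE)[[1L]]
  up_pos <- site$start - seq_len(window)          # 0-based, k-th from edge
  down_pos <- site$end - 1L + seq_len(window)
  w <- 1 / seq_len(window)
  num <- 0; den <- 0
  for (side in list(up_pos, down_pos)) {
    ok <- side >= 0L & side < n
    if (!any(ok)) next
    b <- chars[side[ok] + 1L]
    if (any(b == "N")) return(NA_real_)
    num <- num + sum(w[ok] * (b %in% c("A", "U")))
    den <- den + sum(w[ok])
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Supplementary pairing at the miRNA 3' end
#'
#' Scores Watson-Crick pairing between miRNA nucleotides 9 and beyond and
#' the 16-nt target region 5' of the seed match.  For each register offset
#' in `offsets`, the maximal-scoring contiguous run is found, counting 1
#' per pair involving miRNA nucleotides 13-16 and 0.5 otherwise, minus an
#' offset penalty of 0.5 per nucleotide; the score is the maximum over
#' runs and offsets, floored at 0.
#'
#' @param member mature miRNA sequence (5'->3').
#' @param utr3 3'-UTR RNA string.
#' @param site site row (`site_type`, `start`).
#' @param region_len target region length 5' of the seed match (default 16).
#' @param offsets integer register offsets searched (default -4..4).
#' @param core_weight,flank_weight per-pair scores for miRNA nt 13-16 and
#'   the rest (defaults 1 and 0.5).
#' @param offset_penalty penalty per nucleotide of register offset
#'   (default 0.5).
#' @return Pairing score >= 0.
#' @export
threep_score <- function(member, utr3, site, region_len = 16L,
                         offsets = -4:4, core_weight = 1, flank_weight = 0.5,
                         offset_penalty = 0.5) {
  member <- .dna_to_rna(member)
  mir <- strsplit(member, "", fixed = TRUE)[[1L]]
  utr <- strsplit(utr3, "", fixed = TRUE)[[1L]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  p8 <- .p8_position(site)
  region_lo <- p8 - region_len                  # 0-based, inclusive
  best <- 0
  for (o in offsets) {
    run <- 0; run_best <- 0
    for (m in 9L:length(mir)) {
      tpos <- p8 - (m - 8L) - o                 # 0-based target position
      ok <- tpos >= max(0L, region_lo) && tpos < p8 &&
        !is.na(comp[mir[m]]) && tpos + 1L <= length(utr) &&
        utr[tpos + 1L] == comp[[mir[m]]]
      if (ok) {
        run <- run + if (m >= 13L && m <= 16L) core_weight else flank_weight
        run_best <- max(run_best, run)
      } else run <- 0
    }
    best <- max(best, run_best - offset_penalty * abs(o))
  }
  max(0, best)
}

#' Minimum distance of a site from a 3'-UTR terminus
#'
#' Per isoform, the distance is the smaller of (i) the number of
#' nucleotides between the site's closest edge and the stop codon and
#' (ii) between that edge and the isoform end, clamped at >= 1; the raw
#' feature is log10 of that distance, averaged over site-containing
#' isoforms with abundance weights ([weighted_feature()]).
#'
#' @param site site row (`start`, `end`).
#' @param profile an [isoform_profile()].
#' @return Isoform-weighted log10 minimum distance.
#' @export
min_dist <- function(site, profile) {
  weighted_feature(profile, site, function(iso_end) {
    log10(max(1, min(site$start, iso_end - site$end)))
  })
}

#' Load the packaged percentile scaling table
#'
#' Per (feature, site type) 5th and 95th percentiles used by
#' [scale_feature()]; shipped defaults reproduce the published scaling
#' parameters of the model.
#'
#' @param path optional path to an alternative table (TSV with columns
#'   `feature`, `site_type`, `p5`, `p95`).
#' @return `data.frame` of class `ScalingTable`.
#' @export
default_scaling_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scaling_table.tsv", package = "contextpp",
                        mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (any(tab$p95 <= tab$p5))
    stop("scaling table requires p95 > p5 for every row")
  class(tab) <- c("ScalingTable", "data.frame")
  tab
}

#' Trimmed percentile scaling of a raw feature value
#'
#' `(raw - p5) / (p95 - p5)` using the per-(feature, site type) percentiles
#' of the table.  Values are deliberately not clipped: trimming implies
#' out-of-\[0,1\] values can occur.  Count features (`off6m`, `ORF8m`) and
#' nucleotide categories pass through unscaled.
#'
#' @param raw raw feature value.
#' @param feature feature name.
#' @param site_type site type.
#' @param table a [default_scaling_table()].
#' @return Scaled value.
#' @export
scale_feature <- function(raw, feature, site_type,
                          table = default_scaling_table()) {
  if (feature %in% c(COUNT_FEATURES, CATEGORY_FEATURES)) return(raw)
  row <- table[table$feature == feature & table$site_type == site_type, ]
  if (nrow(row) != 1L)
    stop(sprintf("no scaling entry for (%s, %s)", feature, site_type))
  (raw - row$p5) / (row$p95 - row$p5)
}

# offset-6mer count for the isoform ending at iso_end (sites fully inside)
.off6m_count <- function(sites_all, iso_end) {
  sum(sites_all$site_type == "offset-6mer" & sites_all$end <= iso_end)
}

#' Assemble the scaled feature vector of a site
#'
#' Computes the fourteen model features for one classified 3'-UTR site and
#' applies the trimmed scaling.  `P_CT` defaults to 0 when no lookup entry
#' exists or the family is not broadly conserved.  `min_dist`, `len_3UTR`
#' and `off6m` are isoform-weighted over the site-containing isoforms.
#'
#' @param site one site row from [find_sites()].
#' @param transcript the `TranscriptModel`.
#' @param family the `MirnaFamily`.
#' @param member mature sequence used for sRNA-dependent features
#'   (defaults to the family's first member).
#' @param profile an [isoform_profile()] (defaults to a single-isoform
#'   profile of the annotated UTR).
#' @param census transcriptome-wide seed-match count for the family.
#' @param pct_lookup optional `data.frame` with columns `transcript_id`,
#'   `family_id`, `start`, `p_ct` giving per-site conservation scores.
#' @param provider accessibility backend.
#' @param scaling a [default_scaling_table()].
#' @param sites_all all sites of the family on this UTR (for the
#'   offset-6mer count); recomputed when `NULL`.
#' @return Named list of class `FeatureVector` (`site_type` plus the 14
#'   features; categories as single characters), or attribute
#'   `unscorable = TRUE` when a hard-missing feature occurs.
#' @export
feature_vector <- function(site, transcript, family,
                           member = family$members[[1L]],
                           profile = NULL, census = 1000L,
                           pct_lookup = NULL,
                           provider = accessibility_provider(),
                           scaling = default_scaling_table(),
                           sites_all = NULL) {
  utr3 <- transcript$utr3
  if (is.null(profile))
    profile <- isoform_profile(transcript$transcript_id, nchar(utr3), 1)
  if (is.null(sites_all))
    sites_all <- find_sites(utr3, family, include_offset_6mer = TRUE)
  st <- site$site_type
  if (!st %in% SITE_TYPES)
    stop("feature vectors are defined for the four canonical site types")
  mir <- strsplit(.dna_to_rna(member), "", fixed = TRUE)[[1L]]
  p8 <- .p8_position(site)
  site8 <- if (p8 >= 0L) substr(utr3, p8 + 1L, p8 + 1L) else NA_character_

  raw <- list(
    TA_3UTR = target_site_abundance(census),
    SPS = seed_pairing_stability(member, st),
    local_AU = local_au(utr3, site),
    threep_score = threep_score(member, utr3, site),
    SA = structural_accessibility(utr3, site, provider),
    min_dist = min_dist(site, profile),
    P_CT = 0,
    len_ORF = log10(max(1L, nchar(transcript$orf))),
    len_3UTR = weighted_feature(profile, site, function(e) log10(max(1, e))),
    off6m = weighted_feature(profile, site,
                             function(e) .off6m_count(sites_all, e)),
    ORF8m = as.numeric(count_orf_sites(transcript$orf, family)[["8mer"]]),
    sRNA1 = mir[1L], sRNA8 = mir[8L], site8 = site8)

  if (!is.null(pct_lookup) &&
      family$conservation_class == "broadly_conserved") {
    hit <- pct_lookup$transcript_id == site$transcript_id &
      pct_lookup$family_id == site$family_id & pct_lookup$start == site$start
    if (any(hit)) raw$P_CT <- pct_lookup$p_ct[which(hit)[1L]]
  }

  scaled <- raw
  for (f in CONTINUOUS_FEATURES)
    scaled[[f]] <- scale_feature(raw[[f]], f, st, scaling)
  scaled$site_type <- st
  unscorable <- any(vapply(scaled[MODEL_FEATURES],
                           function(v) is.na(v) || (is.character(v) &&
                                                    !v %in% RNA_ALPHABET),
                           logical(1)))
  structure(scaled, class = "FeatureVector", raw = raw,
            unscorable = unscorable)
}

#' Expand a feature vector into a numeric model row
#'
#' Nucleotide categories become A/C/G indicators with U as the reference
#' level, matching how the model reports effects relative to a position-8
#' U.
#'
#' @param fv a [feature_vector()].
#' @return Named numeric vector over the expanded feature set.
#' @export
expand_feature_vector <- function(fv) {
  out <- unlist(fv[c(CONTINUOUS_FEATURES, COUNT_FEATURES)])
  for (f in CATEGORY_FEATURES) {
    for (nt in c("A", "C", "G"))
      out[[paste0(f, "_", nt)]] <- as.numeric(identical(fv[[f]], nt))
  }
  out
}
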