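# Canonical seed-matched site discovery and classification.
#
# Site types, on the target strand 5'->3' (rc = reverse complement of the
# indicated miRNA positions):
#   8mer        rc(nt 2-8) + A   (A opposite miRNA position 1)
#   7mer-m8     rc(nt 2-8)
#   7mer-A1     rc(nt 2-7) + A
#   6mer        rc(nt 2-7)
#   offset-6mer rc(nt 3-8)

.rc_rna <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Target-strand signatures of the canonical site types
#'
#' @param family a [mirna_family()] (or a bare 7-nt seed string).
#' @return Named character vector with elements `8mer`, `7mer-m8`,
#'   `7mer-A1`, `6mer`, `offset-6mer`.
#' @examples
#' seed_signatures("GGAAUGU")
#' @export
seed_signatures <- function(family) {
  seed7 <- if (inherits(family, "MirnaFamily")) family$seed7 else
    .dna_to_rna(family)
  .check_rna(seed7, "seed", allow_n = FALSE)
  if (nchar(seed7) != 7L) stop("seed must be 7 nt (miRNA positions 2-8)")
  rc_2_8 <- .rc_rna(seed7)                       # matches miRNA nt 2-8
  rc_2_7 <- .rc_rna(substr(seed7, 1L, 6L))       # matches miRNA nt 2-7
  rc_3_8 <- .rc_rna(substr(seed7, 2L, 7L))       # matches miRNA nt 3-8
  c("8mer" = paste0(rc_2_8, "A"),
    "7mer-m8" = rc_2_8,
    "7mer-A1" = paste0(rc_2_7, "A"),
    "6mer" = rc_2_7,
    "offset-6mer" = rc_3_8)
}

# all start offsets (0-based) of pattern in subject; 'N' never matches
.match_starts <- function(subject, pattern) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  hits <- Biostrings::matchPattern(pattern, subject, fixed = TRUE)
  as.integer(BiocGenerics::start(hits)) - 1L
}

#' Locate and classify canonical sites in a 3' UTR
#'
#' Each seed-match locus receives exactly one label using the hierarchy
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer > offset-6mer.  Overlapping distinct
#' loci are resolved by keeping the higher-priority type; on equal priority
#' the 5'-most site wins.  Offset-6mers overlapping any retained
#' 6mer/7mer/8mer call are suppressed by default.  Sites whose match
#' overlaps the first 15 nt of the 3' UTR (the path of the ribosome) are
#' flagged `in_ribosome_shadow`.
#'
#' @param utr3 3'-UTR RNA string (or a `TranscriptModel`).
#' @param family a [mirna_family()].
#' @param include_offset_6mer report offset-6mer sites.
#' @param resolve_overlaps drop lower-priority sites that overlap a
#'   higher-priority (or 5'-more) retained site.
#' @param transcript_id id recorded in the output (taken from `utr3` when a
#'   transcript model is supplied).
#' @return `data.frame` with columns `transcript_id`, `family_id`,
#'   `site_type`, `start`, `end` (0-based half-open within the 3' UTR),
#'   `region` (`"utr3"`) and `in_ribosome_shadow`; rows ordered 5'->3'.
#' @export
find_sites <- function(utr3, family, include_offset_6mer = TRUE,
                       resolve_overlaps = TRUE, transcript_id = NA_character_) {
  if (inherits(utr3, "TranscriptModel")) {
    transcript_id <- utr3$transcript_id
    utr3 <- utr3$utr3
  }
  if (nchar(utr3) < 1L) stop("3' UTR must be nonempty")
  sig <- seed_signatures(family)
  chars <- strsplit(utr3, "", fixed = TRUE)[[1L]]
  m8_char <- substr(sig[["7mer-m8"]], 1L, 1L)  # target match to miRNA nt 8

  # per-locus classification: each 6mer-core match (to miRNA nt 2-7) is one
  # locus, labelled by whether the m8 match precedes it and an A follows it
  cores <- .match_starts(utr3, sig[["6mer"]])
  cand <- NULL
  if (length(cores) > 0L) {
    has_m8 <- cores > 0L & chars[pmax(cores, 1L)] == m8_char
    has_a1 <- cores + 7L <= nchar(utr3) & chars[pmin(cores + 7L,
                                                     nchar(utr3))] == "A"
    site_type <- ifelse(has_m8 & has_a1, "8mer",
                 ifelse(has_m8, "7mer-m8",
                 ifelse(has_a1, "7mer-A1", "6mer")))
    start <- ifelse(has_m8, cores - 1L, cores)
    cand <- data.frame(site_type = site_type, start = as.integer(start),
                       end = as.integer(start) + SITE_LEN[site_type],
                       stringsAsFactors = FALSE)
  }
  # offset-6mer loci (match to miRNA nt 3-8), reported only where no
  # retained canonical call covers the locus (default: suppressed on any
  # overlap with a canonical call)
  if (include_offset_6mer) {
    off <- .match_starts(utr3, sig[["offset-6mer"]])
    if (length(off) > 0L) {
      covered <- vapply(off, function(s) {
        !is.null(cand) && any(s < cand$end & s + 6L > cand$start)
      }, logical(1))
      off <- off[!covered]
      if (length(off) > 0L)
        cand <- rbind(cand, data.frame(site_type = "offset-6mer",
                                       start = off, end = off + 6L,
                                       stringsAsFactors = FALSE))
    }
  }
  empty <- data.frame(transcript_id = character(0), family_id = character(0),
                      site_type = character(0), start = integer(0),
                      end = integer(0), region = character(0),
                      in_ribosome_shadow = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)

  # cross-locus resolution: keep the higher-priority type; on equal
  # priority keep the 5'-most
  prio <- setNames(seq_along(SITE_TYPES_ALL), SITE_TYPES_ALL)
  cand$prio <- prio[cand$site_type]
  if (resolve_overlaps) {
    cand <- cand[order(cand$prio, cand$start), , drop = FALSE]
    keep <- logical(nrow(cand))
    occ_start <- integer(0); occ_end <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (any(cand$start[i] < occ_end & cand$end[i] > occ_start)) next
      keep[i] <- TRUE
      occ_start <- c(occ_start, cand$start[i])
      occ_end <- c(occ_end, cand$end[i])
    }
    cand <- cand[keep, , drop = FALSE]
  }
  cand <- cand[order(cand$start, cand$prio), , drop = FALSE]
  data.frame(transcript_id = transcript_id,
             family_id = if (inherits(family, "MirnaFamily"))
               family$family_id else NA_character_,
             site_type = cand$site_type, start = cand$start, end = cand$end,
             region = "utr3", in_ribosome_shadow = cand$start < 15L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count canonical sites in an ORF
#'
#' Counts occurrences of each site-type signature in the ORF with the same
#' per-locus hierarchy and overlap resolution as [find_sites()].
#'
#' @param orf ORF RNA string.
#' @param family a [mirna_family()].
#' @return Named integer vector over the five site types.
#' @export
count_orf_sites <- function(orf, family) {
  if (nchar(orf) < 1L) stop("ORF must be nonempty")
  sites <- find_sites(orf, family, include_offset_6mer = TRUE,
                      resolve_overlaps = TRUE)
  counts <- table(factor(sites$site_type, levels = SITE_TYPES_ALL))
  setNames(as.integer(counts), SITE_TYPES_ALL)
}

#' Transcriptome-wide target-site census for a miRNA family
#'
#' Counts occurrences of the 6mer seed core (match to miRNA nt 2-7) at
#' distinct start offsets across all annotated 3' UTRs; this subsumes the
#' 7mer and 8mer loci and feeds the target-site-abundance feature.
#'
#' @param transcriptome list of transcript models.
#' @param family a [mirna_family()].
#' @return Total site count (integer).
#' @export
target_site_census <- function(transcriptome, family) {
  if (length(transcriptome) == 0L) stop("empty transcriptome")
  core <- seed_signatures(family)[["6mer"]]
  sum(vapply(transcriptome,
             function(tx) length(.match_starts(tx$utr3, core)), integer(1)))
}
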