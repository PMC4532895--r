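# Structural accessibility: probability that a target segment is unpaired
# under local folding.  Two backends: a built-in simplified partition
# function (pair energies only, compiled) and a reader for RNAplfold
# `_lunp` output for bit-compatible reproduction of precomputed profiles.

#' Create an accessibility provider
#'
#' @param type `"builtin"` for the compiled simplified partition function,
#'   or `"lunp"` to look probabilities up in an RNAplfold `_lunp` table.
#' @param maxspan maximal span of a base pair (nt; default 40).
#' @param fold_window length of the local folding window centered on the
#'   target segment (nt; default 80).
#' @param lunp matrix from [read_lunp()] (required for `type = "lunp"`).
#' @return An `AccessibilityProvider`.
#' @export
accessibility_provider <- function(type = c("builtin", "lunp"),
                                   maxspan = 40L, fold_window = 80L,
                                   lunp = NULL) {
  type <- match.arg(type)
  if (type == "lunp" && is.null(lunp))
    stop("type = 'lunp' requires a lunp matrix (see read_lunp)")
  structure(list(type = type, maxspan = as.integer(maxspan),
                 fold_window = as.integer(fold_window), lunp = lunp),
            class = "AccessibilityProvider")
}

#' Read an RNAplfold `_lunp` unpaired-probability file
#'
#' The file has one row per sequence position i (1-based) and one column
#' per window length u; entry (i, u) is the probability that the window of
#' length u ending at position i is unpaired.  `NA` marks undefined
#' entries.
#'
#' @param path path to the `_lunp` file.
#' @return Numeric matrix with rownames = positions, colnames = window
#'   lengths.
#' @export
read_lunp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  ncol <- max(vapply(fields, length, integer(1))) - 1L
  mat <- matrix(NA_real_, nrow = length(fields), ncol = ncol)
  pos <- integer(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    pos[i] <- as.integer(f[1L])
    v <- suppressWarnings(as.numeric(f[-1L]))
    mat[i, seq_along(v)] <- v
  }
  rownames(mat) <- pos
  colnames(mat) <- seq_len(ncol)
  mat
}

#' Probability that a segment is simultaneously unpaired
#'
#' For the built-in backend the sequence is folded locally: a window of
#' `fold_window` nt centered on the target segment (clipped to the
#' sequence) defines the folding universe, pairs are restricted to a
#' maximal span of `maxspan` nt, and the returned value is the ratio of
#' the constrained to the unconstrained partition function.  For the
#' `lunp` backend the value is looked up by segment end position and
#' length.
#'
#' @param utr3 RNA string.
#' @param window_start 0-based offset of the segment within `utr3`.
#' @param window_len segment length (nt).
#' @param provider an [accessibility_provider()].
#' @return Probability in (0, 1\], or `NA` if the segment contains `N` or
#'   the lookup is undefined.
#' @export
unpaired_probability <- function(utr3, window_start, window_len,
                                 provider = accessibility_provider()) {
  n <- nchar(utr3)
  if (window_start < 0L || window_start + window_len > n)
    stop("window outside the sequence")
  if (provider$type == "lunp") {
    endpos <- window_start + window_len          # 1-based inclusive end
    if (endpos > nrow(provider$lunp) || window_len > ncol(provider$lunp))
      return(NA_real_)
    return(provider$lunp[endpos, window_len])
  }
  # clip a fold_window-long universe around the segment
  center <- window_start + window_len / 2
  fw <- provider$fold_window
  from <- max(0L, min(n - fw, as.integer(round(center - fw / 2))))
  to <- min(n, from + fw)                        # 0-based half-open
  sub <- substr(utr3, from + 1L, to)
  if (grepl("N", substr(utr3, window_start + 1L, window_start + window_len),
            fixed = TRUE))
    return(NA_real_)
  .pf_unpaired(sub, window_start - from, window_len, provider$maxspan)
}

# target position opposite miRNA nucleotide 8, given a classified site
.p8_position <- function(site) {
  if (site$site_type %in% c("8mer", "7mer-m8")) site$start else
    site$start - 1L
}

#' Structural accessibility (SA) of a site
#'
#' log10 of the probability that the 14-nt segment centered on the target
#' match to miRNA positions 7 and 8 is unpaired; the segment is truncated
#' at the UTR ends.
#'
#' @param utr3 3'-UTR RNA string.
#' @param site a classified site row (uses `site_type` and `start`).
#' @param provider an [accessibility_provider()].
#' @return SA value (<= 0), or `NA` when the probability is unavailable.
#' @export
structural_accessibility <- function(utr3, site,
                                     provider = accessibility_provider()) {
  p8 <- .p8_position(site)
  from <- max(0L, p8 - 6L)
  to <- min(nchar(utr3), p8 + 8L)               # 0-based half-open
  if (to <= from) return(NA_real_)
  p <- unpaired_probability(utr3, from, to - from, provider)
  if (is.na(p)) return(NA_real_)
  log10(p)
}
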