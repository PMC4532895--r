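# Shared fixtures and independent oracles used across the suite.

rc_rna <- function(x)
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1L]]), collapse = "")

rand_rna <- function(n, gc = 0.4)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")

# the family used throughout the worked examples (miR-1-like seed)
example_family <- function()
  mirna_family("fam-ex", "GGAAUGU", "UGGAAUGUAAAGAAGUAUGUAU",
               conservation_class = "broadly_conserved")

make_transcript <- function(utr3, id = "tx1", gene = "g1",
                            utr5 = "ACGUACGUAC",
                            orf = "AUGGCCGCAUAG") {
  transcript_model(id, gene, utr5, orf, utr3)
}

# --- exhaustive structure-enumeration oracle for the accessibility model
# (independent of the compiled recursion): enumerates every non-crossing
# set of admissible pairs with min loop 3 and bounded span, sums Boltzmann
# weights with the same per-pair energies.
.oracle_RT <- 0.0019872 * 310.15
.oracle_pair_ok <- function(a, b)
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
.oracle_pair_e <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) -3.0 else if (p %in% c("AU", "UA")) -2.0 else -1.0
}
.oracle_enum <- function(chars, i, j, maxspan) {
  if (i > j) return(list(list(w = 1, pairs = integer(0))))
  out <- list()
  for (s in .oracle_enum(chars, i + 1L, j, maxspan))
    out[[length(out) + 1L]] <- s
  if (i + 4L <= j) for (k in (i + 4L):j) {
    if (k - i > maxspan) next
    if (!.oracle_pair_ok(chars[i], chars[k])) next
    w0 <- exp(-.oracle_pair_e(chars[i], chars[k]) / .oracle_RT)
    for (a in .oracle_enum(chars, i + 1L, k - 1L, maxspan))
      for (b in .oracle_enum(chars, k + 1L, j, maxspan))
        out[[length(out) + 1L]] <- list(w = w0 * a$w * b$w,
                                        pairs = c(i, k, a$pairs, b$pairs))
  }
  out
}
oracle_unpaired <- function(seq, win_start, win_len, maxspan = 40L) {
  chars <- strsplit(seq, "")[[1L]]
  st <- .oracle_enum(chars, 1L, nchar(seq), maxspan)
  w <- vapply(st, `[[`, numeric(1), "w")
  win <- (win_start + 1L):(win_start + win_len)
  free <- vapply(st, function(s) length(intersect(s$pairs, win)) == 0L,
                 logical(1))
  sum(w[free]) / sum(w)
}

# --- isoform-expectation oracle for the cumulative weighted score:
# log2 of the abundance-weighted mean, over isoform classes, of the
# product of per-site remaining fractions.  Sites ordered distal ->
# proximal with nondecreasing AIR; class i contains sites i..n.
oracle_cwcs <- function(cs, airs) {
  n <- length(cs)
  if (n == 0L) return(0)
  prev <- c(0, airs[-n])
  remain <- (1 - airs[n])
  for (i in seq_len(n))
    remain <- remain + (airs[i] - prev[i]) * prod(2^cs[i:n])
  log2(remain)
}
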