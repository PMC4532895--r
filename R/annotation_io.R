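# Readers/writers for the external file formats and validated constructors
# for the in-memory transcript, miRNA-family, cluster, and fold-change
# objects.  Internal coordinates are 0-based half-open; user-facing output
# is 1-based inclusive.

.check_rna <- function(seq, what = "sequence", allow_n = TRUE) {
  alphabet <- if (allow_n) c(RNA_ALPHABET, "N") else RNA_ALPHABET
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("non-nucleotide character '%s' in %s at position %d",
                 chars[bad[1L]], what, bad[1L]), call. = FALSE)
  }
  invisible(seq)
}

.dna_to_rna <- function(seq) chartr("Tt", "Uu", toupper(seq))

#' Construct a transcript model
#'
#' A transcript model holds the 5' UTR, ORF and 3' UTR of one representative
#' mRNA (one per unique stop codon), over the alphabet A/C/G/U/N.  The 3'
#' UTR is the longest annotated isoform; shorter tandem isoforms are
#' represented separately by [build_profile()].
#'
#' @param transcript_id,gene_id identifiers.
#' @param utr5,orf,utr3 RNA sequences (character scalars; T is converted to
#'   U).  `utr3` must be non-empty.
#' @param validate_orf require ORF length divisible by 3.
#' @return An object of class `TranscriptModel` with fields
#'   `transcript_id`, `gene_id`, `utr5`, `orf`, `utr3` and
#'   `stop_codon_end`, the 0-based offset of the first 3'-UTR nucleotide
#'   within the mRNA.
#' @export
transcript_model <- function(transcript_id, gene_id, utr5, orf, utr3,
                             validate_orf = TRUE) {
  utr5 <- .dna_to_rna(utr5); orf <- .dna_to_rna(orf); utr3 <- .dna_to_rna(utr3)
  .check_rna(utr5, sprintf("%s 5' UTR", transcript_id))
  .check_rna(orf, sprintf("%s ORF", transcript_id))
  .check_rna(utr3, sprintf("%s 3' UTR", transcript_id))
  if (nchar(utr3) < 1L)
    stop(sprintf("transcript %s: 3' UTR must have length >= 1", transcript_id))
  if (validate_orf && nchar(orf) %% 3L != 0L)
    stop(sprintf("transcript %s: ORF length %d not divisible by 3",
                 transcript_id, nchar(orf)))
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 utr5 = utr5, orf = orf, utr3 = utr3,
                 stop_codon_end = nchar(utr5) + nchar(orf)),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s): |5'UTR|=%d |ORF|=%d |3'UTR|=%d\n",
              x$transcript_id, x$gene_id,
              nchar(x$utr5), nchar(x$orf), nchar(x$utr3)))
  invisible(x)
}

#' Construct a miRNA family
#'
#' Members are mature miRNA sequences (5'->3', >= 18 nt) grouped by the
#' identity of nucleotides 2-8 (the 7-nt seed region).
#'
#' @param family_id identifier.
#' @param seed7 7-nt RNA string equal to nucleotides 2-8 of every member.
#' @param members character vector of mature sequences.
#' @param conservation_class one of `"broadly_conserved"`,
#'   `"mammalian_conserved"`, `"poorly_conserved"`.
#' @return An object of class `MirnaFamily`.
#' @export
mirna_family <- function(family_id, seed7, members,
                         conservation_class = "poorly_conserved") {
  seed7 <- .dna_to_rna(seed7)
  .check_rna(seed7, sprintf("%s seed", family_id), allow_n = FALSE)
  if (nchar(seed7) != 7L)
    stop(sprintf("family %s: seed must be 7 nt, got %d", family_id,
                 nchar(seed7)))
  conservation_class <- match.arg(conservation_class,
    c("broadly_conserved", "mammalian_conserved", "poorly_conserved"))
  members <- vapply(members, .dna_to_rna, character(1), USE.NAMES = FALSE)
  for (m in members) {
    if (nchar(m) < 8L)
      stop(sprintf("family %s: member '%s' shorter than 8 nt", family_id, m))
    if (nchar(m) < 18L)
      warning(sprintf("family %s: member '%s' shorter than a typical mature miRNA",
                      family_id, m))
    .check_rna(m, sprintf("%s member", family_id), allow_n = FALSE)
    if (substr(m, 2L, 8L) != seed7)
      stop(sprintf("family %s: member nt 2-8 '%s' != declared seed '%s'",
                   family_id, substr(m, 2L, 8L), seed7))
  }
  structure(list(family_id = family_id, seed7 = seed7, members = members,
                 conservation_class = conservation_class),
            class = "MirnaFamily")
}

#' Read transcript models from FASTA plus an annotation table
#'
#' The annotation TSV has columns `transcript_id`, `gene_id`, `utr5_len`,
#' `orf_len`, `utr3_len`; the FASTA record of each transcript is the full
#' mRNA (5' UTR + ORF + 3' UTR).  T is converted to U on input.
#'
#' @param fasta_path path to a FASTA file of mRNA sequences.
#' @param annotation_tsv_path path to the annotation table.
#' @param validate_orf require ORF length divisible by 3.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcripts <- function(fasta_path, annotation_tsv_path,
                             validate_orf = TRUE) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- read.delim(annotation_tsv_path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "gene_id", "utr5_len", "orf_len", "utr3_len")
  if (!all(req %in% names(ann)))
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(ann$transcript_id))
    stop("duplicate transcript_id in annotation: ",
         ann$transcript_id[duplicated(ann$transcript_id)][1L])
  missing_ids <- setdiff(ann$transcript_id, ids)
  if (length(missing_ids) > 0L)
    stop("annotation references ids absent from FASTA: ",
         paste(missing_ids, collapse = ", "))
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    id <- ann$transcript_id[i]
    full <- .dna_to_rna(as.character(seqs[[match(id, ids)]]))
    n5 <- ann$utr5_len[i]; no <- ann$orf_len[i]; n3 <- ann$utr3_len[i]
    if (n5 + no + n3 != nchar(full))
      stop(sprintf(
        "transcript %s: boundaries (%d,%d,%d) do not sum to sequence length %d",
        id, n5, no, n3, nchar(full)))
    out[[i]] <- transcript_model(
      id, ann$gene_id[i],
      utr5 = substr(full, 1L, n5),
      orf  = substr(full, n5 + 1L, n5 + no),
      utr3 = substr(full, n5 + no + 1L, n5 + no + n3),
      validate_orf = validate_orf)
  }
  names(out) <- ann$transcript_id
  out
}

#' Write transcript models to FASTA plus annotation table
#'
#' Inverse of [read_transcripts()]; a write-then-read round trip reproduces
#' the input exactly.
#'
#' @param transcripts named list of transcript models.
#' @param fasta_path,annotation_tsv_path output paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_tsv_path) {
  seqs <- vapply(transcripts, function(tx) paste0(tx$utr5, tx$orf, tx$utr3),
                 character(1))
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- vapply(transcripts, `[[`, character(1), "transcript_id")
  Biostrings::writeXStringSet(ss, fasta_path)
  ann <- data.frame(
    transcript_id = names(ss),
    gene_id = vapply(transcripts, `[[`, character(1), "gene_id"),
    utr5_len = vapply(transcripts, function(tx) nchar(tx$utr5), integer(1)),
    orf_len = vapply(transcripts, function(tx) nchar(tx$orf), integer(1)),
    utr3_len = vapply(transcripts, function(tx) nchar(tx$utr3), integer(1)),
    stringsAsFactors = FALSE)
  write.table(ann, annotation_tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Read miRNA families from a TSV table
#'
#' Table columns: `family_id`, `seed7`, `member_seq`, `conservation_class`;
#' one row per mature member.  Members are grouped by family id and must
#' share nucleotides 2-8 with the declared seed.
#'
#' @param tsv_path path to the family table.
#' @return Named list of [mirna_family()] objects.
#' @export
read_mirna_families <- function(tsv_path) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("family_id", "seed7", "member_seq", "conservation_class")
  if (!all(req %in% names(tab)))
    stop("family table must have columns: ", paste(req, collapse = ", "))
  fams <- split(tab, tab$family_id)
  out <- lapply(fams, function(ft) {
    if (length(unique(ft$seed7)) != 1L)
      stop(sprintf("family %s: conflicting seed declarations", ft$family_id[1L]))
    if (length(unique(ft$conservation_class)) != 1L)
      stop(sprintf("family %s: conflicting conservation classes",
                   ft$family_id[1L]))
    mirna_family(ft$family_id[1L], ft$seed7[1L], ft$member_seq,
                 ft$conservation_class[1L])
  })
  out[order(names(out))]
}

#' Write miRNA families to a TSV table
#' @param families named list of miRNA families.
#' @param tsv_path output path.
#' @export
write_mirna_families <- function(families, tsv_path) {
  rows <- do.call(rbind, lapply(families, function(f) {
    data.frame(family_id = f$family_id, seed7 = f$seed7,
               member_seq = f$members,
               conservation_class = f$conservation_class,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read 3P-seq clusters
#'
#' BED-like TSV with columns `transcript_id`, `end_offset` (1-based
#' inclusive position of the isoform 3' end within the 3' UTR, counted from
#' the stop codon), `tag_count`, `dataset_id`.  Stored internally with the
#' same 1-based inclusive ends (equivalently: number of 3'-UTR nucleotides
#' retained in the isoform).
#'
#' @param tsv_path path to the cluster table.
#' @param transcripts optional named list of transcript models; when given,
#'   cluster positions are checked against the 3'-UTR lengths.
#' @return A `data.frame` of class `ClusterSet`.
#' @export
read_clusters <- function(tsv_path, transcripts = NULL) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "end_offset", "tag_count", "dataset_id")
  if (!all(req %in% names(tab)))
    stop("cluster table must have columns: ", paste(req, collapse = ", "))
  cluster_set(tab, transcripts)
}

#' Construct a validated cluster set
#' @param tab data.frame with columns `transcript_id`, `end_offset`,
#'   `tag_count`, `dataset_id`.
#' @param transcripts optional transcript list for bounds checking.
#' @return `tab` with class `ClusterSet` prepended.
#' @export
cluster_set <- function(tab, transcripts = NULL) {
  if (any(tab$tag_count < 0)) stop("negative tag count in cluster set")
  if (any(tab$end_offset < 1L)) stop("cluster end offset < 1")
  if (!is.null(transcripts)) {
    len3 <- vapply(transcripts, function(tx) nchar(tx$utr3), integer(1))
    idx <- match(tab$transcript_id, names(transcripts))
    if (anyNA(idx))
      stop("cluster references unknown transcript: ",
           tab$transcript_id[which(is.na(idx))[1L]])
    over <- tab$end_offset > len3[idx]
    if (any(over))
      stop(sprintf("cluster beyond 3'-UTR end for transcript %s (%d > %d)",
                   tab$transcript_id[which(over)[1L]],
                   tab$end_offset[which(over)[1L]], len3[idx][which(over)[1L]]))
  }
  class(tab) <- c("ClusterSet", "data.frame")
  tab
}

#' Write 3P-seq clusters
#' @param clusters a `ClusterSet`.
#' @param tsv_path output path.
#' @export
write_clusters <- function(clusters, tsv_path) {
  write.table(as.data.frame(clusters), tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Construct a fold-change compendium
#'
#' @param Z numeric genes x experiments matrix of log2 mRNA fold changes
#'   (NA = not measured), with row and column names.
#' @param T binary mask of the same shape; `T[j,k] = 1` iff gene j carries a
#'   canonical 7-8 nt 3'-UTR site to the small RNA perturbed in experiment
#'   k.
#' @return An object of class `FoldChangeCompendium`.
#' @export
fold_change_compendium <- function(Z, T) {
  if (!all(dim(Z) == dim(T)))
    stop(sprintf("Z (%dx%d) and T (%dx%d) differ in shape",
                 nrow(Z), ncol(Z), nrow(T), ncol(T)))
  if (!all(T %in% c(0, 1))) stop("site mask T must be binary")
  if (is.null(rownames(Z)) || is.null(colnames(Z)))
    stop("Z must have gene row names and experiment column names")
  if (anyDuplicated(rownames(Z)))
    stop("duplicate gene id: ", rownames(Z)[duplicated(rownames(Z))][1L])
  structure(list(Z = Z, T = T, gene_ids = rownames(Z),
                 experiment_ids = colnames(Z)),
            class = "FoldChangeCompendium")
}

#' Read a fold-change matrix and site mask into a compendium
#'
#' Both TSVs have a header row of experiment ids and a first column of gene
#' ids; empty cells in the matrix are missing values (never zero).
#'
#' @param tsv_path log2 fold-change matrix.
#' @param site_mask_tsv_path binary site-indicator matrix with identical
#'   row/column keys.
#' @return A [fold_change_compendium()].
#' @export
read_fold_change_matrix <- function(tsv_path, site_mask_tsv_path) {
  rd <- function(p) {
    tab <- read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(tab[[1L]]))
      stop("duplicate gene id in ", p, ": ",
           tab[[1L]][duplicated(tab[[1L]])][1L])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    storage.mode(m) <- "double"
    m
  }
  Z <- rd(tsv_path)
  T <- rd(site_mask_tsv_path)
  if (!identical(dim(Z), dim(T)) ||
      !identical(rownames(Z), rownames(T)) ||
      !identical(colnames(Z), colnames(T)))
    stop("fold-change matrix and site mask must share row/column keys")
  T[is.na(T)] <- 0
  fold_change_compendium(Z, T)
}

#' Write a fold-change compendium to two TSVs
#' @param compendium a `FoldChangeCompendium`.
#' @param tsv_path,site_mask_tsv_path output paths.
#' @export
write_fold_change_matrix <- function(compendium, tsv_path,
                                     site_mask_tsv_path) {
  wr <- function(m, p) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(compendium$Z, tsv_path)
  wr(compendium$T, site_mask_tsv_path)
  invisible(NULL)
}
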