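# Synthetic-data generator: random transcriptomes with planted canonical
# sites, tandem-isoform 3P-seq tag profiles, and fold-change compendia
# with planted linear feature effects, shared batch structure and noise.
# Every generator is fully determined by the configuration seed.

#' Simulation configuration
#'
#' @param n_transcripts number of mRNAs.
#' @param n_mirnas number of miRNA families.
#' @param n_experiments number of perturbation experiments (families are
#'   assigned round-robin).
#' @param utr3_meanlog,utr3_sdlog log-normal 3'-UTR length distribution
#'   (defaults give a median of ~600 nt).
#' @param gc_content G+C fraction of generated sequence.
#' @param p_site probability that a transcript carries one planted site.
#' @param site_type_probs planting probabilities over the four canonical
#'   site types.
#' @param true_model named list per site type with `intercept` and
#'   `coefficients` (named, over expanded feature columns) generating the
#'   per-site repression; caps are not applied when generating.
#' @param noise_sd iid Gaussian noise SD of log2 fold changes.
#' @param batch_rank,batch_sd rank and loading scale of the shared
#'   batch component (rows tied to 3'-UTR length / AU content).
#' @param tag_depth expected 3P-seq tags per transcript.
#' @param n_datasets number of 3P-seq datasets.
#' @param p_single_isoform fraction of transcripts with a single 3'-UTR
#'   isoform.
#' @param missing_frac fraction of fold-change cells set missing.
#' @param endogenous_families,endogenous_offset optional derepression
#'   artifact: genes with sites to these families gain a positive offset
#'   in every experiment.
#' @param seed integer seed; fully determines all outputs.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(n_transcripts = 300L, n_mirnas = 4L,
                       n_experiments = 12L,
                       utr3_meanlog = log(600), utr3_sdlog = 0.45,
                       gc_content = 0.4, p_site = 0.8,
                       site_type_probs = c("8mer" = 0.25, "7mer-m8" = 0.25,
                                           "7mer-A1" = 0.25, "6mer" = 0.25),
                       true_model = default_true_model(),
                       noise_sd = 0.15, batch_rank = 1L, batch_sd = 0,
                       tag_depth = 200L, n_datasets = 2L,
                       p_single_isoform = 0.7, missing_frac = 0.03,
                       endogenous_families = character(0),
                       endogenous_offset = 0.1, seed = 1L) {
  stopifnot(n_transcripts >= 1L, n_mirnas >= 1L, n_experiments >= 1L)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Default generating model for the synthetic compendium
#'
#' Site-type intercepts ordered by efficacy (8mer strongest) and nonzero
#' coefficients on three context features; all other features carry no
#' planted effect.
#'
#' @return Named list per site type with `intercept` and `coefficients`.
#' @export
default_true_model <- function() {
  co <- c(local_AU = -0.35, min_dist = 0.30, len_3UTR = 0.30)
  list("8mer" = list(intercept = -0.50, coefficients = co),
       "7mer-m8" = list(intercept = -0.35, coefficients = co),
       "7mer-A1" = list(intercept = -0.20, coefficients = co),
       "6mer" = list(intercept = -0.08, coefficients = co))
}

.rand_rna <- function(n, gc) {
  paste(sample(RNA_ALPHABET, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.rand_families <- function(n_mirnas, gc) {
  fams <- list()
  seeds_seen <- character(0)
  i <- 0L
  while (length(fams) < n_mirnas) {
    i <- i + 1L
    mat <- .rand_rna(22L, gc)
    seed7 <- substr(mat, 2L, 8L)
    if (seed7 %in% seeds_seen) next
    seeds_seen <- c(seeds_seen, seed7)
    id <- sprintf("fam%02d", length(fams) + 1L)
    fams[[id]] <- mirna_family(id, seed7, mat,
                               conservation_class = "broadly_conserved")
  }
  fams
}

# overwrite positions [at, at+len) of seq (0-based) with repl
.splice <- function(seq, at, repl) {
  paste0(substr(seq, 1L, at), repl, substr(seq, at + nchar(repl) + 1L,
                                           nchar(seq)))
}

# replacement bases honoring the configured base composition (a GC-free
# transcriptome stays GC-free under flank fixing and scrubbing)
.alt_bases <- function(exclude, gc) {
  pool <- if (gc <= 0) c("A", "U") else if (gc >= 1) c("C", "G") else
    RNA_ALPHABET
  out <- setdiff(pool, exclude)
  if (length(out) == 0L) setdiff(RNA_ALPHABET, exclude) else out
}

# mutate accidental seed-core and offset-6mer matches so that discovered
# sites equal the planted registry exactly
.scrub_utr <- function(utr3, families, protected, gc) {
  for (iter in 1:25) {
    dirty <- FALSE
    for (f in families) {
      sig <- seed_signatures(f)
      for (pat in c(sig[["6mer"]], sig[["offset-6mer"]])) {
        for (s in .match_starts(utr3, pat)) {
          span <- s:(s + 5L)
          if (any(span %in% protected)) next
          pos <- span[!span %in% protected][3L %% length(span) + 1L]
          cur <- substr(utr3, pos + 1L, pos + 1L)
          utr3 <- .splice(utr3, pos, sample(.alt_bases(cur, gc), 1L))
          dirty <- TRUE
        }
      }
    }
    if (!dirty) break
  }
  utr3
}

#' Simulate a transcriptome with planted canonical sites
#'
#' Generates random mRNAs and miRNA families and plants at most one
#' canonical 3'-UTR site per transcript at controlled type frequencies;
#' flanking bases are fixed so the planted type classifies as intended,
#' and accidental seed matches are mutated away, so site discovery
#' recovers exactly the emitted registry.
#'
#' @param config a [sim_config()].
#' @param families optional pre-built family list (overrides random
#'   families).
#' @return List with `transcripts`, `families`, `registry` (planted-site
#'   table in 0-based half-open coordinates).
#' @export
simulate_transcriptome <- function(config, families = NULL) {
  set.seed(config$seed)
  gc <- config$gc_content
  if (is.null(families)) families <- .rand_families(config$n_mirnas, gc)
  fam_ids <- names(families)
  transcripts <- list()
  reg <- list()
  # verify a 3' UTR discovers exactly the intended planted site (or none)
  .clean <- function(utr3, planted) {
    for (fid in fam_ids) {
      s <- find_sites(utr3, families[[fid]])
      want <- !is.null(planted) && planted$family_id == fid
      if (want) {
        if (nrow(s) != 1L || s$site_type != planted$site_type ||
            s$start != planted$start) return(FALSE)
      } else if (nrow(s) != 0L) return(FALSE)
    }
    TRUE
  }
  for (i in seq_len(config$n_transcripts)) {
    id <- sprintf("tx%04d", i)
    len3 <- max(60L, min(5400L, round(rlnorm(1, config$utr3_meanlog,
                                             config$utr3_sdlog))))
    utr5 <- .rand_rna(sample(30:150, 1L), gc)
    orf <- .rand_rna(3L * sample(100:400, 1L), gc)
    plant <- runif(1) < config$p_site
    for (attempt in 1:20) {
      utr3 <- .rand_rna(len3, gc)
      planted <- NULL
      protected <- integer(0)
      if (plant) {
        fam <- families[[sample(fam_ids, 1L)]]
        st <- sample(names(config$site_type_probs), 1L,
                     prob = config$site_type_probs)
        slen <- SITE_LEN[[st]]
        if (len3 < slen + 40L)
          stop("3' UTR too short to plant a site; raise utr3_meanlog")
        s <- sample(16:(len3 - slen - 12L), 1L)
        sig <- seed_signatures(fam)
        utr3 <- .splice(utr3, s, sig[[st]])
        m8c <- substr(sig[["7mer-m8"]], 1L, 1L)
        # fix flanks so the locus classifies as the intended type
        if (st %in% c("7mer-A1", "6mer"))         # no m8 pair upstream
          utr3 <- .splice(utr3, s - 1L, sample(.alt_bases(m8c, gc), 1L))
        if (st %in% c("7mer-m8", "6mer"))         # no A downstream
          utr3 <- .splice(utr3, s + slen, sample(.alt_bases("A", gc), 1L))
        protected <- (s - 1L):(s + slen)
        planted <- data.frame(
          transcript_id = id, family_id = fam$family_id, site_type = st,
          start = s, end = s + slen, stringsAsFactors = FALSE)
      }
      utr3 <- .scrub_utr(utr3, families, protected, gc)
      if (.clean(utr3, planted)) break
      if (attempt == 20L)
        stop("could not generate a clean 3' UTR; lower n_mirnas or GC")
    }
    if (!is.null(planted)) reg[[length(reg) + 1L]] <- planted
    transcripts[[id]] <- transcript_model(id, sprintf("gene%04d", i),
                                          utr5, orf, utr3)
  }
  registry <- if (length(reg) > 0L) do.call(rbind, reg) else
    data.frame(transcript_id = character(0), family_id = character(0),
               site_type = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  list(transcripts = transcripts, families = families, registry = registry)
}

#' Simulate 3P-seq cluster profiles
#'
#' Draws 1-4 tandem isoform ends per 3' UTR with Dirichlet-distributed
#' truth abundances (the most distal end is always the annotated end) and
#' multinomial tag counts split over datasets.
#'
#' @param transcripts named list of transcript models.
#' @param config a [sim_config()].
#' @return List with `clusters` (a `ClusterSet`) and `truth` (per
#'   transcript: `ends`, `abundances`).
#' @export
simulate_profiles <- function(transcripts, config) {
  set.seed(config$seed + 1L)
  rows <- list(); truth <- list()
  for (tx in transcripts) {
    len3 <- nchar(tx$utr3)
    if (runif(1) < config$p_single_isoform || len3 < 80L) {
      ends <- len3
      ab <- 1
    } else {
      k <- sample(2:4, 1L)
      prox <- sort(sample(30:(len3 - 10L), k - 1L))
      ends <- c(prox, len3)
      g <- rgamma(k, shape = 2)
      ab <- g / sum(g)
    }
    truth[[tx$transcript_id]] <- list(ends = ends, abundances = ab)
    if (config$tag_depth > 0L) {
      for (ds in seq_len(config$n_datasets)) {
        depth <- ceiling(config$tag_depth / config$n_datasets)
        tags <- as.integer(rmultinom(1L, depth, ab))
        keep <- tags > 0L
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tx$transcript_id, end_offset = ends[keep],
          tag_count = tags[keep], dataset_id = sprintf("ds%d", ds),
          stringsAsFactors = FALSE)
      }
    }
  }
  clusters <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), end_offset = integer(0),
               tag_count = numeric(0), dataset_id = character(0),
               stringsAsFactors = FALSE)
  list(clusters = cluster_set(clusters, transcripts), truth = truth)
}

# per-site generating score: intercept + coefficients on the expanded
# scaled feature row (no cap)
.true_site_score <- function(fv_row, site_type, true_model) {
  tm <- true_model[[site_type]]
  co <- tm$coefficients
  tm$intercept + sum(co * fv_row[names(co)])
}

#' Simulate a fold-change compendium with planted effects
#'
#' Each experiment perturbs one family (round-robin).  The fold change of
#' a gene is the sum of the generating linear-model scores of its
#' canonical 3'-UTR sites to that family (computed from the same scaled
#' features the scoring pipeline uses, without caps), plus a shared
#' low-rank batch component tied to 3'-UTR length and AU content, plus
#' iid Gaussian noise; a fraction of cells is set missing.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param profiles output of [simulate_profiles()] (annotated-isoform
#'   profiles are used when `NULL`).
#' @param config a [sim_config()].
#' @param scaling percentile scaling table.
#' @param provider accessibility backend.
#' @return List with the `compendium` ([fold_change_compendium()]),
#'   `experiment_families`, `effect` and `batch` truth matrices, and
#'   `site_features` (per-site expanded feature rows and generating
#'   scores).
#' @export
simulate_compendium <- function(sim, profiles = NULL, config,
                                scaling = default_scaling_table(),
                                provider = accessibility_provider()) {
  set.seed(config$seed + 2L)
  transcripts <- sim$transcripts; families <- sim$families
  n <- length(transcripts); ids <- names(transcripts)
  fam_ids <- names(families)
  exp_fam <- fam_ids[(seq_len(config$n_experiments) - 1L) %%
                       length(fam_ids) + 1L]
  exp_ids <- sprintf("exp%02d", seq_len(config$n_experiments))
  censuses <- vapply(families, function(f)
    target_site_census(transcripts, f), integer(1))

  prof_of <- function(id) {
    if (!is.null(profiles) && !is.null(profiles$truth[[id]]))
      isoform_profile(id, profiles$truth[[id]]$ends,
                      profiles$truth[[id]]$abundances)
    else isoform_profile(id, nchar(transcripts[[id]]$utr3), 1)
  }

  # per (transcript, family): site table, expanded features, truth scores
  site_features <- list()
  effect_by_fam <- matrix(0, n, length(fam_ids),
                          dimnames = list(ids, fam_ids))
  mask_by_fam <- matrix(0, n, length(fam_ids),
                        dimnames = list(ids, fam_ids))
  for (fid in fam_ids) {
    fam <- families[[fid]]
    for (id in ids) {
      tx <- transcripts[[id]]
      sites_all <- find_sites(tx$utr3, fam, transcript_id = id)
      sites <- sites_all[sites_all$site_type %in% SITE_TYPES &
                           !sites_all$in_ribosome_shadow, , drop = FALSE]
      if (nrow(sites) == 0L) next
      if (any(sites$site_type %in% c("8mer", "7mer-m8", "7mer-A1")))
        mask_by_fam[id, fid] <- 1
      pr <- prof_of(id)
      for (i in seq_len(nrow(sites))) {
        fv <- feature_vector(sites[i, ], tx, fam, profile = pr,
                             census = max(1L, censuses[[fid]]),
                             provider = provider, scaling = scaling,
                             sites_all = sites_all)
        row <- expand_feature_vector(fv)
        sc <- .true_site_score(row, sites$site_type[i], config$true_model)
        effect_by_fam[id, fid] <- effect_by_fam[id, fid] + sc
        site_features[[length(site_features) + 1L]] <- list(
          transcript_id = id, family_id = fid,
          site_type = sites$site_type[i], start = sites$start[i],
          features = row, score = sc,
          n_sites = nrow(sites))
      }
    }
  }

  effect <- effect_by_fam[, exp_fam, drop = FALSE]
  Tmask <- mask_by_fam[, exp_fam, drop = FALSE]
  colnames(effect) <- colnames(Tmask) <- exp_ids

  # batch component tied to gene covariates
  len3 <- vapply(transcripts, function(tx) nchar(tx$utr3), numeric(1))
  au3 <- vapply(transcripts, function(tx) {
    ch <- strsplit(tx$utr3, "", fixed = TRUE)[[1L]]
    mean(ch %in% c("A", "U"))
  }, numeric(1))
  U <- cbind(as.numeric(scale(log10(len3))), as.numeric(scale(au3)))
  batch <- matrix(0, n, config$n_experiments)
  if (config$batch_sd > 0 && config$batch_rank > 0L) {
    for (r in seq_len(min(config$batch_rank, ncol(U)))) {
      v <- config$batch_sd * (1 + 0.2 * rnorm(config$n_experiments))
      batch <- batch + U[, r] %*% t(v)
    }
  }
  Z <- effect + batch +
    matrix(rnorm(n * config$n_experiments, sd = config$noise_sd), n)
  if (length(config$endogenous_families) > 0L) {
    endo <- rowSums(mask_by_fam[, config$endogenous_families,
                                drop = FALSE]) > 0
    Z[endo, ] <- Z[endo, ] + config$endogenous_offset
  }
  if (config$missing_frac > 0) {
    holes <- runif(length(Z)) < config$missing_frac
    Z[holes] <- NA_real_
  }
  dimnames(Z) <- list(ids, exp_ids)
  list(compendium = fold_change_compendium(Z, Tmask),
       experiment_families = setNames(exp_fam, exp_ids),
       effect = effect, batch = batch, site_features = site_features,
       censuses = censuses)
}

#' Assemble the per-site-type training set from a compendium
#'
#' One row per (mRNA, experiment) pair where the mRNA's dominant isoform
#' holds >= 90% of 3P-seq tags and its 3' UTR carries a single canonical
#' site to the perturbed small RNA; the design holds the expanded scaled
#' features of that site, optionally augmented with pure-noise candidate
#' columns, and the response is the (normalized) log2 fold change.
#'
#' @param Z fold-change matrix used as the response (e.g.
#'   `NormalizationResult$Z_norm`).
#' @param simc output of [simulate_compendium()] (provides site features
#'   and experiment-family assignment).
#' @param profiles output of [simulate_profiles()] (for the dominance
#'   filter); `NULL` treats every transcript as single-isoform.
#' @param noise_candidates number of extra iid-noise candidate columns.
#' @param dominant_frac isoform-dominance threshold (default 0.9).
#' @param seed seed for the noise columns.
#' @return Named list per site type: `design`, `response`, `experiment`.
#' @export
build_training_set <- function(Z, simc, profiles = NULL,
                               noise_candidates = 0L, dominant_frac = 0.9,
                               seed = 1L) {
  set.seed(seed)
  sf <- simc$site_features
  if (length(sf) == 0L) stop("no sites in the simulated compendium")
  singles <- Filter(function(s) s$n_sites == 1L, sf)
  key <- vapply(singles, function(s) paste(s$transcript_id, s$family_id),
                character(1))
  dominant_ok <- function(id) {
    if (is.null(profiles)) return(TRUE)
    tr <- profiles$truth[[id]]
    !is.null(tr) && max(tr$abundances) >= dominant_frac
  }
  out <- list()
  for (st in SITE_TYPES) {
    rows <- list(); resp <- numeric(0); expt <- character(0)
    for (s in singles) {
      if (s$site_type != st || !dominant_ok(s$transcript_id)) next
      for (e in names(simc$experiment_families)) {
        if (simc$experiment_families[[e]] != s$family_id) next
        y <- Z[s$transcript_id, e]
        if (is.na(y)) next
        rows[[length(rows) + 1L]] <- s$features
        resp <- c(resp, y)
        expt <- c(expt, e)
      }
    }
    if (length(rows) == 0L) next
    design <- as.data.frame(do.call(rbind, rows))
    if (noise_candidates > 0L) {
      for (j in seq_len(noise_candidates))
        design[[sprintf("noise%d", j)]] <- rnorm(nrow(design))
    }
    out[[st]] <- list(design = design, response = resp, experiment = expt)
  }
  out
}
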