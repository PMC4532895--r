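#!/usr/bin/env Rscript
# Regenerates inst/extdata/context_model_synthetic.tsv: the packaged
# default scoring model, trained by the package's own pipeline on its
# synthetic compendium (clearly labelled synthetic; substitute a real
# coefficient table via read_context_model() for production scoring).
#
# Eight families are constructed so that the first and eighth miRNA
# nucleotides cycle through A/C/G/U, giving the nucleotide-identity
# indicator columns support in the training design.  The full expanded
# feature set is fit per site type by OLS on the normalized compendium;
# structurally aliased columns (e.g. the site-8 identity of m8-paired
# site types, which is determined by the sRNA-8 identity) receive a zero
# coefficient.

suppressMessages(library(contextpp))
set.seed(20260901)

make_families <- function() {
  nts <- c("A", "C", "G", "U")
  fams <- list()
  seen <- character(0)
  i <- 0L
  while (length(fams) < 8L) {
    i <- i + 1L
    mat <- paste(sample(nts, 22L, replace = TRUE), collapse = "")
    k <- length(fams) + 1L
    substr(mat, 1L, 1L) <- nts[(k - 1L) %% 4L + 1L]
    substr(mat, 8L, 8L) <- nts[(k - 1L) %/% 2L %% 4L + 1L]
    seed7 <- substr(mat, 2L, 8L)
    if (seed7 %in% seen) next
    seen <- c(seen, seed7)
    id <- sprintf("fam%02d", k)
    fams[[id]] <- mirna_family(id, seed7, mat,
                               conservation_class = "broadly_conserved")
  }
  fams
}

cfg <- sim_config(n_transcripts = 500L, n_mirnas = 8L, n_experiments = 24L,
                  batch_sd = 0.2, seed = 20260901)
sim <- simulate_transcriptome(cfg, families = make_families())
pro <- simulate_profiles(sim$transcripts, cfg)
simc <- simulate_compendium(sim, pro, cfg)
norm <- normalize_compendium(simc$compendium, seed = 20260901)
ts <- build_training_set(norm$Z_norm, simc, pro, noise_candidates = 0L)

rows <- list()
for (st in names(ts)) {
  d <- ts[[st]]
  dat <- cbind(.response = d$response, d$design)
  fml <- as.formula(paste(".response ~",
                          paste(sprintf("`%s`", colnames(d$design)),
                                collapse = " + ")))
  fit <- lm(fml, data = dat)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0            # aliased / constant columns
  names(cf) <- gsub("`", "", names(cf), fixed = TRUE)
  rows[[st]] <- data.frame(site_type = st, term = names(cf),
                           estimate = unname(cf), stringsAsFactors = FALSE)
  cat(st, ": n =", nrow(dat), " sigma =", round(summary(fit)$sigma, 3), "\n")
}
tab <- do.call(rbind, rows)
tab$estimate <- round(tab$estimate, 6)
out <- file.path("inst", "extdata", "context_model_synthetic.tsv")
write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "with", nrow(tab), "terms\n")
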