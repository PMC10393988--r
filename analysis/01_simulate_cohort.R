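#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort with known truth.
#
# Simulates the reference family cohort (three generations plus unrelated
# adults from the same population), sequences it at ancient-DNA-like
# coverage with terminal deamination, and writes the genotype data in the
# standard formats (EIGENSTRAT triplet, VCF with genotype likelihoods)
# together with the truth tables downstream stages are judged against.

library(paleokin)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out_dir <- file.path("results", "cohort")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_sites <- 40000L
ped <- kinship_study_pedigree()
panel <- snp_panel(synth_panel_sites(n_sites))
set.seed(seed)
panel$freq <- matrix(runif(n_sites, 0.05, 0.95), ncol = 1,
                     dimnames = list(NULL, "POP"))
drop <- gene_drop(ped, panel, "POP", seed = seed)
prof <- flat_damage(0.2, span = 3L)
reads <- simulate_reads(drop, sequencing_spec(mean_depth = 4,
                                              base_error = 0.001,
                                              damage = prof,
                                              seed = seed + 1L))

ids <- ped$members$id
hap <- sapply(ids, function(id) call_pseudohaploid(reads[[id]], panel,
                                                   seed = seed, id = id))
gl <- array(NA_real_, c(n_sites, length(ids), 3))
gq <- matrix(NA_real_, n_sites, length(ids))
dip <- matrix(NA_integer_, n_sites, length(ids))
for (k in seq_along(ids)) {
  cl <- call_genotype_likelihoods(reads[[ids[k]]], panel, damage = prof)
  gl[, k, ] <- cl$lik
  gq[, k] <- cl$gq
  # hard diploid calls only where confidently resolved; GLs keep the rest
  conf <- !is.na(cl$gq) & cl$gq >= 30
  dip[conf, k] <- cl$best[conf]
}
meta <- data.frame(id = ids, sex = ped$members$sex, group = "SIM")
store <- geno_store(panel, meta, diploid = dip, haploid = hap,
                    gl = gl, gq = gq)

write_eigenstrat(store, file.path(out_dir, "cohort"))
write_vcf_gl(store, file.path(out_dir, "cohort.vcf"))
write.table(data.frame(site = panel$sites$id, hap),
            file.path(out_dir, "cohort_pseudohaploid.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(drop$labels, file.path(out_dir, "truth_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth_k <- do.call(rbind, lapply(
  combn(ids, 2, simplify = FALSE),
  function(p) data.frame(id1 = p[1], id2 = p[2],
                         t(realized_k(drop, p[1], p[2])))))
write.table(truth_k, file.path(out_dir, "truth_realized_k.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Cohort of", length(ids), "individuals at", n_sites, "sites written to",
    out_dir, "\n")
cat("Depth condition: lambda = 4; terminal C>T/G>A rate 0.2\n")
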