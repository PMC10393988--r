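#!/usr/bin/env Rscript
# Stage 3: rule-based pedigree reconstruction from the stage-2 dyad table.
#
# Gates the pairwise evidence (10,000 autosomal / 1,000 X overlapping
# SNPs), types first-degree pairs with uniparental markers, age classes
# and k-coefficients, triangulates second-degree edges against sibling
# pairs, and writes the typed edge table plus a DOT rendering and a
# social-structure summary.

library(paleokin)

kin_path <- file.path("results", "kinship_pairs.tsv")
if (!file.exists(kin_path)) stop("run analysis/02_kinship.R first")
kin <- read.table(kin_path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
labels <- read.table(file.path("results", "cohort", "truth_labels.tsv"),
                     header = TRUE, sep = "\t", stringsAsFactors = FALSE)
meta <- data.frame(id = labels$id, sex = labels$sex,
                   age_class = labels$age_class, mito = labels$mito,
                   y = labels$y, stringsAsFactors = FALSE)

graph <- build_pedigree(kin, meta)
print(graph)
write.table(graph$edges, file.path("results", "pedigree_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_pedigree_dot(graph, file.path("results", "pedigree.dot"))

ss <- summarize_social_structure(graph)
cat("Adult males with kin:", ss$kin_counts[["adult_males_with_kin"]], "/",
    ss$kin_counts[["adult_males_total"]], "\n")
cat("Adult females with kin:", ss$kin_counts[["adult_females_with_kin"]], "/",
    ss$kin_counts[["adult_females_total"]], "\n")
cat("Haplotype diversity among males: Y =", round(ss$h_y_males, 3),
    " mito =", round(ss$h_mito_males, 3), "\n")
writeLines(graph$log, file.path("results", "pedigree_rule_log.txt"))
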