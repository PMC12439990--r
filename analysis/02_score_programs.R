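#!/usr/bin/env Rscript

# Score gene programs per cell and gate intermediate-state cells.  The
# co-expression score (minimum of contraction and ECM) marks cells in which
# both myofibroblast-defining programs are simultaneously active; the gate
# counts double-positive cells per subject for the proportion model.

suppressMessages(library(pmtstats))

counts <- read_counts_mtx("results/synth")
cells <- read.table("results/synth/cells.tsv", header = TRUE, sep = "\t")
genesets <- lapply(c(contraction = "contraction", ecm = "ecm",
                     pericyte = "pericyte", myofibroblast = "myofibroblast"),
                   function(p) gene_set(p, readLines(
                     file.path("results/synth", paste0("geneset_", p, ".txt")))))

norm <- normalize_cp10k(counts)
s_con <- module_score(norm, genesets$contraction, seed = 1)
s_ecm <- module_score(norm, genesets$ecm, seed = 1)
s_myo <- module_score(norm, genesets$myofibroblast, seed = 1)
s_co <- coexpression_score(s_con, s_ecm)

scores <- data.frame(cell_id = names(s_co$score),
                     contraction = as.numeric(s_con$score),
                     ecm = as.numeric(s_ecm$score),
                     myofibroblast = as.numeric(s_myo$score),
                     coexpression = as.numeric(s_co$score))
write.table(scores, "results/scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# gate on one contraction-program and one pericyte-program marker, the
# synthetic analogues of ACTA2 and CSPG4
gate <- gate_intermediate(norm, cells,
                          gene_a = genesets$contraction$genes[1],
                          gene_b = genesets$pericyte$genes[1], cutoff = 1.5)
write.table(gate$subject_counts, "results/gate_subject_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Scored", nrow(scores), "cells.\n")
cat("Mean co-expression score by genotype:\n")
print(round(tapply(scores$coexpression,
                   cells$genotype[match(scores$cell_id, cells$cell_id)],
                   mean), 3))
cat("Intermediate (double-positive) cells:", sum(gate$positive), "of",
    length(gate$positive), "\n")
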