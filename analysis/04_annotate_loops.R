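#!/usr/bin/env Rscript
# Stage 4 — classify loop anchors against the gene annotation.
#
# Promoter windows are +/- 2.5 kb around each TSS; anchors take the
# highest-precedence overlapped feature (promoter > UTR > exon > intron >
# downstream > distal intergenic) and loops are grouped into the
# promoter-centric categories.

suppressMessages(library(hichipTargets))

annotation <- read_gtf("results/sim/genes.gtf")
loops <- read_loops_bedpe("results/loops.bedpe")

categories <- classify_loops(loops, annotation)
tab <- as.data.frame(table(category = categories))
tab$fraction <- tab$Freq / sum(tab$Freq)
write.table(tab, "results/loop_categories.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(tab)
pa <- sum(tab$Freq[tab$category != "non_promoter"])
cat(sprintf("%d/%d loops are promoter-associated\n", pa, nrow(loops)))
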