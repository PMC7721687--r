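#!/usr/bin/env Rscript
# Step 2 -- annotate the simulated genomes.
#
# Partition into extra/canonical zones, annotate Gag, the -1 frameshift
# slippery site, Pol and the Gag-Pol fusion, and locate the five
# cis-signals (5' motif, AU-rich window, frameshift / packaging /
# replication stem loops). Artifacts are written as GFF3 plus a JSON
# report; this step re-derives everything from the FASTA alone and
# prints how the annotation compares with the planted truth.

suppressPackageStartupMessages(library(lahelper))
truth <- jsonlite::read_json("results/planted_truth.json",
                             simplifyVector = TRUE)

seqs <- read_fasta("results/synthetic_genomes.fasta")
main <- seqs[[1]]

p <- partition_genome(main, anchor_5 = "AATTAA", anchor_3 = "CCATAAGC")
gp <- build_gagpol_model(p)
sg <- find_signal_stemloops(p, gp)

dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)
partition_gff3(p, "results/annotation/main.regions.gff3")
gagpol_gff3(p, gp, "results/annotation/main.gagpol.gff3")
signals_gff3(p, sg, "results/annotation/main.signals.gff3")

cat("Partition:", p$five_extra_len, "/", p$canonical_len, "/",
    p$three_extra_len,
    if (p$five_extra_len == truth$main$five_extra_len)
      "(matches planted truth)\n" else "(MISMATCH)\n")
cat(sprintf("Gag ORF canonical %d..%d (%d aa); planted %d..%d\n",
            gp$gag$start, gp$gag$end, nchar(gp$gag$protein),
            truth$main$gag[1], truth$main$gag[2]))
cat(sprintf("Slippery heptamer %s at canonical %d (planted %d)\n",
            gp$slippery$heptamer, gp$slippery$position,
            truth$main$slippery_pos))
cat(sprintf("Pol ORF canonical %d..%d (%d aa); fusion protein %d aa\n",
            gp$pol$start, gp$pol$end, nchar(gp$pol$protein),
            nchar(gp$fusion_protein)))
for (s in sg) {
  cat(sprintf("  %-17s %s%s\n", s$kind, s$location,
              if (!is.null(s$hairpin))
                sprintf("  dG = %.1f kJ/mol", s$hairpin$dG_kJ) else ""))
}
cat("Wrote GFF3 annotation under results/annotation/\n")
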