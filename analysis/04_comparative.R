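#!/usr/bin/env Rscript
# Step 4 -- comparative analysis of the simulated family.
#
# Full-genome nucleotide and Gag-Pol amino-acid identity matrices, the
# neighbor-joining phylogram on 1 - identity/100 distances, a check that
# the tree recovers the guide topology, and a conserved-residue panel of
# one family member against the root's Gag-Pol.

suppressPackageStartupMessages(library(lahelper))
seqs <- read_fasta("results/synthetic_genomes.fasta")
fam <- seqs[-(1:2)]
names(fam) <- vapply(fam, `[[`, "", "id")

nt <- identity_matrix(vapply(fam, `[[`, "", "residues"), kind = "NT")
identity_matrix_tsv(nt, "results/identity_nt.tsv")

gagpol <- vapply(fam, function(v) {
  p <- partition_genome(v, anchor_5 = "AATTAA", anchor_3 = "CCATAAGC")
  build_gagpol_model(p)$fusion_protein
}, "")
aa <- identity_matrix(gagpol, kind = "AA")
identity_matrix_tsv(aa, "results/identity_gagpol_aa.tsv")

ph <- nj_phylogram(aa)
writeLines(ph$newick, "results/phylogram_gagpol.nwk")

guide <- ape::read.tree("results/guide_tree.nwk")
rf <- ape::dist.topo(ape::unroot(ph$tree), ape::unroot(guide))

cat("Nucleotide identity range:",
    sprintf("%.1f-%.1f%%\n", min(nt$values[upper.tri(nt$values)]),
            max(nt$values[upper.tri(nt$values)])))
a <- grep("^A", aa$labels); b <- grep("^B", aa$labels)
cat(sprintf("Gag-Pol identity within cluster A: %.1f-%.1f%%\n",
            min(aa$values[a, a][upper.tri(aa$values[a, a])]),
            max(aa$values[a, a][upper.tri(aa$values[a, a])])))
cat(sprintf("Gag-Pol identity between clusters: %.1f-%.1f%%\n",
            min(aa$values[a, b]), max(aa$values[a, b])))
cat("NJ phylogram:", ph$newick, "\n")
cat("Robinson-Foulds distance to the guide topology:", as.numeric(rf), "\n")

panel <- check_conserved_residues(gagpol[[2]], gagpol[[1]],
                                  motifs = list(A = c(900, 910),
                                                B = c(950, 960),
                                                C = c(1000, 1010),
                                                D = c(1050, 1060)))
cat("Conserved-residue panel of", names(gagpol)[2], "vs",
    names(gagpol)[1], ": His154", panel$h154, "; cap residues",
    paste(names(panel$cap_residues), panel$cap_residues, collapse = " "),
    "\n")
cat("Wrote results/identity_nt.tsv, identity_gagpol_aa.tsv,",
    "phylogram_gagpol.nwk\n")
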