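#!/usr/bin/env Rscript
# Step 3 -- characterize the extra sequences.
#
# Self-identity between the extra zones and the canonical interior,
# near-palindromes around the zone boundary, the stem loops the repeats
# fold into, the kissing complex their loops can form, and host-sequence
# matches for the genome carrying a planted rRNA-like fragment.

suppressPackageStartupMessages(library(lahelper))
seqs <- read_fasta("results/synthetic_genomes.fasta")
main <- seqs[[1]]
hostg <- seqs[[2]]

p <- partition_genome(main, anchor_5 = "AATTAA", anchor_3 = "CCATAAGC")
si <- find_self_identity(p)
write.table(si, "results/self_identity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Self-identity matches (>= 13 nt, disjoint intervals):\n")
print(si[, c("length", "query_label", "subject_label")], row.names = FALSE)

pal <- palindrome_scan(substr(main$residues, 1, p$five_extra_len + 80))
write.table(pal, "results/palindromes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Near-palindromes near the 5' boundary:", nrow(pal), "hit(s)\n")

# fold the boundary-spanning repeat and its canonical copy; their loops
# can anneal into a kissing complex
rep5 <- substr(main$residues, si$q_start[1], si$q_end[1])
h1 <- fold_hairpin(substr(rep5, 1, 31))
h2 <- fold_hairpin(substr(main$residues, si$s_start[1], si$s_start[1] + 30))
kc <- kissing_pairs(h1$loop_seq, h2$loop_seq)
cat(sprintf("Boundary repeat hairpin: dG = %.1f kJ/mol, loop %s\n",
            h1$dG_kJ, h1$loop_seq))
cat(sprintf("Kissing complex between the two copies: %d bp\n", kc$n_pairs))

# the worked folding example: the printed 31-nt near-palindromic stretch
h31 <- fold_hairpin("CACGTAGCTTTATTAATTAATATGCTACGTG")
cat(sprintf("Printed 31-mer: dG = %.1f kJ/mol (%.2f kcal/mol), loop %s\n",
            h31$dG_kJ, h31$dG_kcal, h31$loop_seq))

ph <- partition_genome(hostg, anchor_5 = "GAAAAA", anchor_3 = "CCATATGC")
hh <- match_host_sequences(ph, "FIVE_EXTRA",
                           read_fasta("results/synthetic_host_db.fasta"))
write.table(hh, "results/host_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Host matches in the 5'-extra of", hostg$id, ":\n")
print(hh[, c("host_id", "identity", "length", "strand")], row.names = FALSE)
cat("Wrote results/self_identity.tsv, palindromes.tsv, host_hits.tsv\n")
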