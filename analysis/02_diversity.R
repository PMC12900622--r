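#!/usr/bin/env Rscript
# Step 2 — haplotype and nucleotide diversity.
#
# Collapses the alignment into haplotypes and reports, per population and
# per group (pooled individuals), the sample size, haplotype count Nh,
# haplotype diversity Hd, number of polymorphic sites S and nucleotide
# diversity pi.  The classic reading: high Hd with low pi indicates a
# recent expansion from a limited ancestral pool.

suppressPackageStartupMessages(library(mtphylogeo))

aln <- read_alignment("results/survey.fasta", "results/survey.popmap.tsv")
faln <- filter_sites(aln, "complete_deletion")

overall <- diversity_summary(faln)
cat(sprintf("Overall: n = %d, Nh = %d, Hd = %.3f, S = %d, pi = %.5f\n",
            overall$n, overall$Nh, overall$Hd, overall$S, overall$pi))
flags <- classify_diversity(overall$Hd, overall$pi)
cat(sprintf("High haplotype diversity (Hd > 0.5): %s; high nucleotide diversity (pi > 0.005): %s\n",
            flags$high_Hd, flags$high_pi))

sc <- classify_sites(faln)
cat(sprintf("Polymorphic sites: %d (%d parsimony-informative, %d singletons)\n",
            sc$S, sc$parsimony_informative, sc$singletons))

hs <- collapse_haplotypes(faln)
write_haplotype_table(hs, "results/haplotypes.tsv")
cat("Haplotype table -> results/haplotypes.tsv\n")
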