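#!/usr/bin/env Rscript
# Stage 0: generate the synthetic study data with known truth.
#
# Three fixture sets are produced under results/synthetic/:
#   * a reference lineage package plus a transcriptome contig set with
#     read counts (inputs of the annotation stage),
#   * codon alignments simulated with and without branch-site positive
#     selection on the 14-taxon working tree (inputs of the selection
#     stage),
#   * per-gene nucleotide alignments on the species chronogram, three of
#     them introgressed at 2.8 Ma (inputs of dating + scan).

suppressPackageStartupMessages(library(alloscan))
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

## transcriptome fixtures -------------------------------------------------
ref <- default_reference_package(seed = seed)
tx <- simulate_transcriptome(ref, seed = seed + 1)
for (fam in names(ref)) {
  write_fasta(ref[[fam]]$alignment, file.path(out, paste0(fam, ".fasta")))
  write_newick(ref[[fam]]$tree, file.path(out, paste0(fam, ".nwk")))
  utils::write.table(
    data.frame(tip = names(ref[[fam]]$labels),
               lineage = unname(ref[[fam]]$labels)),
    file.path(out, paste0(fam, ".labels.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
}
write_fasta(tx$contigs, file.path(out, "contigs.fasta"))
utils::write.table(tx$counts, file.path(out, "read_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tx$truth, file.path(out, "contig_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("transcriptome: ", length(tx$contigs), " contigs from ",
        nrow(tx$truth_rpm), " lineages, ", tx$total_reads,
        " mapped reads")

## selection fixtures ------------------------------------------------------
tree14 <- alloscan:::study_tree_14()
write_newick(tree14, file.path(out, "selection_tree.nwk"))
neutral <- simulate_codon_alignment(tree14, 500, kappa = 2, p0 = 0.7,
                                    omega0 = 0.2, seed = seed + 2)
write_fasta(neutral$alignment, file.path(out, "codon_neutral.fasta"))
scen <- alloscan:::study_scenarios_14()$cimicina_only
tr_fg <- label_foreground(tree14, scen)
selected <- simulate_codon_alignment(tr_fg, 500, kappa = 2, p0 = 0.6,
                                     p1 = 0.25, omega0 = 0.2, omega2 = 4,
                                     seed = seed + 3)
write_fasta(selected$alignment, file.path(out, "codon_selected.fasta"))
utils::write.table(selected$truth, file.path(out, "codon_selected_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("selection: neutral + cimicina-foreground alignments, 500 codons")

## gene histories with introgression ---------------------------------------
events <- data.frame(gene = 1:3, node = "angusta_semialata_split",
                     age = 2.8)
panel <- simulate_gene_histories(60, sites = 600, events = events,
                                 seed = seed + 4)
dir.create(file.path(out, "genes"), showWarnings = FALSE)
for (g in panel$genes[1:10]) {   # a browsable subset; tests regenerate all
  write_fasta(g$alignment, file.path(out, "genes", paste0(g$id, ".fasta")))
  write_newick(g$tree, file.path(out, "genes", paste0(g$id, ".nwk")))
}
utils::write.table(panel$truth, file.path(out, "gene_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("histories: 60 genes (3 introgressed at 2.8 Ma), ",
        "first 10 written as FASTA/Newick")
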