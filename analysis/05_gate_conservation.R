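#!/usr/bin/env Rscript
# Stage 5: evolutionary profiling of the extracellular gate.
#
# Generates taxon-structured ABCG-like sequence panels, screens them with
# the full-size length + PDR-motif filter, maps the four gate positions
# through the alignment, tabulates per-taxon residue occurrence, and
# computes logo information content and the gate consensus.

library(abcgate)
dir.create("results", showWarnings = FALSE)

pan <- make_sequence_panel(sequence_panel_spec(
  taxa = default_taxa(c(Brassicaceae = 598, Fabaceae = 762,
                        Solanaceae = 450)), seed = 6))
write_fasta(pan$records, "results/05_panel.fasta")

flt <- filter_full_size(pan$records)
cat(sprintf("full-size filter kept %d / %d sequences\n",
            nrow(flt$kept), nrow(pan$records)))

msa <- pad_to_msa(flt$kept)
gates <- extract_gate_residues_msa(msa, "AtABCG36")
long <- gate_residues_long(gates, flt$kept$taxon)
long <- long[long$taxon != "reference", ]
occ <- occurrence_by_taxon(long)
write.table(occ, "results/05_gate_occurrence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (posn in c(703, 704, 1374, 1375)) {
  sub <- occ[occ$position == posn, ]
  counts <- tapply(sub$count, sub$residue, sum)
  ic <- information_content(counts)
  top <- sort(tapply(sub$fraction * sub$count, sub$residue, sum),
              decreasing = TRUE)
  cat(sprintf("position %4d: %.2f bits; top residues %s\n", posn, ic,
              paste(names(head(top, 3)), collapse = "/")))
}

# consensus over the pooled panel at the four gate positions
pooled <- long
pooled$taxon <- "all"
cons <- consensus_motif(occurrence_by_taxon(pooled), t_single = 0.5,
                        t_pair = 0.5, t_member = 0.2)
cat("gate-position consensus tokens:", cons, "\n")
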