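#!/usr/bin/env Rscript

# Build the synthetic repertoires every downstream analysis consumes:
#   (a) a TCR repertoire with canonical CDR1/CDR2 clusters, VJ-organised
#       CDR3 conformations, and gene labels (the "annotated" set);
#   (b) a fully diffuse-CDR3 TCR repertoire (the "repertoire-scale" set);
#   (c) an antibody-like repertoire whose light-chain CDR3 is canonical and
#       heavy-chain CDR3 diffuse, for the cross-receptor contrast.
# Everything is written under scratch/data/ (bulk
# structure dumps stay out of the tracked results/ tables) as PDB + CSV + JSON.

suppressPackageStartupMessages(library(tcrshape))

out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Generating annotated TCR repertoire (500 records, 50 VJ pairs)...")
annotated <- generate_repertoire(generator_config(
  n_records = 500, n_vj_pairs = 50, seed = 101))
write_repertoire(annotated, file.path(out, "tcr_annotated"))

message("Generating diffuse-CDR3 TCR repertoire (300 records)...")
diffuse <- generate_repertoire(generator_config(
  n_records = 300, seed = 102, vj_coherence = NULL))
write_repertoire(diffuse, file.path(out, "tcr_diffuse"))

message("Generating antibody-like repertoire (300 records)...")
antibody <- generate_repertoire(generator_config(
  n_records = 300, seed = 103, receptor = "antibody",
  clusters_per_region = list(CDR1 = 6, CDR2 = 4, CDR3 = c(5, 0)),
  vj_coherence = NULL))
write_repertoire(antibody, file.path(out, "antibody"))

cat(sprintf("Wrote %d + %d + %d records under %s\n",
            length(annotated$records), length(diffuse$records),
            length(antibody$records), out))
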