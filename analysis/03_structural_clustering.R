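#!/usr/bin/env Rscript

# Repertoire-scale conformational clustering: do the loops fall into
# discrete canonical forms? Greedy-clusters each region's pairwise
# (upsampled) RMSD matrix at 1 A, reports the census per region for the TCR
# and the antibody-like repertoires, and embeds each CDR3 distance matrix
# with t-SNE (perplexity 10) coloured by the greedy clusters.

suppressPackageStartupMessages(library(tcrshape))

dir.create("results", showWarnings = FALSE)
tau <- 1

census_row <- function(records, chain, region) {
  loops <- collect_loops(records, chain, region)
  D <- pairwise_distance_matrix(loops)
  ca <- greedy_cluster(D, tau)
  cc <- cluster_census(ca)
  list(D = D, assignment = ca,
       row = data.frame(chain = chain, region = region,
                        n_loops = cc$n_items, n_clusters = cc$n_clusters,
                        singleton_fraction = cc$singleton_fraction))
}

message("TCR repertoire (diffuse CDR3)...")
tcr <- generate_repertoire(generator_config(
  n_records = 300, seed = 102, vj_coherence = NULL))
message("Antibody-like repertoire (canonical CDR3L, diffuse CDR3H)...")
ab <- generate_repertoire(generator_config(
  n_records = 300, seed = 103, receptor = "antibody",
  clusters_per_region = list(CDR1 = 6, CDR2 = 4, CDR3 = c(5, 0)),
  vj_coherence = NULL))

tab <- NULL
embeddings <- list()
for (set in list(list(name = "tcr", rec = tcr$records,
                      chains = c("alpha", "beta")),
                 list(name = "antibody", rec = ab$records,
                      chains = c("light", "heavy")))) {
  for (chain in set$chains) {
    for (region in c("CDR1", "CDR2", "CDR3")) {
      res <- census_row(set$rec, chain, region)
      res$row$receptor <- set$name
      tab <- rbind(tab, res$row)
      if (region == "CDR3") {
        emb <- embed_tsne(res$D, perplexity = 10, seed = 11,
                          labels = cluster_labels(res$assignment))
        emb$receptor <- set$name
        emb$chain <- chain
        embeddings[[paste(set$name, chain)]] <- emb
      }
    }
  }
}
tab <- tab[, c("receptor", "chain", "region", "n_loops", "n_clusters",
               "singleton_fraction")]
print(tab, row.names = FALSE)
write.csv(tab, "results/cluster_census.csv", row.names = FALSE)
write.csv(do.call(rbind, embeddings), "results/cdr3_tsne.csv",
          row.names = FALSE)

cat("\nReading of the census: canonical regions (planted clusters) stay in\n")
cat("the single digits; diffuse CDR3 regions fragment into hundreds of\n")
cat("clusters -- most loops are structural singletons at 1 A, while the\n")
cat("canonical antibody CDR3L collapses to its few planted forms.\n")
cat("Wrote results/cluster_census.csv and results/cdr3_tsne.csv\n")
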