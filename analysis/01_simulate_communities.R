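#!/usr/bin/env Rscript
# Step 1: generate the synthetic three-domain survey that stands in for the
# study data: one shared 46-site, 7-land-use metadata table, a neutrally
# assembled "bacteria" community, a strongly environment-filtered "fungi"
# community, and a weakly connected neutral "protists" community.  Tables
# are written to scratch/sim_data/ (regenerated deterministically; run this
# script before steps 02-05).

suppressMessages(library(subcomm))

data_dir <- "scratch/sim_data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 20240901

meta <- simulate_metadata(n_samples = 46, n_landuse = 7, seed = seed)
write_metadata(meta, file.path(data_dir, "metadata.tsv"))
cat(sprintf("metadata: %d sites, land-use replicates %s\n", nrow(meta),
            paste(table(meta$land_use), collapse = "/")))

domains <- list(
  bacteria = list(model = "neutral", n_otus = 5000, depth = 16000, m = 0.161),
  fungi    = list(model = "niche", n_otus = 3000, depth = 10000,
                  n_gradients = 2, niche_breadth = 0.4, noise_sd = 0.3),
  protists = list(model = "neutral", n_otus = 3000, depth = 10000, m = 0.03))

for (dn in names(domains)) {
  d <- domains[[dn]]
  if (d$model == "neutral") {
    tab <- simulate_neutral(n_samples = 46, n_otus = d$n_otus,
                            depth = d$depth, m = d$m, seed = seed + match(dn, names(domains)))
    tab$counts <- `rownames<-`(otu_counts(tab), meta$sample_id)
  } else {
    sim <- simulate_niche(n_otus = d$n_otus, depth = d$depth,
                          n_gradients = d$n_gradients,
                          niche_breadth = d$niche_breadth,
                          noise_sd = d$noise_sd, metadata = meta,
                          seed = seed + match(dn, names(domains)))
    tab <- sim$table
  }
  write_otu_table(tab, file.path(data_dir, paste0(dn, "_otu.tsv")))
  cat(sprintf("%s: %s model, %d OTUs x %d samples at depth %d\n",
              dn, d$model, ncol(otu_counts(tab)), nrow(otu_counts(tab)),
              sum(otu_counts(tab)[1, ])))
}

jsonlite::write_json(list(seed = seed, domains = domains),
                     file.path(data_dir, "generating_params.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("wrote", data_dir, "\n")
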