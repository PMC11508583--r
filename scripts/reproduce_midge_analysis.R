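#!/usr/bin/env Rscript

# Full-scale comparative run on real mitogenomes (requires the GenBank flat
# files fetched by scripts/fetch_accessions.R; needs network once, then runs
# offline). Prints the quantities a family-level codon-usage study reports:
# the frequent/infrequent codon partition size, per-species mean ENC, and
# the per-gene tallies of the ENC-ratio selection screen.
#
#   Rscript scripts/reproduce_midge_analysis.R --dir data/genbank --out results/midges

suppressPackageStartupMessages({
  library(optparse)
  library(mitocodon)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--dir", type = "character", default = "data/genbank"),
  make_option("--out", type = "character", default = "results/midges"))))

files <- list.files(opts$dir, pattern = "\\.gb$", full.names = TRUE)
if (length(files) < 2) stop("need >= 2 GenBank files in ", opts$dir,
                            " (run scripts/fetch_accessions.R first)")

cds <- do.call(rbind, lapply(files, function(f)
  as.data.frame(read_cds_genbank(f))))
class(cds) <- c("cds_set", "data.frame")
cds <- cds[cds$gene %in% pcg_names(), , drop = FALSE]

print(suppressWarnings(validate_cds(cds))[
  , c("species", "gene", "terminal_stop", "n_internal_stops")])

cmp <- compare_codon_usage(cds, exclude_genes = "ATP8")
print(cmp)
per_sp <- summary(cmp$fit)$per_species
print(format(per_sp[order(-per_sp$mean_enc), ], digits = 4), row.names = FALSE)
print(cmp$selection)

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
write_table(cmp$fit$genes, file.path(opts$out, "gene_metrics.tsv"))
write_table(cmp$selection$per_gene,
            file.path(opts$out, "selection_by_gene.tsv"))
write_table(cmp$selection$per_species,
            file.path(opts$out, "selection_by_species.tsv"))
m <- cbind(species = rownames(cmp$matrix), as.data.frame(unclass(cmp$matrix)))
write_table(m, file.path(opts$out, "rscu_matrix.tsv"))
message("tables written to ", opts$out)
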