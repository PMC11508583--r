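#!/usr/bin/env Rscript

# Network helper (not used by the test suite): downloads GenBank flat files
# for a list of accessions into a local directory, for use with
# read_cds_genbank() / scripts/reproduce_midge_analysis.R.
#
#   Rscript scripts/fetch_accessions.R --out data/genbank ACC1 ACC2 ...
#
# With no accessions on the command line, fetches the 29 Chironomidae
# mitogenomes analysed in the worked comparative study.

suppressPackageStartupMessages(library(optparse))

default_accessions <- c(
  "PP831866", "ON099430", "MZ150770", "ON838257", "MZ747091", "MZ261913",
  "MZ981734", "ON838256", "MZ981735", "OL753645", "ON838255", "MZ043575",
  "MZ127839", "MZ231025", "OM302504", "MZ231026", "MZ424311", "OP006251",
  "MZ041033", "MW837768", "MW846254", "MW373526", "ON838254", "MZ424312",
  "KT003702", "MW837770", "MW373525", "MW373524", "MZ475054")

pa <- parse_args(OptionParser(
  usage = "Rscript scripts/fetch_accessions.R --out DIR [accessions...]",
  option_list = list(
    make_option("--out", type = "character", default = "data/genbank"))),
  positional_arguments = TRUE)

accs <- if (length(pa$args)) pa$args else default_accessions
dir.create(pa$options$out, showWarnings = FALSE, recursive = TRUE)
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=gbwithparts&retmode=text&id=")
for (acc in accs) {
  dest <- file.path(pa$options$out, paste0(acc, ".gb"))
  if (file.exists(dest)) next
  message("fetching ", acc)
  utils::download.file(paste0(base, acc), dest, quiet = TRUE, mode = "wb")
  Sys.sleep(0.5)   # NCBI rate limit
}
message("done: ", length(accs), " records in ", pa$options$out)
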