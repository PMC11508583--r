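#' Per-gene codon-usage bias analysis
#'
#' The package's central fit: for every CDS record it counts codons and
#' computes RSCU, GC3s, Wright's observed ENC, the mutation-only expected ENC,
#' the ENC ratio and the selection flag. This is the per-gene layer of an
#' ENC-plot analysis; \code{\link{compare_codon_usage}} builds the
#' cross-species layer on top of it.
#'
#' @param cds a \code{cds_set} from \code{\link{read_cds_fasta}},
#'   \code{\link{read_cds_genbank}} or \code{\link{generate_cds}}.
#' @param code a \code{\link{genetic_code}} (default: invertebrate
#'   mitochondrial, table 5).
#' @param min_codons genes with fewer counted codons get \code{NA} ENC
#'   (default 50).
#' @param exclude_genes gene names whose ENC is forced to \code{NA}
#'   regardless of length (e.g. \code{"ATP8"}); RSCU is still computed.
#' @param threshold selection threshold on the ENC ratio (default 0.15).
#' @return An object of class \code{"codon_usage"}: a list with
#'   \item{genes}{data frame, one row per gene: \code{species}, \code{gene},
#'     \code{total_codons}, \code{gc3s}, \code{enc_obs}, \code{enc_exp},
#'     \code{enc_ratio}, \code{selected}.}
#'   \item{rscu}{long data frame: \code{species}, \code{gene}, \code{codon},
#'     \code{amino_acid}, \code{count}, \code{rscu}.}
#'   \item{counts}{list of \code{codon_counts}, one per gene.}
#'   \item{code, min_codons, threshold, call}{the fit's configuration.}
#' @examples
#' spec <- synthetic_spec(seed = 1, n_genes = 3, codons_per_gene = 200,
#'                        regime = "uniform")
#' fit <- codon_usage(generate_cds(spec)$cds)
#' summary(fit)
#' @export
codon_usage <- function(cds, code = genetic_code(5), min_codons = 50L,
                        exclude_genes = NULL, threshold = 0.15) {
  stopifnot(inherits(cds, "cds_set"), inherits(code, "genetic_code"))
  n <- nrow(cds)
  counts_list <- vector("list", n)
  gene_rows <- vector("list", n)
  rscu_rows <- vector("list", n)
  aa_of <- code$codon_to_aa[code$sense_codons]
  for (i in seq_len(n)) {
    cc <- count_codons(cds$sequence[i], code)
    counts_list[[i]] <- cc
    g3 <- gc3s(cc, code)
    e_obs <- if (cds$gene[i] %in% exclude_genes) NA_real_
             else enc(cc, code, min_codons = min_codons)
    e_exp <- if (is.na(g3)) NA_real_ else enc_exp(g3)
    sel <- selection_flag(e_obs, e_exp, threshold)
    r <- rscu(cc, code)
    gene_rows[[i]] <- data.frame(
      species = cds$species[i], gene = cds$gene[i],
      total_codons = cc$total_codons, gc3s = g3,
      enc_obs = e_obs, enc_exp = e_exp,
      enc_ratio = sel$enc_ratio, selected = sel$selected,
      stringsAsFactors = FALSE)
    rscu_rows[[i]] <- data.frame(
      species = cds$species[i], gene = cds$gene[i],
      codon = names(r), amino_acid = unname(aa_of),
      count = unname(cc$counts), rscu = unname(r),
      stringsAsFactors = FALSE)
  }
  structure(list(
    genes = do.call(rbind, gene_rows),
    rscu = do.call(rbind, rscu_rows),
    counts = stats::setNames(counts_list, paste(cds$species, cds$gene, sep = "|")),
    code = code, min_codons = min_codons, threshold = threshold,
    call = match.call()
  ), class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  g <- x$genes
  cat("Codon-usage analysis (NCBI table", x$code$table_id, ")\n")
  cat(sprintf(" %d gene(s) from %d species\n",
              nrow(g), length(unique(g$species))))
  cat(sprintf(" ENC computed for %d gene(s); %d flagged selected (ratio > %.2f)\n",
              sum(!is.na(g$enc_obs)), sum(g$selected, na.rm = TRUE),
              x$threshold))
  invisible(x)
}

#' @export
summary.codon_usage <- function(object, ...) {
  g <- object$genes
  per_species <- do.call(rbind, lapply(split(g, g$species), function(d) {
    data.frame(species = d$species[1L],
               n_genes = nrow(d),
               mean_enc = mean(d$enc_obs, na.rm = TRUE),
               mean_gc3s = mean(d$gc3s, na.rm = TRUE),
               n_selected = sum(d$selected, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(per_species) <- NULL
  structure(list(genes = g, per_species = per_species,
                 threshold = object$threshold),
            class = "summary.codon_usage")
}

#' @export
print.summary.codon_usage <- function(x, ...) {
  cat("Per-species summary (ENC averaged over analyzed genes):\n")
  print(format(x$per_species, digits = 4), row.names = FALSE)
  cat("\nPer-gene metrics:\n")
  print(format(x$genes, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.codon_usage <- function(x, ...) x$genes

#' ENC plot of a codon-usage fit
#'
#' The classic diagnostic: observed ENC against GC3s with Wright's
#' mutation-only null curve and its 85\% line. Genes below the grey line are
#' the selection candidates flagged in the fit.
#'
#' @param x a \code{\link{codon_usage}} object.
#' @param ... passed to \code{plot}.
#' @export
plot.codon_usage <- function(x, ...) {
  g <- x$genes[!is.na(x$genes$enc_obs) & !is.na(x$genes$gc3s), , drop = FALSE]
  sp <- factor(g$species)
  graphics::plot(g$gc3s, g$enc_obs, xlim = c(0, 1),
                 ylim = c(0, length(x$code$sense_codons) + 2),
                 xlab = "GC3s", ylab = "ENC",
                 col = as.integer(sp), pch = 19, ...)
  gg <- seq(0.001, 0.999, length.out = 200)
  graphics::lines(gg, enc_exp(gg), lwd = 2)
  graphics::lines(gg, (1 - x$threshold) * enc_exp(gg), lwd = 2, col = "grey50")
  invisible(x)
}
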