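#' Default amino-acid frequencies for synthetic mitochondrial CDS
#'
#' A mitochondrial-PCG-like amino-acid composition (Leu/Ile/Ser/Phe-rich),
#' used so that synthetic genes exercise the 2-, 4-, 6- and 8-fold degeneracy
#' classes in realistic proportions. Fully overridable in
#' \code{\link{synthetic_spec}}.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
mito_aa_frequencies <- function() {
  f <- c(L = 0.150, S = 0.100, I = 0.090, F = 0.085, M = 0.060, G = 0.060,
         N = 0.050, T = 0.050, A = 0.050, V = 0.050, P = 0.040, K = 0.035,
         Y = 0.035, W = 0.030, E = 0.025, D = 0.020, Q = 0.020, H = 0.020,
         R = 0.020, C = 0.010)
  f / sum(f)
}

# Typical mitochondrial PCG lengths in codons (start included, stop excluded).
default_gene_lengths <- function() {
  c(ATP6 = 226L, ATP8 = 53L, COX1 = 512L, COX2 = 229L, COX3 = 262L,
    CYTB = 378L, ND1 = 312L, ND2 = 341L, ND3 = 117L, ND4 = 446L,
    ND4L = 96L, ND5 = 572L, ND6 = 165L)
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed deterministically from a parent seed
#'
#' A fixed linear-congruential step (multiplier 48271 modulo 2^31 - 1, plus
#' an index offset), so multi-species panels are reproducible across
#' platforms from a single parent seed.
#'
#' @param parent parent seed (integer).
#' @param index child index (positive integer).
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(parent, index) {
  m <- 2147483647
  s <- ((as.double(parent) %% m) * 48271 + as.double(index) * 9973) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Specify a synthetic codon-usage regime
#'
#' Ground-truth parameters for the CDS generator. Three regimes cover the
#' mutation-vs-selection structure an ENC plot dissects:
#' \describe{
#'   \item{uniform}{codons drawn uniformly within each synonymous family —
#'     the no-bias limit (RSCU = 1, ENC near the sense-codon count).}
#'   \item{mutation_gc3}{within-family codon probabilities proportional to a
#'     third-base composition with total G+C mass \code{gc3_target} (split
#'     equally between G and C, and between A and T) — mutation pressure with
#'     no selection, placing genes on Wright's expected-ENC curve.}
#'   \item{biased}{per-family codon probabilities drawn once (from the spec
#'     seed) from a symmetric Dirichlet with concentration
#'     \code{bias_concentration}; small concentrations give strongly skewed
#'     usage and depress ENC below the null curve — the selection regime.}
#' }
#'
#' @param seed integer seed; fixes both the regime's probability draws and
#'   the default codon sampling.
#' @param table_id genetic-code table (default 5).
#' @param n_genes number of genes (default 13, named after the mitochondrial
#'   PCGs).
#' @param codons_per_gene codon count per gene (start codon included,
#'   terminal stop appended on top): a scalar, a vector of length
#'   \code{n_genes}, or \code{NULL} for realistic per-PCG lengths.
#' @param regime \code{"uniform"}, \code{"mutation_gc3"} or \code{"biased"}.
#' @param gc3_target target third-position G+C proportion
#'   (\code{mutation_gc3} only).
#' @param bias_concentration symmetric-Dirichlet concentration
#'   (\code{biased} only; smaller = stronger skew).
#' @param gene_probs \code{"shared"} (default) draws the within-family codon
#'   distributions once per spec, shared by all genes — the realistic case,
#'   since mutational and selective pressure on mitochondrial codon usage
#'   acts genome-wide; \code{"independent"} redraws them per gene
#'   (\code{biased} regime only; the deterministic regimes are identical
#'   across genes either way).
#' @param aa_frequencies amino-acid sampling frequencies (normalized
#'   internally; must be positive over amino acids of the chosen code).
#' @return A list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(seed, table_id = 5L, n_genes = 13L,
                           codons_per_gene = NULL,
                           regime = c("uniform", "mutation_gc3", "biased"),
                           gc3_target = 0.5, bias_concentration = 1,
                           gene_probs = c("shared", "independent"),
                           aa_frequencies = mito_aa_frequencies()) {
  regime <- match.arg(regime)
  gene_probs <- match.arg(gene_probs)
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1L)
  genes <- if (n_genes <= 13L) pcg_names()[seq_len(n_genes)]
           else c(pcg_names(), sprintf("G%02d", 14:n_genes))
  if (is.null(codons_per_gene)) {
    codons_per_gene <- unname(default_gene_lengths()[genes])
    codons_per_gene[is.na(codons_per_gene)] <- 300L
  }
  codons_per_gene <- as.integer(rep_len(codons_per_gene, n_genes))
  stopifnot(all(codons_per_gene >= 2L))
  if (gc3_target < 0 || gc3_target > 1) stop("'gc3_target' must be in [0, 1]")
  if (bias_concentration <= 0) stop("'bias_concentration' must be positive")
  if (any(aa_frequencies < 0) || sum(aa_frequencies) <= 0) {
    stop("'aa_frequencies' must be non-negative with positive sum")
  }
  aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  structure(list(seed = as.integer(seed), table_id = as.integer(table_id),
                 n_genes = n_genes, genes = genes,
                 codons_per_gene = codons_per_gene, regime = regime,
                 gc3_target = gc3_target,
                 bias_concentration = bias_concentration,
                 gene_probs = gene_probs,
                 aa_frequencies = aa_frequencies),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic CDS spec: %d gene(s), regime '%s', seed %d, table %d\n",
              x$n_genes, x$regime, x$seed, x$table_id))
  invisible(x)
}

# Ground-truth per-gene, per-family codon probabilities for a spec. The draws
# (biased regime) depend only on spec$seed, so every generate_cds() call and
# every panel member built from the same spec shares one true distribution.
synthetic_truth <- function(spec, code = genetic_code(spec$table_id)) {
  fam_probs_one <- function() {
    lapply(code$families, function(fam) {
      k <- length(fam)
      p <- switch(spec$regime,
        uniform = rep(1 / k, k),
        mutation_gc3 = {
          g <- spec$gc3_target
          w <- c(A = (1 - g) / 2, T = (1 - g) / 2, G = g / 2, C = g / 2)
          wk <- w[substr(fam, 3L, 3L)]
          if (sum(wk) == 0) rep(1 / k, k) else wk / sum(wk)
        },
        biased = {
          gam <- stats::rgamma(k, shape = spec$bias_concentration)
          while (sum(gam) == 0) gam <- stats::rgamma(k, shape = spec$bias_concentration)
          gam / sum(gam)
        })
      stats::setNames(as.numeric(p), fam)
    })
  }
  shared <- !identical(spec$gene_probs, "independent")
  genes <- with_seed(spec$seed, {
    shared_probs <- if (shared) fam_probs_one()
    lapply(seq_len(spec$n_genes), function(i) {
      list(gene = spec$genes[i], n_codons = spec$codons_per_gene[i],
           probs = if (shared) shared_probs else fam_probs_one())
    })
  })
  names(genes) <- spec$genes
  structure(list(spec = spec, genes = genes, regime = spec$regime),
            class = "synthetic_truth")
}

#' Generate synthetic CDS with known codon-usage structure
#'
#' Draws each gene's amino-acid sequence from the spec's amino-acid
#' frequencies and each codon from the gene's true within-family
#' distribution. Genes start with a codon drawn from the Met family (ATG/ATA
#' under the invertebrate mitochondrial code) and end with an appended TAA;
#' stop codons are never sampled internally, so generated fixtures are clean
#' by construction.
#'
#' Reproducibility contract: the true distributions depend only on
#' \code{spec$seed}; the codon sampling depends on \code{sample_seed}
#' (default \code{spec$seed}). Two calls with the same spec and sample seed
#' produce byte-identical sequences; panel members share the spec but get
#' distinct sample seeds.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param species species label for the generated records.
#' @param sample_seed seed for the codon sampling.
#' @param truth optionally a precomputed \code{synthetic_truth} to reuse.
#' @return A list with \code{cds} (a \code{cds_set}) and \code{truth} (the
#'   \code{synthetic_truth}, augmented with each gene's realized GC3s).
#' @export
generate_cds <- function(spec, species = "synthetic",
                         sample_seed = spec$seed, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code(spec$table_id)
  if (is.null(truth)) truth <- synthetic_truth(spec, code)
  aaf <- spec$aa_frequencies[names(spec$aa_frequencies) %in% names(code$families)]
  aaf <- aaf / sum(aaf)
  met <- if ("M" %in% names(code$families)) "M" else names(code$families)[1L]
  seqs <- with_seed(sample_seed, {
    vapply(seq_len(spec$n_genes), function(i) {
      tg <- truth$genes[[i]]
      n <- tg$n_codons
      aa_seq <- c(met, sample(names(aaf), n - 1L, replace = TRUE, prob = aaf))
      codons <- character(n)
      for (aa in unique(aa_seq)) {
        idx <- which(aa_seq == aa)
        p <- tg$probs[[aa]]
        codons[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
      }
      paste0(paste(codons, collapse = ""), "TAA")
    }, character(1))
  })
  cds <- new_cds_set(species, spec$genes, seqs,
                     sprintf("synthetic:%s:%d", spec$regime, sample_seed))
  for (i in seq_len(spec$n_genes)) {
    truth$genes[[i]]$realized_gc3s <- gc3s(count_codons(seqs[i], code), code)
  }
  list(cds = cds, truth = truth)
}

#' Generate a multi-species panel from a shared codon-usage distribution
#'
#' Emulates the comparative design of a family-level codon-usage study: most
#' species share one true codon-usage distribution (only codon-sampling noise
#' differs between them, via deterministically derived child seeds), with an
#' optional outlier species drawn from its own spec — e.g. a weak-bias
#' (uniform) outlier that should show the highest mean ENC and cluster alone.
#'
#' @param n_species total species count (>= 2).
#' @param shared_spec \code{\link{synthetic_spec}} shared by the first
#'   \code{n_species - 1} species (all \code{n_species} when no outlier).
#' @param outlier_spec optional spec for the last species.
#' @return A list with \code{cds} (combined \code{cds_set}),
#'   \code{truth_shared} and \code{truth_outlier} (\code{NULL} without an
#'   outlier), and \code{outlier} (the outlier's species label or
#'   \code{NULL}).
#' @export
make_species_panel <- function(n_species, shared_spec, outlier_spec = NULL) {
  stopifnot(n_species >= 2L, inherits(shared_spec, "synthetic_spec"))
  labels <- sprintf("species%02d", seq_len(n_species))
  n_shared <- if (is.null(outlier_spec)) n_species else n_species - 1L
  truth_shared <- synthetic_truth(shared_spec)
  parts <- lapply(seq_len(n_shared), function(i) {
    generate_cds(shared_spec, species = labels[i],
                 sample_seed = derive_seed(shared_spec$seed, i),
                 truth = truth_shared)$cds
  })
  truth_outlier <- NULL
  outlier <- NULL
  if (!is.null(outlier_spec)) {
    stopifnot(inherits(outlier_spec, "synthetic_spec"))
    outlier <- labels[n_species]
    g <- generate_cds(outlier_spec, species = outlier,
                      sample_seed = derive_seed(outlier_spec$seed, n_species))
    truth_outlier <- g$truth
    parts[[n_species]] <- g$cds
  }
  cds <- do.call(rbind, lapply(parts, as.data.frame))
  class(cds) <- c("cds_set", "data.frame")
  rownames(cds) <- NULL
  list(cds = cds, truth_shared = truth_shared,
       truth_outlier = truth_outlier, outlier = outlier)
}

#' Write a synthetic truth file
#'
#' Serializes the ground-truth codon probabilities as plain-text
#' \code{key=value} lines (\code{gene.aminoacid.codon=prob}, plus per-gene
#' regime and realized GC3s when present), so generated fixtures carry their
#' own answers.
#'
#' @param truth a \code{synthetic_truth}.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("regime=", truth$regime),
               paste0("seed=", truth$spec$seed),
               paste0("table_id=", truth$spec$table_id)), con)
  for (tg in truth$genes) {
    if (!is.null(tg$realized_gc3s)) {
      writeLines(sprintf("%s.realized_gc3s=%.6f", tg$gene, tg$realized_gc3s), con)
    }
    for (aa in names(tg$probs)) {
      p <- tg$probs[[aa]]
      writeLines(sprintf("%s.%s.%s=%.8f", tg$gene, aa, names(p), p), con)
    }
  }
  invisible(path)
}
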