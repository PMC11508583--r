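#' Species-by-codon RSCU matrix
#'
#' Builds the species x sense-codon RSCU table underlying the comparative
#' heat maps. In \code{"concatenated"} mode (default) all of a species' CDS
#' codon counts are pooled and RSCU computed once per species — the natural
#' reading of "RSCU of the mitochondrial genome". In \code{"gene_averaged"}
#' mode per-gene RSCU vectors are averaged, ignoring missing values.
#'
#' @param cds a multi-species \code{cds_set}.
#' @param code a \code{\link{genetic_code}}.
#' @param mode \code{"concatenated"} or \code{"gene_averaged"}.
#' @return A numeric matrix (species x sense codons) of class
#'   \code{"rscu_matrix"}, with attributes \code{mode}, \code{amino_acid}
#'   (codon labels) and \code{table_id}.
#' @export
rscu_matrix <- function(cds, code = genetic_code(5),
                        mode = c("concatenated", "gene_averaged")) {
  stopifnot(inherits(cds, "cds_set"))
  mode <- match.arg(mode)
  species <- unique(cds$species)
  rows <- lapply(species, function(sp) {
    d <- cds[cds$species == sp, , drop = FALSE]
    if (mode == "concatenated") {
      cc <- count_codons(paste(d$sequence, collapse = ""), code)
      if (cc$total_codons == 0L) return(NULL)
      rscu(cc, code)
    } else {
      per_gene <- vapply(d$sequence,
                         function(s) rscu(count_codons(s, code), code),
                         numeric(length(code$sense_codons)))
      if (all(is.na(per_gene))) return(NULL)
      rowMeans(per_gene, na.rm = TRUE)
    }
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) {
    warning("species with no countable codons excluded: ",
            paste(species[empty], collapse = ", "))
  }
  m <- do.call(rbind, rows[!empty])
  rownames(m) <- species[!empty]
  structure(m, mode = mode,
            amino_acid = unname(code$codon_to_aa[colnames(m)]),
            table_id = code$table_id,
            class = c("rscu_matrix", class(m)))
}

#' Partition codons into frequently and infrequently used sets
#'
#' A codon is "frequently used" when its mean RSCU across species (missing
#' values ignored) strictly exceeds 1; the rest are "infrequently used". This
#' is the split behind the two comparative heat maps.
#'
#' @param m an \code{\link{rscu_matrix}}.
#' @return A list of class \code{"codon_partition"} with \code{frequent},
#'   \code{infrequent} (codon name vectors) and \code{mean_rscu}.
#' @export
partition_codons <- function(m) {
  stopifnot(inherits(m, "rscu_matrix"))
  mean_rscu <- colMeans(unclass(m), na.rm = TRUE)
  structure(list(frequent = names(mean_rscu)[!is.na(mean_rscu) & mean_rscu > 1],
                 infrequent = names(mean_rscu)[is.na(mean_rscu) | mean_rscu <= 1],
                 mean_rscu = mean_rscu),
            class = "codon_partition")
}

#' @export
print.codon_partition <- function(x, ...) {
  cat(sprintf("Codon partition: %d frequently used (mean RSCU > 1), %d infrequent\n",
              length(x$frequent), length(x$infrequent)))
  invisible(x)
}

#' Hierarchical clustering of species by RSCU
#'
#' Clusters species on their RSCU profiles the way heat-map tools do
#' (defaults: Euclidean distance, complete linkage), optionally restricted to
#' a codon subset such as the frequent set. Missing entries are dropped
#' pairwise inside the distance computation, never imputed as 0 — 0 is a real
#' RSCU value (an avoided codon in an observed family).
#'
#' @param m an \code{\link{rscu_matrix}} with at least two species.
#' @param subset optional codon names to restrict to.
#' @param metric distance measure passed to \code{\link[stats]{dist}}.
#' @param linkage agglomeration method passed to
#'   \code{\link[stats]{hclust}}.
#' @return A list of class \code{"species_clust"} wrapping the
#'   \code{hclust} tree, with \code{metric}, \code{linkage},
#'   \code{leaf_order} (species names in dendrogram order) and
#'   \code{merge_heights}.
#' @export
cluster_species <- function(m, subset = NULL, metric = "euclidean",
                            linkage = "complete") {
  stopifnot(inherits(m, "rscu_matrix"))
  v <- unclass(m)
  if (!is.null(subset)) v <- v[, intersect(colnames(v), subset), drop = FALSE]
  if (nrow(v) < 2L) stop("clustering needs at least two species")
  h <- stats::hclust(stats::dist(v, method = metric), method = linkage)
  structure(list(hclust = h, metric = metric, linkage = linkage,
                 leaf_order = h$labels[h$order],
                 merge_heights = h$height),
            class = "species_clust")
}

#' @export
print.species_clust <- function(x, ...) {
  cat(sprintf("Species clustering (%s distance, %s linkage)\n",
              x$metric, x$linkage))
  cat(" leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.species_clust <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "", ...)
  invisible(x)
}

#' Paired t-test of RSCU values between two species
#'
#' Compares two species' RSCU profiles by a paired t-test over codons (two
#' RSCU values per codon form a pair), preceded — as is conventional in this
#' literature — by a Shapiro-Wilk normality check on the paired differences
#' and an F-ratio comparison of the two species' RSCU variances. Both checks
#' are reported, never silently acted on: the t statistic is computed
#' regardless, with the normality p-value alongside. Codons missing in either
#' species are dropped pairwise.
#'
#' Degenerate inputs are reported honestly: identical profiles give t = 0,
#' p = 1; a constant nonzero difference has zero variance and no finite t.
#'
#' @param m an \code{\link{rscu_matrix}}.
#' @param species_a,species_b row names of the two species.
#' @param subset optional codon subset (e.g. the frequent set).
#' @param subset_name label stored in the result.
#' @return A list of class \code{"paired_rscu_test"}: \code{species_a},
#'   \code{species_b}, \code{subset_name}, \code{n} (pairs used),
#'   \code{normality_p}, \code{variance_test_p}, \code{t_statistic},
#'   \code{p_value}, \code{degenerate}, \code{reason}.
#' @export
paired_rscu_test <- function(m, species_a, species_b, subset = NULL,
                             subset_name = if (is.null(subset)) "all" else "subset") {
  stopifnot(inherits(m, "rscu_matrix"))
  v <- unclass(m)
  stopifnot(species_a %in% rownames(v), species_b %in% rownames(v))
  if (!is.null(subset)) v <- v[, intersect(colnames(v), subset), drop = FALSE]
  a <- v[species_a, ]; b <- v[species_b, ]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  res <- list(species_a = species_a, species_b = species_b,
              subset_name = subset_name, n = sum(ok),
              normality_p = NA_real_, variance_test_p = NA_real_,
              t_statistic = NA_real_, p_value = NA_real_,
              degenerate = FALSE, reason = NA_character_)
  if (res$n < 3L) {
    res$degenerate <- TRUE
    res$reason <- "fewer than 3 shared non-missing codons"
    return(structure(res, class = "paired_rscu_test"))
  }
  d <- a - b
  # sd relative to scale, so a constant difference is degenerate even when
  # floating-point noise leaves sd(d) a few ulp above zero
  d_degenerate <- stats::sd(d) <= 1e-10 * max(abs(d), 1)
  if (res$n >= 3L && res$n <= 5000L && !d_degenerate) {
    res$normality_p <- stats::shapiro.test(d)$p.value
  }
  if (stats::sd(a) > 0 && stats::sd(b) > 0) {
    res$variance_test_p <- stats::var.test(a, b)$p.value
  }
  if (d_degenerate) {
    if (all(abs(d) <= 1e-12)) {
      res$t_statistic <- 0; res$p_value <- 1
    } else {
      res$degenerate <- TRUE
      res$reason <- "constant nonzero difference: zero variance, no finite t"
    }
    return(structure(res, class = "paired_rscu_test"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  res$t_statistic <- unname(tt$statistic)
  res$p_value <- tt$p.value
  structure(res, class = "paired_rscu_test")
}

#' @export
print.paired_rscu_test <- function(x, ...) {
  cat(sprintf("Paired RSCU t-test: %s vs %s (%s codons, n = %d)\n",
              x$species_a, x$species_b, x$subset_name, x$n))
  if (x$degenerate) {
    cat(" degenerate:", x$reason, "\n")
  } else {
    cat(sprintf(" t = %.4f, p = %.4g (normality p = %.3g, variance F-test p = %.3g)\n",
                x$t_statistic, x$p_value, x$normality_p, x$variance_test_p))
  }
  invisible(x)
}

#' Tally the ENC selection screen across genes and species
#'
#' From a multi-species \code{\link{codon_usage}} fit, counts how many
#' species flag each gene as selected (ENC ratio above threshold) and how
#' many genes are flagged per species, alongside mean ENC by gene and by
#' species (unweighted means over the analyzed genes, missing ENC excluded).
#'
#' @param fit a \code{\link{codon_usage}} object.
#' @return A list of class \code{"selection_summary"} with data frames
#'   \code{per_gene} (\code{gene}, \code{n_selected}, \code{mean_enc}) and
#'   \code{per_species} (\code{species}, \code{n_selected},
#'   \code{mean_enc}).
#' @export
selection_summary <- function(fit) {
  stopifnot(inherits(fit, "codon_usage"))
  g <- fit$genes
  per_gene <- do.call(rbind, lapply(split(g, g$gene), function(d) {
    data.frame(gene = d$gene[1L],
               n_selected = sum(d$selected, na.rm = TRUE),
               mean_enc = mean(d$enc_obs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  per_species <- do.call(rbind, lapply(split(g, g$species), function(d) {
    data.frame(species = d$species[1L],
               n_selected = sum(d$selected, na.rm = TRUE),
               mean_enc = mean(d$enc_obs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- rownames(per_species) <- NULL
  structure(list(per_gene = per_gene, per_species = per_species),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("Selection screen by gene:\n")
  print(format(x$per_gene, digits = 4), row.names = FALSE)
  cat("By species:\n")
  print(format(x$per_species, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Cross-species codon-usage comparison
#'
#' The full comparative layer in one call: per-gene metrics for every
#' species (\code{\link{codon_usage}}), the species x codon RSCU matrix, the
#' frequent/infrequent codon partition, hierarchical clustering of species on
#' each partition subset, all pairwise paired RSCU t-tests on each subset,
#' and the selection-screen tallies.
#'
#' @inheritParams codon_usage
#' @param mode RSCU aggregation per species, see \code{\link{rscu_matrix}}.
#' @param metric,linkage clustering configuration, see
#'   \code{\link{cluster_species}}.
#' @param test_subsets which codon subsets to run the pairwise tests on:
#'   \code{"partition"} (frequent and infrequent separately, the default) or
#'   \code{"all"} (all sense codons).
#' @return An object of class \code{"codon_usage_panel"} with elements
#'   \code{fit}, \code{matrix}, \code{partition}, \code{clustering} (one
#'   \code{species_clust} per subset), \code{tests} (data frame of all pair
#'   results), \code{selection} and the configuration.
#' @export
compare_codon_usage <- function(cds, code = genetic_code(5),
                                mode = c("concatenated", "gene_averaged"),
                                min_codons = 50L, exclude_genes = NULL,
                                threshold = 0.15,
                                metric = "euclidean", linkage = "complete",
                                test_subsets = c("partition", "all")) {
  mode <- match.arg(mode)
  test_subsets <- match.arg(test_subsets)
  fit <- codon_usage(cds, code, min_codons = min_codons,
                     exclude_genes = exclude_genes, threshold = threshold)
  m <- rscu_matrix(cds, code, mode = mode)
  part <- partition_codons(m)
  subsets <- if (test_subsets == "partition") {
    list(frequent = part$frequent, infrequent = part$infrequent)
  } else {
    list(all = colnames(m))
  }
  single <- nrow(m) < 2L
  if (single) {
    warning("only one species: clustering and pairwise tests skipped")
  }
  clustering <- if (single) list() else {
    lapply(subsets, function(s) {
      if (length(s) < 1L) NULL else cluster_species(m, s, metric, linkage)
    })
  }
  tests <- if (single) NULL else {
    sp <- rownames(m)
    pairs <- utils::combn(sp, 2L)
    do.call(rbind, unlist(lapply(names(subsets), function(nm) {
      lapply(seq_len(ncol(pairs)), function(j) {
        r <- paired_rscu_test(m, pairs[1L, j], pairs[2L, j],
                              subset = subsets[[nm]], subset_name = nm)
        data.frame(species_a = r$species_a, species_b = r$species_b,
                   subset = nm, n = r$n, normality_p = r$normality_p,
                   variance_test_p = r$variance_test_p,
                   t_statistic = r$t_statistic, p_value = r$p_value,
                   degenerate = r$degenerate, stringsAsFactors = FALSE)
      })
    }), recursive = FALSE))
  }
  structure(list(fit = fit, matrix = m, partition = part,
                 clustering = clustering, tests = tests,
                 selection = selection_summary(fit),
                 mode = mode, metric = metric, linkage = linkage),
            class = "codon_usage_panel")
}

#' @export
print.codon_usage_panel <- function(x, ...) {
  cat("Cross-species codon-usage comparison (", nrow(x$matrix),
      " species, ", x$mode, " RSCU)\n", sep = "")
  print(x$partition)
  if (!is.null(x$tests)) {
    sig <- sum(x$tests$p_value < 0.05, na.rm = TRUE)
    cat(sprintf(" pairwise tests: %d run, %d with p < 0.05\n",
                nrow(x$tests), sig))
  }
  invisible(x)
}

#' @export
summary.codon_usage_panel <- function(object, ...) {
  list(partition = object$partition,
       selection = object$selection,
       per_species = summary(object$fit)$per_species,
       leaf_order = lapply(object$clustering,
                           function(cl) if (is.null(cl)) NULL else cl$leaf_order))
}

#' @export
plot.codon_usage_panel <- function(x, subset = "frequent", ...) {
  cl <- x$clustering[[subset]]
  if (is.null(cl)) stop("no clustering available for subset '", subset, "'")
  plot(cl, main = paste("Species clustering on", subset, "codons"), ...)
  invisible(x)
}
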