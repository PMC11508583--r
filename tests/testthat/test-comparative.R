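code5 <- genetic_code(5)

all_sense_once <- function() paste0(paste(code5$sense_codons, collapse = ""), "TAA")

test_that("single-species, single-gene matrix row equals the gene's RSCU", {
  cds <- make_cds("spA", "COX1", "ATGAAATTTTTCTAA")
  m <- rscu_matrix(cds, code5)
  r <- rscu(count_codons(cds$sequence, code5), code5)
  expect_identical(rownames(m), "spA")
  expect_equal(unclass(m)["spA", ], r)
})

test_that("identical species give identical matrix rows", {
  g <- random_sense_gene(200, code5)
  cds <- bind_cds(make_cds("spA", "ND1", g), make_cds("spB", "ND1", g))
  m <- rscu_matrix(cds, code5)
  expect_equal(unclass(m)["spA", ], unclass(m)["spB", ])
})

test_that("gene-averaged and concatenated modes differ as designed", {
  cds <- bind_cds(make_cds("sp", "g1", "TTTTTTTTTTTC"),   # Phe-heavy
                  make_cds("sp", "g2", "TTCTTC"))
  conc <- unclass(rscu_matrix(cds, code5, mode = "concatenated"))
  avg <- unclass(rscu_matrix(cds, code5, mode = "gene_averaged"))
  # concatenated pools counts: TTT=3, TTC=3 -> both 1
  expect_equal(conc["sp", "TTT"], 1)
  # gene-averaged: mean(RSCU per gene) = mean(3/2, 0) = 0.75
  expect_equal(avg["sp", "TTT"], 0.75)
})

test_that("uniform usage across species leaves the frequent set empty", {
  cds <- bind_cds(make_cds("spA", "g", all_sense_once()),
                  make_cds("spB", "g", all_sense_once()))
  part <- partition_codons(rscu_matrix(cds, code5))
  expect_length(part$frequent, 0)
  expect_length(part$infrequent, 62)
})

test_that("partition is a disjoint cover of the sense codons", {
  panel <- make_species_panel(4, synthetic_spec(seed = 77, n_genes = 5,
                                                codons_per_gene = 250,
                                                regime = "biased",
                                                bias_concentration = 0.4))
  part <- partition_codons(rscu_matrix(panel$cds, code5))
  expect_length(c(part$frequent, part$infrequent), 62)
  expect_length(intersect(part$frequent, part$infrequent), 0)
})

test_that("clustering merges identical species first and is order-invariant", {
  g1 <- random_sense_gene(200, code5)
  g2 <- random_sense_gene(200, code5)
  cds <- bind_cds(make_cds("A", "g", g1), make_cds("B", "g", g2),
                  make_cds("C", "g", g1))   # C identical to A
  m <- rscu_matrix(cds, code5)
  cl <- cluster_species(m)
  expect_equal(cl$merge_heights[1], 0)      # zero-distance pair merges first
  first <- cl$hclust$labels[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("A", "C"))
  # two species: a single merge
  m2 <- rscu_matrix(bind_cds(make_cds("A", "g", g1), make_cds("B", "g", g2)),
                    code5)
  expect_length(cluster_species(m2)$merge_heights, 1)
  # reordering input species leaves the tree isomorphic (same cophenetic)
  mm <- unclass(m)
  perm <- structure(mm[c(3, 1, 2), ], class = class(m),
                    amino_acid = attr(m, "amino_acid"))
  d1 <- as.matrix(stats::cophenetic(cluster_species(m)$hclust))
  d2 <- as.matrix(stats::cophenetic(cluster_species(perm)$hclust))
  expect_equal(d1[rownames(d2), colnames(d2)], d2)
  expect_error(cluster_species(rscu_matrix(make_cds("A", "g", g1), code5)),
               "two species")
})

test_that("duplicating a species preserves other complete-linkage heights", {
  set.seed(31)
  genes <- replicate(4, random_sense_gene(150, code5))
  cds <- bind_cds(make_cds("A", "g", genes[1]), make_cds("B", "g", genes[2]),
                  make_cds("C", "g", genes[3]), make_cds("D", "g", genes[4]))
  base_h <- cluster_species(rscu_matrix(cds, code5))$merge_heights
  dup <- bind_cds(cds, make_cds("A2", "g", genes[1]))
  dup_h <- cluster_species(rscu_matrix(dup, code5))$merge_heights
  expect_equal(sort(dup_h), sort(c(0, base_h)))
})

test_that("paired test handles identity, degeneracy and antisymmetry", {
  panel <- make_species_panel(2, synthetic_spec(seed = 88, n_genes = 6,
                                                codons_per_gene = 300,
                                                regime = "biased",
                                                bias_concentration = 0.4))
  m <- rscu_matrix(panel$cds, code5)
  sp <- rownames(m)
  self <- paired_rscu_test(m, sp[1], sp[1])
  expect_equal(self$t_statistic, 0)
  expect_equal(self$p_value, 1)
  ab <- paired_rscu_test(m, sp[1], sp[2])
  ba <- paired_rscu_test(m, sp[2], sp[1])
  expect_equal(ba$t_statistic, -ab$t_statistic)
  expect_equal(ba$p_value, ab$p_value)
  expect_identical(ab$n, sum(!is.na(unclass(m)[1, ]) & !is.na(unclass(m)[2, ])))
  # constant nonzero difference: zero variance, reported degenerate
  fake <- unclass(m)[1:2, ]
  fake[2, ] <- fake[1, ] + 0.5
  rownames(fake) <- c("X", "Y")
  fake <- structure(fake, class = class(m))
  deg <- paired_rscu_test(fake, "X", "Y")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t_statistic))
})

test_that("paired t matches the textbook formula on a small fixture", {
  vals <- rbind(X = c(1.6, 0.4, 1.2, 0.8, 2.1, 0.3),
                Y = c(1.3, 0.7, 1.1, 0.8, 1.6, 0.5))
  colnames(vals) <- c("TTT", "TTC", "AAA", "AAG", "TTA", "CTA")
  fixture <- structure(vals, class = c("rscu_matrix", "matrix", "array"))
  res <- paired_rscu_test(fixture, "X", "Y")
  d <- vals["X", ] - vals["Y", ]
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_identical(res$n, 6L)
})

test_that("type I error of the paired test never exceeds the nominal band", {
  # same-distribution species pairs; frequent-codon subset. The within-family
  # correlation structure makes the codon-wise paired t conservative, so its
  # rejection rate must stay at or below nominal + 2 binomial SD.
  spec <- synthetic_spec(seed = 424242, n_genes = 12, codons_per_gene = 300,
                         regime = "biased", bias_concentration = 0.25)
  truth <- mitocodon:::synthetic_truth(spec)
  nrep <- 200
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    a <- generate_cds(spec, species = "A",
                      sample_seed = derive_seed(spec$seed, 2 * r - 1),
                      truth = truth)$cds
    b <- generate_cds(spec, species = "B",
                      sample_seed = derive_seed(spec$seed, 2 * r),
                      truth = truth)$cds
    m <- rscu_matrix(bind_cds(a, b), code5)
    part <- partition_codons(m)
    tt <- paired_rscu_test(m, "A", "B", subset = part$frequent)
    rej[r] <- !is.na(tt$p_value) && tt$p_value < 0.05
  }
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / nrep))
})

test_that("the paired test is calibrated on independent one-per-family codons", {
  # with one codon per synonymous family the paired differences are
  # independent and the test should reject at the nominal rate
  fixed <- vapply(code5$families, `[[`, character(1), 1L)
  spec <- synthetic_spec(seed = 424242, n_genes = 12, codons_per_gene = 300,
                         regime = "mutation_gc3", gc3_target = 0.35)
  truth <- mitocodon:::synthetic_truth(spec)
  nrep <- 400
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    a <- generate_cds(spec, species = "A",
                      sample_seed = derive_seed(spec$seed, 2 * r - 1),
                      truth = truth)$cds
    b <- generate_cds(spec, species = "B",
                      sample_seed = derive_seed(spec$seed, 2 * r),
                      truth = truth)$cds
    m <- rscu_matrix(bind_cds(a, b), code5)
    rej[r] <- paired_rscu_test(m, "A", "B", subset = fixed)$p_value < 0.05
  }
  expect_gt(mean(rej), 0.05 - 2 * sqrt(0.05 * 0.95 / nrep))
  expect_lt(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / nrep))
})

test_that("selection summary tallies flags by gene and species", {
  # uniform species sit above the null curve: nothing selected
  uni <- make_species_panel(3, synthetic_spec(seed = 99, n_genes = 4,
                                              codons_per_gene = 300,
                                              regime = "uniform"))
  fit <- codon_usage(uni$cds, code5)
  ss <- selection_summary(fit)
  expect_true(all(ss$per_gene$n_selected == 0))
  expect_true(all(ss$per_species$n_selected == 0))
  # strongly biased species: every count bounded by the panel dimensions
  bia <- make_species_panel(3, synthetic_spec(seed = 100, n_genes = 4,
                                              codons_per_gene = 300,
                                              regime = "biased",
                                              bias_concentration = 0.1))
  ss2 <- selection_summary(codon_usage(bia$cds, code5))
  expect_true(all(ss2$per_gene$n_selected <= 3))
  expect_true(all(ss2$per_species$n_selected <= 4))
  expect_gt(sum(ss2$per_gene$n_selected), 0)
})

test_that("compare_codon_usage assembles a coherent panel", {
  panel <- make_species_panel(4, synthetic_spec(seed = 55, n_genes = 5,
                                                codons_per_gene = 250,
                                                regime = "biased",
                                                bias_concentration = 0.3))
  cmp <- compare_codon_usage(panel$cds, code5)
  expect_s3_class(cmp, "codon_usage_panel")
  expect_identical(nrow(cmp$matrix), 4L)
  expect_length(c(cmp$partition$frequent, cmp$partition$infrequent), 62)
  # 4 species -> 6 pairs, two subsets
  expect_identical(nrow(cmp$tests), 12L)
  expect_setequal(names(cmp$clustering), c("frequent", "infrequent"))
  # single species: comparative steps skipped with a warning
  single <- panel$cds[panel$cds$species == "species01", ]
  class(single) <- c("cds_set", "data.frame")
  expect_warning(one <- compare_codon_usage(single, code5), "one species")
  expect_null(one$tests)
})
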