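code5 <- genetic_code(5)
code1 <- genetic_code(1)

test_that("codon counting excludes stops and ambiguous triplets", {
  cc <- count_codons("ATGAAATAA", code5)
  expect_identical(cc$counts[["ATG"]], 1L)
  expect_identical(cc$counts[["AAA"]], 1L)
  expect_identical(cc$total_codons, 2L)
  expect_identical(cc$excluded[["stop_codons"]], 1L)

  cc <- count_codons("TTTTTCTTT", code5)
  expect_identical(unname(cc$counts[c("TTT", "TTC")]), c(2L, 1L))

  cc <- count_codons("ATGNNNAAA", code5)
  expect_identical(cc$total_codons, 2L)
  expect_identical(cc$excluded[["ambiguous"]], 1L)

  # trailing 1-2 nt beyond the last full codon are simply not counted
  expect_identical(count_codons("ATGAAAT", code5)$total_codons, 2L)
})

test_that("RSCU matches hand-computed values and conventions", {
  cc <- count_codons("TTTTTCTTT", code5)
  r <- rscu(cc, code5)
  expect_equal(r[["TTT"]], 4 / 3)
  expect_equal(r[["TTC"]], 2 / 3)
  # equal usage of both Phe codons: both exactly 1
  r2 <- rscu(count_codons("TTTTTC", code5), code5)
  expect_equal(unname(r2[c("TTT", "TTC")]), c(1, 1))
  # no Cys observed: whole family missing (NA), not zero
  expect_true(all(is.na(r[c("TGT", "TGC")])))
  # observed family, unobserved member: 0, distinct from NA
  expect_identical(r[["TTA"]], NA_real_)   # Leu family absent here
  r3 <- rscu(count_codons("TTATTA", code5), code5)
  expect_equal(r3[["TTA"]], 6)             # sole used codon of a 6-fold family
  expect_equal(r3[["CTC"]], 0)
})

test_that("RSCU family sums equal degeneracy for observed families", {
  set.seed(101)
  for (i in 1:20) {
    g <- random_sense_gene(sample(20:200, 1), code5)
    r <- rscu(count_codons(g, code5), code5)
    for (aa in names(code5$families)) {
      fam <- code5$families[[aa]]
      if (!all(is.na(r[fam]))) {
        expect_equal(sum(r[fam]), code5$degeneracy[[aa]],
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("1/k-weighted mean RSCU over fully observed genes is 1", {
  set.seed(55)
  g <- random_sense_gene(4000, code5)   # long enough to observe all families
  r <- rscu(count_codons(g, code5), code5)
  expect_false(anyNA(r))
  w <- 1 / code5$degeneracy[code5$codon_to_aa[names(r)]]
  expect_equal(sum(w * r) / sum(w), 1, tolerance = 1e-12)
})

test_that("GC3s counts synonymous third positions only", {
  expect_equal(gc3s(count_codons("TTTTTC", code5), code5), 0.5)
  expect_equal(gc3s(count_codons("TTATTAAAA", code5), code5), 0)
  # table 1: single-codon families (ATG, TGG) leave numerator and denominator
  cc <- count_codons("ATGTGGTTC", code1)
  expect_equal(gc3s(cc, code1), 1)      # only TTC qualifies; it ends in C
  expect_true(is.na(gc3s(count_codons("ATGTGG", code1), code1)))
})

test_that("ENC hits its analytic limits", {
  # maximal bias: one codon per family, all 20 amino acids present -> 20
  counts <- stats::setNames(rep(0L, 62), code5$sense_codons)
  for (fam in code5$families) counts[fam[1]] <- 10L
  expect_equal(enc(counts, code5), 20)
  # perfectly uniform usage at large n: raw estimate exceeds 62, capped there
  uniform <- stats::setNames(rep(100L, 62), code5$sense_codons)
  expect_equal(enc(uniform, code5), 62)
})

test_that("a missing degeneracy class is imputed from neighbouring classes", {
  # 2-folds (2,2): F = 1/3; 4-folds (3,1): F = 1/2; Ser (2,2): F = 1/3;
  # Leu absent -> F6 imputed as mean(F4, F8) = 5/12
  # ENC = 12/(1/3) + 6/(1/2) + 1/(5/12) + 1/(1/3) = 36 + 12 + 2.4 + 3 = 53.4
  counts <- stats::setNames(rep(0L, 62), code5$sense_codons)
  for (aa in names(code5$families)) {
    fam <- code5$families[[aa]]
    if (aa == "L") next
    if (length(fam) == 2) counts[fam] <- c(2L, 2L)
    if (length(fam) == 4) counts[fam] <- c(3L, 1L, 0L, 0L)
    if (length(fam) == 8) counts[fam] <- c(2L, 2L, rep(0L, 6))
  }
  expect_equal(enc(counts, code5, min_codons = 0), 53.4, tolerance = 1e-12)
})

test_that("genes below the codon floor return missing ENC", {
  short <- random_sense_gene(30, code5)
  expect_true(is.na(enc(count_codons(short, code5), code5, min_codons = 50)))
  expect_false(is.na(enc(count_codons(short, code5), code5, min_codons = 10)))
})

test_that("the expected-ENC null curve evaluates exactly", {
  expect_equal(enc_exp(0.5), 60.5)
  expect_equal(enc_exp(0), 31)
  expect_equal(enc_exp(1), 32)
  expect_equal(enc_exp(c(0, 0.5, 1)), c(31, 60.5, 32))
  expect_error(enc_exp(1.2))
})

test_that("selection flag uses a strict 0.15 boundary", {
  at <- selection_flag(34, 40)
  expect_equal(at$enc_ratio, 0.15)
  expect_false(at$selected)              # exactly 0.15 is NOT selected
  above <- selection_flag(30, 40)
  expect_equal(above$enc_ratio, 0.25)
  expect_true(above$selected)
  same <- selection_flag(40, 40)
  expect_equal(same$enc_ratio, 0)
  expect_false(same$selected)
  expect_error(selection_flag(30, 0), "positive")
})

test_that("RSCU and ENC match the brute-force oracle on small genes", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    cc <- count_codons(random_sense_gene(n, code5), code5)
    r_main <- rscu(cc, code5)
    r_oracle <- oracle_rscu(cc$counts, code5)
    expect_equal(r_main, r_oracle, tolerance = 1e-9)
    e_main <- enc(cc, code5, min_codons = 0)
    e_oracle <- oracle_enc(cc$counts, code5)
    expect_equal(e_main, e_oracle, tolerance = 1e-9)
    if (!is.na(e_main)) {
      n_observed_fams <- sum(vapply(code5$families,
                                    function(f) sum(cc$counts[f]) > 0,
                                    logical(1)))
      expect_gte(e_main, n_observed_fams)
      expect_lte(e_main, 62)
    }
  }
})

test_that("stronger within-family skew lowers expected ENC", {
  mean_enc <- vapply(c(5, 0.5, 0.05), function(conc) {
    spec <- synthetic_spec(seed = 303, n_genes = 30, codons_per_gene = 300,
                           regime = "biased", bias_concentration = conc,
                           gene_probs = "independent")
    fit <- codon_usage(generate_cds(spec)$cds, code5, min_codons = 50)
    mean(fit$genes$enc_obs)
  }, numeric(1))
  expect_true(all(diff(mean_enc) < 0))
})

test_that("mutation-only genes sit near the expected-ENC curve", {
  spec <- synthetic_spec(seed = 404, n_genes = 20, codons_per_gene = 300,
                         regime = "mutation_gc3", gc3_target = 0.3)
  fit <- codon_usage(generate_cds(spec)$cds, code5)
  dev <- abs(fit$genes$enc_obs - enc_exp(fit$genes$gc3s))
  expect_lt(mean(dev), 3)
})
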