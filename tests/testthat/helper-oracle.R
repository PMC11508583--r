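# Brute-force reference implementations of RSCU and Wright's ENC, written as
# plain loops over the code's families, independent of the package's
# vectorized code paths. Used to cross-check the main implementation on small
# random genes.

oracle_rscu <- function(counts, code) {
  out <- rep(NA_real_, length(code$sense_codons))
  names(out) <- code$sense_codons
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    total <- 0
    for (cd in fam) total <- total + counts[[cd]]
    if (total > 0) {
      k <- length(fam)
      for (cd in fam) out[[cd]] <- counts[[cd]] / (total / k)
    }
  }
  out
}

oracle_enc <- function(counts, code, min_codons = 0) {
  if (sum(counts) < min_codons) return(NA_real_)
  # per-family homozygosity
  f_by_class <- list()
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    k <- as.character(length(fam))
    n <- 0
    for (cd in fam) n <- n + counts[[cd]]
    if (n >= 2) {
      sp2 <- 0
      for (cd in fam) sp2 <- sp2 + (counts[[cd]] / n)^2
      f <- (n * sp2 - 1) / (n - 1)
      if (f > 0) f_by_class[[k]] <- c(f_by_class[[k]], f)
    }
  }
  ks <- sort(unique(unname(sapply(code$families, length))))
  fbar <- sapply(as.character(ks), function(k) {
    v <- f_by_class[[k]]
    if (is.null(v)) NA_real_ else mean(v)
  })
  multi <- ks > 1
  if (all(is.na(fbar[multi]))) return(NA_real_)
  for (i in seq_along(ks)) {
    if (multi[i] && is.na(fbar[i])) {
      lower <- which(!is.na(fbar) & multi & ks < ks[i])
      upper <- which(!is.na(fbar) & multi & ks > ks[i])
      neigh <- c(if (length(lower)) lower[length(lower)],
                 if (length(upper)) upper[1])
      fbar[i] <- mean(fbar[neigh])
    }
  }
  total <- 0
  for (i in seq_along(ks)) {
    nk <- sum(sapply(code$families, length) == ks[i])
    total <- total + if (multi[i]) nk / fbar[i] else nk
  }
  min(total, length(code$sense_codons))
}

# Random gene: a sequence of n random sense codons (start Met, no stops).
random_sense_gene <- function(n, code) {
  body <- sample(code$sense_codons, n - 1, replace = TRUE)
  paste0(c(code$families[["M"]][1], body), collapse = "")
}

# Bind two cds_set objects.
bind_cds <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("cds_set", "data.frame")
  rownames(df) <- NULL
  df
}

make_cds <- function(species, gene, sequence) {
  df <- data.frame(species = species, gene = gene, sequence = sequence,
                   source = "test", stringsAsFactors = FALSE)
  class(df) <- c("cds_set", "data.frame")
  df
}
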