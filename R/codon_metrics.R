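#' Count sense codons of a coding sequence
#'
#' Splits the sequence into consecutive triplets (exactly
#' \code{floor(length/3)} codons; trailing 1-2 nt are ignored) and tallies the
#' sense codons of the genetic code. Stop codons — terminal or internal — and
#' codons containing ambiguity codes are never counted as usage; they are
#' routed to the \code{excluded} bookkeeping instead, because neither RSCU nor
#' ENC is defined for them.
#'
#' @param sequence a DNA string (a single CDS).
#' @param code a \code{\link{genetic_code}}.
#' @return A list of class \code{"codon_counts"}: \code{counts} (named
#'   integer over the code's sense codons), \code{total_codons}
#'   (\code{sum(counts)}) and \code{excluded} (\code{stop_codons},
#'   \code{ambiguous}).
#' @examples
#' cc <- count_codons("ATGAAATAA", genetic_code(5))
#' cc$counts[c("ATG", "AAA")]   # 1, 1; the terminal TAA is excluded
#' @export
count_codons <- function(sequence, code = genetic_code(5)) {
  stopifnot(inherits(code, "genetic_code"))
  codons <- split_codons(sequence)
  is_amb <- !grepl("^[ACGT]{3}$", codons)
  is_stop <- !is_amb & codons %in% code$stop_codons
  keep <- codons[!is_amb & !is_stop]
  counts <- table(factor(keep, levels = code$sense_codons))
  counts <- stats::setNames(as.integer(counts), code$sense_codons)
  structure(list(counts = counts,
                 total_codons = sum(counts),
                 excluded = c(stop_codons = sum(is_stop),
                              ambiguous = sum(is_amb))),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("Codon counts: %d sense codons (%d stop, %d ambiguous excluded)\n",
              x$total_codons, x$excluded[["stop_codons"]],
              x$excluded[["ambiguous"]]))
  invisible(x)
}

# Internal: counts as named integer, whether given a codon_counts or raw vector.
as_counts <- function(x, code) {
  if (inherits(x, "codon_counts")) return(x$counts)
  stopifnot(all(code$sense_codons %in% names(x)))
  x[code$sense_codons]
}

#' Relative synonymous codon usage
#'
#' RSCU of codon j in a synonymous family of size k is the observed count
#' divided by the count expected under equal use of the family's codons:
#' \eqn{RSCU_j = X_j / (\sum_{family} X / k)}. Values above 1 mark over-used
#' codons. A family with zero observations yields \code{NA} for all its codons
#' (no usage to measure); an unobserved codon inside an observed family yields
#' 0 — a real value, distinct from \code{NA}, recording that the codon is
#' avoided.
#'
#' @param counts a \code{\link{count_codons}} result (or a named count vector
#'   covering the sense codons).
#' @param code a \code{\link{genetic_code}}.
#' @return Named numeric vector over the code's sense codons.
#' @export
rscu <- function(counts, code = genetic_code(5)) {
  x <- as_counts(counts, code)
  out <- stats::setNames(rep(NA_real_, length(x)), names(x))
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    tot <- sum(x[fam])
    if (tot > 0L) out[fam] <- x[fam] * length(fam) / tot
  }
  out
}

#' GC content at synonymous third codon positions (GC3s)
#'
#' The fraction of counted sense codons, restricted to codons whose amino
#' acid has a synonymous choice (family degeneracy >= 2), whose third base is
#' G or C. Under the invertebrate mitochondrial code every sense codon
#' qualifies; under the standard code the single-codon families Met (ATG) and
#' Trp (TGG) are excluded from numerator and denominator.
#'
#' @inheritParams rscu
#' @return Proportion in [0, 1], or \code{NA} if no qualifying codons were
#'   counted.
#' @export
gc3s <- function(counts, code = genetic_code(5)) {
  x <- as_counts(counts, code)
  syn_aa <- names(code$degeneracy)[code$degeneracy >= 2L]
  syn <- unlist(code$families[syn_aa], use.names = FALSE)
  den <- sum(x[syn])
  if (den == 0L) return(NA_real_)
  third_gc <- substr(syn, 3L, 3L) %in% c("G", "C")
  sum(x[syn][third_gc]) / den
}

#' Wright's effective number of codons (ENC / Nc)
#'
#' Wright's estimator of codon-usage bias. For each amino-acid family with
#' n >= 2 observations the codon homozygosity is
#' \eqn{\hat F = (n \sum p_i^2 - 1)/(n - 1)} with \eqn{p_i} the within-family
#' codon frequencies. Homozygosities are averaged within degeneracy classes
#' (families of equal size k), excluding undefined (n < 2) and zero values —
#' a single \eqn{\hat F = 0} would make a class's contribution infinite. ENC
#' is then \eqn{N_1 + \sum_k N_k / \bar F_k} with \eqn{N_k} the number of
#' families of size k in the code (invertebrate mitochondrial code:
#' \eqn{N_1 = 0}, \eqn{N_2 = 12}, \eqn{N_4 = 6}, \eqn{N_6 = 1},
#' \eqn{N_8 = 1}). A class with no usable family has its \eqn{\bar F}
#' imputed from the nearest available classes (the mean of the adjacent
#' lower and upper classes' \eqn{\bar F}, one side if only one exists),
#' generalizing Wright's rule for a missing 3-fold class. The estimate is
#' capped at the code's sense-codon count (62 for table 5, 61 for table 1);
#' on small samples the raw estimator can exceed it.
#'
#' Short genes carry too few observations per family for the estimator to be
#' meaningful; genes with fewer than \code{min_codons} counted codons return
#' \code{NA} (mitochondrial ATP8 is the classic casualty).
#'
#' @inheritParams rscu
#' @param min_codons minimum counted codons required (default 50).
#' @return ENC estimate, or \code{NA} when not computable.
#' @export
enc <- function(counts, code = genetic_code(5), min_codons = 50L) {
  x <- as_counts(counts, code)
  if (sum(x) < min_codons) return(NA_real_)
  k_of <- code$degeneracy
  f_hat <- rep(NA_real_, length(k_of))
  names(f_hat) <- names(k_of)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    n <- sum(x[fam])
    if (n >= 2L) {
      p <- x[fam] / n
      f_hat[[aa]] <- (n * sum(p^2) - 1) / (n - 1)
    }
  }
  classes <- sort(unique(k_of))
  n_k <- vapply(classes, function(k) sum(k_of == k), integer(1))
  f_bar <- vapply(classes, function(k) {
    v <- f_hat[names(k_of)[k_of == k]]
    v <- v[!is.na(v) & v > 0]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  names(f_bar) <- names(n_k) <- classes
  multi <- classes > 1L
  if (all(is.na(f_bar[multi]))) return(NA_real_)
  # Impute empty classes from the nearest defined neighbours on the k axis.
  for (i in which(multi & is.na(f_bar))) {
    below <- which(!is.na(f_bar) & classes < classes[i] & multi)
    above <- which(!is.na(f_bar) & classes > classes[i] & multi)
    nb <- c(if (length(below)) max(below), if (length(above)) min(above))
    f_bar[i] <- mean(f_bar[nb])
  }
  value <- sum(n_k[!multi]) + sum(n_k[multi] / f_bar[multi])
  min(value, length(code$sense_codons))
}

#' Expected ENC under mutation pressure alone
#'
#' Wright's null curve: the ENC a gene is expected to show if its codon usage
#' is driven purely by the mutational G+C pressure at silent sites, with no
#' selection among synonymous codons:
#' \deqn{ENC_{exp} = 2 + GC3s + 29 / [GC3s^2 + (1 - GC3s)^2].}
#' Genes on or near the curve are read as mutation-shaped; genes well below
#' it as candidates for selection on codon usage.
#'
#' @param gc3s proportion(s) in [0, 1].
#' @return Expected ENC (vectorized).
#' @examples
#' enc_exp(0.5)   # 60.5
#' @export
enc_exp <- function(gc3s) {
  stopifnot(all(is.na(gc3s) | (gc3s >= 0 & gc3s <= 1)))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC ratio and the selection flag
#'
#' The ENC ratio \eqn{(ENC_{exp} - ENC_{obs}) / ENC_{exp}} measures how far an
#' observed ENC falls below the mutation-only expectation. A gene is flagged
#' as a selection candidate when the ratio strictly exceeds the threshold
#' (default 0.15, i.e. observed ENC below 85\% of expected).
#'
#' @param enc_obs observed ENC (may be \code{NA}).
#' @param enc_expected expected ENC from \code{\link{enc_exp}}; must be
#'   positive.
#' @param threshold selection threshold on the ratio (default 0.15, strict
#'   inequality).
#' @return A list with \code{enc_ratio} and \code{selected} (both \code{NA}
#'   when \code{enc_obs} is \code{NA}).
#' @export
selection_flag <- function(enc_obs, enc_expected, threshold = 0.15) {
  if (any(!is.na(enc_expected) & enc_expected <= 0)) {
    stop("'enc_expected' must be positive")
  }
  ratio <- (enc_expected - enc_obs) / enc_expected
  list(enc_ratio = ratio, selected = ratio > threshold)
}
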