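#' Nucleotide composition of a sequence
#'
#' Base counts, percentages, A+T and G+C content, and the strand-asymmetry
#' skews AT skew = (A - T)/(A + T) and GC skew = (G - C)/(G + C). Ambiguous
#' bases are excluded from every numerator and denominator, so percentages
#' are on the unambiguous total. A skew whose denominator is zero is reported
#' as \code{NA}, not 0: zero would assert a balance that was never observed.
#'
#' @param seq a DNA string.
#' @return A list of class \code{"composition_stats"} with counts,
#'   percentages, \code{at_content}, \code{gc_content}, \code{at_skew},
#'   \code{gc_skew}, \code{length} (total bp) and \code{n_ambiguous}.
#' @examples
#' composition_stats("GGGC")$gc_skew   # (3 - 1) / 4 = 0.5
#' @export
composition_stats <- function(seq) {
  seq <- normalize_dna(seq)
  if (is.na(seq) || nchar(seq) == 0L) stop("empty sequence")
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cnt <- c(A = sum(bases == "A"), C = sum(bases == "C"),
           G = sum(bases == "G"), T = sum(bases == "T"))
  tot <- sum(cnt)
  if (tot == 0L) stop("sequence contains no unambiguous bases")
  pct <- 100 * cnt / tot
  skew <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    counts = cnt,
    pct_A = pct[["A"]], pct_C = pct[["C"]],
    pct_G = pct[["G"]], pct_T = pct[["T"]],
    at_content = pct[["A"]] + pct[["T"]],
    gc_content = pct[["G"]] + pct[["C"]],
    at_skew = skew(cnt[["A"]] - cnt[["T"]], cnt[["A"]] + cnt[["T"]]),
    gc_skew = skew(cnt[["G"]] - cnt[["C"]], cnt[["G"]] + cnt[["C"]]),
    length = nchar(seq),
    n_ambiguous = nchar(seq) - tot
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("Sequence of %d bp (%d ambiguous)\n", x$length, x$n_ambiguous))
  cat(sprintf(" A %.1f%%  C %.1f%%  G %.1f%%  T %.1f%%\n",
              x$pct_A, x$pct_C, x$pct_G, x$pct_T))
  cat(sprintf(" A+T %.1f%%  G+C %.1f%%  AT skew %s  GC skew %s\n",
              x$at_content, x$gc_content,
              formatC(x$at_skew, format = "f", digits = 3),
              formatC(x$gc_skew, format = "f", digits = 3)))
  invisible(x)
}

#' @export
as.data.frame.composition_stats <- function(x, ...) {
  data.frame(length = x$length,
             A = x$counts[["A"]], C = x$counts[["C"]],
             G = x$counts[["G"]], T = x$counts[["T"]],
             pct_A = x$pct_A, pct_C = x$pct_C, pct_G = x$pct_G,
             pct_T = x$pct_T, at_content = x$at_content,
             gc_content = x$gc_content, at_skew = x$at_skew,
             gc_skew = x$gc_skew, n_ambiguous = x$n_ambiguous)
}

#' Sliding-window GC content and GC skew
#'
#' Windowed composition profile as drawn on circular mitogenome maps
#' (default: 500 bp window, 1 bp step, circular). In circular mode windows
#' wrap past the end, so with step 1 there are exactly as many windows as
#' bases. Window values follow the same conventions as
#' \code{\link{composition_stats}} (ambiguous bases excluded; undefined skew
#' is \code{NA}).
#'
#' @param seq a DNA string.
#' @param window window size in bp (must not exceed the length).
#' @param step step in bp.
#' @param circular wrap windows past the end (default TRUE, the mitogenome
#'   convention).
#' @return A list of class \code{"window_profile"}: \code{window},
#'   \code{step}, \code{circular} and \code{values}, a data frame with
#'   columns \code{start} (0-based bp), \code{gc_content}, \code{gc_skew}.
#' @export
windowed_profile <- function(seq, window = 500L, step = 1L, circular = TRUE) {
  seq <- normalize_dna(seq)
  L <- nchar(seq)
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L) stop("'step' must be >= 1")
  if (window < 1L || window > L) stop("'window' must be in [1, sequence length]")
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (circular) bases <- c(bases, bases[seq_len(window - 1L)])
  isG <- bases == "G"; isC <- bases == "C"
  isOK <- bases %in% c("A", "C", "G", "T")
  csG <- c(0, cumsum(isG)); csC <- c(0, cumsum(isC)); csN <- c(0, cumsum(isOK))
  starts <- if (circular) seq(1L, L, by = step) else seq(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  g <- csG[ends + 1L] - csG[starts]
  cc <- csC[ends + 1L] - csC[starts]
  n <- csN[ends + 1L] - csN[starts]
  gc_content <- ifelse(n == 0L, NA_real_, 100 * (g + cc) / n)
  gc_skew <- ifelse(g + cc == 0L, NA_real_, (g - cc) / (g + cc))
  structure(list(window = window, step = step, circular = circular,
                 values = data.frame(start = starts - 1L,
                                     gc_content = gc_content,
                                     gc_skew = gc_skew)),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("Windowed profile: %d windows (%d bp window, %d bp step, %s)\n",
              nrow(x$values), x$window, x$step,
              if (x$circular) "circular" else "linear"))
  cat(sprintf(" GC content: %.1f-%.1f%%  GC skew: %.3f-%.3f\n",
              min(x$values$gc_content, na.rm = TRUE),
              max(x$values$gc_content, na.rm = TRUE),
              min(x$values$gc_skew, na.rm = TRUE),
              max(x$values$gc_skew, na.rm = TRUE)))
  invisible(x)
}
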