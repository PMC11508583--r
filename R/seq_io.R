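#' Gene-name alias table
#'
#' Mitochondrial protein-coding gene names vary across GenBank annotations
#' (COI/COX1, COB/CYTB, NAD2/ND2, ...). The package normalizes them through a
#' packaged, editable alias table onto the canonical 13 names: ATP6, ATP8,
#' COX1, COX2, COX3, CYTB, ND1-ND6, ND4L.
#'
#' @param path optional path to a two-column TSV (\code{alias},
#'   \code{canonical}) replacing the packaged table.
#' @return Named character vector mapping upper-case alias to canonical name.
#' @export
gene_aliases <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_aliases.tsv", package = "mitocodon")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$canonical, toupper(tab$alias))
}

#' The 13 mitochondrial protein-coding gene names
#' @return Character vector of canonical PCG names.
#' @export
pcg_names <- function() {
  c("ATP6", "ATP8", "COX1", "COX2", "COX3", "CYTB",
    "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6")
}

normalize_gene_name <- function(x, aliases = gene_aliases()) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  hit <- aliases[key]
  out <- ifelse(is.na(hit), x, hit)
  unresolved <- is.na(hit) & !(key %in% aliases)
  if (any(unresolved)) {
    warning("unresolved gene name(s) kept as-is: ",
            paste(unique(x[unresolved]), collapse = ", "))
  }
  unname(out)
}

normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

new_cds_set <- function(species, gene, sequence, source) {
  df <- data.frame(species = species, gene = gene, sequence = sequence,
                   source = source, stringsAsFactors = FALSE)
  bad <- nchar(df$sequence) < 6L
  if (any(bad)) {
    warning("dropping ", sum(bad), " record(s) shorter than 6 nt")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("cds_set", "data.frame")
  df
}

#' Read a set of CDS sequences from a multi-FASTA file
#'
#' Headers are either \code{"species|gene"} or a bare gene name (then
#' \code{species} supplies the label, defaulting to the file name). Gene names
#' are normalized through the alias table; sequences are upper-cased with
#' U -> T so downstream codon work sees DNA only. Ambiguity codes are kept in
#' the sequence and handled (excluded codon-wise) by the metrics.
#'
#' @param path FASTA file.
#' @param species species label used when headers carry no species field.
#' @param aliases alias map from \code{\link{gene_aliases}}.
#' @return A \code{cds_set}: a data frame with columns \code{species},
#'   \code{gene}, \code{sequence}, \code{source}.
#' @export
read_cds_fasta <- function(path, species = NULL, aliases = gene_aliases()) {
  # BStringSet so RNA-alphabet and lower-case records survive to be normalized
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("cannot parse FASTA file '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("no records in FASTA file '", path, "'")
  headers <- names(seqs)
  has_species <- grepl("|", headers, fixed = TRUE)
  sp <- ifelse(has_species, sub("\\|.*$", "", headers),
               if (is.null(species)) tools::file_path_sans_ext(basename(path))
               else species)
  gn <- ifelse(has_species, sub("^[^|]*\\|", "", headers), headers)
  gn <- sub("\\s.*$", "", gn)              # drop description after first token
  new_cds_set(sp, normalize_gene_name(gn, aliases),
              normalize_dna(as.character(seqs)),
              paste0(basename(path), ":", seq_along(seqs)))
}

#' Write a cds_set as multi-FASTA with "species|gene" headers
#'
#' @param cds a \code{cds_set}.
#' @param path output file.
#' @param width line-wrap width for sequence lines.
#' @export
write_cds_fasta <- function(cds, path, width = 70L) {
  stopifnot(inherits(cds, "cds_set"))
  con <- file(path, open = "wb")     # "wb": Unix newlines on every platform
  on.exit(close(con))
  for (i in seq_len(nrow(cds))) {
    writeLines(paste0(">", cds$species[i], "|", cds$gene[i]), con)
    s <- cds$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read annotated CDS features from a GenBank flat file
#'
#' A minimal flat-file reader for locally stored GenBank records: it walks the
#' FEATURES table, keeps CDS features, honours \code{join(...)} and
#' \code{complement(...)} locations (minus-strand features are returned
#' reverse-complemented, 5'->3' in coding sense) and the \code{/gene},
#' \code{/product} and \code{/transl_table} qualifiers, and takes the
#' nucleotides from the ORIGIN block. Partial-location markers (\code{<},
#' \code{>}) are stripped.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @param species species label; default is the record's LOCUS name.
#' @param aliases alias map from \code{\link{gene_aliases}}.
#' @return A \code{cds_set} (one row per CDS feature).
#' @export
read_cds_genbank <- function(path, species = NULL, aliases = gene_aliases()) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines))) {
    stop("cannot parse GenBank file '", path, "': no LOCUS line")
  }
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- c(rec_starts[-1L] - 1L, length(lines))
  out <- list()
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    locus <- strsplit(trimws(sub("^LOCUS", "", rec[1L])), "\\s+")[[1L]][1L]
    sp <- if (is.null(species)) locus else species
    ori <- grep("^ORIGIN", rec)
    if (length(ori) != 1L) stop("GenBank record '", locus, "' has no ORIGIN block")
    seq_lines <- rec[(ori + 1L):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    genome <- normalize_dna(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    feats <- parse_genbank_cds(rec[seq_len(ori - 1L)])
    for (f in feats) {
      s <- extract_location(genome, f$location)
      gname <- if (!is.null(f$gene)) f$gene else if (!is.null(f$product)) f$product
               else "unknown"
      out[[length(out) + 1L]] <- data.frame(
        species = sp, gene = gname, sequence = s,
        source = paste0(basename(path), ":", locus),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no CDS features found in '", path, "'")
  df <- do.call(rbind, out)
  df$gene <- normalize_gene_name(df$gene, aliases)
  new_cds_set(df$species, df$gene, df$sequence, df$source)
}

# Pull CDS features (location string + qualifiers) out of a FEATURES table.
parse_genbank_cds <- function(header_lines) {
  fstart <- grep("^FEATURES", header_lines)
  if (length(fstart) != 1L) return(list())
  ft <- header_lines[(fstart + 1L):length(header_lines)]
  ft <- ft[grepl("^ {5}", ft)]                 # feature-table lines only
  feats <- list()
  cur <- NULL
  for (ln in ft) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- trimws(sub("^ {5}\\S+\\s*", "", ln))
      cur <- list(key = key, location = loc, in_location = TRUE)
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$in_location <- FALSE
        q <- sub("^/", "", txt)
        if (grepl("=", q, fixed = TRUE)) {
          qn <- sub("=.*$", "", q)
          qv <- gsub("\"", "", sub("^[^=]*=", "", q))
          cur[[qn]] <- qv
          cur$last_q <- qn
        }
      } else if (isTRUE(cur$in_location)) {
        cur$location <- paste0(cur$location, txt)
      } else if (!is.null(cur$last_q)) {       # wrapped qualifier value
        cur[[cur$last_q]] <- paste0(cur[[cur$last_q]], gsub("\"", "", txt))
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  Filter(function(f) identical(f$key, "CDS"), feats)
}

# Evaluate a GenBank location string against the full nucleotide sequence.
extract_location <- function(genome, loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  revcomp <- FALSE
  if (grepl("^complement\\(", loc)) {
    revcomp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  seg <- vapply(parts, function(p) {
    p_rc <- grepl("^complement\\(", p)
    p <- sub("^complement\\((.*)\\)$", "\\1", p)
    ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    s <- substr(genome, ab[1L], ab[2L])
    if (p_rc) reverse_complement(s) else s
  }, character(1))
  s <- paste(seg, collapse = "")
  if (revcomp) reverse_complement(s) else s
}

#' Reverse complement of a DNA string
#' @param x a DNA string (ambiguity codes allowed).
#' @return The reverse complement.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", normalize_dna(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

split_codons <- function(sequence) {
  sequence <- normalize_dna(sequence)
  n <- nchar(sequence) %/% 3L
  if (n == 0L) return(character(0))
  substring(sequence, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Validate CDS records against a genetic code
#'
#' Report-only checks of annotation sanity: reading frame (a trailing 1-2 nt
#' beyond the last full codon is flagged as a truncated terminal stop, the
#' usual signature of mitochondrial genes completed by polyadenylation, not an
#' error), start codon, terminal stop, internal stops and ambiguous codons.
#' The sequence is never altered; downstream codon metrics consume exactly
#' \code{floor(length/3)} codons.
#'
#' @param cds a \code{cds_set}.
#' @param code a \code{\link{genetic_code}}.
#' @return A data frame with one row per record: \code{species}, \code{gene},
#'   \code{n_codons}, \code{frame_remainder}, \code{frame_ok},
#'   \code{start_codon_ok}, \code{terminal_stop} (\code{"complete"},
#'   \code{"truncated"} or \code{"absent"}), \code{n_internal_stops},
#'   \code{internal_stop_positions} (comma-separated 0-based codon indices),
#'   \code{ambiguous_codon_count}.
#' @export
validate_cds <- function(cds, code = genetic_code(5)) {
  stopifnot(inherits(cds, "cds_set"), inherits(code, "genetic_code"))
  rows <- lapply(seq_len(nrow(cds)), function(i) {
    s <- cds$sequence[i]
    codons <- split_codons(s)
    n <- length(codons)
    rem <- nchar(s) %% 3L
    is_amb <- !grepl("^[ACGT]{3}$", codons)
    is_stop <- !is_amb & codons %in% code$stop_codons
    terminal <- if (rem > 0L) "truncated"
                else if (n > 0L && is_stop[n]) "complete" else "absent"
    internal_idx <- which(is_stop[-n]) - 1L          # 0-based, excl. final codon
    data.frame(
      species = cds$species[i], gene = cds$gene[i],
      n_codons = n, frame_remainder = rem,
      frame_ok = TRUE,                                # remainder handled, not fatal
      start_codon_ok = n > 0L && !is_amb[1L] && codons[1L] %in% code$start_codons,
      terminal_stop = terminal,
      n_internal_stops = length(internal_idx),
      internal_stop_positions = paste(internal_idx, collapse = ","),
      ambiguous_codon_count = sum(is_amb),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_int <- sum(out$n_internal_stops)
  if (n_int > 0L) {
    warning(n_int, " internal stop codon(s) found across ",
            sum(out$n_internal_stops > 0L),
            " record(s); they are excluded from codon metrics ",
            "and usually indicate annotation errors")
  }
  out
}

#' Write a table as TSV with fixed numeric precision
#'
#' Deterministic tabular output: tab-separated, UTF-8, Unix newlines, a fixed
#' column order (the data frame's own) and numeric columns formatted at a
#' configurable number of decimals.
#'
#' @param rows a data frame.
#' @param path output file.
#' @param digits decimals for numeric columns (default 3).
#' @export
write_table <- function(rows, path, digits = 3L) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], format = "f", digits = digits))
    }
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read the first (or named) sequence of a FASTA file as a plain string
#' @param path FASTA file.
#' @return Uppercase DNA string.
#' @export
read_fasta_seq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file '", path, "'")
  normalize_dna(as.character(seqs[[1L]]))
}
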