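IUPAC_CODES <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

#' The two CAMTA recognition cis-elements
#'
#' `MCGCGB` is the CGCG-box (A/C)CGCG(C/G/T), the CG-1 domain binding site;
#' `MCGTGT` is (A/C)CGTGT, whose ACGTGT expansion is the classical
#' ABA-responsive element (ABRE).
#'
#' @return Named character vector of IUPAC patterns.
#' @export
camta_motifs <- function() c(MCGCGB = "MCGCGB", MCGTGT = "MCGTGT")

#' Expand an IUPAC degenerate pattern into its concrete words
#'
#' @param pattern String over the IUPAC nucleotide alphabet.
#' @return Character vector of all concrete A/C/G/T words, in lexicographic
#'   enumeration order; length equals the product of per-symbol degeneracies.
#' @export
iupac_expand <- function(pattern) {
  syms <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  if (length(syms) == 0L) stop("empty motif pattern")
  bad <- setdiff(syms, names(IUPAC_CODES))
  if (length(bad) > 0L)
    stop("invalid IUPAC symbol(s): ", paste(unique(bad), collapse = ", "))
  words <- ""
  for (s in syms)
    words <- as.vector(outer(words, IUPAC_CODES[[s]], paste0))
  sort(words)
}

#' Reverse complement of a sequence or IUPAC pattern
#'
#' @param x Character string over the IUPAC alphabet.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

iupac_regex <- function(pattern) {
  syms <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  bad <- setdiff(syms, names(IUPAC_CODES))
  if (length(bad) > 0L)
    stop("invalid IUPAC symbol(s): ", paste(unique(bad), collapse = ", "))
  paste(vapply(syms, function(s) {
    chars <- IUPAC_CODES[[s]]
    if (length(chars) == 1L) chars else
      paste0("[", paste(chars, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan one sequence for a degenerate motif
#'
#' Every window position is tested; overlapping hits are all reported.
#' Minus-strand hits are found by scanning the reverse complement and
#' mapping coordinates back to the forward strand. An `N` in the sequence
#' matches no motif symbol. Hits are ordered by start, then strand.
#'
#' @param sequence Uppercase A/C/G/T/N string.
#' @param pattern IUPAC pattern.
#' @param name Motif name recorded in the output (defaults to the pattern).
#' @param strand_policy `"both"` or `"forward"`.
#' @return Data frame with `motif`, `start` (0-based), `end` (half-open),
#'   `strand`, `match` (forward-strand text of the hit window). A sequence
#'   shorter than the motif yields zero rows.
#' @export
scan_sequence <- function(sequence, pattern, name = pattern,
                          strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  w <- nchar(pattern)
  L <- nchar(sequence)
  empty <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (L < w) return(empty)
  rx <- paste0("(?=", iupac_regex(pattern), ")")  # lookahead => overlaps kept
  find_starts <- function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  starts_f <- find_starts(sequence)
  out <- list()
  if (length(starts_f) > 0L)
    out$f <- data.frame(motif = name, start = starts_f, end = starts_f + w,
                        strand = "+",
                        match = substring(sequence, starts_f + 1L,
                                          starts_f + w),
                        stringsAsFactors = FALSE)
  if (strand_policy == "both") {
    starts_rc <- find_starts(revcomp(sequence))
    if (length(starts_rc) > 0L) {
      starts_m <- L - (starts_rc + w)            # map back to forward strand
      out$r <- data.frame(motif = name, start = starts_m, end = starts_m + w,
                          strand = "-",
                          match = substring(sequence, starts_m + 1L,
                                            starts_m + w),
                          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a promoter set for a collection of motifs
#'
#' @param promoters Named character vector of uppercase sequences.
#' @param motifs Named character vector of IUPAC patterns
#'   (default [camta_motifs()]).
#' @param strand_policy `"both"` (default) or `"forward"`.
#' @return Data frame of hits with `gene_id`, `motif`, `start`, `end`,
#'   `strand`, `match`.
#' @export
scan_promoters <- function(promoters, motifs = camta_motifs(),
                           strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  if (is.null(names(motifs))) names(motifs) <- motifs
  out <- list()
  for (g in names(promoters)) {
    for (m in names(motifs)) {
      h <- scan_sequence(promoters[[g]], motifs[[m]], name = m,
                         strand_policy = strand_policy)
      if (nrow(h) > 0L) {
        h$gene_id <- g
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), match = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[, c("gene_id", "motif", "start", "end", "strand", "match")]
}

#' Per-class motif frequency table
#'
#' For each gene class and motif, the percentage of class genes whose
#' promoter carries at least one hit, in the style of the published
#' "21.4% genes containing CGCG core motif" summaries; per-gene occurrence
#' counts are returned alongside.
#'
#' @param hits Hit table from [scan_promoters()].
#' @param promoters Promoter set (defines which genes were scanned).
#' @param gene_classes Data frame with columns `gene_id` and `class`.
#' @return List with `frequency` (class x motif: `n_genes`, `n_with_hit`,
#'   `frequency` percent, `NA` for empty classes) and `gene_counts`
#'   (per gene x motif occurrence counts).
#' @export
motif_gene_frequency <- function(hits, promoters, gene_classes) {
  stopifnot(all(c("gene_id", "class") %in% colnames(gene_classes)))
  motifs <- unique(hits$motif)
  if (length(motifs) == 0L) motifs <- names(camta_motifs())
  classes <- unique(gene_classes$class)
  counts <- matrix(0L, nrow = nrow(gene_classes), ncol = length(motifs),
                   dimnames = list(gene_classes$gene_id, motifs))
  if (nrow(hits) > 0L) {
    tab <- table(factor(hits$gene_id, levels = gene_classes$gene_id),
                 factor(hits$motif, levels = motifs))
    counts[] <- as.integer(tab)
  }
  rows <- list()
  for (cl in classes) {
    members <- gene_classes$gene_id[gene_classes$class == cl]
    n <- length(members)
    for (m in motifs) {
      n_hit <- if (n > 0L) sum(counts[members, m] > 0L) else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, motif = m, n_genes = n, n_with_hit = n_hit,
        frequency = if (n > 0L) round_half_up(100 * n_hit / n, 1L)
                    else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  gene_counts <- data.frame(gene_id = gene_classes$gene_id,
                            class = gene_classes$class, counts,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            row.names = NULL)
  list(frequency = do.call(rbind, rows), gene_counts = gene_counts)
}

#' Round half away from zero to a fixed number of decimals
#'
#' Matches the reporting convention of the published percentage tables
#' (e.g. 28.15 -> 28.2), unlike banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  # tiny nudge so values stored just below .5 by binary representation
  # (e.g. 28.15 * 10 = 281.4999...) still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}
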