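#' Three-set Venn partition of a query gene list
#'
#' Counts the seven exclusive regions of the intersection of a query gene
#' list with three annotation sets (e.g. drought/cold/salt responders), plus
#' the query genes outside all three.
#'
#' @param query Character vector of gene ids.
#' @param setA,setB,setC Character vectors of gene ids.
#' @param names Length-3 names for the sets.
#' @return Data frame with `region` (`A`, `B`, `C`, `AB`, `AC`, `BC`,
#'   `ABC`, `outside`) and `count`; region labels use `names`. The seven
#'   exclusive counts sum to `|query n (A u B u C)|` (asserted).
#' @export
venn3 <- function(query, setA, setB, setC, names = c("A", "B", "C")) {
  stopifnot(length(names) == 3L)
  query <- unique(query)
  inA <- query %in% setA
  inB <- query %in% setB
  inC <- query %in% setC
  counts <- c(sum(inA & !inB & !inC), sum(!inA & inB & !inC),
              sum(!inA & !inB & inC), sum(inA & inB & !inC),
              sum(inA & !inB & inC), sum(!inA & inB & inC),
              sum(inA & inB & inC), sum(!inA & !inB & !inC))
  stopifnot(sum(counts[1:7]) == sum(inA | inB | inC))
  region <- c(names, paste0(names[1], "&", names[2]),
              paste0(names[1], "&", names[3]),
              paste0(names[2], "&", names[3]),
              paste(names, collapse = "&"), "outside")
  data.frame(region = region, count = counts, stringsAsFactors = FALSE)
}

#' Cross-tabulate dependence classes against annotation gene sets
#'
#' For each class and set, the member count and the percentage of the
#' class's set-annotated genes (the reporting convention of the published
#' hormone tables: 14 ABA genes among 35 hormone-annotated class genes =
#' 40.0%). Percentages are rounded half-up to one decimal. When motif hits
#' are supplied, counts of motif-bearing genes per cell are added.
#'
#' @param classification A `dependence_classification` or any data frame
#'   with `gene_id` and `class` columns.
#' @param gsc Gene-set collection.
#' @param hits Optional motif hit table from [scan_promoters()].
#' @return Data frame with one row per class x set: `class`, `set`,
#'   `n_members` (class genes in the set), `n_annotated` (class genes in any
#'   set), `percent`, and per-motif hit counts when `hits` is given.
#' @export
crosstab_classes <- function(classification, gsc, hits = NULL) {
  classes <- if (inherits(classification, "dependence_classification"))
    classification$classes else classification
  stopifnot(all(c("gene_id", "class") %in% colnames(classes)))
  outside <- setdiff(classes$gene_id, gsc$universe)
  if (length(outside) > 0L)
    warning(length(outside),
            " classified gene(s) missing from the annotation universe; ",
            "counted as unannotated")
  annotated <- unique(unlist(gsc$sets, use.names = FALSE))
  motifs <- if (!is.null(hits)) unique(hits$motif) else character(0)
  rows <- list()
  for (cl in unique(classes$class)) {
    members <- classes$gene_id[classes$class == cl]
    n_annot <- sum(members %in% annotated)
    for (s in names(gsc$sets)) {
      in_set <- members[members %in% gsc$sets[[s]]]
      row <- data.frame(class = cl, set = s, n_members = length(in_set),
                        n_annotated = n_annot,
                        percent = if (n_annot > 0L)
                          round_half_up(100 * length(in_set) / n_annot, 1L)
                        else NA_real_,
                        stringsAsFactors = FALSE)
      for (m in motifs)
        row[[paste0("n_", m)]] <-
          sum(in_set %in% hits$gene_id[hits$motif == m])
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' One-sided Fisher (hypergeometric) over-representation test per term
#'
#' For each term set, the upper-tail hypergeometric probability
#' `P(X >= k)` with `X ~ Hypergeom(N, K, n)` where `k` is the query-term
#' overlap, `K` the term size, `n` the query size and `N` the universe size
#' (the SEA semantics: over-representation only). The odds ratio comes from
#' the 2x2 table, with 0.5 added to every cell when any cell is zero.
#' Adjusted p-values use Benjamini-Yekutieli.
#'
#' @param query Character vector of gene ids; must lie in the universe.
#' @param gsc Gene-set collection supplying the term sets and universe.
#' @return Data frame with `term`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p_value`, `p_adjusted`, ordered as in `gsc$sets`.
#' @export
fisher_enrichment <- function(query, gsc) {
  universe <- gsc$universe
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  stray <- setdiff(query, universe)
  if (length(stray) > 0L)
    stop("query gene(s) outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gsc$sets), function(term) {
    members <- intersect(gsc$sets[[term]], universe)
    K <- length(members)
    k <- sum(query %in% members)
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- K - k; c_ <- n - k; d <- N - K - n + k
    if (min(a, b, c_, d) == 0L) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    }
    data.frame(term = term, k = k, K = K, n = n, N = N,
               odds_ratio = (a * d) / (b * c_), p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- adjust_by(res$p_value)
  rownames(res) <- NULL
  res
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' FDR control under arbitrary dependence:
#' `p_adj(i) = min over j >= i of min(1, c(m) * m * p(j) / j)` on
#' ascending-sorted p, with harmonic inflation `c(m) = sum_{l=1..m} 1/l`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values (same order as input).
#' @export
adjust_by <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BY")
}
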