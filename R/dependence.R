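#' Mutant-to-wild-type response ratios for drought-responsive genes
#'
#' For every gene called UP or DOWN in the wild type, computes
#' `rho = mut_log2fc / wt_log2fc` (same-sign responses give rho > 0) and the
#' attenuation `a = 1 - rho`: a = 0 means the mutant responds exactly like
#' the wild type, a = 1 means the response is abolished, a > 1 means the
#' mutant responds in the opposite direction.
#'
#' @param de_wt,de_mut Differential-expression tables from [run_de()] for
#'   the same tissue and gene universe (wild type and mutant).
#' @return Data frame with `gene_id`, `wt_call`, `wt_log2fc`, `mut_log2fc`,
#'   `rho`, `attenuation`, restricted to WT-significant genes.
#' @export
response_ratio <- function(de_wt, de_mut) {
  missing_genes <- setdiff(de_wt$gene_id, de_mut$gene_id)
  if (length(missing_genes) > 0L)
    stop("gene(s) missing from mutant table: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  sig <- de_wt$call %in% c("UP", "DOWN")
  wt <- de_wt[sig, , drop = FALSE]
  mut_lfc <- de_mut$log2fc[match(wt$gene_id, de_mut$gene_id)]
  rho <- mut_lfc / wt$log2fc     # WT gate guarantees |wt_log2fc| >= 1
  data.frame(gene_id = wt$gene_id, wt_call = wt$call,
             wt_log2fc = wt$log2fc, mut_log2fc = mut_lfc, rho = rho,
             attenuation = 1 - rho, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Descriptive column statistics with a t-interval for the mean
#'
#' The "column statistics" summary used to threshold the attenuation
#' distribution: mean, sd (n-1 denominator), sem and the t-distribution
#' confidence interval for the mean.
#'
#' @param values Numeric vector, length >= 2.
#' @param ci_level Confidence level (default 0.99).
#' @return List with `n`, `mean`, `sd`, `sem`, `ci_level`, `ci_low`,
#'   `ci_high`.
#' @export
column_stats <- function(values, ci_level = 0.99) {
  n <- length(values)
  if (n < 2L) stop("column_stats needs at least 2 values")
  stopifnot(ci_level > 0, ci_level < 1)
  m <- mean(values)
  s <- stats::sd(values)
  sem <- s / sqrt(n)
  tq <- stats::qt((1 + ci_level) / 2, df = n - 1)
  list(n = n, mean = m, sd = s, sem = sem, ci_level = ci_level,
       ci_low = m - tq * sem, ci_high = m + tq * sem)
}

#' Classify wild-type drought-responsive genes by CAMTA1 dependence
#'
#' The core procedure: for every WT-significant gene the attenuation
#' `a = 1 - mut_log2fc / wt_log2fc` is computed; the threshold is the upper
#' bound of the `ci_level` confidence interval of the mean of the
#' attenuation column; genes with `a >= threshold` are DEPENDENT, the rest
#' INDEPENDENT. Crossing with the WT call direction gives the four classes:
#' CDPRG (dependent, WT UP), CDNRG (dependent, WT DOWN), CIDIG (independent,
#' WT UP) and CIDRG (independent, WT DOWN). In the degenerate zero-variance
#' case the threshold equals the common attenuation value and ties are
#' classified INDEPENDENT (dependence requires strict evidence).
#'
#' @inheritParams response_ratio
#' @param ci_level Confidence level of the attenuation-mean interval
#'   (default 0.99).
#' @param tissue Optional tissue label carried into the result.
#' @return List of class `dependence_classification` with `classes` (the
#'   [response_ratio()] table plus `dependent` and `class` columns),
#'   `threshold`, `stats` (the [column_stats()] of the attenuation column),
#'   `counts` (named: CDPRG, CDNRG, CIDIG, CIDRG), `ci_level` and `tissue`.
#'   An empty WT-significant set yields an empty classification with a
#'   warning.
#' @export
classify_dependence <- function(de_wt, de_mut, ci_level = 0.99,
                                tissue = NA_character_) {
  ratios <- response_ratio(de_wt, de_mut)
  empty_counts <- c(CDPRG = 0L, CDNRG = 0L, CIDIG = 0L, CIDRG = 0L)
  if (nrow(ratios) == 0L) {
    warning("no WT-significant genes; empty classification")
    ratios$dependent <- logical(0)
    ratios$class <- character(0)
    return(structure(list(classes = ratios, threshold = NA_real_,
                          stats = NULL, counts = empty_counts,
                          ci_level = ci_level, tissue = tissue),
                     class = "dependence_classification"))
  }
  if (nrow(ratios) == 1L) {
    # a single gene has no attenuation distribution; conservative call
    threshold <- ratios$attenuation
    dependent <- FALSE
    st <- NULL
  } else {
    st <- column_stats(ratios$attenuation, ci_level)
    threshold <- st$ci_high
    dependent <- if (st$sd > 0) ratios$attenuation >= threshold
                 else ratios$attenuation > threshold
  }
  ratios$dependent <- dependent
  ratios$class <- ifelse(ratios$wt_call == "UP",
                         ifelse(dependent, "CDPRG", "CIDIG"),
                         ifelse(dependent, "CDNRG", "CIDRG"))
  counts <- empty_counts
  tab <- table(ratios$class)
  counts[names(tab)] <- as.integer(tab)
  # partition identities, asserted on every run
  stopifnot(counts[["CDPRG"]] + counts[["CIDIG"]] ==
              sum(ratios$wt_call == "UP"),
            counts[["CDNRG"]] + counts[["CIDRG"]] ==
              sum(ratios$wt_call == "DOWN"))
  structure(list(classes = ratios, threshold = threshold, stats = st,
                 counts = counts, ci_level = ci_level, tissue = tissue),
            class = "dependence_classification")
}

#' Summarise a dependence classification as a counts table
#'
#' @param classification A `dependence_classification`, or a list of them
#'   (one per tissue).
#' @return Data frame with one row per tissue: the four class counts,
#'   `wt_up` (= CDPRG + CIDIG), `wt_down` (= CDNRG + CIDRG) and `total`.
#' @export
partition_summary <- function(classification) {
  if (inherits(classification, "dependence_classification"))
    classification <- list(classification)
  rows <- lapply(classification, function(cl) {
    ct <- cl$counts
    data.frame(tissue = cl$tissue,
               CDPRG = ct[["CDPRG"]], CDNRG = ct[["CDNRG"]],
               CIDIG = ct[["CIDIG"]], CIDRG = ct[["CIDRG"]],
               wt_up = ct[["CDPRG"]] + ct[["CIDIG"]],
               wt_down = ct[["CDNRG"]] + ct[["CIDRG"]],
               total = sum(ct), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' @export
print.dependence_classification <- function(x, ...) {
  cat(sprintf("Dependence classification (%s), threshold a >= %.4f (CI %.0f%%)\n",
              ifelse(is.na(x$tissue), "unspecified tissue", x$tissue),
              x$threshold, 100 * x$ci_level))
  print(x$counts)
  invisible(x)
}

#' Reconstruct a class partition from reported totals
#'
#' Builds the four-class partition implied by a tissue's total WT
#' up/down-regulated gene counts and the number classified dependent in each
#' direction, and checks the partition identities. Useful for working with
#' published count tables when the underlying arrays are not at hand.
#'
#' @param wt_up,wt_down Total WT drought-induced / -repressed genes.
#' @param dep_up,dep_down Of those, the number classified dependent.
#' @param tissue Tissue label.
#' @return A `dependence_classification` carrying only counts (placeholder
#'   gene ids), suitable for [partition_summary()].
#' @export
partition_from_totals <- function(wt_up, dep_up, wt_down, dep_down,
                                  tissue = NA_character_) {
  stopifnot(dep_up <= wt_up, dep_down <= wt_down)
  n <- wt_up + wt_down
  classes <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    wt_call = rep(c("UP", "DOWN"), c(wt_up, wt_down)),
    dependent = c(rep(c(TRUE, FALSE), c(dep_up, wt_up - dep_up)),
                  rep(c(TRUE, FALSE), c(dep_down, wt_down - dep_down))),
    stringsAsFactors = FALSE)
  classes$class <- ifelse(classes$wt_call == "UP",
                          ifelse(classes$dependent, "CDPRG", "CIDIG"),
                          ifelse(classes$dependent, "CDNRG", "CIDRG"))
  counts <- c(CDPRG = 0L, CDNRG = 0L, CIDIG = 0L, CIDRG = 0L)
  tab <- table(classes$class)
  counts[names(tab)] <- as.integer(tab)
  stopifnot(counts[["CDPRG"]] + counts[["CIDIG"]] == wt_up,
            counts[["CDNRG"]] + counts[["CIDRG"]] == wt_down)
  structure(list(classes = classes, threshold = NA_real_, stats = NULL,
                 counts = counts, ci_level = NA_real_, tissue = tissue),
            class = "dependence_classification")
}
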