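#' Run the full dependence-classification pipeline
#'
#' Orchestrates the whole analysis on one dataset: differential expression
#' per genotype and tissue, dependence classification, promoter motif
#' scanning and per-class frequencies, Venn partition against the stress
#' sets, class-by-set cross-tabulation, Fisher/BY enrichment of the
#' dependent classes, and a plain-text report. Input is either a simulation
#' configuration (the generator supplies expression, promoters and gene sets
#' with ground truth) or pre-loaded data. Every table is written to
#' `out_dir` and listed in the returned manifest; the partition identities
#' are asserted for every tissue.
#'
#' @param config A [sim_config()] (simulation mode), or `NULL` when `data`
#'   is supplied.
#' @param data Optional list with `matrix`, `design`, and optionally
#'   `promoters` and `gene_sets`, replacing simulation.
#' @param out_dir Output directory for the TSV tables and report.
#' @param de DE parameters, a [de_params()].
#' @param ci_level Confidence level of the dependence threshold.
#' @param motifs Named IUPAC motif vector.
#' @param strand_policy `"both"` or `"forward"`.
#' @return List of class `camta_run` with `classifications` (per tissue),
#'   `de` (per tissue/genotype), `motif_frequency`, `venn`, `crosstab`,
#'   `enrichment`, `truth` (simulation mode), `manifest` (file table) and
#'   `report` (character lines).
#' @export
run_pipeline <- function(config = sim_config(), data = NULL,
                         out_dir = tempfile("camta_run"),
                         de = de_params(), ci_level = 0.99,
                         motifs = camta_motifs(),
                         strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  if (is.null(data)) {
    stopifnot(inherits(config, "sim_config"))
    sim <- simulate_expression(config)
    prom <- simulate_promoters(config, sim$truth, motifs = motifs)
    gsc <- simulate_gene_sets(config, sim$truth)
    mat <- sim$matrix; design <- sim$design
    promoters <- prom$promoters
    truth <- sim$truth
  } else {
    mat <- data$matrix; design <- data$design
    validate_design(design); validate_expression(mat, design)
    promoters <- data$promoters
    gsc <- data$gene_sets
    truth <- NULL
  }

  tissues <- unique(design$tissue)
  de_tables <- list()
  classifications <- list()
  for (tis in tissues) {
    de_wt <- run_de(mat, design, tis, "WT", de)
    de_mut <- run_de(mat, design, tis, "MUT", de)
    de_tables[[paste0(tis, "_WT")]] <- de_wt
    de_tables[[paste0(tis, "_MUT")]] <- de_mut
    classifications[[tis]] <- classify_dependence(de_wt, de_mut,
                                                  ci_level = ci_level,
                                                  tissue = tis)
  }

  hits <- NULL; freq <- NULL
  if (!is.null(promoters)) {
    hits <- scan_promoters(promoters, motifs, strand_policy)
  }

  venn_tabs <- list(); crosstabs <- list(); enrich_tabs <- list()
  freq_tabs <- list()
  for (tis in tissues) {
    cl <- classifications[[tis]]
    if (!is.null(hits) && nrow(cl$classes) > 0L) {
      mf <- motif_gene_frequency(
        hits[hits$gene_id %in% names(promoters), , drop = FALSE],
        promoters, cl$classes[, c("gene_id", "class")])
      freq_tabs[[tis]] <- cbind(tissue = tis, mf$frequency)
    }
    if (!is.null(gsc) && nrow(cl$classes) > 0L) {
      stress <- intersect(c("drought", "cold", "salt"), names(gsc$sets))
      if (length(stress) == 3L) {
        for (cls in c("CDPRG", "CDNRG")) {
          q <- cl$classes$gene_id[cl$classes$class == cls]
          venn_tabs[[paste(tis, cls, sep = "_")]] <-
            cbind(tissue = tis, class = cls,
                  venn3(q, gsc$sets[[stress[1]]], gsc$sets[[stress[2]]],
                        gsc$sets[[stress[3]]], names = stress))
        }
      }
      crosstabs[[tis]] <- cbind(tissue = tis,
                                crosstab_classes(cl, gsc, hits = hits))
      dep <- cl$classes$gene_id[cl$classes$dependent]
      if (length(dep) > 0L)
        enrich_tabs[[tis]] <- cbind(tissue = tis,
                                    fisher_enrichment(dep, gsc))
    }
  }
  freq <- if (length(freq_tabs) > 0L) do.call(rbind, freq_tabs) else NULL

  summary_tab <- partition_summary(classifications)
  tables <- list(partition_summary = summary_tab)
  for (nm in names(de_tables)) tables[[paste0("de_", nm)]] <- de_tables[[nm]]
  for (tis in tissues)
    tables[[paste0("classes_", tis)]] <- classifications[[tis]]$classes
  if (!is.null(hits)) tables$motif_hits <- hits
  if (!is.null(freq)) tables$motif_frequency <- freq
  if (length(venn_tabs) > 0L) tables$venn <- do.call(rbind, venn_tabs)
  if (length(crosstabs) > 0L) tables$crosstab <- do.call(rbind, crosstabs)
  if (length(enrich_tabs) > 0L)
    tables$enrichment <- do.call(rbind, enrich_tabs)
  manifest <- write_results(tables, out_dir)

  run <- structure(list(classifications = classifications, de = de_tables,
                        motif_hits = hits, motif_frequency = freq,
                        venn = tables$venn, crosstab = tables$crosstab,
                        enrichment = tables$enrichment, truth = truth,
                        manifest = manifest, out_dir = out_dir),
                   class = "camta_run")
  run$report <- report(run)
  writeLines(run$report, file.path(out_dir, "report.txt"))
  run$manifest <- rbind(manifest,
                        data.frame(table = "report",
                                   file = file.path(out_dir, "report.txt"),
                                   n_rows = length(run$report),
                                   stringsAsFactors = FALSE))
  run
}

#' Plain-text summary report of a pipeline run
#'
#' Mirrors the reporting structure of the study the pipeline emulates:
#' per-tissue UP/DOWN and four-class counts, per-class motif frequencies,
#' Venn counts and top enrichment terms.
#'
#' @param run A `camta_run` from [run_pipeline()].
#' @param top_terms Number of enrichment terms to print per tissue.
#' @return Character vector of report lines.
#' @export
report <- function(run, top_terms = 3L) {
  lines <- c("CAMTA1 dependence classification - run summary",
             strrep("=", 46), "")
  summ <- partition_summary(run$classifications)
  for (i in seq_len(nrow(summ))) {
    r <- summ[i, ]
    lines <- c(lines, sprintf("Tissue %s:", r$tissue),
               sprintf("  WT drought-induced: %d (dependent %d, independent %d)",
                       r$wt_up, r$CDPRG, r$CIDIG),
               sprintf("  WT drought-repressed: %d (dependent %d, independent %d)",
                       r$wt_down, r$CDNRG, r$CIDRG))
  }
  if (!is.null(run$motif_frequency)) {
    lines <- c(lines, "", "Motif frequencies (% genes with >= 1 hit):")
    mf <- run$motif_frequency
    lines <- c(lines,
               sprintf("  %s %s %s: %s%% (%d/%d)", mf$tissue, mf$class,
                       mf$motif, format(mf$frequency), mf$n_with_hit,
                       mf$n_genes))
  }
  if (!is.null(run$venn)) {
    lines <- c(lines, "", "Stress-set Venn regions (dependent classes):")
    v <- run$venn
    lines <- c(lines, sprintf("  %s %s %s: %d", v$tissue, v$class,
                              v$region, v$count))
  }
  if (!is.null(run$enrichment)) {
    lines <- c(lines, "", "Top enriched terms among dependent genes:")
    for (tis in unique(run$enrichment$tissue)) {
      e <- run$enrichment[run$enrichment$tissue == tis, ]
      e <- e[order(e$p_adjusted), ][seq_len(min(top_terms, nrow(e))), ]
      lines <- c(lines,
                 sprintf("  %s %s: k=%d/%d, p=%.3g, p.adj=%.3g", tis,
                         e$term, e$k, e$K, e$p_value, e$p_adjusted))
    }
  }
  lines
}

#' @export
print.camta_run <- function(x, ...) {
  writeLines(x$report)
  invisible(x)
}
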