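#' Parameters for the SAM-style differential-expression call
#'
#' @param s0 Fudge factor added to the denominator of the d-statistic;
#'   `"auto"` (default) uses the median per-gene standard error, a simple
#'   stabiliser in the spirit of the original procedure.
#' @param n_perm Requested number of label permutations (>= 100); when the
#'   number of distinct condition-label assignments is smaller, all of them
#'   are enumerated exactly instead.
#' @param seed Seed for Monte-Carlo permutations.
#' @param p_threshold,fc_threshold Significance gates: a gene is called
#'   UP/DOWN when `p <= p_threshold` and `|fc_linear| >= fc_threshold`
#'   (both inclusive).
#' @return List of class `de_params`.
#' @export
de_params <- function(s0 = "auto", n_perm = 1000L, seed = 1L,
                      p_threshold = 0.05, fc_threshold = 2) {
  stopifnot(n_perm >= 100L, p_threshold > 0, p_threshold <= 1,
            fc_threshold >= 1)
  if (!identical(s0, "auto")) stopifnot(is.numeric(s0), s0 >= 0)
  structure(list(s0 = s0, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), p_threshold = p_threshold,
                 fc_threshold = fc_threshold),
            class = "de_params")
}

contrast_columns <- function(design, tissue, genotype) {
  sel <- design$tissue == tissue & design$genotype == genotype
  drought <- design$sample_id[sel & design$condition == "DROUGHT"]
  control <- design$sample_id[sel & design$condition == "CONTROL"]
  if (length(drought) < 2L || length(control) < 2L)
    stop(sprintf("contrast %s/%s needs >= 2 replicates in both conditions",
                 tissue, genotype))
  list(drought = drought, control = control)
}

#' Per-gene log2 fold change for a drought-vs-control contrast
#'
#' `log2fc = mean(drought replicates) - mean(control replicates)` on the
#' already-log2 matrix.
#'
#' @param mat Expression matrix (genes x samples, log2).
#' @param design Experiment design.
#' @param tissue,genotype Contrast cell selectors.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mat, design, tissue, genotype) {
  cc <- contrast_columns(design, tissue, genotype)
  rowMeans(mat[, cc$drought, drop = FALSE]) -
    rowMeans(mat[, cc$control, drop = FALSE])
}

#' Signed linear fold change from a log2 fold change
#'
#' Signed "fold" convention: +2 means doubled, -2 means halved, so
#' `|fc| >= 1` always and the FC >= 2 gate reads identically in both
#' directions.
#'
#' @param log2fc Numeric vector.
#' @return Signed linear fold changes; `fc = sign(log2fc) * 2^|log2fc|`
#'   (1 when `log2fc = 0`).
#' @export
linear_fold_change <- function(log2fc) {
  ifelse(log2fc == 0, 1, sign(log2fc) * 2^abs(log2fc))
}

row_var <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

pooled_se <- function(mat, drought, control) {
  xd <- mat[, drought, drop = FALSE]
  xc <- mat[, control, drop = FALSE]
  n1 <- ncol(xd); n2 <- ncol(xc)
  pooled_var <- ((n1 - 1) * row_var(xd) + (n2 - 1) * row_var(xc)) /
    (n1 + n2 - 2)
  sqrt(pooled_var * (1 / n1 + 1 / n2))
}

#' SAM-style d-statistic for a drought-vs-control contrast
#'
#' `d_g = (mean_drought - mean_control) / (s_g + s0)` where `s_g` is the
#' pooled standard error of the mean difference. With `s0 = 0` and zero
#' variance in both groups, a non-zero difference gives an infinite d that
#' ranks most extreme (never NaN); a zero difference gives d = 0.
#'
#' @inheritParams log2_fold_change
#' @param s0 Non-negative fudge factor, or `"auto"` for the median `s_g`.
#' @return Named numeric vector of d values.
#' @export
sam_d_statistic <- function(mat, design, tissue, genotype, s0 = "auto") {
  cc <- contrast_columns(design, tissue, genotype)
  diff <- rowMeans(mat[, cc$drought, drop = FALSE]) -
    rowMeans(mat[, cc$control, drop = FALSE])
  se <- pooled_se(mat, cc$drought, cc$control)
  if (identical(s0, "auto")) s0 <- stats::median(se)
  denom <- se + s0
  d <- ifelse(denom == 0, ifelse(diff == 0, 0, sign(diff) * Inf),
              diff / denom)
  names(d) <- rownames(mat)
  d
}

# All distinct assignments of n1 "drought" labels to n1+n2 samples, as a
# matrix with one column per assignment listing the drought column indices.
all_assignments <- function(n1, n2) utils::combn(n1 + n2, n1)

permuted_d <- function(sub, idx_sets, s0) {
  n_tot <- ncol(sub)
  vapply(seq_len(ncol(idx_sets)), function(b) {
    dcols <- idx_sets[, b]
    ccols <- setdiff(seq_len(n_tot), dcols)
    diff <- rowMeans(sub[, dcols, drop = FALSE]) -
      rowMeans(sub[, ccols, drop = FALSE])
    se <- pooled_se(sub, dcols, ccols)
    denom <- se + s0
    ifelse(denom == 0, ifelse(diff == 0, 0, sign(diff) * Inf), diff / denom)
  }, numeric(nrow(sub)))
}

#' Permutation p- and q-values for the d-statistic
#'
#' Condition labels are shuffled within the contrast's samples; permuted d
#' values are pooled across genes (standard SAM practice, required with only
#' 20 distinct assignments at n = 3 vs 3). The p-value is the smoothed
#' pooled-null tail `p_g = (1 + #\{|d*| >= |d_g|\}) / (1 + N_pool)`. The
#' q-value is the SAM FDR ratio: median over permutations of the count of
#' permuted values at least as extreme as `|d_g|`, divided by the observed
#' count, capped at 1 and monotonized to be non-increasing in `|d|`. When
#' fewer distinct label assignments exist than `n_perm`, all assignments are
#' enumerated exactly (reported via `exhaustive`).
#'
#' @inheritParams log2_fold_change
#' @param params A [de_params()].
#' @return List with `p_value`, `q_value` (named vectors), `d` (the observed
#'   statistics), `s0` (value used), `n_assignments` and `exhaustive`.
#' @export
permutation_pq <- function(mat, design, tissue, genotype,
                           params = de_params()) {
  cc <- contrast_columns(design, tissue, genotype)
  sub <- mat[, c(cc$drought, cc$control), drop = FALSE]
  n1 <- length(cc$drought); n2 <- length(cc$control)
  se <- pooled_se(mat, cc$drought, cc$control)
  s0 <- if (identical(params$s0, "auto")) stats::median(se) else params$s0
  d <- sam_d_statistic(mat, design, tissue, genotype, s0 = s0)

  n_distinct <- choose(n1 + n2, n1)
  exhaustive <- n_distinct <= params$n_perm
  if (exhaustive) {
    idx_sets <- all_assignments(n1, n2)
  } else {
    set.seed(params$seed)
    idx_sets <- replicate(params$n_perm, sample.int(n1 + n2, n1))
  }
  dstar <- permuted_d(sub, idx_sets, s0)          # genes x assignments

  abs_pool <- sort(abs(as.vector(dstar)))
  n_pool <- length(abs_pool)
  # elements of the pool >= |d_g|, with exact tie handling
  count_ge <- n_pool - findInterval(abs(d), abs_pool, left.open = TRUE)
  p <- (1 + count_ge) / (1 + n_pool)

  # SAM q: per-assignment false-positive counts at threshold |d_g|
  abs_d_sorted <- sort(abs(d))
  obs_ge <- length(d) - findInterval(abs(d), abs_d_sorted, left.open = TRUE)
  fp <- matrix(0, nrow = length(d), ncol = ncol(dstar))
  for (b in seq_len(ncol(dstar))) {
    col_sorted <- sort(abs(dstar[, b]))
    fp[, b] <- length(col_sorted) -
      findInterval(abs(d), col_sorted, left.open = TRUE)
  }
  fp_med <- apply(fp, 1L, stats::median)
  q <- pmin(1, fp_med / obs_ge)
  ord <- order(abs(d), decreasing = TRUE)
  q[ord] <- cummax(q[ord])                        # non-increasing in |d|
  names(p) <- names(q) <- names(d)
  list(p_value = p, q_value = q, d = d, s0 = s0,
       n_assignments = ncol(idx_sets), exhaustive = exhaustive)
}

#' Apply the significance gates to a differential-expression table
#'
#' UP iff `fc_linear >= fc_threshold` and `p <= p_threshold`; DOWN
#' symmetric; otherwise NS. Both thresholds are inclusive.
#'
#' @param de Data frame with at least `fc_linear` and `p_value`.
#' @param params A [de_params()] supplying the thresholds.
#' @return `de` with a `call` column in `{UP, DOWN, NS}`.
#' @export
call_de <- function(de, params = de_params()) {
  sig <- de$p_value <= params$p_threshold
  de$call <- ifelse(sig & de$fc_linear >= params$fc_threshold, "UP",
                    ifelse(sig & de$fc_linear <= -params$fc_threshold,
                           "DOWN", "NS"))
  de
}

#' Run the full differential-expression call for one contrast
#'
#' Computes fold changes, the d-statistic, permutation p/q and the UP/DOWN/NS
#' calls for drought vs control in one tissue and genotype.
#'
#' @inheritParams log2_fold_change
#' @param params A [de_params()].
#' @return Data frame with `gene_id`, `log2fc`, `fc_linear`, `d_stat`,
#'   `p_value`, `q_value`, `call`; attribute `s0` records the fudge factor
#'   used and `exhaustive` whether the permutation null was enumerated.
#' @export
run_de <- function(mat, design, tissue, genotype, params = de_params()) {
  lfc <- log2_fold_change(mat, design, tissue, genotype)
  pq <- permutation_pq(mat, design, tissue, genotype, params)
  de <- data.frame(gene_id = rownames(mat), log2fc = lfc,
                   fc_linear = linear_fold_change(lfc), d_stat = pq$d,
                   p_value = pq$p_value, q_value = pq$q_value,
                   stringsAsFactors = FALSE, row.names = NULL)
  de <- call_de(de, params)
  attr(de, "s0") <- pq$s0
  attr(de, "exhaustive") <- pq$exhaustive
  de
}
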