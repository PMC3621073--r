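#' Relative water content from fresh, turgid and dry weights
#'
#' `RWC = 100 * (FW - DW) / (TW - DW)`, in percent. Unit-invariant (grams
#' vs milligrams). A fully turgid leaf (FW = TW) gives 100; FW = DW gives 0.
#' Weights violating `DW <= FW <= TW` are permitted but flagged with a
#' warning (the result then falls outside [0, 100]).
#'
#' @param fw,tw,dw Fresh, turgid and dry weights (same unit).
#' @return RWC in percent.
#' @export
rwc <- function(fw, tw, dw) {
  if (any(tw == dw)) stop("TW must exceed DW (zero denominator)")
  out <- 100 * (fw - dw) / (tw - dw)
  if (any(fw < dw) || any(fw > tw))
    warning("weights violate DW <= FW <= TW; RWC outside [0, 100]")
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Livak scheme: `dCt = Ct_target - Ct_reference` within each sample,
#' `ddCt = dCt_condition - dCt_control`, relative fold change
#' `2^(-ddCt)`. Reference-gene normalisation (here ubiquitin in the
#' validation assays this mirrors) is the subtraction of the reference Ct.
#'
#' @param ct_target_condition,ct_ref_condition Ct of target and reference
#'   gene in the treated sample.
#' @param ct_target_control,ct_ref_control Ct in the control sample.
#' @return List with `ddct` (cycles) and `fold_change` (`2^-ddct`, > 0).
#' @export
ddct_fold_change <- function(ct_target_condition, ct_ref_condition,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_condition, ct_ref_condition, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (ct_target_condition - ct_ref_condition) -
    (ct_target_control - ct_ref_control)
  list(ddct = ddct, fold_change = 2^(-ddct))
}

#' Post-recovery survival rate
#'
#' @param n_survived,n_total Plant counts, `0 <= n_survived <= n_total`,
#'   `n_total > 0`.
#' @param digits Decimal places of the reported percentage (default 0,
#'   matching whole-percent reporting).
#' @return Survival in percent.
#' @export
survival_rate <- function(n_survived, n_total, digits = 0L) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_survived < 0) || any(n_survived > n_total))
    stop("n_survived must lie in [0, n_total]")
  round_half_up(100 * n_survived / n_total, digits)
}

#' Two-sample Student's t comparison with a significance flag
#'
#' Classical equal-variance two-sample t-test, two-sided, the comparison
#' behind the significance asterisks in physiology figures. Welch's
#' correction is available behind `var_equal = FALSE`. Two groups with zero
#' variance and equal means give `t = 0`, `p = 1` rather than an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05); the flag is `p < alpha`.
#' @param var_equal Pool the variances (default TRUE)?
#' @return List with `t`, `df`, `p_value`, `significant`, and `asterisk`
#'   (`"*"` or `""`).
#' @export
two_sample_t <- function(x, y, alpha = 0.05, var_equal = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(t = 0, df = length(x) + length(y) - 2, p_value = 1)
    } else {
      res <- list(t = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p_value = 0)
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = var_equal)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  res$significant <- res$p_value < alpha
  res$asterisk <- if (res$significant) "*" else ""
  res
}
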