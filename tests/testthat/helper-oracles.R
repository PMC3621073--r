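# Independent oracles used across tests: each is a deliberately naive
# reimplementation kept separate from the package's code paths.

# Sliding-window motif scan by expansion-set membership at every position.
naive_scan <- function(sequence, pattern, strand_policy = "both") {
  words <- iupac_expand(pattern)
  w <- nchar(pattern)
  L <- nchar(sequence)
  if (L < w) return(data.frame(start = integer(0), strand = character(0)))
  starts <- 0:(L - w)
  wins <- substring(sequence, starts + 1L, starts + w)
  fwd <- starts[wins %in% words]
  out <- data.frame(start = fwd, strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (strand_policy == "both") {
    rc_words <- vapply(words, revcomp, character(1), USE.NAMES = FALSE)
    rev <- starts[wins %in% rc_words]
    out <- rbind(out,
                 data.frame(start = rev, strand = rep("-", length(rev)),
                            stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws (feasible for N <= 12).
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K)
  overlaps <- apply(draws, 2L, function(cols) sum(cols %in% in_term))
  mean(overlaps >= k)
}

# Two-group mean difference and pooled SE, recomputed with explicit loops.
loop_log2fc <- function(mat, drought_cols, control_cols) {
  out <- numeric(nrow(mat))
  for (g in seq_len(nrow(mat)))
    out[[g]] <- mean(mat[g, drought_cols]) - mean(mat[g, control_cols])
  out
}

# Small 4-gene x 12-sample single-tissue fixture with exact values.
tiny_dataset <- function() {
  design <- expand.grid(replicate = 1:3,
                        condition = c("CONTROL", "DROUGHT"),
                        genotype = c("WT", "MUT"),
                        stringsAsFactors = FALSE)
  design$tissue <- "LEAF"
  design$sample_id <- sprintf("S%02d", seq_len(nrow(design)))
  design <- design[, c("sample_id", "genotype", "condition", "tissue",
                       "replicate")]
  set.seed(42)
  mat <- matrix(rnorm(4 * 12, mean = 8), nrow = 4,
                dimnames = list(paste0("g", 1:4), design$sample_id))
  list(matrix = mat, design = design)
}
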