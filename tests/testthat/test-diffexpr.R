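make_contrast_matrix <- function(drought_rows, control_rows) {
  # one gene; three replicates per condition, WT LEAF
  d <- tiny_dataset()
  mat <- d$matrix[1, , drop = FALSE]
  cc <- list(drought = d$design$sample_id[d$design$genotype == "WT" &
                                            d$design$condition == "DROUGHT"],
             control = d$design$sample_id[d$design$genotype == "WT" &
                                            d$design$condition == "CONTROL"])
  mat[1, cc$drought] <- drought_rows
  mat[1, cc$control] <- control_rows
  list(matrix = mat, design = d$design)
}

test_that("log2 fold change is exact mean-difference arithmetic", {
  d <- make_contrast_matrix(c(9, 9, 9), c(8, 8, 8))
  fc <- log2_fold_change(d$matrix, d$design, "LEAF", "WT")
  expect_equal(unname(fc[1]), 1)
  expect_equal(linear_fold_change(1), 2)
  expect_equal(linear_fold_change(0), 1)
  expect_equal(linear_fold_change(-1), -2)

  d0 <- make_contrast_matrix(c(5, 6, 7), c(7, 6, 5))
  expect_equal(unname(log2_fold_change(d0$matrix, d0$design, "LEAF", "WT")[1]),
               0)
})

test_that("fold changes match an independent two-loop recomputation", {
  set.seed(31)
  d <- tiny_dataset()
  mat <- matrix(rnorm(50 * 12, 8), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), d$design$sample_id))
  fc <- log2_fold_change(mat, d$design, "LEAF", "MUT")
  dcols <- d$design$sample_id[d$design$genotype == "MUT" &
                                d$design$condition == "DROUGHT"]
  ccols <- d$design$sample_id[d$design$genotype == "MUT" &
                                d$design$condition == "CONTROL"]
  expect_equal(unname(fc), loop_log2fc(mat, dcols, ccols))
})

test_that("d-statistic matches the pooled-SE hand computation", {
  d <- make_contrast_matrix(c(1, 2, 3), c(3, 4, 5))
  dd <- sam_d_statistic(d$matrix, d$design, "LEAF", "WT", s0 = 0)
  # pooled SE = sqrt(1 * (1/3 + 1/3)) = 0.8165; d = -2/0.8165 = -2.449
  expect_equal(unname(dd[1]), -2 / sqrt(2 / 3), tolerance = 1e-12)

  equal <- make_contrast_matrix(c(1, 2, 3), c(2, 2, 2))
  expect_equal(unname(sam_d_statistic(equal$matrix, equal$design, "LEAF",
                                      "WT", s0 = 5)[1]), 0)

  # |d| is monotonically decreasing in s0
  s0s <- c(0, 0.1, 0.5, 1, 2)
  vals <- vapply(s0s, function(s)
    abs(unname(sam_d_statistic(d$matrix, d$design, "LEAF", "WT", s0 = s)[1])),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("zero variance with s0 = 0 gives an infinite flag, never NaN", {
  d <- make_contrast_matrix(c(9, 9, 9), c(8, 8, 8))
  dd <- sam_d_statistic(d$matrix, d$design, "LEAF", "WT", s0 = 0)
  expect_identical(unname(dd[1]), Inf)
  d0 <- make_contrast_matrix(c(8, 8, 8), c(8, 8, 8))
  expect_identical(unname(sam_d_statistic(d0$matrix, d0$design, "LEAF", "WT",
                                          s0 = 0)[1]), 0)
})

test_that("3v3 permutations enumerate all 20 assignments exactly", {
  cfg <- sim_config(n_genes = 30, tissues = "LEAF", seed = 14)
  sim <- simulate_expression(cfg)
  pq <- permutation_pq(sim$matrix, sim$design, "LEAF", "WT")
  expect_true(pq$exhaustive)
  expect_equal(pq$n_assignments, choose(6, 3))
  # p values lie on the smoothed grid k/(1 + 20 * n_genes)
  n_pool <- 20L * 30L
  expect_true(all(abs(pq$p_value * (1 + n_pool) -
                        round(pq$p_value * (1 + n_pool))) < 1e-9))
  expect_true(all(pq$p_value > 0 & pq$p_value <= 1))
  # determinism
  pq2 <- permutation_pq(sim$matrix, sim$design, "LEAF", "WT")
  expect_identical(pq$p_value, pq2$p_value)
})

test_that("a gene with d = 0 has p = 1 within smoothing", {
  d <- tiny_dataset()
  mat <- d$matrix
  mat[2, ] <- 8                      # flat gene: d exactly 0
  pq <- permutation_pq(mat, d$design, "LEAF", "WT")
  expect_equal(pq$p_value[["g2"]], 1)
})

test_that("null data give ~5% of genes at p <= 0.05 and uniform p", {
  cfg <- sim_config(n_genes = 1000, tissues = "LEAF",
                    class_fractions = c(dep_pos = 0, dep_neg = 0,
                                        indep_up = 0, indep_down = 0,
                                        null = 1), seed = 15)
  sim <- simulate_expression(cfg)
  pq <- permutation_pq(sim$matrix, sim$design, "LEAF", "WT")
  expect_lt(abs(mean(pq$p_value <= 0.05) - 0.05), 0.02)
  ks <- suppressWarnings(stats::ks.test(pq$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("significance gates are inclusive and partition all genes", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   fc_linear = c(2.0, 1.99, -2.5, 3),
                   p_value = c(0.05, 0.001, 0.04, 0.051))
  called <- call_de(de, de_params())
  expect_equal(called$call, c("UP", "NS", "DOWN", "NS"))
  expect_true(all(called$call %in% c("UP", "DOWN", "NS")))
})

test_that("q-values are non-increasing in |d| and within [0, 1]", {
  cfg <- sim_config(n_genes = 300, tissues = "LEAF", seed = 16)
  sim <- simulate_expression(cfg)
  pq <- permutation_pq(sim$matrix, sim$design, "LEAF", "WT")
  ord <- order(abs(pq$d), decreasing = TRUE)
  expect_true(all(diff(pq$q_value[ord]) >= 0))
  expect_true(all(pq$q_value >= 0 & pq$q_value <= 1))
  # strongly responsive genes should have much smaller q than flat genes
  dep <- sim$truth$class %in% c("dep_pos", "dep_neg")
  expect_lt(stats::median(pq$q_value[dep]),
            stats::median(pq$q_value[sim$truth$class == "null"]))
})
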