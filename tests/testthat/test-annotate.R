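test_that("three-set Venn regions match exhaustive membership enumeration", {
  A <- c("1", "2", "3"); B <- c("2", "3", "4"); C <- c("3", "4", "5")
  v <- venn3(as.character(1:5), A, B, C)
  counts <- setNames(v$count, v$region)
  expect_equal(unname(counts[c("A", "B", "C")]), c(1L, 0L, 1L))
  expect_equal(unname(counts[c("A&B", "A&C", "B&C")]), c(1L, 0L, 1L))
  expect_equal(unname(counts[["A&B&C"]]), 1L)
  expect_equal(sum(v$count[v$region != "outside"]), 5L)

  # disjoint sets: all multi-set regions zero
  vd <- venn3(as.character(1:6), "1", "2", "3")
  expect_true(all(vd$count[grepl("&", vd$region)] == 0L))
  expect_equal(vd$count[vd$region == "outside"], 3L)

  # identical sets: everything in the triple region
  vi <- venn3(c("x", "y"), c("x", "y"), c("x", "y"), c("x", "y"))
  expect_equal(vi$count[vi$region == "A&B&C"], 2L)
  expect_equal(sum(vi$count) - vi$count[vi$region == "A&B&C"], 0L)
})

test_that("class-by-set percentages reproduce the reporting convention", {
  # 35 hormone-annotated genes in a class, 14 of them ABA -> 40.0%;
  # a second class with 39 annotated, 11 auxin (28.2%), 8 BR (20.5%)
  pos <- sprintf("p%02d", 1:35)
  neg <- sprintf("n%02d", 1:39)
  sets <- list(abscisic = pos[1:14], auxin = neg[1:11],
               brassinosteroid = neg[12:19],
               other = c(pos[15:35], neg[20:39]))
  gsc <- gene_set_collection(sets, universe = c(pos, neg))
  classes <- data.frame(gene_id = c(pos, neg),
                        class = rep(c("CDPRG", "CDNRG"), c(35, 39)))
  ct <- crosstab_classes(classes, gsc)
  get <- function(cl, s) ct[ct$class == cl & ct$set == s, ]
  expect_equal(get("CDPRG", "abscisic")$n_members, 14L)
  expect_equal(get("CDPRG", "abscisic")$percent, 40.0)
  expect_equal(get("CDNRG", "auxin")$percent, 28.2)
  expect_equal(get("CDNRG", "brassinosteroid")$percent, 20.5)

  # empty class yields a zero row, genes outside universe warn
  classes_empty <- data.frame(gene_id = pos, class = "CDPRG")
  ct2 <- crosstab_classes(classes_empty, gsc)
  expect_true(all(ct2$n_members[ct2$set == "auxin"] == 0L))
  stray <- rbind(classes, data.frame(gene_id = "zz", class = "CDPRG"))
  expect_warning(crosstab_classes(stray, gsc), "unannotated")
})

test_that("hypergeometric p matches direct and exhaustive enumeration", {
  # N=10, K=5, n=4, k=4 -> C(5,4) C(5,0) / C(10,4) = 5/210
  gsc <- gene_set_collection(list(term = as.character(1:5)),
                             universe = as.character(1:10))
  res <- fisher_enrichment(as.character(2:5), gsc)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  # closed form equals exhaustive draw enumeration for all tables N <= 12
  for (N in c(6L, 9L, 12L)) {
    for (K in c(2L, N %/% 2)) {
      for (n in c(2L, N %/% 3 + 1L)) {
        universe <- as.character(seq_len(N))
        gsc <- gene_set_collection(list(t = universe[seq_len(K)]), universe)
        for (k in 0:min(K, n)) {
          if (n - k > N - K) next
          query <- c(universe[seq_len(k)],
                     universe[K + seq_len(n - k)])
          res <- fisher_enrichment(query, gsc)
          expect_equal(res$p_value, enum_hyper_tail(N, K, n, k),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("degenerate enrichment inputs are handled as specified", {
  gsc <- gene_set_collection(list(t = c("a", "b")),
                             universe = c("a", "b", "c"))
  res <- fisher_enrichment(character(0), gsc)     # k = 0, n = 0
  expect_equal(res$p_value, 1)
  expect_true(is.finite(res$odds_ratio))          # 0.5-corrected table
  expect_error(fisher_enrichment("zz", gsc), "outside the universe")
  expect_error(fisher_enrichment("a", gene_set_collection(
    list(t = character(0)), universe = character(0))), "empty universe")
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("BY adjustment matches the hand-computed step-up", {
  expect_equal(adjust_by(0.2), 0.2)               # c(1) = 1
  # m=3, c(m) = 11/6: raw BY = (0.055, 0.055, 0.055)
  expect_equal(adjust_by(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  expect_error(adjust_by(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_by(c(0.5, 1.2)), "\\(0, 1\\]")

  # BY dominates BH for every input
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_true(all(adjust_by(p) >= stats::p.adjust(p, "BH") - 1e-12))
  }
})

test_that("enrichment is invariant to gene relabeling", {
  set.seed(43)
  universe <- sprintf("g%03d", 1:60)
  gsc <- gene_set_collection(list(t1 = universe[1:20],
                                  t2 = universe[15:40]), universe)
  query <- universe[c(1:10, 30:35)]
  res <- fisher_enrichment(query, gsc)

  perm <- setNames(sample(universe), universe)    # random relabeling
  gsc_p <- gene_set_collection(lapply(gsc$sets, function(s) unname(perm[s])),
                               unname(perm[universe]))
  res_p <- fisher_enrichment(unname(perm[query]), gsc_p)
  expect_equal(res_p$p_value, res$p_value)
  expect_equal(res_p$k, res$k)
})

test_that("a planted enriched set attains the smallest adjusted p", {
  cfg <- sim_config(n_genes = 2000, tissues = "LEAF", seed = 44)
  sim <- simulate_expression(cfg)
  gsc <- simulate_gene_sets(cfg, sim$truth)
  dep <- sim$truth$gene_id[sim$truth$class %in% c("dep_pos", "dep_neg")]
  res <- fisher_enrichment(dep, gsc)
  # "drought" recruits responsive classes at 0.30 vs 0.02 background
  expect_equal(res$term[which.min(res$p_adjusted)], "drought")
})
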