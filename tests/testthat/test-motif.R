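test_that("IUPAC expansion enumerates the CAMTA motifs correctly", {
  expect_equal(iupac_expand("A"), "A")
  expect_setequal(iupac_expand("MCGTGT"), c("ACGTGT", "CCGTGT"))
  # nested-loop enumeration oracle for MCGCGB: {A,C} x {C,G,T}
  oracle <- character(0)
  for (first in c("A", "C")) for (last in c("C", "G", "T"))
    oracle <- c(oracle, paste0(first, "CGCG", last))
  expect_setequal(iupac_expand("MCGCGB"), oracle)
  expect_length(iupac_expand("MCGCGB"), 6L)
  expect_length(iupac_expand("NN"), 16L)
  expect_error(iupac_expand("ACGJ"), "J")
})

test_that("reverse complement handles IUPAC symbols", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AACC"), "GGTT")
  expect_equal(revcomp("MCGCGB"), "VCGCGK")
  # involution on random words
  set.seed(1)
  for (i in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T", "N", "M", "B"), 8, TRUE),
               collapse = "")
    expect_equal(revcomp(revcomp(w)), w)
  }
})

test_that("scanner finds the ABRE word and respects strand policy", {
  hits <- scan_sequence("ACGTGT", "MCGTGT", strand_policy = "forward")
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 6L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$match, "ACGTGT")

  expect_equal(nrow(scan_sequence(strrep("A", 100), "MCGTGT", "b", "both")),
               0L)
  expect_equal(nrow(scan_sequence("ACG", "MCGTGT")), 0L)  # shorter than motif

  # 60-mer with planted forward matches at 5 and 20 plus one
  # reverse-complement instance at 40
  s <- strrep("A", 60)
  substr(s, 6, 11) <- "ACGTGT"
  substr(s, 21, 26) <- "CCGTGT"
  substr(s, 41, 46) <- revcomp("ACGTGT")
  fwd <- scan_sequence(s, "MCGTGT", strand_policy = "forward")
  both <- scan_sequence(s, "MCGTGT", strand_policy = "both")
  expect_equal(fwd$start, c(5L, 20L))
  expect_equal(both$start, c(5L, 20L, 40L))
  expect_equal(both$strand, c("+", "+", "-"))
})

test_that("N in the sequence matches no motif symbol", {
  expect_equal(nrow(scan_sequence("ACGTGN", "MCGTGT", strand_policy = "both")),
               0L)
  expect_equal(nrow(scan_sequence("NNNNNN", "NNNNNN", strand_policy = "both")),
               0L)
})

test_that("overlapping occurrences are all reported", {
  # "ACA" occurs at starts 0 and 2 in "ACACA", sharing position 2; a
  # consuming regex search would report only the first
  hits <- scan_sequence("ACACA", "ACA", strand_policy = "forward")
  expect_equal(hits$start, c(0L, 2L))
  # both-strand scan of a palindromic word reports both strands per site
  pal <- scan_sequence("ACGT", "ACGT", strand_policy = "both")
  expect_equal(nrow(pal), 2L)
  expect_setequal(pal$strand, c("+", "-"))
})

test_that("scan equals the naive expansion-membership oracle", {
  set.seed(33)
  motifs <- camta_motifs()
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200, TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    for (m in motifs) {
      got <- scan_sequence(s, m, strand_policy = "both")
      want <- naive_scan(s, m, "both")
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("strand - scan equals forward scan of the reverse complement", {
  set.seed(34)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    for (m in camta_motifs()) {
      minus <- scan_sequence(s, m, strand_policy = "both")
      minus <- minus[minus$strand == "-", ]
      fwd_rc <- scan_sequence(revcomp(s), m, strand_policy = "forward")
      w <- nchar(m)
      expect_setequal(minus$start, 150 - (fwd_rc$start + w))
    }
  }
})

test_that("per-class frequencies follow the percentage arithmetic", {
  genes <- sprintf("g%02d", 1:10)
  promoters <- setNames(rep(strrep("A", 50), 10), genes)
  # give genes 1..3 one MCGTGT hit each
  for (g in genes[1:3]) {
    s <- promoters[[g]]; substr(s, 11, 16) <- "ACGTGT"; promoters[[g]] <- s
  }
  hits <- scan_promoters(promoters, camta_motifs(), "both")
  classes <- data.frame(gene_id = genes, class = "CDPRG")
  mf <- motif_gene_frequency(hits, promoters, classes)
  row <- mf$frequency[mf$frequency$motif == "MCGTGT", ]
  expect_equal(row$n_with_hit, 3L)
  expect_equal(row$frequency, 30.0)
  expect_true(all(mf$frequency$frequency >= 0 &
                    mf$frequency$frequency <= 100, na.rm = TRUE))

  # all genes hit -> 100%; empty class -> NA
  classes2 <- data.frame(gene_id = genes[1:3], class = "CDPRG")
  mf2 <- motif_gene_frequency(hits, promoters[1:3], classes2)
  expect_equal(mf2$frequency$frequency[mf2$frequency$motif == "MCGTGT"], 100)
  # frequency invariant to gene order
  shuffled <- classes[sample(nrow(classes)), ]
  mf3 <- motif_gene_frequency(hits, promoters, shuffled)
  expect_equal(mf3$frequency$frequency, mf$frequency$frequency)
})

test_that("planted per-gene probability is recovered as a frequency", {
  cfg <- sim_config(n_genes = 1000, promoter_length = 150, plant_prob = 0.4,
                    seed = 35)
  prom <- simulate_promoters(cfg)
  hits <- scan_promoters(prom$promoters, camta_motifs(), "both")
  classes <- data.frame(gene_id = names(prom$promoters), class = "ALL")
  mf <- motif_gene_frequency(hits, prom$promoters, classes)
  bounds <- 100 * qbinom(c(0.005, 0.995), 1000, 0.4) / 1000
  for (f in mf$frequency$frequency) {
    expect_gte(f, bounds[1])
    expect_lte(f, bounds[2])
  }
})

test_that("half-up rounding matches the reporting convention", {
  expect_equal(round_half_up(28.15, 1), 28.2)
  expect_equal(round_half_up(20.45, 1), 20.5)
  expect_equal(round_half_up(-28.15, 1), -28.2)
  expect_equal(round_half_up(40, 1), 40)
})
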