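#' Simulation configuration for the factorial drought experiment
#'
#' Defaults mirror the study design the package targets: 3 biological
#' replicates per genotype-by-condition cell in each of two tissues
#' (3 x 2 x 2 = 12 arrays per tissue), log2-scale intensities with additive
#' Gaussian noise, a drought effect of 2 log2 units in the wild type that is
#' multiplied by a per-gene attenuation coefficient kappa in the mutant, and
#' 1000-bp promoters.
#'
#' @param n_genes Number of genes.
#' @param n_reps Biological replicates per design cell.
#' @param tissues Tissues to simulate (`"LEAF"`, `"ROOT"` or both).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity
#'   distribution.
#' @param effect_size Absolute drought effect delta in wild type, log2 units.
#' @param noise_sd Residual standard deviation sigma, log2 units.
#' @param class_fractions Named fractions for `dep_pos`, `dep_neg`,
#'   `indep_up`, `indep_down`, `null`; must sum to 1.
#' @param attenuation Kappa in `[0, 1]` applied to the drought effect of
#'   dependent genes in the mutant (0 = response abolished).
#' @param promoter_length Promoter length in bp.
#' @param plant_prob Per-gene, per-motif probability of one planted motif
#'   instance.
#' @param gc_fraction GC content of background promoter sequence.
#' @param seed Integer seed; expression, promoters and gene sets use
#'   independent streams derived from it (seed, seed + 1, seed + 2).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_reps = 3L,
                       tissues = c("LEAF", "ROOT"),
                       baseline_mean = 8, baseline_sd = 2,
                       effect_size = 2, noise_sd = 0.25,
                       class_fractions = c(dep_pos = 0.11, dep_neg = 0.11,
                                           indep_up = 0.04, indep_down = 0.04,
                                           null = 0.70),
                       attenuation = 0, promoter_length = 1000L,
                       plant_prob = 0.4, gc_fraction = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1L, n_reps >= 2L, noise_sd >= 0,
            attenuation >= 0, attenuation <= 1,
            promoter_length >= 6L, gc_fraction > 0, gc_fraction < 1,
            plant_prob >= 0, plant_prob <= 1)
  tissues <- match.arg(tissues, c("LEAF", "ROOT"), several.ok = TRUE)
  needed <- c("dep_pos", "dep_neg", "indep_up", "indep_down", "null")
  if (!all(needed %in% names(class_fractions)))
    stop("class_fractions must name: ", paste(needed, collapse = ", "))
  class_fractions <- class_fractions[needed]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 tissues = tissues, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, effect_size = effect_size,
                 noise_sd = noise_sd, class_fractions = class_fractions,
                 attenuation = attenuation,
                 promoter_length = as.integer(promoter_length),
                 plant_prob = plant_prob, gc_fraction = gc_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_classes <- function(config) {
  fr <- config$class_fractions
  n <- config$n_genes
  counts <- floor(fr * n)
  # distribute the rounding remainder by largest fractional part
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- fr * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  rep(names(fr), times = counts)
}

#' Simulate a factorial expression dataset with known ground truth
#'
#' Generative model on the log2 scale:
#' `x = b_g + delta_g * [drought] * (kappa_g if genotype = MUT else 1) + eps`,
#' `eps ~ Normal(0, sigma^2)`. Dependent genes carry `kappa_g = attenuation`
#' (default 0), independent drought-responsive genes `kappa_g = 1`, null
#' genes `delta_g = 0`. `dep_pos`/`indep_up` genes have `delta_g =
#' +effect_size`, `dep_neg`/`indep_down` have `-effect_size`. Output is
#' bit-identical for identical config and seed.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (genes x samples), `design` (data frame) and
#'   `truth` (data frame: `gene_id`, `class`, `delta`, `kappa`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  cls <- sim_classes(config)
  delta <- ifelse(cls %in% c("dep_pos", "indep_up"), config$effect_size,
                  ifelse(cls %in% c("dep_neg", "indep_down"),
                         -config$effect_size, 0))
  kappa <- ifelse(cls %in% c("dep_pos", "dep_neg"), config$attenuation,
                  ifelse(cls %in% c("indep_up", "indep_down"), 1, 1))
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)

  design <- expand.grid(replicate = seq_len(config$n_reps),
                        condition = c("CONTROL", "DROUGHT"),
                        genotype = c("WT", "MUT"),
                        tissue = config$tissues,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_%s_r%d",
                              substr(design$tissue, 1, 1),
                              ifelse(design$genotype == "WT", "WT", "M1"),
                              substr(design$condition, 1, 1),
                              design$replicate)
  design <- design[, c("sample_id", "genotype", "condition", "tissue",
                       "replicate")]

  mat <- matrix(0, nrow = n, ncol = nrow(design),
                dimnames = list(gene_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    drought <- design$condition[[j]] == "DROUGHT"
    mut <- design$genotype[[j]] == "MUT"
    mu <- baseline + delta * drought * (if (mut) kappa else 1)
    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd)
             else 0
    mat[, j] <- mu + noise
  }
  truth <- data.frame(gene_id = gene_ids, class = cls, delta = delta,
                      kappa = kappa, stringsAsFactors = FALSE)
  list(matrix = mat, design = design, truth = truth)
}

#' Simulate promoter sequences with planted motif instances
#'
#' Each gene receives a `promoter_length`-bp sequence. With probability
#' `plant_prob` per motif, one concrete expansion of the motif is planted at
#' a uniformly chosen position and strand without overlapping other planted
#' instances. With `clean_background = TRUE` (default) the background is
#' rejection-resampled locally until it contains no accidental match to any
#' of the motifs on either strand, so the planted coordinates are the
#' complete ground truth.
#'
#' @param config A [sim_config()].
#' @param truth Expression truth data frame (supplies gene ids); optional,
#'   gene ids are regenerated from `config` when `NULL`.
#' @param motifs Named character vector of IUPAC patterns to plant/avoid.
#' @param clean_background Scrub accidental matches from background sequence?
#' @return List with `promoters` (named character vector) and `planted`
#'   (data frame: `gene_id`, `motif`, `start` 0-based, `strand`, `word`).
#' @export
simulate_promoters <- function(config, truth = NULL, motifs = camta_motifs(),
                               clean_background = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  widths <- nchar(motifs)
  if (config$promoter_length < max(widths))
    stop("promoter_length shorter than the widest motif")
  set.seed(config$seed + 1L)
  gene_ids <- if (is.null(truth)) sprintf("g%04d", seq_len(config$n_genes))
              else truth$gene_id
  L <- config$promoter_length
  gc <- config$gc_fraction
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  # plant only words that are unambiguous under both-strand scanning: the
  # word must match no other motif in the set, and its reverse complement
  # must match none of them (some CGCG-box expansions are palindromic or
  # map onto other expansions, which would create a second hit at the same
  # position on the opposite strand)
  all_words <- lapply(motifs, iupac_expand)
  words <- lapply(names(motifs), function(m) {
    w <- all_words[[m]]
    others <- unlist(all_words[setdiff(names(motifs), m)])
    keep <- !(vapply(w, revcomp, character(1)) %in% unlist(all_words)) &
      !(w %in% others)
    if (!any(keep))
      stop("motif ", m, " has no strand-unambiguous expansion to plant")
    w[keep]
  })
  names(words) <- names(motifs)

  planted <- vector("list", length(gene_ids))
  promoters <- character(length(gene_ids))
  for (i in seq_along(gene_ids)) {
    # decide planted instances first so placement cannot collide
    plant <- names(motifs)[stats::runif(length(motifs)) < config$plant_prob]
    spots <- data.frame(motif = character(0), start = integer(0),
                        strand = character(0), word = character(0),
                        stringsAsFactors = FALSE)
    occupied <- integer(0)
    for (m in plant) {
      w <- widths[[m]]
      for (try in 1:200) {
        s <- sample.int(L - w + 1L, 1L) - 1L      # 0-based
        if (!any((s:(s + w - 1L)) %in% occupied)) break
        s <- NA_integer_
      }
      if (is.na(s)) stop("cannot place planted instances in promoter_length")
      strand <- sample(c("+", "-"), 1L)
      word <- sample(words[[m]], 1L)
      occupied <- c(occupied, s:(s + w - 1L))
      spots <- rbind(spots, data.frame(motif = m, start = s, strand = strand,
                                       word = word, stringsAsFactors = FALSE))
    }
    seq_chars <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
    seqstr <- paste(seq_chars, collapse = "")
    if (clean_background)
      seqstr <- scrub_matches(seqstr, motifs, base_prob)
    # overwrite with planted words (forward-strand text of the instance)
    if (nrow(spots) > 0L) {
      for (k in seq_len(nrow(spots))) {
        txt <- if (spots$strand[[k]] == "+") spots$word[[k]]
               else revcomp(spots$word[[k]])
        substr(seqstr, spots$start[[k]] + 1L,
               spots$start[[k]] + nchar(txt)) <- txt
      }
      # planting can create new accidental matches at junctions; scrub
      # everything outside the planted footprints
      if (clean_background)
        seqstr <- scrub_matches(seqstr, motifs, base_prob, keep = occupied)
    }
    promoters[[i]] <- seqstr
    if (nrow(spots) > 0L) spots$gene_id <- gene_ids[[i]]
    planted[[i]] <- spots
  }
  names(promoters) <- gene_ids
  planted <- do.call(rbind, planted[vapply(planted, nrow, integer(1)) > 0L])
  if (is.null(planted))
    planted <- data.frame(gene_id = character(0), motif = character(0),
                          start = integer(0), strand = character(0),
                          word = character(0), stringsAsFactors = FALSE)
  else
    planted <- planted[, c("gene_id", "motif", "start", "strand", "word")]
  rownames(planted) <- NULL
  list(promoters = promoters, planted = planted)
}

# Resample bases of accidental motif matches (both strands) until none
# remain, never touching positions in `keep` (0-based).
scrub_matches <- function(seqstr, motifs, base_prob, keep = integer(0)) {
  for (iter in 1:100) {
    hits <- do.call(rbind, lapply(names(motifs), function(m)
      scan_sequence(seqstr, motifs[[m]], name = m, strand_policy = "both")))
    if (!is.null(hits) && nrow(hits) > 0L) {
      pos <- unique(unlist(mapply(function(s, e) s:(e - 1L),
                                  hits$start, hits$end, SIMPLIFY = FALSE)))
      pos <- setdiff(pos, keep)
      if (length(pos) == 0L) return(seqstr)  # all remaining hits are planted
      repl <- sample(names(base_prob), length(pos), replace = TRUE,
                     prob = base_prob)
      chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
      chars[pos + 1L] <- repl
      seqstr <- paste(chars, collapse = "")
    } else return(seqstr)
  }
  stop("background scrubbing did not converge")
}

#' Simulate annotation gene sets with class-dependent membership rates
#'
#' Each named set samples genes independently: a gene of truth class `c`
#' joins set `s` with probability `rates[[s]][c]`. Defaults emulate stress
#' (drought/cold/salt), hormone and TF-family annotation lists, with
#' drought-responsive classes enriched in the stress sets.
#'
#' @param config A [sim_config()].
#' @param truth Expression truth data frame.
#' @param rates Named list; each element is a named numeric vector of
#'   per-class inclusion probabilities in `[0, 1]` (classes absent from the
#'   vector default to 0).
#' @return A gene-set collection (universe = all simulated genes) whose
#'   membership is itself the ground truth.
#' @export
simulate_gene_sets <- function(config, truth, rates = default_set_rates()) {
  stopifnot(inherits(config, "sim_config"))
  bad <- unlist(rates) < 0 | unlist(rates) > 1
  if (any(bad)) stop("membership rates must lie in [0, 1]")
  set.seed(config$seed + 2L)
  sets <- lapply(rates, function(r) {
    p <- r[truth$class]
    p[is.na(p)] <- 0
    truth$gene_id[stats::runif(nrow(truth)) < p]
  })
  gene_set_collection(sets, universe = truth$gene_id)
}

#' Default class-dependent membership rates for simulated gene sets
#'
#' Stress sets preferentially recruit drought-responsive genes (dependent or
#' not); hormone and TF-family sets are sampled at a flat background rate so
#' enrichment analyses have unenriched terms to rank against.
#'
#' @return Named list of per-class rate vectors.
#' @export
default_set_rates <- function() {
  responsive <- c(dep_pos = 0.30, dep_neg = 0.30, indep_up = 0.30,
                  indep_down = 0.30, null = 0.02)
  flat <- c(dep_pos = 0.05, dep_neg = 0.05, indep_up = 0.05,
            indep_down = 0.05, null = 0.05)
  list(drought = responsive,
       cold = c(dep_pos = 0.15, dep_neg = 0.15, indep_up = 0.15,
                indep_down = 0.15, null = 0.03),
       salt = c(dep_pos = 0.15, dep_neg = 0.15, indep_up = 0.15,
                indep_down = 0.15, null = 0.03),
       abscisic = c(dep_pos = 0.10, dep_neg = 0.02, indep_up = 0.05,
                    indep_down = 0.02, null = 0.02),
       auxin = flat, ethylene = flat, gibberellin = flat,
       brassinosteroid = flat, jasmonic = flat, salicylic = flat,
       cytokinin = flat,
       `AP2-EREBP` = flat, MYB = flat, WRKY = flat, bHLH = flat)
}
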