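#' Read a normalized expression matrix and its experiment design
#'
#' The matrix file is TSV with a header row of sample ids and gene ids in the
#' first column; values are normalized log2 intensities. The design file is
#' TSV with columns `sample_id`, `genotype` (`WT`/`MUT`), `condition`
#' (`CONTROL`/`DROUGHT`), `tissue` (`LEAF`/`ROOT`) and `replicate`. Both are
#' validated strictly: the two sample universes must match exactly, every
#' genotype-by-condition cell present in a tissue must have at least two
#' replicates (required by the d-statistic), and each tissue must carry all
#' four genotype-by-condition cells.
#'
#' @param path_matrix Path to the TSV expression matrix.
#' @param path_design Path to the TSV design table.
#' @return A list with components `matrix` (numeric matrix, genes x samples,
#'   dimnames set) and `design` (data frame, one row per sample, in matrix
#'   column order).
#' @export
read_expression <- function(path_matrix, path_design) {
  raw <- utils::read.delim(path_matrix, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(raw) < 2L)
    stop("expression matrix must have gene ids plus at least one sample column")
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids in expression matrix: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids in expression matrix: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  dimnames(num) <- list(gene_ids, sample_ids)

  design <- read_design(path_design)
  validate_expression(num, design)
  design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  list(matrix = num, design = design)
}

#' Read and validate an experiment design table
#'
#' @param path Path to a TSV with columns `sample_id`, `genotype`,
#'   `condition`, `tissue`, `replicate`.
#' @return Validated design data frame.
#' @export
read_design <- function(path) {
  design <- utils::read.delim(path, header = TRUE, sep = "\t",
                              colClasses = "character", quote = "")
  needed <- c("sample_id", "genotype", "condition", "tissue", "replicate")
  missing_cols <- setdiff(needed, colnames(design))
  if (length(missing_cols) > 0L)
    stop("design table missing columns: ", paste(missing_cols, collapse = ", "))
  design <- design[, needed]
  design$replicate <- suppressWarnings(as.integer(design$replicate))
  validate_design(design)
  design
}

#' Validate an experiment design data frame
#'
#' @param design Data frame with `sample_id`, `genotype`, `condition`,
#'   `tissue`, `replicate`.
#' @return The design, invisibly, after validation.
#' @export
validate_design <- function(design) {
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample ids in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  if (!all(design$genotype %in% c("WT", "MUT")))
    stop("genotype must be one of WT, MUT")
  if (!all(design$condition %in% c("CONTROL", "DROUGHT")))
    stop("condition must be one of CONTROL, DROUGHT")
  if (!all(design$tissue %in% c("LEAF", "ROOT")))
    stop("tissue must be one of LEAF, ROOT")
  if (anyNA(design$replicate) || any(design$replicate < 1L))
    stop("replicate must be a positive integer")
  for (tis in unique(design$tissue)) {
    sub <- design[design$tissue == tis, ]
    cells <- table(sub$genotype, sub$condition)
    if (!all(dim(cells) == c(2L, 2L)))
      stop(sprintf("tissue %s: all four genotype x condition cells required",
                   tis))
    if (any(cells < 2L))
      stop(sprintf("tissue %s: every design cell needs >= 2 replicates", tis))
  }
  invisible(design)
}

validate_expression <- function(mat, design) {
  extra <- setdiff(colnames(mat), design$sample_id)
  if (length(extra) > 0L)
    stop("sample(s) in matrix absent from design: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(design$sample_id, colnames(mat))
  if (length(absent) > 0L)
    stop("sample(s) in design absent from matrix: ",
         paste(absent, collapse = ", "))
  if (nrow(mat) == 0L) stop("expression matrix has no genes")
  if (any(!is.finite(mat))) stop("expression matrix has non-finite values")
  invisible(mat)
}

#' Write an expression matrix and design to TSV
#'
#' Inverse of [read_expression()]: round-trips losslessly on valid data.
#'
#' @param mat Numeric matrix, genes x samples, dimnames set.
#' @param design Design data frame.
#' @param path_matrix,path_design Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(mat, design, path_matrix, path_design) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path_matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design, path_design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_matrix, path_design))
}

#' Read promoter sequences from a FASTA file
#'
#' Record ids (token before the first whitespace) are gene ids. Sequences are
#' uppercased; only A/C/G/T/N are accepted; duplicate ids are fatal.
#'
#' @param path Path to a FASTA file of promoter sequences (nominally 1000 bp
#'   upstream regions, one per gene).
#' @return Named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate promoter id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("invalid character(s) outside {A,C,G,T,N} in record(s): ",
         paste(ids[bad], collapse = ", "))
  out
}

#' Write promoter sequences to FASTA
#'
#' @param promoters Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters)
  names(x) <- names(promoters)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Lines with fewer than three fields are fatal (a set must have at least one
#' member).
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector of background gene ids; defaults
#'   to the union of all members.
#' @return A list with components `sets` (named list of character vectors)
#'   and `universe` (character vector).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                   i, length(fields)))
    nms[[i]] <- fields[[1L]]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  gene_set_collection(sets, universe)
}

#' Construct a validated gene-set collection
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Background gene ids; defaults to the union of all members.
#'   Every set member must belong to the universe.
#' @return List with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) universe <- members
  stray <- setdiff(members, universe)
  if (length(stray) > 0L)
    stop("set member(s) outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  list(sets = lapply(sets, unique), universe = unique(universe))
}

#' Write a gene-set collection to GMT
#'
#' @param gsc Gene-set collection from [gene_set_collection()] or
#'   [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, nm, gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write result tables to a directory with a manifest
#'
#' Every table is written as an unquoted TSV with stable column order. A
#' table named `motif_hits` is written BED-like (gene_id, start, end,
#' motif_name, strand; 0-based half-open coordinates). The returned manifest
#' lists one row per file written.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Data frame manifest with columns `table`, `file`, `n_rows`.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  stopifnot(is.list(tables), !is.null(names(tables)))
  files <- character(length(tables))
  for (i in seq_along(tables)) {
    nm <- names(tables)[[i]]
    tab <- tables[[i]]
    if (identical(nm, "motif_hits")) tab <- hits_to_bed(tab)
    file <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[i]] <- file
  }
  data.frame(table = names(tables), file = files,
             n_rows = vapply(tables, nrow, integer(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

hits_to_bed <- function(hits) {
  data.frame(gene_id = hits$gene_id, start = hits$start, end = hits$end,
             motif_name = hits$motif, strand = hits$strand,
             stringsAsFactors = FALSE)
}
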