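#' Convert read counts to FPKM
#'
#' FPKM(g, s) = count(g, s) * 1e9 / (length(g) * librarySize(s)), with the
#' library size taken as the column sum of assigned counts, so the result
#' is self-contained and invariant to proportional rescaling of a sample's
#' counts.
#'
#' @param counts A `counts_table` from [read_counts()] or an integer matrix.
#' @param lengths Named vector of gene lengths in bp; defaults to the
#'   lengths carried by the `counts_table`.
#' @return Numeric matrix of FPKM values (genes x samples) with attribute
#'   `library_sizes`.
#' @export
compute_fpkm <- function(counts, lengths = NULL) {
  if (inherits(counts, "counts_table")) {
    if (is.null(lengths)) lengths <- counts$lengths
    counts <- counts$counts
  }
  if (is.null(lengths)) stop("gene lengths required to compute FPKM")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stop("missing gene length for: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  }
  len <- as.numeric(lengths[rownames(counts)])
  if (any(len <= 0)) stop("non-positive gene length")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  fpkm <- sweep(counts * 1e9 / len, 2L, lib, "/")
  attr(fpkm, "library_sizes") <- lib
  fpkm
}

#' Average replicate FPKM per (cultivar, stage) group
#'
#' @param expr FPKM matrix (genes x samples).
#' @param sheet `sample_sheet` describing the columns of `expr`.
#' @return Matrix of group-mean FPKM, one column per (cultivar, stage),
#'   named `"<cultivar>:<stage>"`, with attribute `groups` (a data frame
#'   of cultivar, stage_dpa, species, n_reps per column).
#' @export
group_mean <- function(expr, sheet) {
  .check_sheet_samples(expr, sheet)
  key <- paste(sheet$cultivar, sheet$stage_dpa, sep = ":")
  groups <- unique(data.frame(key = key, cultivar = sheet$cultivar,
                              stage_dpa = sheet$stage_dpa,
                              species = sheet$species,
                              stringsAsFactors = FALSE))
  out <- matrix(NA_real_, nrow = nrow(expr), ncol = nrow(groups),
                dimnames = list(rownames(expr), groups$key))
  n_reps <- integer(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    cols <- sheet$sample_id[key == groups$key[i]]
    n_reps[i] <- length(cols)
    out[, i] <- rowMeans(expr[, cols, drop = FALSE])
  }
  groups$n_reps <- n_reps
  rownames(groups) <- NULL
  attr(out, "groups") <- groups
  out
}

.check_sheet_samples <- function(expr, sheet) {
  missing <- setdiff(sheet$sample_id, colnames(expr))
  if (length(missing)) {
    stop("sample(s) in sheet absent from expression/count columns: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Replicate-concordance QC by Pearson correlation
#'
#' Pearson correlation of log2(FPKM + 1) for every within-group replicate
#' pair.  A pair passes when r >= `threshold`; pairs whose vectors are
#' constant have undefined correlation and are reported with `r = NA` and
#' `pass = NA` (not computable, not failed).
#'
#' @param expr FPKM matrix (genes x samples).
#' @param sheet `sample_sheet`.
#' @param threshold Pass threshold on r (default 0.84).
#' @return Data frame with one row per replicate pair:
#'   cultivar, stage_dpa, sample_1, sample_2, r, pass.
#' @export
replicate_correlation <- function(expr, sheet, threshold = 0.84) {
  .check_sheet_samples(expr, sheet)
  lg <- log2(expr + 1)
  key <- paste(sheet$cultivar, sheet$stage_dpa, sep = ":")
  rows <- list()
  for (k in unique(key)) {
    ids <- sheet$sample_id[key == k]
    if (length(ids) < 2L) next
    cv <- sheet$cultivar[key == k][1L]
    st <- sheet$stage_dpa[key == k][1L]
    cmb <- utils::combn(ids, 2L)
    for (j in seq_len(ncol(cmb))) {
      x <- lg[, cmb[1L, j]]; y <- lg[, cmb[2L, j]]
      r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
        stats::cor(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        cultivar = cv, stage_dpa = st,
        sample_1 = cmb[1L, j], sample_2 = cmb[2L, j],
        r = r, pass = if (is.na(r)) NA else r >= threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cultivar = character(), stage_dpa = integer(),
                      sample_1 = character(), sample_2 = character(),
                      r = numeric(), pass = logical()))
  }
  do.call(rbind, rows)
}

#' Flag expressed homoeolog pairs per (cultivar, stage) group
#'
#' A pair counts as expressed in a group when the larger of its two
#' homoeologs' group-mean FPKM values reaches `min_fpkm`, so a silenced
#' homoeolog cannot mask a strongly expressed partner.
#'
#' @param group_expr Group-mean FPKM matrix from [group_mean()].
#' @param pairs `pair_map`.
#' @param min_fpkm Expression threshold (default 1 FPKM).
#' @return Logical matrix (pairs x groups, rownames = pair ids) with
#'   attributes `n_expressed` (per-group totals) and `n_skipped` (pairs
#'   whose genes were absent from the matrix).
#' @export
filter_expressed_pairs <- function(group_expr, pairs, min_fpkm = 1) {
  present <- pairs$a_gene %in% rownames(group_expr) &
    pairs$d_gene %in% rownames(group_expr)
  n_skipped <- sum(!present)
  if (n_skipped > 0L) {
    warning(n_skipped, " pair(s) skipped: gene absent from matrix")
  }
  p <- pairs[present, , drop = FALSE]
  a <- group_expr[p$a_gene, , drop = FALSE]
  d <- group_expr[p$d_gene, , drop = FALSE]
  ok <- pmax(a, d) >= min_fpkm
  dimnames(ok) <- list(p$pair_id, colnames(group_expr))
  attr(ok, "n_expressed") <- colSums(ok)
  attr(ok, "n_skipped") <- n_skipped
  ok
}
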