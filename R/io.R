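#' Read a gene-level read-count table
#'
#' Parses either the native output of featureCounts (an optional leading
#' `#` comment line, then a header `Geneid Chr Start End Strand Length`
#' followed by one column per sample) or a plain counts table (a gene-id
#' column followed by sample columns).
#'
#' @param path Path to a tab-separated counts file.
#' @param dialect `"featurecounts"` or `"plain"`.
#' @return A `counts_table`: a list with `counts` (integer matrix, genes x
#'   samples, rownames = gene ids) and `lengths` (named integer vector of
#'   gene lengths in bp, or `NULL` for the plain dialect).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "gA\t5\t2", "gB\t0\t7"), tf)
#' ct <- read_counts(tf, dialect = "plain")
#' ct$counts
#' @export
read_counts <- function(path, dialect = c("featurecounts", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("not a valid ", dialect, " counts file (need a gene id column ",
         "plus at least one sample column): ", path)
  }
  if (dialect == "featurecounts") {
    anno <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
    if (!all(anno %in% names(df))) {
      stop("missing featurecounts header columns (",
           paste(setdiff(anno, names(df)), collapse = ", "),
           "): not a featurecounts file?")
    }
    gene_id <- df[["Geneid"]]
    lengths <- .parse_int_column(df[["Length"]], "Length")
    if (any(lengths <= 0L)) stop("non-positive gene length in Length column")
    sample_cols <- setdiff(names(df), anno)
    names(lengths) <- gene_id
  } else {
    gene_id <- df[[1L]]
    sample_cols <- names(df)[-1L]
    lengths <- NULL
  }
  if (length(sample_cols) == 0L) stop("counts file has no sample columns")
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  counts <- matrix(0L, nrow = length(gene_id), ncol = length(sample_cols),
                   dimnames = list(gene_id, sample_cols))
  for (s in sample_cols) {
    counts[, s] <- .parse_int_column(df[[s]], s, gene_id)
  }
  if (any(counts < 0L)) stop("negative count encountered")
  structure(list(counts = counts, lengths = lengths), class = "counts_table")
}

# strict integer parse; report row/column of the first bad cell
.parse_int_column <- function(x, col, ids = NULL) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad)) {
    i <- which(bad)[1L]
    where <- if (is.null(ids)) paste0("row ", i) else paste0("row ", i,
      " (", ids[i], ")")
    stop("non-integer value ", dQuote(x[i]), " in column ", sQuote(col),
         ", ", where)
  }
  as.integer(round(v))
}

#' @export
print.counts_table <- function(x, ...) {
  cat("counts_table: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples", if (!is.null(x$lengths)) " (with gene lengths)", "\n",
      sep = "")
  invisible(x)
}

.species_codes <- c("Gh", "Gb")

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `species` (`Gh`/`Gb`),
#'   `cultivar`, `stage_dpa`, `replicate`.
#' @param stages Integer vector of admissible stages (days post-anthesis).
#' @return A validated `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path, stages = c(0L, 1L, 3L, 5L, 10L, 20L, 25L)) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "cultivar", "stage_dpa", "replicate")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  df$species <- as.character(df$species)
  df$cultivar <- as.character(df$cultivar)
  df$stage_dpa <- .parse_int_column(as.character(df$stage_dpa), "stage_dpa")
  df$replicate <- .parse_int_column(as.character(df$replicate), "replicate")
  as_sample_sheet(df, stages = stages)
}

#' Validate a data frame as a sample sheet
#'
#' @param df Data frame with the five sample-sheet columns.
#' @param stages Admissible stage values.
#' @return The validated `sample_sheet`.
#' @export
as_sample_sheet <- function(df, stages = c(0L, 1L, 3L, 5L, 10L, 20L, 25L)) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_sp <- setdiff(unique(df$species), .species_codes)
  if (length(bad_sp)) {
    stop("unknown species code(s): ", paste(bad_sp, collapse = ", "),
         " (expected ", paste(.species_codes, collapse = "/"), ")")
  }
  bad_stage <- setdiff(unique(df$stage_dpa), stages)
  if (length(bad_stage)) {
    stop("stage_dpa value(s) outside declared stage set: ",
         paste(sort(bad_stage), collapse = ", "))
  }
  if (any(df$replicate < 1L)) stop("replicate must be a positive integer")
  sp_per_cv <- tapply(df$species, df$cultivar, function(s) length(unique(s)))
  if (any(sp_per_cv > 1L)) {
    stop("cultivar(s) assigned to more than one species: ",
         paste(names(sp_per_cv)[sp_per_cv > 1L], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a homoeolog pair map
#'
#' Columns `pair_id`, `a_gene`, `d_gene`; optionally `species` and
#' `ortholog_pair` (the id of the linked pair in the other species), which
#' enable cross-species analyses.
#'
#' @param path TSV path.
#' @return A validated `pair_map` data frame.
#' @export
read_pair_map <- function(path) {
  if (!file.exists(path)) stop("pair map not found: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  as_pair_map(df)
}

#' Validate a data frame as a homoeolog pair map
#' @param df Data frame with at least `pair_id`, `a_gene`, `d_gene`.
#' @return The validated `pair_map`.
#' @export
as_pair_map <- function(df) {
  need <- c("pair_id", "a_gene", "d_gene")
  if (!all(need %in% names(df))) {
    stop("pair map must have columns: ", paste(need, collapse = ", "))
  }
  keep <- intersect(c(need, "species", "ortholog_pair"), names(df))
  df <- df[, keep, drop = FALSE]
  if (anyDuplicated(df$pair_id)) {
    stop("duplicate pair_id: ",
         paste(unique(df$pair_id[duplicated(df$pair_id)]), collapse = ", "))
  }
  if (any(df$a_gene == df$d_gene)) {
    stop("a_gene equals d_gene for pair(s): ",
         paste(df$pair_id[df$a_gene == df$d_gene], collapse = ", "))
  }
  genes <- c(df$a_gene, df$d_gene)
  if (anyDuplicated(genes)) {
    stop("gene(s) listed in more than one pair: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if ("species" %in% names(df)) {
    bad <- setdiff(unique(df$species), .species_codes)
    if (length(bad)) stop("unknown species code(s) in pair map: ",
                          paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("pair_map", "data.frame")
  df
}

#' Read a two-column gene-length table
#' @param path TSV with columns gene id and length (bp).
#' @return Named integer vector of lengths.
#' @export
read_lengths <- function(path) {
  if (!file.exists(path)) stop("length table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("length table needs two columns (gene, length)")
  len <- .parse_int_column(df[[2L]], names(df)[2L], df[[1L]])
  if (any(len <= 0L)) stop("non-positive gene length")
  if (anyDuplicated(df[[1L]])) stop("duplicate gene id in length table")
  stats::setNames(len, df[[1L]])
}

#' Write a tabular result as TSV
#'
#' Fixed column order, `.` decimal mark, scientific notation for values
#' below 1e-4 in magnitude, 12 significant digits (so a write/read
#' round-trip reproduces values), newline-terminated.  Optional `#`
#' comment header lines carry provenance (seed, parameters).
#'
#' @param x Data frame (or matrix) to write.
#' @param path Output path.
#' @param comments Character vector of header comment lines (written with a
#'   leading `"# "`).
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, comments = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  out <- x
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v) && !is.integer(v)) {
      s <- formatC(v, digits = 15, format = "g")
      s[is.na(v)] <- "NA"
      s[is.infinite(v)] <- ifelse(v[is.infinite(v)] > 0, "Inf", "-Inf")
      out[[j]] <- trimws(s)
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
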