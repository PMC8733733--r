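#' Parameters for homoeolog bias calling
#'
#' @param fold_change_min Minimum FPKM fold change between homoeologs
#'   (default 2: a two-fold rule).
#' @param fdr_alpha Benjamini-Hochberg FDR threshold (default 0.05).
#' @param min_fpkm Expression filter passed to [filter_expressed_pairs()]
#'   (default 1 FPKM).
#' @param direction_alpha Significance level for the per-table direction
#'   test in summaries (default 0.05).
#' @return A `bias_params` list.
#' @export
bias_params <- function(fold_change_min = 2, fdr_alpha = 0.05,
                        min_fpkm = 1, direction_alpha = 0.05) {
  stopifnot(fold_change_min > 1, fdr_alpha > 0, fdr_alpha < 1,
            min_fpkm >= 0, direction_alpha > 0, direction_alpha < 1)
  structure(list(fold_change_min = fold_change_min, fdr_alpha = fdr_alpha,
                 min_fpkm = min_fpkm, direction_alpha = direction_alpha),
            class = "bias_params")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `(a, b; c, d)`, computed by
#' summing all hypergeometric outcome probabilities not exceeding the
#' probability of the observed table (the standard two-sided convention).
#' Vectorised over the four entries.
#'
#' @param a,b,c,d Non-negative integer cell counts (top-left, top-right,
#'   bottom-left, bottom-right).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_2x2(5, 5, 95, 95)   # symmetric table: p = 1
#' fisher_exact_2x2(8, 2, 2, 8)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative cell count")
  if (any(a != floor(a) | b != floor(b) | c != floor(c) | d != floor(d))) {
    stop("cell counts must be integers")
  }
  if (any(a + b + c + d == 0)) stop("empty table: all margins zero")
  vapply(seq_len(n), function(i) .fisher_p1(a[i], b[i], c[i], d[i]), 0)
}

.fisher_p1 <- function(a, b, c, d) {
  m <- a + c            # first-column margin
  nn <- b + d           # second-column margin
  k <- a + b            # first-row margin
  lo <- max(0, k - nn)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, nn, k)
  # tolerance guards against ties broken by floating-point rounding
  min(1, sum(probs[probs <= probs[x == a] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is preserved and q-values are
#' clipped at 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Exact binomial test for bias direction
#'
#' Tests whether the split of biased pairs between the A and D subgenomes
#' departs from 50:50, by an exact two-sided binomial test (outcomes with
#' probability not exceeding that of the observed count are summed).
#'
#' @param n_a,n_d Counts of A-biased and D-biased pairs.
#' @param alpha Significance level for declaring a direction (default 0.05).
#' @return List with `p` and `direction` (`"At"`, `"Dt"` or `"none"`).
#' @export
binomial_direction_test <- function(n_a, n_d, alpha = 0.05) {
  if (n_a < 0 || n_d < 0) stop("negative count")
  if (n_a + n_d < 1) stop("direction test needs at least one biased pair")
  p <- stats::binom.test(n_a, n_a + n_d, p = 0.5)$p.value
  direction <- if (p < alpha) {
    if (n_a > n_d) "At" else "Dt"
  } else "none"
  list(p = p, direction = direction)
}

#' Call homoeolog expression bias per pair and (cultivar, stage) group
#'
#' For every expressed pair in every group, replicate read counts are
#' pooled by summation and the pooled count of the A homoeolog is compared
#' with that of the D homoeolog by Fisher's exact test against the
#' rest-of-library margins; p-values are BH-adjusted within each
#' (cultivar, stage) family.  A pair is called `A_biased` when its
#' group-mean FPKM ratio A/D reaches `fold_change_min`, FPKM_A > FPKM_D,
#' and q < `fdr_alpha` (symmetrically for `D_biased`).  A homoeolog with
#' zero FPKM opposite an expressed partner yields an infinite log2 ratio
#' and passes the fold-change gate.  Pairs failing the expression filter
#' are returned as `not_expressed` with no test performed.
#'
#' @param counts A `counts_table` (or integer matrix; then supply `lengths`).
#' @param sheet `sample_sheet` for the count columns.
#' @param pairs `pair_map`; if it has a `species` column only pairs of the
#'   cultivar's species are evaluated in each group.
#' @param params `bias_params()`.
#' @param stages Stages (DPA) to analyse; default all stages in the sheet.
#' @param lengths Gene lengths if `counts` is a bare matrix.
#' @return Data frame of class `bias_calls`: pair_id, species, cultivar,
#'   stage_dpa, fpkm_a, fpkm_d, log2fc, count_a, count_d, p_raw, q, call.
#' @export
call_pair_bias <- function(counts, sheet, pairs, params = bias_params(),
                           stages = NULL, lengths = NULL) {
  fpkm <- compute_fpkm(counts, lengths)
  if (inherits(counts, "counts_table")) counts <- counts$counts
  gm <- group_mean(fpkm, sheet)
  groups <- attr(gm, "groups")
  if (!is.null(stages)) groups <- groups[groups$stage_dpa %in% stages, ]
  if (nrow(groups) == 0L) stop("no (cultivar, stage) groups to analyse")
  expressed <- filter_expressed_pairs(gm, pairs, params$min_fpkm)
  pairs <- pairs[pairs$pair_id %in% rownames(expressed), , drop = FALSE]
  lib <- colSums(counts)
  res <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    p_sp <- if ("species" %in% names(pairs)) {
      pairs[pairs$species == g$species, , drop = FALSE]
    } else pairs
    if (nrow(p_sp) == 0L) next
    ids <- sheet$sample_id[sheet$cultivar == g$cultivar &
                             sheet$stage_dpa == g$stage_dpa]
    csum <- rowSums(counts[, ids, drop = FALSE])
    L <- sum(lib[ids])
    fa <- gm[p_sp$a_gene, g$key]
    fd <- gm[p_sp$d_gene, g$key]
    ca <- csum[p_sp$a_gene]
    cd <- csum[p_sp$d_gene]
    expr_ok <- expressed[p_sp$pair_id, g$key]
    lfc <- .log2_ratio(fa, fd)
    p_raw <- rep(NA_real_, nrow(p_sp))
    if (any(expr_ok)) {
      p_raw[expr_ok] <- fisher_exact_2x2(ca[expr_ok], cd[expr_ok],
                                         L - ca[expr_ok], L - cd[expr_ok])
    }
    q <- rep(NA_real_, nrow(p_sp))
    q[expr_ok] <- bh_adjust(p_raw[expr_ok])
    thr <- log2(params$fold_change_min)
    call <- rep("unbiased", nrow(p_sp))
    call[!expr_ok] <- "not_expressed"
    sig <- expr_ok & !is.na(q) & q < params$fdr_alpha
    call[sig & fa > fd & lfc >= thr] <- "A_biased"
    call[sig & fa < fd & lfc <= -thr] <- "D_biased"
    res[[i]] <- data.frame(
      pair_id = p_sp$pair_id, species = g$species, cultivar = g$cultivar,
      stage_dpa = g$stage_dpa, fpkm_a = unname(fa), fpkm_d = unname(fd),
      log2fc = unname(lfc), count_a = unname(ca), count_d = unname(cd),
      p_raw = p_raw, q = q, call = call, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("bias_calls", "data.frame")
  out
}

# log2(a/d) with zero handling: one-sided zero -> +/-Inf, both zero -> NA
.log2_ratio <- function(a, d) {
  out <- ifelse(a == 0 & d == 0, NA_real_,
         ifelse(d == 0, Inf, ifelse(a == 0, -Inf, log2(a / d))))
  unname(out)
}

#' Assemble one bias summary row from counts
#'
#' Computes total biased pairs, the biased percentage and the exact
#' binomial direction test from the raw tallies; used by
#' [summarize_bias()] and directly applicable to reported tallies.
#'
#' @param total_expressed Number of expressed pairs in the group.
#' @param n_a_biased,n_d_biased Number of A- and D-biased pairs.
#' @param alpha Direction-test significance level.
#' @return One-row data frame: total_expressed, total_biased, n_a_biased,
#'   n_d_biased, pct_biased, direction_p, direction.
#' @export
bias_summary_row <- function(total_expressed, n_a_biased, n_d_biased,
                             alpha = 0.05) {
  total_biased <- n_a_biased + n_d_biased
  if (total_biased > total_expressed) {
    stop("biased pairs exceed expressed pairs")
  }
  pct <- if (total_expressed > 0) 100 * total_biased / total_expressed else 0
  if (total_biased >= 1) {
    dt <- binomial_direction_test(n_a_biased, n_d_biased, alpha)
  } else {
    dt <- list(p = NA_real_, direction = "none")
  }
  data.frame(total_expressed = total_expressed, total_biased = total_biased,
             n_a_biased = n_a_biased, n_d_biased = n_d_biased,
             pct_biased = pct, direction_p = dt$p, direction = dt$direction,
             stringsAsFactors = FALSE)
}

#' Summarise bias calls per cultivar and stage
#'
#' @param calls `bias_calls` from [call_pair_bias()].
#' @param alpha Direction-test significance level.
#' @return Data frame with one row per (cultivar, stage): species,
#'   cultivar, stage_dpa plus the columns of [bias_summary_row()].
#'   `pct_biased` is kept at full precision; round on output.
#' @export
summarize_bias <- function(calls, alpha = 0.05) {
  key <- paste(calls$cultivar, calls$stage_dpa, sep = ":")
  rows <- lapply(unique(key), function(k) {
    cc <- calls[key == k, ]
    r <- bias_summary_row(sum(cc$call != "not_expressed"),
                          sum(cc$call == "A_biased"),
                          sum(cc$call == "D_biased"), alpha)
    cbind(data.frame(species = cc$species[1L], cultivar = cc$cultivar[1L],
                     stage_dpa = cc$stage_dpa[1L], stringsAsFactors = FALSE),
          r)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$stage_dpa, out$cultivar), ]
  rownames(out) <- NULL
  out
}

#' Strict cross-cultivar consensus bias pattern per pair
#'
#' Within one species at one stage, a pair is `A_all` when called
#' `A_biased` in every cultivar, `D_all` when `D_biased` in every
#' cultivar, `none_all` when unbiased in every cultivar, and `mixed`
#' otherwise.  Pairs not expressed in at least one cultivar are excluded.
#'
#' @param calls `bias_calls` covering the cultivars of one species at one
#'   stage (rows for other species/stages are ignored via `species`/`stage`).
#' @param species Species code (`"Gh"` or `"Gb"`).
#' @param stage Stage in DPA.
#' @return Data frame pair_id, species, stage_dpa, n_cultivars, pattern,
#'   with attribute `shared_counts` (number of `A_all` and `D_all` pairs,
#'   the Venn-intersection tallies).
#' @export
species_consensus <- function(calls, species, stage) {
  cc <- calls[calls$species == species & calls$stage_dpa == stage, ]
  if (nrow(cc) == 0L) stop("no calls for species ", species,
                           " at stage ", stage)
  cvs <- unique(cc$cultivar)
  tab <- tapply(cc$call, list(cc$pair_id, cc$cultivar), function(x) x[1L])
  full <- rowSums(!is.na(tab) & tab != "not_expressed") == length(cvs)
  tab <- tab[full, , drop = FALSE]
  pattern <- apply(tab, 1L, function(x) {
    if (all(x == "A_biased")) "A_all"
    else if (all(x == "D_biased")) "D_all"
    else if (all(x == "unbiased")) "none_all"
    else "mixed"
  })
  out <- data.frame(pair_id = rownames(tab), species = species,
                    stage_dpa = stage, n_cultivars = length(cvs),
                    pattern = unname(pattern), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "shared_counts") <- c(A_all = sum(pattern == "A_all"),
                                  D_all = sum(pattern == "D_all"))
  out
}

.interspecific_levels <- c("A:none", "A:D", "A:A", "D:none", "D:A", "D:D",
                           "none:A", "none:D")

#' Classify interspecific bias-pattern categories
#'
#' Joins the strict consensus patterns of the two species over linked
#' pairs and maps each pair with both patterns in
#' \{A_all, D_all, none_all\} to one of the eight extreme categories
#' (`"<Gh>:<Gb>"` with codes A/D/none); mixed patterns and the
#' (none, none) combination receive no category.
#'
#' @param cons_gh,cons_gb Outputs of [species_consensus()] for the two
#'   species at the same stage.
#' @param links Data frame linking pairs across species, columns
#'   `pair_gh`, `pair_gb` (see [ortholog_pair_links()]).
#' @return Data frame pair_gh, pair_gb, stage_dpa, gh_pattern, gb_pattern,
#'   category (factor over the 8 levels), differing (logical).
#' @export
classify_interspecific <- function(cons_gh, cons_gb, links) {
  if (cons_gh$stage_dpa[1L] != cons_gb$stage_dpa[1L]) {
    stop("consensus inputs are for different stages")
  }
  code <- c(A_all = "A", D_all = "D", none_all = "none")
  gh <- cons_gh[cons_gh$pattern != "mixed", c("pair_id", "pattern")]
  gb <- cons_gb[cons_gb$pattern != "mixed", c("pair_id", "pattern")]
  m <- merge(links, gh, by.x = "pair_gh", by.y = "pair_id")
  names(m)[names(m) == "pattern"] <- "gh_pattern"
  m <- merge(m, gb, by.x = "pair_gb", by.y = "pair_id")
  names(m)[names(m) == "pattern"] <- "gb_pattern"
  m <- m[!(m$gh_pattern == "none_all" & m$gb_pattern == "none_all"), ]
  category <- paste(code[m$gh_pattern], code[m$gb_pattern], sep = ":")
  out <- data.frame(pair_gh = m$pair_gh, pair_gb = m$pair_gb,
                    stage_dpa = rep(cons_gh$stage_dpa[1L], nrow(m)),
                    gh_pattern = m$gh_pattern, gb_pattern = m$gb_pattern,
                    category = factor(category,
                                      levels = .interspecific_levels),
                    differing = m$gh_pattern != m$gb_pattern,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pair_gh), ]
  rownames(out) <- NULL
  out
}

#' Tally interspecific bias categories
#'
#' @param categories Output of [classify_interspecific()], or a factor /
#'   character vector of category labels, or a named count vector over the
#'   8 category levels.
#' @return List with `total_extreme` (all 8 categories), `n_differing`
#'   (total minus the two same-direction categories `A:A` and `D:D`) and
#'   `by_category` (named count vector).
#' @export
count_interspecific <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  if (is.numeric(categories)) {
    if (is.null(names(categories)) ||
        !all(names(categories) %in% .interspecific_levels)) {
      stop("count vector must be named by the 8 category levels")
    }
    counts <- stats::setNames(numeric(length(.interspecific_levels)),
                              .interspecific_levels)
    counts[names(categories)] <- categories
  } else {
    categories <- factor(as.character(categories),
                         levels = .interspecific_levels)
    if (anyNA(categories)) stop("unknown category label")
    counts <- table(categories)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  total <- sum(counts)
  same <- sum(counts[c("A:A", "D:D")])
  list(total_extreme = total, n_differing = total - same,
       by_category = counts)
}

#' Ortholog linkage tables from a pair map
#'
#' From a `pair_map` carrying `species` and `ortholog_pair` columns,
#' builds (i) the pair-level link table Gh pair <-> Gb pair and (ii) the
#' gene-level ortholog table linking A genes to A genes and D genes to D
#' genes of linked pairs.
#'
#' @param pairs `pair_map` with `species` and `ortholog_pair` columns.
#' @return List with `pairs` (pair_gh, pair_gb) and `genes`
#'   (gene_gh, gene_gb, subgenome).
#' @export
ortholog_pair_links <- function(pairs) {
  if (!all(c("species", "ortholog_pair") %in% names(pairs))) {
    stop("pair map lacks species/ortholog_pair columns; no cross-species links")
  }
  gh <- pairs[pairs$species == "Gh" & !is.na(pairs$ortholog_pair) &
                pairs$ortholog_pair != "", ]
  gb <- pairs[pairs$species == "Gb", ]
  m <- merge(gh, gb, by.x = "ortholog_pair", by.y = "pair_id",
             suffixes = c("_gh", "_gb"))
  plinks <- data.frame(pair_gh = m$pair_id, pair_gb = m$ortholog_pair,
                       stringsAsFactors = FALSE)
  glinks <- rbind(
    data.frame(gene_gh = m$a_gene_gh, gene_gb = m$a_gene_gb,
               subgenome = "A", stringsAsFactors = FALSE),
    data.frame(gene_gh = m$d_gene_gh, gene_gb = m$d_gene_gb,
               subgenome = "D", stringsAsFactors = FALSE))
  list(pairs = plinks[order(plinks$pair_gh), , drop = FALSE],
       genes = glinks[order(glinks$gene_gh), , drop = FALSE])
}
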