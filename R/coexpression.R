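#' Parameters for co-expression network construction
#'
#' @param beta_candidates Candidate soft-threshold powers (default 1..20).
#' @param scale_free_r2_target Scale-free topology fit target R^2
#'   (default 0.8).
#' @param min_module_size Smallest cluster kept as a module (default 30).
#' @param merge_cor_min Modules whose eigengenes correlate above this are
#'   merged (default 0.75).
#' @param top_edges Number of top-weight edges exported (default 100;
#'   the conventional range is 50-100).
#' @param n_hubs Hub genes per module (default 3).
#' @return A `network_params` list.
#' @export
network_params <- function(beta_candidates = 1:20, scale_free_r2_target = 0.8,
                           min_module_size = 30L, merge_cor_min = 0.75,
                           top_edges = 100L, n_hubs = 3L) {
  stopifnot(all(beta_candidates >= 1), min_module_size >= 1L,
            merge_cor_min > 0, merge_cor_min <= 1, top_edges >= 1L,
            n_hubs >= 1L)
  structure(list(beta_candidates = as.integer(beta_candidates),
                 scale_free_r2_target = scale_free_r2_target,
                 min_module_size = as.integer(min_module_size),
                 merge_cor_min = merge_cor_min,
                 top_edges = as.integer(top_edges),
                 n_hubs = as.integer(n_hubs)),
            class = "network_params")
}

#' Choose a soft-threshold power by scale-free topology fit
#'
#' For each candidate power the connectivity `k_i = sum_j |cor|^beta` is
#' computed and the linearity of log10 frequency(k) vs log10 k (10 bins)
#' is scored by R^2; the smallest power reaching the target R^2 is chosen,
#' or the power with the best fit if none reaches it.
#'
#' @param expr Expression matrix (genes x samples), typically
#'   log2(FPKM + 1).
#' @param powers Candidate powers.
#' @param r2_target Target fit (default 0.8).
#' @param n_bins Histogram bins for the fit (default 10).
#' @return The chosen power (integer), with attribute `fit_table`
#'   (power, r2, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.8,
                                n_bins = 10L) {
  if (ncol(expr) < 8L) {
    stop("need at least 8 samples for stable correlations (got ",
         ncol(expr), ")")
  }
  ac <- abs(.safe_cor(t(expr)))
  diag(ac) <- 0
  r2 <- vapply(powers, function(b) {
    k <- rowSums(ac^b)
    .scale_free_r2(k, n_bins)
  }, 0)
  fit <- data.frame(power = powers, r2 = r2)
  hit <- which(r2 >= r2_target)
  beta <- if (length(hit)) powers[hit[1L]] else powers[which.max(r2)]
  attr(beta, "fit_table") <- fit
  beta
}

.scale_free_r2 <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mid <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(0)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mid[ok]))
  summary(fit)$r.squared
}

# correlation with constant rows mapped to 0 (with one warning)
.safe_cor <- function(x) {
  sds <- apply(x, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s): correlations set to 0")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta`, diagonal 1.  Constant genes get zero
#' adjacency to everything (with a warning).
#'
#' @param expr Expression matrix (genes x samples).
#' @param beta Soft-threshold power (>= 1).
#' @return Symmetric adjacency matrix in \[0, 1\].
#' @export
wgcna_adjacency <- function(expr, beta) {
  if (beta < 1) stop("beta must be >= 1")
  a <- abs(.safe_cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over u distinct from i and j and
#' `k_i = sum_u a_iu` (u != i); diagonal set to 1.
#'
#' @param adj Symmetric adjacency matrix (values in \[0, 1\]).
#' @return `tom_matrix`: symmetric, unit diagonal, entries in \[0, 1\].
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) {
    stop("adjacency must be symmetric")
  }
  a <- adj
  diag(a) <- 0
  l <- a %*% a                       # includes no i/j self terms: diag is 0
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM;
#' the tree is cut statically at the height that yields the largest
#' number of clusters of at least `min_module_size` genes (ties resolved
#' toward the greater height, so completed modules absorb their
#' stragglers), small clusters are left unassigned ("grey"), modules whose
#' eigengenes correlate above `merge_cor_min` are merged iteratively, and
#' a final kME sweep re-assigns each gene to its best-fitting module.
#'
#' @param tom TOM (or any similarity) matrix from [tom_similarity()].
#' @param expr Expression matrix (genes x samples) used for eigengene
#'   computation during merging.
#' @param min_module_size Minimum module size (default 30).
#' @param merge_cor_min Eigengene-correlation merge threshold (default
#'   0.75).
#' @param kme_min After merging, every gene is re-assigned to the module
#'   whose eigengene it correlates with most; genes whose best kME falls
#'   below `kme_min` are left unassigned (default 0.55).  Set to `NA` to
#'   skip the reassignment sweep.
#' @return A `module_set` list: `labels` (named character vector,
#'   `"M1"`, `"M2"`, ... by decreasing size, `"grey"` = unassigned),
#'   `eigengenes` (samples x modules), `cut_height`, `dendrogram`.
#' @export
detect_modules <- function(tom, expr, min_module_size = 30L,
                           merge_cor_min = 0.75, kme_min = 0.55) {
  stopifnot(nrow(tom) == nrow(expr))
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  heights <- unique(h$height)
  best_n <- -1L
  best_height <- NA_real_
  best_cut <- NULL
  for (ht in sort(heights)) {
    cut <- stats::cutree(h, h = ht)
    n_big <- sum(table(cut) >= min_module_size)
    if (n_big > best_n) {      # lowest height achieving the max count;
      best_n <- n_big          # stragglers are collected by the kME sweep
      best_height <- ht
      best_cut <- cut
    }
  }
  if (best_n < 1L) {
    warning("no cluster reaches min_module_size; all genes unassigned")
    labels <- stats::setNames(rep("grey", nrow(tom)), rownames(tom))
    return(structure(list(labels = labels,
                          eigengenes = NULL, cut_height = NA_real_,
                          dendrogram = h), class = "module_set"))
  }
  sizes <- table(best_cut)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- ifelse(best_cut %in% as.integer(keep), as.character(best_cut), "grey")
  names(lab) <- rownames(tom)
  lab <- .merge_modules(lab, expr, merge_cor_min)
  if (!is.na(kme_min)) lab <- .kme_reassign(lab, expr, kme_min,
                                            min_module_size)
  lab <- .rename_modules(lab)
  eig <- .module_eigengenes(expr, lab)
  structure(list(labels = lab, eigengenes = eig, cut_height = best_height,
                 dendrogram = h), class = "module_set")
}

.merge_modules <- function(lab, expr, merge_cor_min) {
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2L) return(lab)
    eig <- sapply(mods, function(m) {
      module_eigengene(expr, names(lab)[lab == m])
    })
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[top[1L], top[2L]] <= merge_cor_min) return(lab)
    lab[lab == mods[top[2L]]] <- mods[top[1L]]
  }
}

# one sweep of kME-based cleanup: each gene joins its best-correlated
# module eigengene, or grey when no module fits
.kme_reassign <- function(lab, expr, kme_min, min_module_size) {
  mods <- setdiff(unique(lab), "grey")
  if (!length(mods)) return(lab)
  eig <- sapply(mods, function(m) module_eigengene(expr,
                                                   names(lab)[lab == m]))
  kme <- suppressWarnings(stats::cor(t(expr), eig))
  kme[is.na(kme)] <- 0
  best <- max.col(kme, ties.method = "first")
  new <- ifelse(kme[cbind(seq_along(best), best)] >= kme_min,
                mods[best], "grey")
  names(new) <- names(lab)
  sizes <- table(new[new != "grey"])
  drop <- names(sizes)[sizes < min_module_size]
  new[new %in% drop] <- "grey"
  new
}

.rename_modules <- function(lab) {
  mods <- setdiff(unique(lab), "grey")
  if (!length(mods)) return(lab)
  sizes <- vapply(mods, function(m) sum(lab == m), 0L)
  first <- vapply(mods, function(m) min(names(lab)[lab == m]), "")
  ord <- order(-sizes, first)
  map <- stats::setNames(paste0("M", seq_along(mods)), mods[ord])
  out <- ifelse(lab == "grey", "grey", map[lab])
  stats::setNames(out, names(lab))
}

.module_eigengenes <- function(expr, lab) {
  mods <- setdiff(sort(unique(lab)), "grey")
  if (!length(mods)) return(NULL)
  sapply(mods, function(m) module_eigengene(expr, names(lab)[lab == m]))
}

#' @export
print.module_set <- function(x, ...) {
  tab <- table(x$labels)
  cat("module_set: ", sum(names(tab) != "grey"), " module(s), ",
      if ("grey" %in% names(tab)) tab[["grey"]] else 0L,
      " unassigned gene(s)\n", sep = "")
  print(tab)
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression
#' across samples, scaled to unit variance and sign-oriented so that it
#' correlates positively with the module's mean standardized expression.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Module member gene ids.
#' @return Numeric eigengene vector over samples (unit variance).
#' @export
module_eigengene <- function(expr, genes) {
  if (!length(genes)) stop("empty module")
  x <- expr[genes, , drop = FALSE]
  z <- t(scale(t(x)))
  z[is.na(z)] <- 0                       # constant genes contribute nothing
  if (nrow(z) == 1L) {
    e <- as.numeric(z)
  } else {
    sv <- svd(t(z), nu = 1L, nv = 0L)
    e <- sv$u[, 1L]
  }
  if (stats::sd(e) == 0) stop("degenerate module: constant eigengene")
  e <- e / stats::sd(e)
  avg <- colMeans(z)
  if (stats::sd(avg) > 0 && stats::cor(e, avg) < 0) e <- -e
  stats::setNames(e, colnames(expr))
}

#' Module-stage correlations
#'
#' Pearson correlation of each module eigengene with each stage indicator
#' (one column per stage, 1 for samples at the stage), with p-values from
#' the t distribution on n - 2 degrees of freedom.
#'
#' @param eigengenes Matrix (samples x modules) or a single eigengene
#'   vector.
#' @param stages Integer vector giving each sample's stage (DPA).
#' @return List with matrices `r` and `p` (modules x stages).
#' @export
module_trait_cor <- function(eigengenes, stages) {
  if (is.null(dim(eigengenes))) {
    eigengenes <- matrix(eigengenes, ncol = 1L,
                         dimnames = list(names(eigengenes), "ME"))
  }
  n <- nrow(eigengenes)
  if (n < 3L) stop("need at least 3 samples")
  if (length(stages) != n) stop("stages must match the sample rows")
  lev <- sort(unique(stages))
  ind <- sapply(lev, function(s) as.numeric(stages == s))
  colnames(ind) <- lev
  r <- t(stats::cor(ind, eigengenes))           # modules x stages
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(r) >= 1] <- 0
  rownames(r) <- rownames(p) <- colnames(eigengenes)
  list(r = r, p = p)
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with a module eigengene.
#' Constant genes get kME 0 with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param eigengene Eigengene vector over the same samples.
#' @return Named numeric vector of kME values in \[-1, 1\].
#' @export
module_kme <- function(expr, eigengene) {
  sds <- apply(expr, 1L, stats::sd)
  kme <- suppressWarnings(as.numeric(stats::cor(t(expr), eigengene)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s): kME set to 0")
    kme[sds == 0] <- 0
  }
  stats::setNames(kme, rownames(expr))
}

#' Select hub genes by kME
#'
#' Top `n_hubs` module members by kME, ties broken by lexicographic gene
#' id; modules smaller than `n_hubs` return all members.
#'
#' @param kme Named kME vector for the module's members.
#' @param n_hubs Number of hubs (default 3).
#' @return Data frame gene_id, kme, rank (sorted by decreasing kME).
#' @export
select_hubs <- function(kme, n_hubs = 3L) {
  ord <- order(-kme, names(kme))
  take <- utils::head(ord, n_hubs)
  data.frame(gene_id = names(kme)[take], kme = unname(kme[take]),
             rank = seq_along(take), stringsAsFactors = FALSE)
}

#' Export the top-weight network edges
#'
#' Upper-triangle edges sorted by decreasing weight, deterministic
#' tie-break by (source, target) gene ids; each unordered pair appears
#' once.
#'
#' @param weights Symmetric weight matrix (TOM or adjacency).
#' @param n Number of edges to keep (conventionally 50-100; all edges if
#'   fewer exist).
#' @param path Optional TSV output path (3 columns: source, target,
#'   weight).
#' @return Data frame source, target, weight.
#' @export
export_top_edges <- function(weights, n = 100L, path = NULL) {
  g <- rownames(weights)
  if (is.null(g)) g <- paste0("g", seq_len(nrow(weights)))
  idx <- which(upper.tri(weights), arr.ind = TRUE)
  src <- g[idx[, 1L]]
  tgt <- g[idx[, 2L]]
  swap <- src > tgt
  tmp <- src[swap]; src[swap] <- tgt[swap]; tgt[swap] <- tmp
  w <- weights[idx]
  ord <- order(-w, src, tgt)
  take <- utils::head(ord, n)
  out <- data.frame(source = src[take], target = tgt[take],
                    weight = w[take], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) write_table(out, path)
  out
}
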