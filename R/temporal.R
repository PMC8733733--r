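#' Parameters for temporal soft clustering
#'
#' @param n_clusters Number of fuzzy clusters c (default 12).
#' @param fuzzifier Fuzziness exponent m > 1 (default 1.25; near-crisp
#'   memberships, the conventional choice for standardized expression
#'   profiles).
#' @param membership_min Minimum membership for a gene to be assigned to
#'   its top cluster (default 0.5).
#' @param max_iter,tol Convergence controls for the alternating updates.
#' @param n_starts Number of seeded random restarts; the run with the
#'   lowest objective is kept (default 5).
#' @param seed Integer seed for the random initial memberships.
#' @return A `fuzzy_params` list.
#' @export
fuzzy_params <- function(n_clusters = 12L, fuzzifier = 1.25,
                         membership_min = 0.5, max_iter = 300L,
                         tol = 1e-6, n_starts = 5L, seed = 1L) {
  stopifnot(n_clusters >= 2L, fuzzifier > 1, membership_min > 0,
            membership_min <= 1, max_iter >= 1L, tol > 0, n_starts >= 1L)
  structure(list(n_clusters = as.integer(n_clusters), fuzzifier = fuzzifier,
                 membership_min = membership_min,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "fuzzy_params")
}

#' Standardize stage-course expression profiles
#'
#' Per gene, z-scores log2(FPKM + 1) across the stage axis.  Genes whose
#' raw profile is constant carry no temporal signal and are excluded.
#'
#' @param group_expr Group-mean FPKM matrix restricted to one cultivar's
#'   stage columns (genes x stages); column names must be `cultivar:stage`
#'   or plain stage values.
#' @param stages Optional integer vector declaring the stage order; by
#'   default parsed from the column names.
#' @return Matrix of standardized profiles (genes x stages, columns named
#'   by stage), with attribute `n_constant` (genes excluded).
#' @export
standardize_profiles <- function(group_expr, stages = NULL) {
  if (is.null(stages)) {
    stages <- as.integer(sub("^.*:", "", colnames(group_expr)))
    if (anyNA(stages)) stop("cannot parse stages from column names; ",
                            "supply `stages`")
  }
  if (length(stages) != ncol(group_expr)) {
    stop("`stages` length must match the number of columns")
  }
  ord <- order(stages)
  x <- log2(group_expr[, ord, drop = FALSE] + 1)
  colnames(x) <- stages[ord]
  sds <- apply(x, 1L, stats::sd)
  keep <- sds > 0
  z <- t(scale(t(x[keep, , drop = FALSE])))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "n_constant") <- sum(!keep)
  z
}

#' Fuzzy c-means clustering
#'
#' Alternating minimisation of the fuzzy c-means objective
#' `J = sum_ij u_ij^m d_ij^2` (Euclidean distance): memberships
#' `u_ij = 1 / sum_k (d_ij/d_ik)^(2/(m-1))`, centers
#' `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`.  Initialised from seeded
#' random memberships; a point coinciding with a center receives full
#' membership in (the nearest of) those clusters.  The run is
#' deterministic given `seed` and leaves the global RNG state untouched.
#'
#' @param x Numeric matrix of profiles (rows = objects).
#' @param centers Number of clusters c.
#' @param m Fuzzifier (> 1).
#' @param max_iter,tol Stop when the objective decreases by less than
#'   `tol` or after `max_iter` iterations.
#' @param n_starts Seeded random restarts (seeds `seed`, `seed + 1`, ...);
#'   the restart with the lowest final objective is returned.
#' @param seed Integer seed for the initial memberships.
#' @return A `fuzzy_cmeans` list: `centers` (c x p), `membership`
#'   (n x c, rows sum to 1), `objective`, `objective_trace`, `iterations`,
#'   `converged`.
#' @export
fuzzy_cmeans <- function(x, centers, m = 1.25, max_iter = 300L,
                         tol = 1e-6, n_starts = 1L, seed = 1L) {
  if (n_starts > 1L) {
    fits <- lapply(seq_len(n_starts) - 1L, function(k) {
      fuzzy_cmeans(x, centers, m = m, max_iter = max_iter, tol = tol,
                   n_starts = 1L, seed = seed + k)
    })
    objs <- vapply(fits, `[[`, 0, "objective")
    return(fits[[which.min(objs)]])
  }
  x <- as.matrix(x)
  n <- nrow(x)
  c <- as.integer(centers)
  if (c < 2L) stop("need at least 2 clusters")
  if (n < c) stop("more clusters (", c, ") than profiles (", n, ")")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  u <- .with_seed(seed, {
    u0 <- matrix(stats::runif(n * c), n, c)
    u0 / rowSums(u0)
  })
  obj_trace <- numeric(0L)
  obj_old <- Inf
  converged <- FALSE
  cent <- NULL
  for (it in seq_len(max_iter)) {
    um <- u^m
    cent <- crossprod(um, x) / colSums(um)
    d2 <- .sqdist(x, cent)                     # n x c squared distances
    obj <- sum(um * d2)
    obj_trace <- c(obj_trace, obj)
    u <- .fcm_memberships(d2, m)
    if (is.finite(obj_old) && abs(obj_old - obj) < tol) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  rownames(cent) <- paste0("C", seq_len(c))
  colnames(cent) <- colnames(x)
  dimnames(u) <- list(rownames(x), rownames(cent))
  structure(list(centers = cent, membership = u, objective = obj_trace[length(obj_trace)],
                 objective_trace = obj_trace, iterations = length(obj_trace),
                 converged = converged, m = m),
            class = "fuzzy_cmeans")
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat("fuzzy_cmeans: ", nrow(x$membership), " profiles, ",
      nrow(x$centers), " clusters, m = ", x$m, "\n",
      "objective ", format(x$objective), " after ", x$iterations,
      " iterations (", if (x$converged) "converged" else "max_iter", ")\n",
      sep = "")
  invisible(x)
}

.sqdist <- function(x, cent) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(cent))) +
    outer(rep(1, nrow(x)), rowSums(cent^2)) - 2 * tcrossprod(x, cent)
  pmax(d2, 0)
}

.fcm_memberships <- function(d2, m) {
  pw <- d2^(-1 / (m - 1))
  zero <- d2 <= .Machine$double.eps
  u <- pw / rowSums(pw)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    for (i in which(hit)) {
      u[i, ] <- 0
      u[i, which(zero[i, ])[1L]] <- 1
    }
  }
  u
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Assign each gene a cluster and predominant (peak) stage
#'
#' A gene is assigned to its maximum-membership cluster when that
#' membership reaches `membership_min`.  A cluster's peak stage is the
#' stage at which its center is maximal; the gene's predominant stage is
#' its cluster's peak if that peak lies in `peak_stages` (by default the
#' elongation / secondary-cell-wall stages 10, 20, 25 DPA), otherwise none.
#'
#' @param fit `fuzzy_cmeans` result on stage profiles (center columns
#'   named by stage).
#' @param membership_min Assignment gate (default 0.5).
#' @param peak_stages Stages eligible as predominant stages.
#' @return Data frame: gene_id, cluster (integer, NA if unassigned),
#'   membership, cluster_peak (stage of the assigned cluster's maximum),
#'   peak_stage (NA when unassigned or when the cluster peaks outside
#'   `peak_stages`).
#' @export
assign_peak_stage <- function(fit, membership_min = 0.5,
                              peak_stages = c(10L, 20L, 25L)) {
  stages <- as.integer(colnames(fit$centers))
  if (anyNA(stages)) stop("cluster centers lack stage column names")
  cluster_peak <- stages[apply(fit$centers, 1L, which.max)]
  top <- apply(fit$membership, 1L, which.max)
  mem <- fit$membership[cbind(seq_along(top), top)]
  assigned <- mem >= membership_min
  peak <- ifelse(assigned, cluster_peak[top], NA_integer_)
  peak[!is.na(peak) & !(peak %in% peak_stages)] <- NA_integer_
  data.frame(gene_id = rownames(fit$membership),
             cluster = ifelse(assigned, top, NA_integer_),
             membership = mem,
             cluster_peak = ifelse(assigned, cluster_peak[top], NA_integer_),
             peak_stage = peak, stringsAsFactors = FALSE)
}

#' Cross-species comparison of predominant stages
#'
#' For each stage, splits linked ortholog pairs into those predominantly
#' expressed at that stage in both species (consistent) and those
#' predominant at the stage in exactly one species.
#'
#' @param assign_gh,assign_gb Outputs of [assign_peak_stage()] for the two
#'   species' reference cultivars.
#' @param orthologs Gene-level link table (`gene_gh`, `gene_gb`), e.g.
#'   `ortholog_pair_links(pairs)$genes`.
#' @param stages Stages to report (default 10, 20, 25 DPA).
#' @return Named list per stage, each with data frames `consistent`,
#'   `gh_only`, `gb_only` and a `counts` vector.
#' @export
compare_predominance <- function(assign_gh, assign_gb, orthologs,
                                 stages = c(10L, 20L, 25L)) {
  m <- .merge_assignments(assign_gh, assign_gb, orthologs)
  out <- lapply(stages, function(s) {
    gh_at <- !is.na(m$stage_gh) & m$stage_gh == s
    gb_at <- !is.na(m$stage_gb) & m$stage_gb == s
    list(consistent = m[gh_at & gb_at, , drop = FALSE],
         gh_only = m[gh_at & !gb_at, , drop = FALSE],
         gb_only = m[gb_at & !gh_at, , drop = FALSE],
         counts = c(consistent = sum(gh_at & gb_at),
                    gh_only = sum(gh_at & !gb_at),
                    gb_only = sum(gb_at & !gh_at)))
  })
  names(out) <- paste0("dpa", stages)
  out
}

.merge_assignments <- function(assign_gh, assign_gb, orthologs) {
  m <- merge(orthologs,
             assign_gh[, c("gene_id", "peak_stage")],
             by.x = "gene_gh", by.y = "gene_id")
  names(m)[names(m) == "peak_stage"] <- "stage_gh"
  m <- merge(m, assign_gb[, c("gene_id", "peak_stage")],
             by.x = "gene_gb", by.y = "gene_id")
  names(m)[names(m) == "peak_stage"] <- "stage_gb"
  m <- m[order(m$gene_gh), ]
  rownames(m) <- NULL
  m
}

.postponement_classes <- c("consistent", "postponed_10_20", "postponed_10_25",
                           "postponed_20_25", "advanced", "other",
                           "unassigned")

#' Classify temporally postponed expression across species
#'
#' Each linked ortholog pair receives exactly one class from its two peak
#' stages: `consistent` (same stage in both species), `postponed_10_20`,
#' `postponed_10_25`, `postponed_20_25` (peak later in the second species),
#' `advanced` (peak earlier in the second species), `unassigned` (either
#' side lacks a predominant stage) or `other`.
#'
#' @inheritParams compare_predominance
#' @return Data frame of class `postponement_calls`: gene_gh, gene_gb,
#'   stage_gh, stage_gb, class (factor); attribute `class_counts` tallies
#'   the classes, and `delayed_to_scw` counts the union of
#'   `postponed_10_20` and `postponed_10_25` (elongation-stage genes
#'   delayed into secondary-cell-wall stages).
#' @export
detect_postponement <- function(assign_gh, assign_gb, orthologs) {
  m <- .merge_assignments(assign_gh, assign_gb, orthologs)
  cls <- mapply(.postponement_class, m$stage_gh, m$stage_gb)
  m$class <- factor(cls, levels = .postponement_classes)
  counts <- table(m$class)
  attr(m, "class_counts") <- stats::setNames(as.integer(counts),
                                             names(counts))
  attr(m, "delayed_to_scw") <-
    sum(cls %in% c("postponed_10_20", "postponed_10_25"))
  class(m) <- c("postponement_calls", "data.frame")
  m
}

.postponement_class <- function(gh, gb) {
  if (is.na(gh) || is.na(gb)) return("unassigned")
  if (gh == gb) return("consistent")
  if (gb > gh) {
    lab <- paste0("postponed_", gh, "_", gb)
    if (lab %in% .postponement_classes) return(lab)
    return("other")
  }
  "advanced"
}
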