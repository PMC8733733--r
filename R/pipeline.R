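#' Run the homoeolog bias stage
#'
#' Calls per-pair bias for every (cultivar, stage) group at the requested
#' stages, summarises per cultivar (expressed / biased / A- vs D-biased
#' tallies, biased percentage, exact binomial direction test), forms the
#' strict cross-cultivar consensus per species, and classifies and counts
#' the interspecific categories when the pair map links the species.
#'
#' @param counts A `counts_table` (or path to a plain counts TSV).
#' @param sheet A `sample_sheet` (or path).
#' @param pairs A `pair_map` (or path).
#' @param params `bias_params()`.
#' @param stages Stages to analyse (default 10 and 20 DPA, the stages
#'   shared by all cultivars).
#' @param outdir Optional output directory for TSV results.
#' @param lengths Gene lengths when `counts` lacks them (vector or path).
#' @return List: `calls`, `summary`, `consensus` (per species/stage),
#'   `interspecific` (categories per stage), `interspecific_counts`.
#' @export
run_bias <- function(counts, sheet, pairs, params = bias_params(),
                     stages = c(10L, 20L), outdir = NULL, lengths = NULL) {
  if (is.character(counts)) counts <- read_counts(counts, "plain")
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(pairs)) pairs <- read_pair_map(pairs)
  if (is.character(lengths)) lengths <- read_lengths(lengths)
  if (!is.null(lengths) && inherits(counts, "counts_table") &&
      is.null(counts$lengths)) {
    counts$lengths <- lengths
  }
  calls <- call_pair_bias(counts, sheet, pairs, params, stages = stages)
  summ <- summarize_bias(calls, alpha = params$direction_alpha)
  consensus <- list()
  for (sp in unique(calls$species)) {
    for (s in intersect(stages, calls$stage_dpa[calls$species == sp])) {
      consensus[[paste0(sp, ":", s)]] <- species_consensus(calls, sp, s)
    }
  }
  interspecific <- list()
  inter_counts <- list()
  if (all(c("species", "ortholog_pair") %in% names(pairs)) &&
      all(c("Gh", "Gb") %in% calls$species)) {
    links <- ortholog_pair_links(pairs)$pairs
    for (s in stages) {
      kg <- paste0("Gh:", s); kb <- paste0("Gb:", s)
      if (is.null(consensus[[kg]]) || is.null(consensus[[kb]])) next
      cats <- classify_interspecific(consensus[[kg]], consensus[[kb]], links)
      interspecific[[as.character(s)]] <- cats
      inter_counts[[as.character(s)]] <- count_interspecific(cats)
    }
  }
  res <- list(calls = calls, summary = summ, consensus = consensus,
              interspecific = interspecific,
              interspecific_counts = inter_counts)
  if (!is.null(outdir)) .write_bias_outputs(res, params, outdir)
  res
}

.param_header <- function(stage, params) {
  flat <- vapply(params, function(v) paste(format(unlist(v), trim = TRUE),
                                           collapse = ","), "")
  c(paste0("polyexpress ", as.character(utils::packageVersion("polyexpress")),
           "; stage=", stage),
    paste0("params: ", paste(names(flat), flat, sep = "=", collapse = "; ")))
}

.write_bias_outputs <- function(res, params, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hdr <- .param_header("bias", params)
  write_table(as.data.frame(res$calls), file.path(outdir, "bias_calls.tsv"),
              comments = hdr)
  summ <- res$summary
  summ$pct_biased <- round(summ$pct_biased, 2L)
  write_table(summ, file.path(outdir, "bias_summary.tsv"), comments = hdr)
  cons <- do.call(rbind, lapply(res$consensus, as.data.frame))
  if (!is.null(cons)) {
    write_table(cons, file.path(outdir, "bias_consensus.tsv"),
                comments = hdr)
    shared <- do.call(rbind, lapply(names(res$consensus), function(k) {
      sc <- attr(res$consensus[[k]], "shared_counts")
      data.frame(species = sub(":.*", "", k),
                 stage_dpa = as.integer(sub(".*:", "", k)),
                 shared_A = sc[["A_all"]], shared_D = sc[["D_all"]],
                 stringsAsFactors = FALSE)
    }))
    write_table(shared, file.path(outdir, "bias_shared_counts.tsv"),
                comments = hdr)
  }
  if (length(res$interspecific)) {
    cats <- do.call(rbind, lapply(res$interspecific, as.data.frame))
    write_table(cats, file.path(outdir, "bias_interspecific.tsv"),
                comments = hdr)
    tab <- do.call(rbind, lapply(names(res$interspecific_counts),
                                 function(s) {
      ic <- res$interspecific_counts[[s]]
      data.frame(stage_dpa = as.integer(s),
                 category = names(ic$by_category),
                 n = as.integer(ic$by_category),
                 stringsAsFactors = FALSE)
    }))
    write_table(tab, file.path(outdir, "bias_interspecific_counts.tsv"),
                comments = hdr)
  }
  invisible(outdir)
}

#' Run the temporal clustering and postponement stage
#'
#' For each species' reference cultivar, builds group-mean stage profiles,
#' standardizes them, soft-clusters with fuzzy c-means, assigns peak
#' stages, then compares predominance across species over the ortholog
#' links and classifies postponed expression.
#'
#' @inheritParams run_bias
#' @param params `fuzzy_params()`.
#' @param cultivar_gh,cultivar_gb Reference cultivars carrying the full
#'   time course (defaults TM-1 and Hai7124).
#' @param stages_required Stages the reference cultivars must have.
#' @return List per species (`profiles`, `fit`, `assignments`) plus
#'   `predominance`, `postponement`.
#' @export
run_temporal <- function(counts, sheet, pairs, params = fuzzy_params(),
                         cultivar_gh = "TM-1", cultivar_gb = "Hai7124",
                         stages_required = c(0L, 1L, 3L, 5L, 10L, 20L, 25L),
                         outdir = NULL, lengths = NULL) {
  if (is.character(counts)) counts <- read_counts(counts, "plain")
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(pairs)) pairs <- read_pair_map(pairs)
  if (is.character(lengths)) lengths <- read_lengths(lengths)
  fpkm <- compute_fpkm(counts, lengths)
  gm <- group_mean(fpkm, sheet)
  groups <- attr(gm, "groups")
  per_species <- list()
  refs <- c(Gh = cultivar_gh, Gb = cultivar_gb)
  for (sp in names(refs)) {
    cv <- refs[[sp]]
    have <- sort(groups$stage_dpa[groups$cultivar == cv])
    miss <- setdiff(stages_required, have)
    if (length(miss)) {
      stop("cultivar ", cv, " lacks stage(s): ",
           paste(miss, collapse = ", "))
    }
    cols <- groups$key[groups$cultivar == cv &
                         groups$stage_dpa %in% stages_required]
    sub <- gm[, cols, drop = FALSE]
    # restrict to this species' genes when the pair map declares species
    if ("species" %in% names(pairs)) {
      g <- with(pairs[pairs$species == sp, ], c(a_gene, d_gene))
      sub <- sub[intersect(rownames(sub), g), , drop = FALSE]
    }
    prof <- standardize_profiles(sub)
    fit <- fuzzy_cmeans(prof, centers = params$n_clusters,
                        m = params$fuzzifier, max_iter = params$max_iter,
                        tol = params$tol, n_starts = params$n_starts,
                        seed = params$seed)
    assign <- assign_peak_stage(fit, params$membership_min)
    per_species[[sp]] <- list(profiles = prof, fit = fit,
                              assignments = assign)
  }
  links <- ortholog_pair_links(pairs)$genes
  pred <- compare_predominance(per_species$Gh$assignments,
                               per_species$Gb$assignments, links)
  post <- detect_postponement(per_species$Gh$assignments,
                              per_species$Gb$assignments, links)
  res <- list(species = per_species, predominance = pred,
              postponement = post)
  if (!is.null(outdir)) .write_temporal_outputs(res, params, outdir)
  res
}

.write_temporal_outputs <- function(res, params, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hdr <- .param_header("temporal", params)
  for (sp in names(res$species)) {
    fit <- res$species[[sp]]$fit
    cent <- data.frame(cluster = rownames(fit$centers), fit$centers,
                       check.names = FALSE, stringsAsFactors = FALSE)
    write_table(cent, file.path(outdir, paste0("clusters_", sp, ".tsv")),
                comments = hdr)
    write_table(res$species[[sp]]$assignments,
                file.path(outdir, paste0("assignments_", sp, ".tsv")),
                comments = hdr)
  }
  post <- as.data.frame(res$postponement)
  write_table(post, file.path(outdir, "postponement.tsv"), comments = hdr)
  cc <- attr(res$postponement, "class_counts")
  write_table(data.frame(class = names(cc), n = as.integer(cc),
                         stringsAsFactors = FALSE),
              file.path(outdir, "postponement_counts.tsv"), comments = hdr)
  pred <- do.call(rbind, lapply(names(res$predominance), function(k) {
    data.frame(stage = k, t(res$predominance[[k]]$counts),
               stringsAsFactors = FALSE)
  }))
  write_table(pred, file.path(outdir, "predominance_counts.tsv"),
              comments = hdr)
  invisible(outdir)
}

#' Run the co-expression network stage for one species
#'
#' On log2(FPKM + 1) sample-level expression of one cultivar's time
#' course: picks a soft threshold, builds the unsigned adjacency and TOM,
#' detects and merges modules, computes module eigengenes, module-stage
#' correlations, kME, per-module hub genes and the top-weight edge list.
#'
#' @inheritParams run_bias
#' @param cultivar Cultivar whose samples form the network (all its
#'   stages' replicates; at least 8 samples).
#' @param params `network_params()`.
#' @param genes Optional gene ids to build the network on; default the
#'   `n_genes` most variable genes.
#' @param n_genes Variance-filter size when `genes` is NULL (default
#'   2000).
#' @return List: `beta`, `modules` (a `module_set`), `stage_cor`, `kme`
#'   (per-gene kME in its own module), `hubs` (per module, with best
#'   stage), `edges`.
#' @export
run_network <- function(counts, sheet, cultivar, params = network_params(),
                        genes = NULL, n_genes = 2000L, outdir = NULL,
                        lengths = NULL) {
  if (is.character(counts)) counts <- read_counts(counts, "plain")
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(lengths)) lengths <- read_lengths(lengths)
  fpkm <- compute_fpkm(counts, lengths)
  ids <- sheet$sample_id[sheet$cultivar == cultivar]
  if (length(ids) < 8L) {
    stop("cultivar ", cultivar, " has ", length(ids),
         " samples; need at least 8 for a network")
  }
  stages <- sheet$stage_dpa[match(ids, sheet$sample_id)]
  x <- log2(fpkm[, ids, drop = FALSE] + 1)
  if (is.null(genes)) {
    v <- apply(x, 1L, stats::var)
    genes <- names(sort(v, decreasing = TRUE))[seq_len(min(n_genes, nrow(x)))]
    genes <- sort(genes)
  }
  x <- x[genes, , drop = FALSE]
  beta <- pick_soft_threshold(x, params$beta_candidates,
                              params$scale_free_r2_target)
  adj <- wgcna_adjacency(x, beta)
  tom <- tom_similarity(adj)
  mods <- detect_modules(tom, x, params$min_module_size,
                         params$merge_cor_min)
  res <- list(beta = as.integer(beta), modules = mods, stage_cor = NULL,
              kme = NULL, hubs = NULL, edges = NULL, cultivar = cultivar)
  if (!is.null(mods$eigengenes)) {
    res$stage_cor <- module_trait_cor(mods$eigengenes, stages)
    kme_all <- list(); hubs <- list()
    for (m in colnames(mods$eigengenes)) {
      members <- names(mods$labels)[mods$labels == m]
      km <- module_kme(x[members, , drop = FALSE], mods$eigengenes[, m])
      kme_all[[m]] <- data.frame(gene_id = names(km), module = m,
                                 kme = unname(km), stringsAsFactors = FALSE)
      best_stage <- colnames(res$stage_cor$r)[which.max(abs(res$stage_cor$r[m, ]))]
      hb <- select_hubs(km, params$n_hubs)
      hb$module <- m
      hb$stage_dpa <- as.integer(best_stage)
      hubs[[m]] <- hb
    }
    res$kme <- do.call(rbind, kme_all)
    res$hubs <- do.call(rbind, hubs)
    rownames(res$kme) <- rownames(res$hubs) <- NULL
  }
  res$edges <- export_top_edges(tom, params$top_edges)
  if (!is.null(outdir)) .write_network_outputs(res, params, outdir)
  res
}

.write_network_outputs <- function(res, params, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hdr <- c(.param_header("network", params),
           paste0("cultivar=", res$cultivar, "; beta=", res$beta))
  tag <- gsub("[^A-Za-z0-9]", "", res$cultivar)
  write_table(data.frame(gene_id = names(res$modules$labels),
                         module = unname(res$modules$labels),
                         stringsAsFactors = FALSE),
              file.path(outdir, paste0("modules_", tag, ".tsv")),
              comments = hdr)
  if (!is.null(res$stage_cor)) {
    r <- res$stage_cor$r; p <- res$stage_cor$p
    long <- data.frame(
      module = rep(rownames(r), ncol(r)),
      stage_dpa = rep(as.integer(colnames(r)), each = nrow(r)),
      r = as.numeric(r), p = as.numeric(p), stringsAsFactors = FALSE)
    write_table(long, file.path(outdir, paste0("module_stage_cor_", tag,
                                               ".tsv")), comments = hdr)
    write_table(res$hubs, file.path(outdir, paste0("hubs_", tag, ".tsv")),
                comments = hdr)
    write_table(res$kme, file.path(outdir, paste0("kme_", tag, ".tsv")),
                comments = hdr)
  }
  write_table(res$edges, file.path(outdir, paste0("edges_", tag, ".tsv")),
              comments = hdr)
  invisible(outdir)
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper pairing [simulate_dataset()] with
#' [write_sim_dataset()].
#'
#' @param config A `sim_config()`.
#' @param outdir Output directory.
#' @return The `sim_dataset`, invisibly.
#' @export
run_simulate <- function(config = sim_config(), outdir) {
  sim <- simulate_dataset(config)
  write_sim_dataset(sim, outdir)
  invisible(sim)
}
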