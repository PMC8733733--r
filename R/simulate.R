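#' Configuration for the synthetic allotetraploid fiber dataset
#'
#' Defaults mirror the design of the study system: four upland-cotton
#' (Gh) and three sea-island-cotton (Gb) cultivars, a 7-stage fiber
#' development time course (0-25 days post-anthesis) for the two reference
#' cultivars and stages 10/20 for the rest, three replicates, ~2e7
#' fragments per library, negative-binomial counts.  Planted effects give
#' every downstream stage a known truth: homoeolog bias (2^(+/-log2fc/2)
#' on the A/D copies), cross-species peak-stage shifts (postponed
#' expression), and latent-factor co-expression modules with flat
#' background genes forming the network benchmark universe.
#'
#' @param n_pairs Homoeolog pairs per species (default 3000).
#' @param cultivars_gh,cultivars_gb Cultivar names; the first of each is
#'   the reference cultivar carrying the full time course.
#' @param stages_full,stages_short Stage sets (DPA) for reference and
#'   non-reference cultivars.
#' @param n_reps Replicates per (cultivar, stage) (default 3).
#' @param library_size Expected fragments per library (default 2e7).
#' @param nb_dispersion Negative-binomial dispersion (default 0.05).
#' @param frac_biased Fraction of pairs with planted bias per species
#'   (default 0.1), split evenly between A- and D-biased.
#' @param bias_log2fc Planted |log2 fold change| (default 2).
#' @param frac_postponed Fraction of pairs with a planted cross-species
#'   peak shift (default 0.1), split evenly among `peak_shifts`.
#' @param peak_shifts List of `c(from, to)` stage shifts
#'   (default 10->20 and 20->25 DPA).
#' @param n_modules,module_size Planted co-expression modules per species
#'   and genes per module (default 3 x 60; `module_size` must be even:
#'   both homoeologs of a reserved pair join the same module).
#' @param n_background Flat background genes in the network benchmark
#'   (default 120, must be even).
#' @param module_noise_sd Residual log-scale noise sd for benchmark genes
#'   (default 0.5).
#' @param base_fpkm_meanlog,base_fpkm_sdlog Log-normal baseline FPKM
#'   (default meanlog log(10), sdlog 1).
#' @param length_range Gene length range in bp (default 500-5000).
#' @param profile_floor Off-peak floor of the temporal profile as a
#'   fraction of baseline (default 0.05).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pairs = 3000L,
                       cultivars_gh = c("TM-1", "J220", "4005", "XLZ42"),
                       cultivars_gb = c("Hai7124", "R4-4", "3-79"),
                       stages_full = c(0L, 1L, 3L, 5L, 10L, 20L, 25L),
                       stages_short = c(10L, 20L),
                       n_reps = 3L,
                       library_size = 2e7,
                       nb_dispersion = 0.05,
                       frac_biased = 0.1,
                       bias_log2fc = 2,
                       frac_postponed = 0.1,
                       peak_shifts = list(c(10L, 20L), c(20L, 25L)),
                       n_modules = 3L,
                       module_size = 60L,
                       n_background = 120L,
                       module_noise_sd = 0.5,
                       base_fpkm_meanlog = log(10),
                       base_fpkm_sdlog = 1,
                       length_range = c(500L, 5000L),
                       profile_floor = 0.05,
                       seed = 1L) {
  stopifnot(n_pairs >= 1L, n_reps >= 1L, library_size > 0,
            nb_dispersion > 0, frac_biased >= 0, frac_biased <= 1,
            frac_postponed >= 0, frac_postponed <= 1,
            n_modules >= 0L, module_size >= 2L, n_background >= 0L,
            module_noise_sd >= 0, length_range[1L] >= 1L,
            length_range[2L] >= length_range[1L],
            all(stages_short %in% stages_full))
  if (module_size %% 2L != 0L || n_background %% 2L != 0L) {
    stop("module_size and n_background must be even (whole homoeolog pairs)")
  }
  n_reserved_pairs <- n_modules * module_size %/% 2L + n_background %/% 2L
  if (n_reserved_pairs >= n_pairs) {
    stop("module and background genes exceed the simulated gene pool")
  }
  for (s in peak_shifts) {
    if (!all(s %in% stages_full) || s[2L] <= s[1L]) {
      stop("each peak shift must be c(from, to) with to later, ",
           "both in stages_full")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a synthetic allotetraploid fiber expression dataset
#'
#' See [sim_config()] for the generative model.  Expected FPKM per gene
#' and sample is baseline x temporal profile (a discrete Gaussian bump
#' over the ordered stage axis, width one stage, floored at
#' `profile_floor` x baseline) x bias multiplier; network-benchmark genes
#' instead follow baseline x exp(loading x module factor + residual
#' noise).  Expected fragment counts are FPKM x length x library / 1e9
#' and observed counts are negative binomial with the configured
#' dispersion.  Deterministic given `config$seed`; the global RNG state
#' is left untouched.
#'
#' @param config A `sim_config`.
#' @return A `sim_dataset` list: `counts` (a `counts_table` with lengths),
#'   `sheet` (`sample_sheet`), `pairs` (`pair_map` with species and
#'   cross-species `ortholog_pair` links), and `truth` with elements
#'   `bias`, `peaks`, `postponement`, `modules`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  .with_seed(config$seed, .simulate_dataset_impl(config))
}

.simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_pairs
  n_mod_pairs <- cfg$n_modules * cfg$module_size %/% 2L
  n_res <- n_mod_pairs + cfg$n_background %/% 2L
  res_idx <- if (n_res > 0L) (n - n_res + 1L):n else integer(0L)
  ord_idx <- setdiff(seq_len(n), res_idx)

  # shared baseline per pair (A = D under the null, same in both species)
  base <- stats::rlnorm(n, cfg$base_fpkm_meanlog, cfg$base_fpkm_sdlog)
  lens <- matrix(sample(cfg$length_range[1L]:cfg$length_range[2L],
                        4L * n, replace = TRUE), nrow = n)

  # planted peaks: same in both species except postponed pairs
  peak_gh <- sample(cfg$stages_full, n, replace = TRUE)
  peak_gb <- peak_gh
  n_post <- round(cfg$frac_postponed * length(ord_idx))
  post_idx <- if (n_post > 0L) sort(sample(ord_idx, n_post)) else integer(0L)
  shift_of <- integer(0L)
  if (n_post > 0L) {
    shift_of <- rep(seq_along(cfg$peak_shifts), length.out = n_post)
    for (j in seq_along(cfg$peak_shifts)) {
      sel <- post_idx[shift_of == j]
      peak_gh[sel] <- cfg$peak_shifts[[j]][1L]
      peak_gb[sel] <- cfg$peak_shifts[[j]][2L]
    }
  }
  peak_gh[res_idx] <- NA_integer_
  peak_gb[res_idx] <- NA_integer_

  # planted bias per species, direction split 50:50
  bias_dir <- list()
  for (sp in c("Gh", "Gb")) {
    dir <- rep("none", n)
    n_b <- round(cfg$frac_biased * length(ord_idx))
    if (n_b > 0L) {
      sel <- sort(sample(ord_idx, n_b))
      dir[sel] <- rep(c("A", "D"), length.out = n_b)
    }
    bias_dir[[sp]] <- dir
  }

  # module structure: labels per reserved pair, per-species factors/loadings
  mod_of_pair <- rep(NA_character_, n)
  if (n_mod_pairs > 0L) {
    msp <- cfg$module_size %/% 2L
    mod_of_pair[res_idx[seq_len(n_mod_pairs)]] <-
      rep(paste0("M", seq_len(cfg$n_modules)), each = msp)
  }
  if (n_res > n_mod_pairs) {
    mod_of_pair[res_idx[(n_mod_pairs + 1L):n_res]] <- "none"
  }
  factors <- list(); loadings <- list()
  for (sp in c("Gh", "Gb")) {
    n_st <- length(cfg$stages_full)
    f <- matrix(0, nrow = max(cfg$n_modules, 1L), ncol = n_st,
                dimnames = list(NULL, cfg$stages_full))
    if (cfg$n_modules > 0L) {
      if (cfg$n_modules >= n_st) {
        stop("n_modules must be smaller than the number of stages")
      }
      # random stage trends, mutually decorrelated so each planted module
      # carries an identifiable signature (centre, orthogonalise, rescale)
      f0 <- matrix(stats::rnorm(n_st * cfg$n_modules), n_st)
      f0 <- sweep(f0, 2L, colMeans(f0))
      q <- qr.Q(qr(f0))
      f <- t(apply(t(q), 1L, function(v) as.numeric(scale(v))))
      dimnames(f) <- list(NULL, cfg$stages_full)
    }
    factors[[sp]] <- f
    loadings[[sp]] <- stats::runif(n, 0.6, 1)   # used for reserved pairs only
  }

  species <- list(Gh = list(cultivars = cfg$cultivars_gh, col = 1:2),
                  Gb = list(cultivars = cfg$cultivars_gb, col = 3:4))
  sheets <- list(); count_blocks <- list(); gene_ids <- list()
  stage_index <- stats::setNames(seq_along(cfg$stages_full),
                                 cfg$stages_full)
  for (sp in names(species)) {
    cvs <- species[[sp]]$cultivars
    ref <- cvs[1L]
    rows <- list()
    for (cv in cvs) {
      st <- if (cv == ref) cfg$stages_full else cfg$stages_short
      for (s in st) for (r in seq_len(cfg$n_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste(cv, s, r, sep = "_"), species = sp,
          cultivar = cv, stage_dpa = s, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
    sheet <- do.call(rbind, rows)
    ga <- sprintf("%sA%05d", sp, seq_len(n))
    gd <- sprintf("%sD%05d", sp, seq_len(n))
    gids <- c(rbind(ga, gd))                 # interleaved A,D per pair
    peak <- if (sp == "Gh") peak_gh else peak_gb
    dirv <- bias_dir[[sp]]
    half <- cfg$bias_log2fc / 2
    mult_a <- ifelse(dirv == "A", 2^half, ifelse(dirv == "D", 2^-half, 1))
    mult_d <- ifelse(dirv == "A", 2^-half, ifelse(dirv == "D", 2^half, 1))
    mu <- matrix(NA_real_, nrow = 2L * n, ncol = nrow(sheet),
                 dimnames = list(gids, sheet$sample_id))
    si <- stage_index[as.character(sheet$stage_dpa)]
    for (p in seq_len(n)) {
      if (p %in% res_idx) {
        lab <- mod_of_pair[p]
        eff <- if (lab == "none") 0 else
          loadings[[sp]][p] * factors[[sp]][as.integer(sub("M", "", lab)), si]
        # residual shared by the two homoeologs: benchmark pairs stay
        # unbiased nulls for the bias caller
        noise <- stats::rnorm(nrow(sheet), 0, cfg$module_noise_sd)
        mu[2L * p - 1L, ] <- base[p] * exp(eff + noise)
        mu[2L * p, ] <- base[p] * exp(eff + noise)
      } else {
        # unit-mean profile: the stage-wise expected mass of the gene pool
        # stays level, so realized library sizes carry no stage trend
        shape <- pmax(exp(-(seq_along(cfg$stages_full) -
                              stage_index[as.character(peak[p])])^2 / 2),
                      cfg$profile_floor)
        bump <- (shape / mean(shape))[si]
        mu[2L * p - 1L, ] <- base[p] * bump * mult_a[p]
        mu[2L * p, ] <- base[p] * bump * mult_d[p]
      }
    }
    len_sp <- if (sp == "Gh") c(rbind(lens[, 1L], lens[, 2L])) else
      c(rbind(lens[, 3L], lens[, 4L]))
    ec <- mu * len_sp * cfg$library_size / 1e9
    obs <- matrix(stats::rnbinom(length(ec), mu = ec,
                                 size = 1 / cfg$nb_dispersion),
                  nrow = nrow(ec), dimnames = dimnames(ec))
    sheets[[sp]] <- sheet
    count_blocks[[sp]] <- obs
    gene_ids[[sp]] <- list(a = ga, d = gd, lengths =
                             stats::setNames(len_sp, gids))
  }

  sheet <- as_sample_sheet(do.call(rbind, sheets),
                           stages = cfg$stages_full)
  all_genes <- c(rownames(count_blocks$Gh), rownames(count_blocks$Gb))
  counts <- matrix(0L, nrow = length(all_genes), ncol = nrow(sheet),
                   dimnames = list(all_genes, sheet$sample_id))
  counts[rownames(count_blocks$Gh), colnames(count_blocks$Gh)] <-
    count_blocks$Gh
  counts[rownames(count_blocks$Gb), colnames(count_blocks$Gb)] <-
    count_blocks$Gb
  storage.mode(counts) <- "integer"
  lengths_all <- c(gene_ids$Gh$lengths, gene_ids$Gb$lengths)
  ct <- structure(list(counts = counts, lengths = lengths_all),
                  class = "counts_table")

  pid <- function(sp) sprintf("%sP%05d", sp, seq_len(n))
  pairs <- rbind(
    data.frame(pair_id = pid("Gh"), a_gene = gene_ids$Gh$a,
               d_gene = gene_ids$Gh$d, species = "Gh",
               ortholog_pair = pid("Gb"), stringsAsFactors = FALSE),
    data.frame(pair_id = pid("Gb"), a_gene = gene_ids$Gb$a,
               d_gene = gene_ids$Gb$d, species = "Gb",
               ortholog_pair = pid("Gh"), stringsAsFactors = FALSE))
  pairs <- as_pair_map(pairs)

  truth_bias <- rbind(
    data.frame(pair_id = pid("Gh"), species = "Gh",
               direction = bias_dir$Gh,
               log2fc = ifelse(bias_dir$Gh == "A", cfg$bias_log2fc,
                               ifelse(bias_dir$Gh == "D",
                                      -cfg$bias_log2fc, 0)),
               stringsAsFactors = FALSE),
    data.frame(pair_id = pid("Gb"), species = "Gb",
               direction = bias_dir$Gb,
               log2fc = ifelse(bias_dir$Gb == "A", cfg$bias_log2fc,
                               ifelse(bias_dir$Gb == "D",
                                      -cfg$bias_log2fc, 0)),
               stringsAsFactors = FALSE))

  truth_peaks <- rbind(
    data.frame(gene_id = rownames(count_blocks$Gh), species = "Gh",
               peak_stage = rep(peak_gh, each = 2L),
               stringsAsFactors = FALSE),
    data.frame(gene_id = rownames(count_blocks$Gb), species = "Gb",
               peak_stage = rep(peak_gb, each = 2L),
               stringsAsFactors = FALSE))

  cls <- rep("consistent", n)
  if (n_post > 0L) {
    for (j in seq_along(cfg$peak_shifts)) {
      sel <- post_idx[shift_of == j]
      cls[sel] <- paste0("postponed_", cfg$peak_shifts[[j]][1L], "_",
                         cfg$peak_shifts[[j]][2L])
    }
  }
  keep <- ord_idx
  truth_post <- data.frame(
    gene_gh = c(rbind(gene_ids$Gh$a[keep], gene_ids$Gh$d[keep])),
    gene_gb = c(rbind(gene_ids$Gb$a[keep], gene_ids$Gb$d[keep])),
    class = rep(cls[keep], each = 2L), stringsAsFactors = FALSE)

  truth_modules <- NULL
  if (n_res > 0L) {
    lab <- mod_of_pair[res_idx]
    truth_modules <- rbind(
      data.frame(gene_id = c(rbind(gene_ids$Gh$a[res_idx],
                                   gene_ids$Gh$d[res_idx])),
                 species = "Gh", module = rep(lab, each = 2L),
                 loading = rep(ifelse(lab == "none", NA_real_,
                                      loadings$Gh[res_idx]), each = 2L),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = c(rbind(gene_ids$Gb$a[res_idx],
                                   gene_ids$Gb$d[res_idx])),
                 species = "Gb", module = rep(lab, each = 2L),
                 loading = rep(ifelse(lab == "none", NA_real_,
                                      loadings$Gb[res_idx]), each = 2L),
                 stringsAsFactors = FALSE))
  }

  structure(list(counts = ct, sheet = sheet, pairs = pairs,
                 truth = list(bias = truth_bias, peaks = truth_peaks,
                              postponement = truth_post,
                              modules = truth_modules),
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: ", nrow(x$counts$counts), " genes x ",
      ncol(x$counts$counts), " samples; ",
      nrow(x$pairs), " homoeolog pairs (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a simulated dataset as a directory of TSV files
#'
#' Emits `counts.tsv` (plain dialect), `lengths.tsv`, `samples.tsv`,
#' `pairs.tsv`, the truth tables (`truth_*.tsv`) and a `config.tsv` echo,
#' all readable back through the package's readers.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_sim_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- paste0("simulated dataset; seed=", sim$config$seed)
  cdf <- data.frame(gene_id = rownames(sim$counts$counts),
                    sim$counts$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_table(cdf, file.path(dir, "counts.tsv"), comments = hdr)
  write_table(data.frame(gene_id = names(sim$counts$lengths),
                         length = unname(sim$counts$lengths),
                         stringsAsFactors = FALSE),
              file.path(dir, "lengths.tsv"), comments = hdr)
  write_table(as.data.frame(sim$sheet), file.path(dir, "samples.tsv"),
              comments = hdr)
  write_table(as.data.frame(sim$pairs), file.path(dir, "pairs.tsv"),
              comments = hdr)
  write_table(sim$truth$bias, file.path(dir, "truth_bias.tsv"),
              comments = hdr)
  write_table(sim$truth$peaks, file.path(dir, "truth_peaks.tsv"),
              comments = hdr)
  write_table(sim$truth$postponement,
              file.path(dir, "truth_postponement.tsv"), comments = hdr)
  if (!is.null(sim$truth$modules)) {
    write_table(sim$truth$modules, file.path(dir, "truth_modules.tsv"),
                comments = hdr)
  }
  cfg <- sim$config
  echo <- data.frame(
    key = names(cfg),
    value = vapply(cfg, function(v)
      paste(format(unlist(v), trim = TRUE), collapse = ","), ""),
    stringsAsFactors = FALSE)
  write_table(echo, file.path(dir, "config.tsv"), comments = hdr)
  invisible(dir)
}

#' Benchmark bias calls against planted truth
#'
#' Sensitivity is the fraction of planted-biased, testable pairs (those
#' passing the expression filter) called biased in the planted direction;
#' `sensitivity_all` uses all planted pairs as denominator.  Empirical
#' FDR is the fraction of biased calls whose pair carries no planted
#' bias; direction accuracy is the fraction of biased calls on planted
#' pairs matching the planted direction.
#'
#' @param calls `bias_calls` from [call_pair_bias()].
#' @param truth Data frame `truth$bias` from [simulate_dataset()].
#' @return List: sensitivity, sensitivity_all, empirical_fdr,
#'   direction_accuracy, n_planted, n_tested_planted, n_called.
#' @export
evaluate_bias_recovery <- function(calls, truth) {
  m <- merge(calls, truth, by = c("pair_id", "species"))
  called <- m$call %in% c("A_biased", "D_biased")
  call_dir <- ifelse(m$call == "A_biased", "A",
                     ifelse(m$call == "D_biased", "D", "none"))
  planted <- m$direction != "none"
  tested <- m$call != "not_expressed"
  correct <- called & planted & call_dir == m$direction
  n_tp <- sum(planted & tested)
  sens <- if (n_tp > 0) sum(correct & tested) / n_tp else NA_real_
  sens_all <- if (sum(planted) > 0) sum(correct) / sum(planted) else NA_real_
  fdr <- if (sum(called) > 0) sum(called & !planted) / sum(called) else
    NA_real_
  dir_acc <- if (sum(called & planted) > 0) {
    sum(correct) / sum(called & planted)
  } else NA_real_
  list(sensitivity = sens, sensitivity_all = sens_all, empirical_fdr = fdr,
       direction_accuracy = dir_acc, n_planted = sum(planted),
       n_tested_planted = n_tp, n_called = sum(called))
}

#' Benchmark postponement calls against planted truth
#'
#' @param calls `postponement_calls` from [detect_postponement()].
#' @param truth Data frame `truth$postponement` from [simulate_dataset()].
#' @return List: `sensitivity` (named, per planted shift class),
#'   `empirical_fdr` (fraction of postponed calls on genes planted
#'   consistent), `advanced_rate` (planted-postponed genes called
#'   advanced), and counts.
#' @export
evaluate_postponement_recovery <- function(calls, truth) {
  m <- merge(as.data.frame(calls), truth, by = c("gene_gh", "gene_gb"),
             suffixes = c("_called", "_planted"))
  names(m)[names(m) == "class_called"] <- "called"
  names(m)[names(m) == "class_planted"] <- "planted"
  shift_classes <- setdiff(unique(m$planted), "consistent")
  sens <- vapply(shift_classes, function(cl) {
    sel <- m$planted == cl
    if (!sum(sel)) return(NA_real_)
    mean(m$called[sel] == cl)
  }, 0)
  called_post <- grepl("^postponed_", m$called)
  fdr <- if (sum(called_post) > 0) {
    sum(called_post & m$planted == "consistent") / sum(called_post)
  } else NA_real_
  adv <- if (length(shift_classes)) {
    sel <- m$planted %in% shift_classes
    mean(m$called[sel] == "advanced")
  } else NA_real_
  list(sensitivity = sens, empirical_fdr = fdr, advanced_rate = adv,
       n_planted = sum(m$planted != "consistent"),
       n_called_postponed = sum(called_post))
}

#' Adjusted Rand index between detected and planted module labels
#'
#' Labels are compared over the genes present in both labelings;
#' unassigned genes (detected "grey" / planted "none") each form one
#' label.
#'
#' @param labels Named label vector (e.g. `module_set$labels`).
#' @param truth Named label vector, or the `truth$modules` data frame
#'   (optionally filtered to one species beforehand).
#' @return Adjusted Rand index (1 = identical partitions, ~0 = random).
#' @export
evaluate_module_recovery <- function(labels, truth) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$module, truth$gene_id)
  }
  common <- intersect(names(labels), names(truth))
  if (!length(common)) stop("no genes shared between labelings")
  mclust::adjustedRandIndex(labels[common], truth[common])
}
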