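# memoised simulated datasets shared across test files
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_dataset(config)
  }
  .sim_cache[[key]]
}

sim_default <- function() cached_sim("default", sim_config(seed = 1L))

sim_small <- function() cached_sim("small", sim_config(n_pairs = 400L,
                                                       seed = 1L))

sim_null <- function() cached_sim("null", sim_config(n_pairs = 2000L,
                                                     frac_biased = 0,
                                                     seed = 1L))

# a tiny counts_table for hand-crafted bias scenarios: one cultivar,
# one stage, one replicate per subgenome-gene row
tiny_counts <- function(counts, lengths = NULL) {
  m <- as.matrix(counts)
  storage.mode(m) <- "integer"
  if (is.null(lengths)) {
    lengths <- stats::setNames(rep(1000L, nrow(m)), rownames(m))
  }
  structure(list(counts = m, lengths = lengths), class = "counts_table")
}

tiny_sheet <- function(sample_ids, cultivar = "TM-1", species = "Gh",
                       stage = 10L) {
  as_sample_sheet(data.frame(
    sample_id = sample_ids, species = species, cultivar = cultivar,
    stage_dpa = stage, replicate = seq_along(sample_ids),
    stringsAsFactors = FALSE))
}

tiny_pairs <- function(a, d, species = NULL) {
  df <- data.frame(pair_id = paste0("p", seq_along(a)), a_gene = a,
                   d_gene = d, stringsAsFactors = FALSE)
  if (!is.null(species)) df$species <- species
  as_pair_map(df)
}

# independent Fisher oracle: enumerate all tables with the observed
# margins, probabilities from the factorial formula via lgamma
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  lo <- max(0L, r1 - c2); hi <- min(r1, c1)
  logp <- vapply(lo:hi, function(x) {
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(n + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(c2 - r1 + x + 1)
  }, 0)
  p <- exp(logp)
  obs <- p[(lo:hi) == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# construct peak-stage assignment tables directly (bypassing clustering)
make_assignment <- function(genes, peaks) {
  data.frame(gene_id = genes, cluster = 1L, membership = 1,
             cluster_peak = peaks, peak_stage = peaks,
             stringsAsFactors = FALSE)
}
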