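# hand-crafted one-group scenarios for the bias caller ------------------

make_bias_fixture <- function(count_a, count_d, filler = 2e6L) {
  genes <- c("a1", "d1", "fillerA", "fillerD")
  m <- matrix(c(count_a, count_d, filler, filler), 4, 1,
              dimnames = list(genes, "s1"))
  list(counts = tiny_counts(m),
       sheet = tiny_sheet("s1"),
       pairs = tiny_pairs(c("a1", "fillerA"), c("d1", "fillerD")))
}

test_that("identical homoeolog counts yield p = 1 and no bias", {
  fx <- make_bias_fixture(5000L, 5000L)
  calls <- call_pair_bias(fx$counts, fx$sheet, fx$pairs)
  row <- calls[calls$pair_id == "p1", ]
  expect_equal(row$p_raw, 1)
  expect_equal(row$call, "unbiased")
  expect_equal(row$log2fc, 0)
})

test_that("the two-fold FPKM gate blocks significant sub-2-fold ratios", {
  # ratio 1.8 with large counts: tiny Fisher p but below the fold gate
  fx <- make_bias_fixture(90000L, 50000L)
  calls <- call_pair_bias(fx$counts, fx$sheet, fx$pairs)
  row <- calls[calls$pair_id == "p1", ]
  expect_lt(row$q, 0.05)
  expect_lt(row$log2fc, 1)
  expect_equal(row$call, "unbiased")
})

test_that("a strong A:D ratio with small q is called in the A direction", {
  fx <- make_bias_fixture(40000L, 5000L)
  calls <- call_pair_bias(fx$counts, fx$sheet, fx$pairs)
  row <- calls[calls$pair_id == "p1", ]
  expect_equal(row$call, "A_biased")
  expect_gt(row$log2fc, 1)
})

test_that("a silenced homoeolog passes the fold gate with infinite log2fc", {
  fx <- make_bias_fixture(20000L, 0L)
  calls <- call_pair_bias(fx$counts, fx$sheet, fx$pairs)
  row <- calls[calls$pair_id == "p1", ]
  expect_identical(row$log2fc, Inf)
  expect_equal(row$call, "A_biased")
})

test_that("pairs under the expression filter are not tested", {
  fx <- make_bias_fixture(3L, 1L)       # FPKM far below 1 at 2e6 library
  calls <- call_pair_bias(fx$counts, fx$sheet, fx$pairs)
  row <- calls[calls$pair_id == "p1", ]
  expect_equal(row$call, "not_expressed")
  expect_true(is.na(row$p_raw))
})

test_that("summaries tally calls and compute the biased percentage", {
  # summary-row arithmetic on reference tallies
  r <- bias_summary_row(14595, 1733, 1924)
  expect_equal(r$total_biased, 3657)
  expect_equal(round(r$pct_biased, 2), 25.06)
  expect_equal(r$direction, "Dt")
  r0 <- bias_summary_row(100, 0, 0)
  expect_equal(r0$pct_biased, 0)
  expect_equal(r0$direction, "none")
  expect_error(bias_summary_row(10, 9, 2), "exceed")
})

test_that("summarize_bias aggregates per cultivar and stage", {
  s <- sim_small()
  calls <- call_pair_bias(s$counts, s$sheet, s$pairs,
                          stages = c(10L, 20L))
  summ <- summarize_bias(calls)
  expect_equal(nrow(summ), 14L)        # 7 cultivars x 2 stages
  expect_equal(summ$total_biased, summ$n_a_biased + summ$n_d_biased)
  expect_equal(summ$pct_biased,
               100 * summ$total_biased / summ$total_expressed)
})

# consensus and interspecific classification ---------------------------

consensus_fixture <- function(patterns_by_cultivar) {
  # patterns_by_cultivar: named list cultivar -> call vector over pairs
  pairs <- paste0("p", seq_along(patterns_by_cultivar[[1L]]))
  do.call(rbind, lapply(names(patterns_by_cultivar), function(cv) {
    data.frame(pair_id = pairs, species = "Gh", cultivar = cv,
               stage_dpa = 10L, call = patterns_by_cultivar[[cv]],
               stringsAsFactors = FALSE)
  }))
}

test_that("species consensus is strict across cultivars", {
  calls <- consensus_fixture(list(
    c1 = c("A_biased", "A_biased", "unbiased", "D_biased", "not_expressed"),
    c2 = c("A_biased", "unbiased", "unbiased", "D_biased", "A_biased"),
    c3 = c("A_biased", "A_biased", "unbiased", "D_biased", "A_biased"),
    c4 = c("A_biased", "A_biased", "unbiased", "D_biased", "A_biased")))
  cons <- species_consensus(calls, "Gh", 10L)
  pat <- stats::setNames(cons$pattern, cons$pair_id)
  expect_equal(pat[["p1"]], "A_all")     # biased in all four cultivars
  expect_equal(pat[["p2"]], "mixed")     # 3 of 4 is not consensus
  expect_equal(pat[["p3"]], "none_all")
  expect_equal(pat[["p4"]], "D_all")
  expect_false("p5" %in% cons$pair_id)   # not expressed somewhere: excluded
  expect_equal(attr(cons, "shared_counts"),
               c(A_all = 1L, D_all = 1L))
})

test_that("interspecific categories cover the 8 extreme combinations", {
  gh <- data.frame(pair_id = paste0("h", 1:4), species = "Gh",
                   stage_dpa = 10L, n_cultivars = 4L,
                   pattern = c("A_all", "A_all", "none_all", "mixed"),
                   stringsAsFactors = FALSE)
  gb <- data.frame(pair_id = paste0("b", 1:4), species = "Gb",
                   stage_dpa = 10L, n_cultivars = 3L,
                   pattern = c("none_all", "D_all", "none_all", "A_all"),
                   stringsAsFactors = FALSE)
  links <- data.frame(pair_gh = paste0("h", 1:4),
                      pair_gb = paste0("b", 1:4),
                      stringsAsFactors = FALSE)
  cats <- classify_interspecific(gh, gb, links)
  expect_equal(nrow(cats), 2L)           # (none,none) and mixed dropped
  expect_equal(as.character(cats$category[cats$pair_gh == "h1"]), "A:none")
  opp <- cats[cats$pair_gh == "h2", ]
  expect_equal(as.character(opp$category), "A:D")
  expect_true(opp$differing)
  counts <- count_interspecific(cats)
  expect_equal(counts$total_extreme, 2)
  expect_equal(counts$n_differing, 2)
})

test_that("category tallies separate same-direction from differing pairs", {
  cats <- factor(c("A:A", "A:A", "D:D", "A:none", "none:D"),
                 levels = names(count_interspecific(
                   stats::setNames(rep(0, 8),
                                   c("A:none", "A:D", "A:A", "D:none",
                                     "D:A", "D:D", "none:A",
                                     "none:D")))$by_category))
  r <- count_interspecific(as.character(cats))
  expect_equal(r$total_extreme, 5)
  expect_equal(r$n_differing, 2)
  expect_equal(count_interspecific(stats::setNames(numeric(0),
                                                   character(0)))$total_extreme,
               0)
})

test_that("planted bias is recovered in the planted direction", {
  s <- sim_small()
  res <- run_bias(s$counts, s$sheet, s$pairs)
  ev <- evaluate_bias_recovery(res$calls, s$truth$bias)
  expect_gt(ev$sensitivity, 0.85)
  expect_lt(ev$empirical_fdr, 0.15)
  expect_gt(ev$direction_accuracy, 0.99)
})
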