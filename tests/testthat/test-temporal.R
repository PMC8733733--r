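test_that("profiles are z-scored and constant genes excluded", {
  gm <- rbind(g1 = c(0, 0, 0, 0, 10, 20, 10),
              g2 = c(5, 5, 5, 5, 5, 5, 5),
              g3 = c(1, 2, 4, 8, 16, 32, 64))
  colnames(gm) <- paste0("TM-1:", c(0, 1, 3, 5, 10, 20, 25))
  z <- standardize_profiles(gm)
  expect_equal(nrow(z), 2L)
  expect_equal(attr(z, "n_constant"), 1L)
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  # z-scoring is invariant to affine transforms of the raw profile on the
  # log scale: scaling FPKM+1 by a constant shifts log2 but not the z-score
  gm2 <- (gm + 1) * 8 - 1
  z2 <- standardize_profiles(gm2)
  expect_equal(z2["g3", ], z["g3", ], tolerance = 1e-12)
})

two_blobs <- function(n = 30, at = 5, sd = 0.3, seed = 11) {
  set.seed(seed)
  x <- matrix(c(rnorm(n, -at, sd), rnorm(n, at, sd)), ncol = 1)
  rownames(x) <- paste0("g", seq_len(2 * n))
  x
}

test_that("well-separated blobs get near-crisp memberships", {
  x <- two_blobs()
  fit <- fuzzy_cmeans(x, 2, m = 2, seed = 1)
  home <- apply(fit$membership, 1, max)
  expect_true(all(home > 0.95))
  expect_true(fit$converged)
  expect_equal(unname(rowSums(fit$membership)), rep(1, nrow(x)),
               tolerance = 1e-9)
  expect_equal(sort(unname(fit$centers[, 1])), c(-5, 5), tolerance = 0.2)
})

test_that("a point equidistant from symmetric centers splits 50:50", {
  x <- rbind(two_blobs(), mid = 0)
  fit <- fuzzy_cmeans(x, 2, m = 2, seed = 1)
  expect_equal(unname(fit$membership["mid", ]), c(0.5, 0.5),
               tolerance = 0.05)
})

test_that("the objective is non-increasing across iterations", {
  x <- two_blobs(sd = 2)
  for (seed in 1:3) {
    fit <- fuzzy_cmeans(x, 3, m = 1.5, seed = seed)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("m near 1 approaches hard k-means on separated data", {
  x <- two_blobs()
  fit <- fuzzy_cmeans(x, 2, m = 1.05, seed = 3)
  km <- kmeans(x, centers = sort(fit$centers[, 1]))
  home <- apply(fit$membership, 1, max)
  expect_true(all(home > 0.999))
  ours <- apply(fit$membership, 1, which.max)
  agree <- mean((ours == ours[1]) == (km$cluster == km$cluster[1]))
  expect_equal(agree, 1)
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  x <- two_blobs(sd = 0.8)
  fit <- fuzzy_cmeans(x, 2, m = 1.5, seed = 2)
  set.seed(2)
  ref <- e1071::cmeans(x, centers = 2, m = 1.5)
  ours <- sort(fit$centers[, 1])
  theirs <- sort(ref$centers[, 1])
  expect_equal(ours, theirs, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("cluster count exceeding the data is rejected", {
  x <- two_blobs(n = 3)
  expect_error(fuzzy_cmeans(x, 10), "clusters")
})

test_that("restarts are deterministic and pick the best objective", {
  x <- two_blobs(sd = 1.5)
  f1 <- fuzzy_cmeans(x, 3, n_starts = 4, seed = 9)
  f2 <- fuzzy_cmeans(x, 3, n_starts = 4, seed = 9)
  expect_identical(f1$membership, f2$membership)
  singles <- sapply(0:3, function(k)
    fuzzy_cmeans(x, 3, seed = 9 + k)$objective)
  expect_equal(f1$objective, min(singles))
})

# peak-stage assignment -------------------------------------------------

fake_fit <- function(centers, membership) {
  structure(list(centers = centers, membership = membership,
                 m = 1.25), class = "fuzzy_cmeans")
}

test_that("genes inherit the peak stage of their assigned cluster", {
  centers <- rbind(C1 = c(0, 1, 2, 1, 0, 0, 0),
                   C2 = c(0, 0, 0, 0, 2, 1, 0),
                   C3 = c(0, 0, 0, 0, 0, 1, 2))
  colnames(centers) <- c(0, 1, 3, 5, 10, 20, 25)
  membership <- rbind(gA = c(0.9, 0.05, 0.05), gB = c(0.05, 0.9, 0.05),
                      gC = c(0.6, 0.2, 0.2), gD = c(0.4, 0.3, 0.3))
  colnames(membership) <- c("C1", "C2", "C3")
  a <- assign_peak_stage(fake_fit(centers, membership))
  expect_equal(a$peak_stage[a$gene_id == "gB"], 10)      # cluster 2 peak
  expect_true(is.na(a$peak_stage[a$gene_id == "gA"]))    # peaks at 3 DPA
  expect_equal(a$cluster_peak[a$gene_id == "gA"], 3)
  expect_true(is.na(a$cluster[a$gene_id == "gD"]))       # gate at 0.5
  expect_true(is.na(a$peak_stage[a$gene_id == "gD"]))
})

test_that("postponement classes partition every ortholog pair", {
  gh <- make_assignment(paste0("h", 1:6), c(10, 20, 20, 10, NA, 25))
  gb <- make_assignment(paste0("b", 1:6), c(20, 20, 10, 25, 10, 20))
  links <- data.frame(gene_gh = paste0("h", 1:6),
                      gene_gb = paste0("b", 1:6),
                      stringsAsFactors = FALSE)
  post <- detect_postponement(gh, gb, links)
  cls <- stats::setNames(as.character(post$class), post$gene_gh)
  expect_equal(cls[["h1"]], "postponed_10_20")
  expect_equal(cls[["h2"]], "consistent")
  expect_equal(cls[["h3"]], "advanced")
  expect_equal(cls[["h4"]], "postponed_10_25")
  expect_equal(cls[["h5"]], "unassigned")
  expect_equal(cls[["h6"]], "advanced")
  expect_equal(sum(attr(post, "class_counts")), nrow(links))
  expect_equal(attr(post, "delayed_to_scw"), 2L)
  expect_false(anyNA(post$class))
})

test_that("predominance sets are disjoint per stage", {
  gh <- make_assignment(paste0("h", 1:5), c(10, 10, 20, NA, 25))
  gb <- make_assignment(paste0("b", 1:5), c(10, 20, 20, 10, NA))
  links <- data.frame(gene_gh = paste0("h", 1:5),
                      gene_gb = paste0("b", 1:5),
                      stringsAsFactors = FALSE)
  pred <- compare_predominance(gh, gb, links)
  d10 <- pred$dpa10
  expect_equal(d10$counts[["consistent"]], 1L)
  expect_equal(d10$counts[["gh_only"]], 1L)
  expect_equal(d10$counts[["gb_only"]], 1L)
  expect_length(intersect(d10$consistent$gene_gh, d10$gh_only$gene_gh), 0L)
  expect_length(intersect(d10$consistent$gene_gh, d10$gb_only$gene_gh), 0L)
})

test_that("planted peak-stage shifts are recovered on simulated data", {
  s <- sim_small()
  tm <- run_temporal(s$counts, s$sheet, s$pairs)
  ev <- evaluate_postponement_recovery(tm$postponement,
                                       s$truth$postponement)
  expect_gte(min(ev$sensitivity), 0.85)
  expect_lte(ev$advanced_rate, 0.05)
  # planted peaks recovered per gene on the Gh side
  tp <- stats::setNames(s$truth$peaks$peak_stage,
                        s$truth$peaks$gene_id)
  a <- tm$species$Gh$assignments
  key <- a$gene_id[!is.na(a$peak_stage)]
  planted <- tp[key]
  sel <- !is.na(planted) & planted %in% c(10, 20, 25)
  expect_gte(mean(a$peak_stage[match(key[sel], a$gene_id)] ==
                    planted[sel]), 0.9)
})
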