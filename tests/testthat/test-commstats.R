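test_that("read-percentage normalisation behaves like a composition", {
  counts <- matrix(c(30L, 70L, 10L, 30L), 2, 2)
  tab <- make_otu_fixture(counts, c("Nematoda", "Annelida"))
  pct <- reads_to_percent(tab)
  expect_equal(unname(pct$counts[, 1]), c(30, 70))
  expect_equal(unname(colSums(pct$counts)), c(100, 100), tolerance = 1e-9)
  # scale invariance: multiplying a sample's counts leaves percentages alone
  tab10 <- make_otu_fixture(counts * c(10L, 10L), c("Nematoda", "Annelida"))
  expect_equal(reads_to_percent(tab10)$counts, pct$counts)
  zero <- make_otu_fixture(matrix(c(1L, 0L, 0L, 0L), 2, 2),
                           c("Nematoda", "Annelida"))
  expect_error(reads_to_percent(zero), "smp2")
})

test_that("presence transform applies the metazoan phylum filter", {
  counts <- matrix(c(5L, 0L, 2L, 1L, 0L, 3L, 0L, 0L, 4L, 9L, 1L, 0L), 4, 3)
  phyla <- c("Nematoda", "Alveolata", "Mollusca", "Fungi")
  tab <- make_otu_fixture(counts, phyla)
  P <- to_presence(tab)
  kept <- colnames(P)
  expect_setequal(kept, rownames(tab$counts)[phyla %in% metazoan_phyla()])
  expect_true(all(P %in% c(0, 1)))
  # custom filter with no matches fails loudly
  expect_error(to_presence(tab, "Tardigrada"), "no OTUs match")
  # all-zero OTUs are dropped
  counts2 <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  tab2 <- make_otu_fixture(counts2, c("Nematoda", "Annelida"))
  expect_equal(colnames(to_presence(tab2)), "OTU1")
})

test_that("Sorensen dissimilarity matches set arithmetic", {
  # {A,B,C} vs {B,C,D}: a=2, b=1, c=1 -> d = 1 - 4/6
  P <- rbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1))
  D <- sorensen_dissimilarity(P)
  expect_equal(D[1, 2], 1 / 3)
  expect_equal(sorensen_dissimilarity(rbind(a = c(1, 1), b = c(1, 1)))[1, 2], 0)
  expect_equal(sorensen_dissimilarity(rbind(a = c(1, 0), b = c(0, 1)))[1, 2], 1)
  # brute-force oracle over random binary matrices
  set.seed(13)
  for (i in 1:10) {
    P <- matrix(rbinom(6 * 12, 1, 0.4), 6, 12,
                dimnames = list(paste0("s", 1:6), NULL))
    P[1, ] <- pmax(P[1, ], 1)  # guard against all-empty rows
    D <- suppressWarnings(sorensen_dissimilarity(P))
    for (a in 1:5) for (b in (a + 1):6) {
      sa <- which(P[a, ] == 1); sb <- which(P[b, ] == 1)
      shared <- length(intersect(sa, sb))
      expected <- if (length(sa) + length(sb) == 0) 0 else
        1 - 2 * shared / (length(sa) + length(sb))
      expect_equal(D[a, b], expected)
      expect_equal(D[b, a], expected)
    }
    expect_true(all(D >= 0 & D <= 1))
    expect_true(all(diag(D) == 0))
  }
  expect_warning(
    sorensen_dissimilarity(rbind(a = c(0, 0), b = c(0, 0))), "empty")
})

test_that("UPGMA reproduces hand-computed merges and is ultrametric", {
  D <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.6,
                0.6, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- upgma(D)
  expect_equal(hc$height, c(0.2, 0.6))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1)) # a and b merge first
  # equal distances: single height, deterministic topology
  De <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  hc1 <- upgma(De); hc2 <- upgma(De)
  expect_identical(hc1$merge, hc2$merge)
  expect_true(all(abs(hc1$height - 0.5) < 1e-12))
  # n-1 merges, non-decreasing heights on random matrices
  set.seed(23)
  P <- matrix(rbinom(8 * 30, 1, 0.3), 8, 30,
              dimnames = list(paste0("s", 1:8), NULL))
  P[, 1] <- 1
  hcr <- upgma(suppressWarnings(sorensen_dissimilarity(P)))
  expect_equal(length(hcr$height), 7)
  expect_true(!is.unsorted(hcr$height))
})

test_that("cutting at 0.75 dissimilarity recovers 25%-similarity groups", {
  # two blocks with disjoint OTU sets: within-block d < 0.75, between = 1
  set.seed(31)
  blockA <- cbind(matrix(rbinom(4 * 20, 1, 0.8), 4, 20), matrix(0L, 4, 20))
  blockB <- cbind(matrix(0L, 4, 20), matrix(rbinom(4 * 20, 1, 0.8), 4, 20))
  P <- rbind(blockA, blockB)
  rownames(P) <- paste0("s", 1:8)
  hc <- upgma(sorensen_dissimilarity(P))
  groups <- cutree(hc, h = 0.75)
  expect_equal(length(unique(groups)), 2)
  expect_equal(length(unique(groups[1:4])), 1)
  expect_equal(length(unique(groups[5:8])), 1)
})

test_that("SIMPROF separates real structure and respects permutation limits", {
  set.seed(37)
  blockA <- cbind(matrix(rbinom(5 * 25, 1, 0.7), 5, 25), matrix(0L, 5, 25))
  blockB <- cbind(matrix(0L, 5, 25), matrix(rbinom(5 * 25, 1, 0.7), 5, 25))
  P <- rbind(blockA, blockB)
  rownames(P) <- paste0("s", 1:10)
  sp <- simprof(P, n_profile_perms = 200, n_test_perms = 199, seed = 5)
  expect_s3_class(sp, "simprof_result")
  # root split detected at the smallest attainable p
  expect_true(sp$tests$significant[1])
  expect_equal(sp$tests$p[1], 1 / 200)
  # the two blocks end up in different groups
  expect_equal(length(unique(sp$groups[1:5])), 1)
  expect_equal(length(unique(sp$groups[6:10])), 1)
  expect_gt(length(unique(sp$groups)), 1)
  # permutation arithmetic: p can never drop below 1/(n_test_perms + 1)
  expect_true(all(sp$tests$p >= 1 / 200))
  # determinism under seed
  sp2 <- simprof(P, n_profile_perms = 200, n_test_perms = 199, seed = 5)
  expect_identical(sp$groups, sp2$groups)
  expect_identical(sp$tests, sp2$tests)
  # groups partition the samples
  expect_true(all(sp$groups >= 1))
  expect_equal(length(sp$groups), 10)
})

test_that("SIMPROF declares tiny nodes non-testable", {
  P <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  sp <- simprof(P, n_profile_perms = 50, n_test_perms = 49)
  expect_equal(nrow(sp$tests), 0)
  expect_equal(length(unique(sp$groups)), 1)
})

test_that("NMDS recovers planted configurations and degenerate cases", {
  # two samples: exact antipodal placement, zero stress
  D2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r2 <- nmds(D2)
  expect_equal(r2$stress, 0)
  expect_equal(abs(r2$points[, 1]), c(a = 0.4, b = 0.4))
  # planted 2-D configuration
  set.seed(41)
  X <- matrix(rnorm(15 * 2), 15, 2)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("p", 1:15)
  fit <- nmds(D, restarts = 10, seed = 7)
  expect_lt(fit$stress, 0.01)
  pro <- vegan::procrustes(X, fit$points, symmetric = TRUE)
  expect_lt(sqrt(mean(residuals(pro)^2)), 1e-2)
  # determinism under seed
  fit2 <- nmds(D, restarts = 10, seed = 7)
  expect_identical(fit$points, fit2$points)
  expect_identical(fit$stress, fit2$stress)
})

test_that("richness tables count OTUs per group and pool replicates", {
  counts <- matrix(c(3L, 1L, 2L, 0L,
                     0L, 0L, 0L, 0L,
                     1L, 4L, 0L, 2L), 4, 3)
  rownames(counts) <- paste0("OTU", 1:4)
  colnames(counts) <- c("stA_r1", "stA_r2", "stB_r1")
  tab <- otu_table(counts,
                   taxonomy = data.frame(otu = paste0("OTU", 1:4),
                                         phylum = c("Nematoda", "Nematoda",
                                                    "Nematoda", "Annelida"),
                                         family = "f"),
                   samples = data.frame(sample = colnames(counts),
                                        station = c("stA", "stA", "stB"),
                                        replicate = c(1L, 2L, 1L),
                                        estuary = "Test"))
  r <- richness_by_group(tab, "phylum")
  expect_equal(r["stA_r1", "Nematoda"], 3)
  expect_equal(r["stA_r1", "Annelida"], 0)
  expect_equal(r["stA_r2", "total"], 0) # empty sample -> all groups zero
  expect_equal(r["stA_r2", "Nematoda"], 0)
  # station pooling: present in any replicate counts
  rs <- richness_by_group(tab, "phylum", by_station = TRUE)
  expect_equal(rs["stA", "Nematoda"], 3)
  expect_equal(rs["stB", "Annelida"], 1)
  # union superset property across two synthetic estuaries
  d1 <- generate_dataset(estuary_scenario(seed = 3, n_stations = 4,
                                          taxon_pool = c(Nematoda = 25)))
  d2 <- generate_dataset(mersey_scenario(seed = 4, n_stations = 4,
                                         taxon_pool = c(Nematoda = 25)))
  tot1 <- sum(rowSums(d1$otu$counts) > 0)
  tot2 <- sum(rowSums(d2$otu$counts) > 0)
  both <- length(union(rownames(d1$otu$counts)[rowSums(d1$otu$counts) > 0],
                       rownames(d2$otu$counts)[rowSums(d2$otu$counts) > 0]))
  expect_gte(both, max(tot1, tot2))
})

test_that("t-test with Levene gate handles identity and the 20+15 design", {
  x <- c(10, 12, 14, 16)
  res <- welch_levene_ttest(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # equal-variance 20 vs 15 stations: pooled t has df = 33
  x20 <- seq(80, 120, length.out = 20)
  y15 <- seq(85, 125, length.out = 15) # same spread -> Levene keeps pooled
  res2 <- welch_levene_ttest(x20, y15)
  expect_true(res2$pooled)
  expect_equal(res2$df, 33)
  expect_error(welch_levene_ttest(1, c(2, 3)), "n >= 2")
})

test_that("dendrograms export as Newick", {
  D <- sorensen_dissimilarity(rbind(a = c(1, 1, 0), b = c(1, 0, 1),
                                    c = c(0, 1, 1)))
  txt <- dendrogram_newick(upgma(D))
  expect_match(txt, "^\\(")
  expect_true(all(vapply(c("a", "b", "c"), grepl, logical(1), txt)))
  tmp <- tempfile(fileext = ".nwk")
  dendrogram_newick(upgma(D), tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})
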