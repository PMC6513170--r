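## deterministic 2-D fixture shared with the frozen external oracle below
hdbscan_fixture <- function() {
  set.seed(7)
  rbind(matrix(rnorm(100, 0, 0.5), ncol = 2),
        matrix(rnorm(80, 6, 0.6), ncol = 2),
        matrix(rnorm(60, c(0, 8), 0.4), ncol = 2),
        matrix(runif(40, -3, 11), ncol = 2))
}

## labels computed once from an independent reference implementation
## (scikit-learn HDBSCAN, min_cluster_size = min_samples = 10) on the
## fixture above; frozen (-1 = noise)
sklearn_oracle_labels <- function() {
  as.integer(strsplit(paste(
    "0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0",
    "0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,-1,1",
    "1,1,1,1,1,1,1,1,1,1,1,1,-1,1,1,1,1,1,1,1,1,1,0,2,0,2,0,2,0,2,0,2,0,2",
    "0,2,0,2,0,2,0,2,0,2,0,2,0,2,0,2,0,2,0,0,-1,0,0,-1,-1,-1,0,-1,-1,-1,0,-1,-1,0",
    "-1,0,-1,-1", sep = ","), ",")[[1L]])
}

test_that("hdbscan labels agree with the frozen reference labeling", {
  pts <- hdbscan_fixture()
  lab <- hdbscanLabels(pts, min_pts = 10L)
  oracle <- sklearn_oracle_labels()
  expect_identical(lab == 0L, oracle == -1L)          # identical noise set
  expect_equal(adjustedRandIndex(lab, oracle), 1)     # identical partition
})

test_that("hdbscan recovers planted Gaussian blobs and handles edge cases", {
  set.seed(11)
  truth <- rep(1:3, each = 200)
  pts <- cbind(rnorm(600, c(0, 10, 20)[truth], 0.7),
               rnorm(600, c(0, 8, -4)[truth], 0.7))
  lab <- hdbscanLabels(pts, min_pts = 20L)
  expect_equal(adjustedRandIndex(lab, truth), 1)
  expect_identical(sort(unique(lab)), 1:3)

  expect_warning(lab_all <- hdbscanLabels(pts[1:10, ], min_pts = 11L),
                 "all noise")
  expect_identical(lab_all, rep(0L, 10))
  expect_error(hdbscanLabels(pts, min_pts = 1L), ">= 2")

  ## one diffuse blob: no sub-root cluster survives, everything is noise
  set.seed(2)
  one <- matrix(runif(400), ncol = 2)
  expect_true(all(hdbscanLabels(one, 100L) == 0L))
})

test_that("embedding is deterministic and separates planted topic blocks", {
  gen <- generateCorpus(syntheticCorpusSpec(
    n_topics = 2L, docs_per_topic = 60L, topic_vocab_size = 20L,
    background_vocab_size = 40L, noise_doc_fraction = 0, seed = 5L))
  tm <- buildTermMatrix(gen$corpus)
  expect_warning(e1 <- embedDocuments(tm, perplexity = 100, seed = 3L),
                 "perplexity.*lowered")
  e2 <- suppressWarnings(embedDocuments(tm, perplexity = 100, seed = 3L))
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))
  expect_identical(ncol(embeddingCoords(e1)), 2L)
  expect_true(all(is.finite(embeddingCoords(e1))))

  co <- embeddingCoords(e1)
  topics <- gen$topics[docIds(tm)]
  c1 <- colMeans(co[topics == "T1", ]); c2 <- colMeans(co[topics == "T2", ])
  between <- sqrt(sum((c1 - c2)^2))
  within <- function(t) mean(sqrt(rowSums(
    sweep(co[topics == t, ], 2, colMeans(co[topics == t, ]))^2)))
  expect_gt(between, within("T1"))
  expect_gt(between, within("T2"))

  ## a different seed moves the layout (stochastic method, seeded)
  e3 <- suppressWarnings(embedDocuments(tm, perplexity = 100, seed = 4L))
  expect_false(identical(embeddingCoords(e1), embeddingCoords(e3)))

  zero <- new("TermMatrix", doc_ids = letters[1:8], terms = c("x", "y"),
              counts = Matrix::Matrix(0, 8, 2, sparse = TRUE),
              tfidf = Matrix::Matrix(0, 8, 2, sparse = TRUE))
  expect_error(embedDocuments(zero), "degenerate")
})

test_that("the minPts sweep labels every document under every setting", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(400, 0, 0.5), ncol = 2),
               matrix(rnorm(400, 7, 0.5), ncol = 2))
  emb <- new("Embedding", doc_ids = sprintf("d%d", 1:400), coords = pts,
             perplexity = 10, seed = 1L)
  sw <- suppressWarnings(sweepMinPts(emb, c(20L, 50L, 401L)))
  expect_identical(dim(sweepLabels(sw)), c(400L, 3L))
  expect_identical(colnames(sweepLabels(sw)), c("20", "50", "401"))
  expect_false(anyNA(sweepLabels(sw)))
  expect_true(all(sweepLabels(sw)[, "401"] == 0L))   # minPts > n: all noise
  expect_identical(sort(setdiff(unique(sweepLabels(sw)[, "20"]), 0L)), 1:2)
  expect_error(sweepMinPts(emb, integer()), "non-empty")
  expect_error(sweepMinPts(emb, c(10L, 1L)), ">= 2")
})

test_that("consolidation applies the primary-then-secondary fallback rule", {
  ## hand-built sweep: 6 docs, settings 75 and 150 (plus an extra 50)
  labels <- cbind(`50` = c(1L, 1L, 0L, 2L, 0L, 0L),
                  `75` = c(1L, 1L, 0L, 0L, 0L, 0L),
                  `150` = c(1L, 1L, 1L, 2L, 2L, 0L))
  sw <- new("SweepResult", doc_ids = sprintf("d%d", 1:6),
            min_pts = c(50L, 75L, 150L), labels = labels)
  asg <- consolidateClusters(sw, primary = 75L, secondary = 150L)
  lab <- unname(finalLabels(asg))
  ## d1,d2 keep their primary cluster
  expect_identical(lab[1:2], c("C1", "C1"))
  ## d3: noise at 75, cluster 1 at 150 -> secondary-namespaced cluster
  ## d4,d5: noise at 75, cluster 2 at 150 (2 contributors -> larger first)
  expect_identical(lab[4], lab[5])
  expect_false(lab[3] == lab[4])
  expect_identical(sort(unique(lab[3:5])), c("C2", "C3"))
  expect_identical(lab[4], "C2")   # two contributed docs beat one
  ## d6: noise everywhere except... noise at all three -> never-clustered
  expect_identical(lab[6], "never-clustered")
  ## provenance records the producing setting
  expect_identical(unname(asg@provenance["C1"]), "minPts=75")
  expect_identical(unname(asg@provenance["C2"]), "minPts=150")

  ## partition invariant
  expect_identical(length(lab), 6L)
  expect_error(consolidateClusters(sw, primary = 99L), "belong to the sweep")
})

test_that("noise-monotonicity: never-clustered is noise at every setting", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(300, 0, 0.6), ncol = 2),
               matrix(rnorm(300, 6, 0.6), ncol = 2),
               matrix(runif(100, -4, 10), ncol = 2))
  emb <- new("Embedding", doc_ids = sprintf("d%d", 1:350), coords = pts,
             perplexity = 10, seed = 1L)
  sw <- suppressWarnings(sweepMinPts(emb, c(15L, 40L, 80L)))
  asg <- consolidateClusters(sw, primary = 40L, secondary = 80L)
  lab <- unname(finalLabels(asg))
  expect_identical(length(lab), 350L)
  never <- lab == "never-clustered"
  for (j in seq_len(ncol(sweepLabels(sw))))
    expect_true(all(sweepLabels(sw)[never, j] == 0L))
})

test_that("clusters are named by their two most frequent terms", {
  co <- toy_corpus(c("influenza influenza virus",
                     "influenza virus virus patient",
                     "genome sequence genome sequence",
                     "genome sequence assembly"))
  tm <- buildTermMatrix(co, min_df = 1L)
  asg <- toy_assignment(docIds(co), c("C1", "C1", "C2", "C2"),
                        topic_names = character())
  named <- nameClusters(asg, tm)
  ## brute-force per-cluster count oracle
  cnt <- as.matrix(termCounts(tm))
  for (cl in c("C1", "C2")) {
    tot <- colSums(cnt[finalLabels(named) == cl, , drop = FALSE])
    top2 <- names(sort(tot, decreasing = TRUE))[1:2]
    expect_identical(unname(topicNames(named)[cl]),
                     paste(top2, collapse = "-"))
  }
  expect_identical(unname(topicNames(named)["C1"]), "influenza-viru")
  expect_identical(unname(topicNames(named)["C2"]), "genom-sequenc")

  ## lexicographic tie-break: counts {alpha 2, beta 2, gamma 1}
  co2 <- toy_corpus(c("beta alpha gamma", "alpha beta"))
  tm2 <- buildTermMatrix(co2, min_df = 1L)
  asg2 <- toy_assignment(docIds(co2), c("C1", "C1"))
  expect_identical(unname(topicNames(nameClusters(asg2, tm2))["C1"]),
                   "alpha-beta")

  ## duplicate names get a numeric suffix
  co3 <- toy_corpus(c("alpha beta", "alpha beta gamma"))
  asg3 <- toy_assignment(docIds(co3), c("C1", "C2"))
  nm3 <- topicNames(nameClusters(asg3, buildTermMatrix(co3, min_df = 1L)))
  expect_identical(unname(nm3["C1"]), "alpha-beta")
  expect_identical(unname(nm3["C2"]), "alpha-beta-2")
})

test_that("adjustedRandIndex matches its closed form on a known example", {
  ## contingency table [[2,1],[1,2]]: hand computation gives
  ## sij = 2, si = sj = 6, n = 6, exp = 2.4, max = 6 -> (2-2.4)/(6-2.4)
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c("x", "x", "y", "x", "y", "y")
  expect_equal(adjustedRandIndex(a, b), (2 - 2.4) / (6 - 2.4))
  expect_equal(adjustedRandIndex(a, a), 1)
  expect_equal(adjustedRandIndex(a, rev(a)), 1)  # label-permutation invariant
})
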