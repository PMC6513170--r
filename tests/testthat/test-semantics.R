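test_that("the default concept vocabulary has 23 concepts in 3 groups", {
  v <- defaultConceptVocabulary()
  tab <- conceptTable(v)
  expect_identical(nrow(tab), 23L)
  counts <- table(tab$group)
  expect_identical(as.integer(counts[c("genomic", "epidemiology", "medical")]),
                   c(7L, 11L, 5L))
  expect_false(anyDuplicated(tab$concept) > 0)
  expect_true(all(c("drug resistance", "surveillance", "phylogeny",
                    "clinical", "outbreaks (hospital)") %in% tab$concept))
})

test_that("concept maps validate against the vocabulary", {
  cm <- defaultConceptMap()
  e <- conceptMapEntries(cm)
  expect_identical(e$concept[e$bigram == "vancomycin resistance"],
                   "drug resistance")
  expect_error(ConceptMap("some bigram", "no such concept",
                          vocabulary = defaultConceptVocabulary()),
               "unknown concepts")
  expect_error(new("ConceptMap",
                   entries = data.frame(bigram = c("a b", "a b"),
                                        concept = c("x", "y"))) |>
                 methods::validObject(),
               "at most one concept")

  f <- withr::local_tempfile(lines = c("bigram\tconcept",
                                       "vancomycin resistance\tdrug resistance",
                                       "case cluster\tclusters"))
  cm2 <- readConceptMap(f)
  expect_identical(nrow(conceptMapEntries(cm2)), 2L)
})

test_that("external vocabulary matching counts whole phrases per cluster", {
  ## planted fixture: "alphavirus x" in 5 docs of C1 and 2 docs of C2
  texts <- c(rep("infection with Alphavirus X spreading", 5),
             rep("alphavirus x detected in samples", 2),
             "an alphavirus xylophone should not match",   # phrase boundary
             "unrelated text about tuberculosis")
  co <- toy_corpus(texts)
  asg <- toy_assignment(docIds(co),
                        c(rep("C1", 5), rep("C2", 3), "C2"))
  mt <- matchExternalVocabulary(co, asg, c("alphavirus x", "tuberculosis"),
                                min_articles = 1L)
  ## substring-scan oracle
  expect_identical(mt$n_docs[mt$term == "alphavirus x" & mt$cluster == "C1"],
                   5L)
  expect_identical(mt$n_docs[mt$term == "alphavirus x" & mt$cluster == "C2"],
                   2L)
  expect_identical(mt$n_docs[mt$term == "tuberculosis"], 1L)

  ## threshold boundary: total matches of 7 kept at 7, dropped at 8
  mt7 <- matchExternalVocabulary(co, asg, "alphavirus x", min_articles = 7L)
  expect_identical(sum(mt7$n_docs), 7L)
  mt8 <- matchExternalVocabulary(co, asg, "alphavirus x", min_articles = 8L)
  expect_identical(nrow(mt8), 0L)
  ## a term matching nothing is dropped
  expect_identical(nrow(matchExternalVocabulary(co, asg, "zika virus",
                                                min_articles = 1L)), 0L)
})

test_that("simplifyClusters retains large clusters and pools the rest", {
  ids <- sprintf("d%03d", 1:300)
  labels <- c(rep("C1", 120), rep("C2", 99), rep("C3", 40),
              rep("currently-unclustered", 30), rep("never-clustered", 11))
  asg <- toy_assignment(ids, labels,
                        topic_names = c(C1 = "influenza-viru",
                                        C2 = "genom-sequenc",
                                        C3 = "zika-viru"))
  simp <- simplifyClusters(asg, min_cluster_docs = 100L)
  lab <- unname(finalLabels(simp))
  expect_identical(sum(lab == "C1"), 120L)
  expect_identical(sum(lab == "other"), 139L)
  expect_false(any(lab %in% c("C2", "C3")))
  ## unclustered labels untouched; document count conserved
  expect_identical(sum(lab == "currently-unclustered"), 30L)
  expect_identical(sum(lab == "never-clustered"), 11L)
  expect_identical(length(lab), 300L)
  expect_identical(unname(topicNames(simp)["other"]), "other")

  ## identity case: all clusters over threshold
  simp2 <- simplifyClusters(asg, min_cluster_docs = 40L)
  expect_identical(finalLabels(simp2), finalLabels(asg))

  ## randomized sizes equal a brute-force size filter
  set.seed(42)
  for (i in 1:5) {
    sizes <- sample(1:60, 6)
    labs <- rep(sprintf("C%d", 1:6), sizes)
    a <- toy_assignment(sprintf("x%03d", seq_along(labs)), labs)
    thr <- sample(10:50, 1)
    s <- simplifyClusters(a, min_cluster_docs = thr)
    expect_setequal(setdiff(clusterIds(s), "other"),
                    sprintf("C%d", which(sizes >= thr)))
  }
})

## helper: build a BigramIndex directly from a cluster_df matrix
index_from_df <- function(df_mat) {
  new("BigramIndex", bigrams = rownames(df_mat),
      membership = structure(rep(list(character()), nrow(df_mat)),
                             names = rownames(df_mat)),
      cluster_df = df_mat)
}

test_that("candidate bigram filtering honors both thresholds", {
  ## 21 clusters -> need presence in ceil(0.10 * 20) = 2 other clusters
  clusters <- sprintf("C%d", 1:21)
  asg <- toy_assignment(sprintf("d%d", 1:21), clusters)
  mk <- function(within, spread) {
    row <- integer(21); row[1] <- within
    if (spread > 0) row[1 + seq_len(spread)] <- 1L
    row
  }
  df <- rbind("kept bigram" = mk(12L, 3L),
              "weak within" = mk(9L, 20L),
              "no spread" = mk(15L, 0L),
              "boundary within" = mk(10L, 2L),
              "boundary below" = mk(10L, 1L))
  colnames(df) <- clusters
  bi <- index_from_df(df)
  out <- findCandidateBigrams(bi, asg, min_within = 10L,
                              min_between_frac = 0.10)
  expect_identical(out, sort(c("kept bigram", "boundary within")))

  ## exhaustive-tally oracle on random small instances
  set.seed(9)
  for (i in 1:10) {
    n_cl <- sample(3:8, 1)
    cl <- sprintf("C%d", seq_len(n_cl))
    a <- toy_assignment(sprintf("d%d", seq_len(n_cl)), cl)
    m <- matrix(rpois(6 * n_cl, 3), nrow = 6,
                dimnames = list(sprintf("bg%d", 1:6), cl))
    got <- findCandidateBigrams(index_from_df(m), a, min_within = 4L,
                                min_between_frac = 0.34)
    want <- sort(rownames(m)[vapply(seq_len(6), function(r) {
      any(vapply(seq_len(n_cl), function(c0)
        m[r, c0] >= 4L &&
          sum(m[r, -c0] >= 1L) >= ceiling(0.34 * (n_cl - 1) - 1e-9), TRUE))
    }, TRUE)])
    expect_identical(got, want)
  }

  ## monotone: raising either threshold never grows the candidate set
  base <- findCandidateBigrams(bi, asg, 10L, 0.10)
  expect_true(all(findCandidateBigrams(bi, asg, 12L, 0.10) %in% base))
  expect_true(all(findCandidateBigrams(bi, asg, 10L, 0.15) %in% base))

  ## fewer than two clusters is an error
  asg1 <- toy_assignment("d1", "C1")
  expect_error(findCandidateBigrams(bi, asg1, 10L, 0.10), "at least two")
})

test_that("documents are linked to concepts through mapped bigrams", {
  texts <- c("vancomycin resistance in enterococci isolates",
             "case cluster of vancomycin resistance detected",
             "routine genomic surveillance of influenza")
  co <- toy_corpus(texts)
  asg <- toy_assignment(docIds(co), c("C1", "C1", "C2"))
  bi <- buildBigramIndex(co, asg)
  cmap <- ConceptMap(c("vancomycin resistance", "case cluster",
                       "genomic surveillance"),
                     c("drug resistance", "clusters", "surveillance"),
                     vocabulary = defaultConceptVocabulary())
  candidates <- c("vancomycin resistance", "case cluster",
                  "genomic surveillance", "unmapped phrase")
  links <- linkConcepts(co, candidates, cmap, bi)
  ll <- conceptLinksList(links)
  expect_identical(ll$d1, "drug resistance")
  expect_identical(ll$d2, sort(c("drug resistance", "clusters")))
  expect_identical(ll$d3, "surveillance")
  expect_identical(attr(links, "unmapped"), "unmapped phrase")

  ## a doc containing no mapped bigram has an empty concept set
  co2 <- toy_corpus("nothing relevant here", ids = "z1")
  links2 <- linkConcepts(co2, candidates, cmap, bi)
  expect_identical(conceptLinksList(links2)$z1, character())

  ## unknown concepts in the map are a validation error
  bad <- new("ConceptMap", entries = data.frame(bigram = "x y",
                                                concept = "nonexistent"))
  expect_error(linkConcepts(co, candidates, bad, bi), "validation error")
})
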