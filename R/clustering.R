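#' Embed a document-term matrix in two dimensions with t-SNE
#'
#' Barnes-Hut t-SNE over the tf-idf weights, with the perplexity default of
#' 100 used for literature corpora and otherwise default parameters of the
#' underlying implementation. The initial layout is drawn from the seeded
#' RNG and passed explicitly (with a single compute thread) so that the
#' embedding is bit-reproducible for a fixed seed.
#'
#' @param tm a [TermMatrix-class].
#' @param perplexity t-SNE perplexity (default 100). When the corpus has
#'   fewer than `3 * perplexity + 1` documents the perplexity is
#'   automatically lowered with a warning.
#' @param seed integer RNG seed (default 42).
#' @param theta Barnes-Hut accuracy trade-off (0 = exact; default 0.5).
#' @param max_iter number of gradient iterations (default 1000).
#' @return an [Embedding-class].
#' @export
embedDocuments <- function(tm, perplexity = 100, seed = 42L, theta = 0.5,
                           max_iter = 1000L) {
  stopifnot(is(tm, "TermMatrix"))
  X <- as.matrix(termTfidf(tm))
  n <- nrow(X)
  if (all(X == 0)) .stopf("degenerate all-zero tf-idf matrix")
  if (n < 7L) .stopf("too few documents to embed (%d)", n)
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    .warnf("perplexity %g too large for %d documents; lowered to %d",
           perplexity, n, max_perp)
    perplexity <- max_perp
  }
  res <- withSeed(seed, {
    y0 <- matrix(stats::rnorm(n * 2L), n, 2L) * 1e-4
    Rtsne::Rtsne(X, dims = 2L, perplexity = perplexity, theta = theta,
                 max_iter = as.integer(max_iter), check_duplicates = FALSE,
                 pca = TRUE, Y_init = y0, num_threads = 1L)
  })
  new("Embedding", doc_ids = docIds(tm), coords = res$Y,
      perplexity = as.numeric(perplexity), seed = as.integer(seed))
}

#' Run the density-clustering stability sweep
#'
#' Clusters the 2-D embedding once per minimum-cluster-size setting,
#' recording every labeling. Cluster composition is sensitive to this
#' parameter, so the sweep is the basis for distinguishing documents that
#' are never clustered from documents that merely fall out of the final
#' consolidated settings.
#'
#' @param emb an [Embedding-class].
#' @param min_pts_list the swept values (default
#'   `c(50, 75, 100, 125, 150, 250, 500, 1000)`); each must be >= 2. A
#'   setting larger than the corpus yields all-noise with a warning.
#' @return a [SweepResult-class].
#' @export
sweepMinPts <- function(emb,
                        min_pts_list = c(50L, 75L, 100L, 125L, 150L,
                                         250L, 500L, 1000L)) {
  stopifnot(is(emb, "Embedding"))
  min_pts_list <- as.integer(min_pts_list)
  if (!length(min_pts_list)) .stopf("min_pts_list must be non-empty")
  if (any(min_pts_list < 2L)) .stopf("every minPts value must be >= 2")
  co <- embeddingCoords(emb)
  labels <- vapply(min_pts_list, function(mp) hdbscanLabels(co, mp),
                   integer(nrow(co)))
  labels <- matrix(labels, nrow = nrow(co),
                   dimnames = list(NULL, as.character(min_pts_list)))
  new("SweepResult", doc_ids = docIds(emb), min_pts = min_pts_list,
      labels = labels)
}

#' Consolidate a sweep into final cluster labels
#'
#' The final labeling combines a primary (fine) and a secondary (coarse)
#' setting: a document keeps its primary-setting cluster when it has one;
#' otherwise it falls back to its secondary-setting cluster (namespaced so
#' ids never collide); otherwise it is "currently-unclustered", or
#' "never-clustered" when it is noise under every swept setting. The three
#' categories partition the corpus.
#'
#' @param sweep a [SweepResult-class].
#' @param primary,secondary minPts settings to combine (defaults 75 and
#'   150); both must belong to the sweep.
#' @return an unnamed [ClusterAssignment-class] (run [nameClusters()] to
#'   attach topic names). Cluster ids are "C1", "C2", ... in decreasing
#'   size order, primary-setting clusters first; provenance records which
#'   setting produced each cluster.
#' @export
consolidateClusters <- function(sweep, primary = 75L, secondary = 150L) {
  stopifnot(is(sweep, "SweepResult"))
  key <- as.character(as.integer(c(primary, secondary)))
  if (!all(key %in% colnames(sweepLabels(sweep))))
    .stopf("primary/secondary settings must belong to the sweep (have: %s)",
           paste(colnames(sweepLabels(sweep)), collapse = ", "))
  lb <- sweepLabels(sweep)
  p <- lb[, key[1L]]; s <- lb[, key[2L]]
  n <- length(p)
  final <- rep(.UNCLUSTERED, n)
  prov <- character(0)
  ## primary clusters are already dense ids in decreasing size order
  for (j in sort(setdiff(unique(p), 0L))) {
    final[p == j] <- sprintf("C%d", j)
    prov[sprintf("C%d", j)] <- sprintf("minPts=%s", key[1L])
  }
  k1 <- length(setdiff(unique(p), 0L))
  ## secondary rescue: only documents that are primary noise
  rescue <- p == 0L & s != 0L
  if (any(rescue)) {
    contrib <- table(s[rescue])
    sec_ids <- as.integer(names(contrib))
    sec_ids <- sec_ids[order(-as.integer(contrib), sec_ids)]
    for (j in seq_along(sec_ids)) {
      id <- sprintf("C%d", k1 + j)
      final[rescue & s == sec_ids[j]] <- id
      prov[id] <- sprintf("minPts=%s", key[2L])
    }
  }
  never <- rowSums(lb != 0L) == 0L
  final[never] <- .NEVER
  new("ClusterAssignment", doc_ids = docIds(sweep), final = final,
      topic_names = character(), provenance = prov, sweep_labels = lb)
}

#' Name clusters by their two most frequent terms
#'
#' Each cluster's topic is the two terms with the highest summed raw counts
#' over its member documents, hyphen-joined with the most frequent first;
#' count ties break lexicographically and duplicate names get a numeric
#' suffix. This yields the stemmed topic labels characteristic of the
#' pipeline (e.g. "influenza-viru").
#'
#' @param assignment a [ClusterAssignment-class].
#' @param tm the [TermMatrix-class] the clustering was derived from (same
#'   documents).
#' @return the assignment with `topicNames()` filled in.
#' @export
nameClusters <- function(assignment, tm) {
  stopifnot(is(assignment, "ClusterAssignment"), is(tm, "TermMatrix"))
  if (!setequal(docIds(assignment), docIds(tm)))
    .stopf("assignment and term matrix must share document ids")
  cnt <- termCounts(tm)
  rows <- match(docIds(assignment), docIds(tm))
  ids <- clusterIds(assignment)
  ## deterministic naming order: by cluster numeric suffix where present
  suf <- suppressWarnings(as.integer(sub("^C", "", ids)))
  ids <- ids[order(is.na(suf), suf, ids)]
  nm <- character(0)
  for (id in ids) {
    members <- rows[finalLabels(assignment) == id]
    if (!length(members)) .stopf("cluster %s has no members", id)
    tot <- Matrix::colSums(cnt[members, , drop = FALSE])
    ord <- order(-tot, termNames(tm))
    top <- termNames(tm)[head(ord[tot[ord] > 0], 2L)]
    if (!length(top)) .stopf("cluster %s has no terms", id)
    base <- paste(top, collapse = "-")
    name <- base
    k <- 1L
    while (name %in% nm) { k <- k + 1L; name <- sprintf("%s-%d", base, k) }
    nm[id] <- name
  }
  methods::initialize(assignment, topic_names = nm)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovered topic clusters against planted ground truth.
#'
#' @param a,b vectors of labels (any atomic type), same length.
#' @return the adjusted Rand index (1 = identical partitions; ~0 =
#'   chance-level agreement).
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
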