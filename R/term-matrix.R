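#' Build the stemmed unigram tf-idf document-term matrix
#'
#' Titles and abstracts are decomposed into single terms, stemmed and
#' filtered (see [preprocessText()]); raw counts and tf-idf weights are
#' assembled as sparse matrices whose rows align with corpus order. The
#' tf-idf variant is `tf * ln(N / df)` with raw-count tf and no smoothing,
#' so a term present in every document has weight 0.
#'
#' @param corpus a non-empty [DocumentCorpus-class].
#' @param min_df drop terms occurring in fewer than `min_df` documents
#'   (default 2; singleton terms only add noise to the embedding).
#' @param include_mesh if TRUE, MeSH terms are appended to the text before
#'   tokenization (default FALSE: topics are derived from titles and
#'   abstracts only).
#' @param stopwords stop-word list; defaults to [defaultStopwords()].
#' @return a [TermMatrix-class].
#' @seealso [buildBigramIndex()], [embedDocuments()]
#' @export
buildTermMatrix <- function(corpus, min_df = 2L, include_mesh = FALSE,
                            stopwords = defaultStopwords()) {
  stopifnot(is(corpus, "DocumentCorpus"))
  d <- corpusDocs(corpus)
  if (nrow(d) == 0L) .stopf("corpus is empty")
  texts <- paste(ifelse(is.na(d$title), "", d$title),
                 ifelse(is.na(d$abstract), "", d$abstract))
  if (include_mesh)
    texts <- paste(texts, vapply(d$mesh_terms, paste, "", collapse = " "))
  toks <- lapply(texts, preprocessText, stopwords = stopwords)
  n_tok <- lengths(toks)
  if (sum(n_tok) == 0L) .stopf("empty vocabulary: corpus has no usable tokens")
  doc_idx <- rep.int(seq_along(toks), n_tok)
  all_tok <- unlist(toks, use.names = FALSE)
  terms <- sort(unique(all_tok))
  counts <- Matrix::sparseMatrix(i = doc_idx, j = match(all_tok, terms),
                                 x = 1, dims = c(nrow(d), length(terms)))
  counts <- methods::as(counts, "CsparseMatrix")   # x now holds summed counts
  df <- Matrix::colSums(counts > 0)
  keep <- df >= min_df
  if (!any(keep))
    .stopf("empty vocabulary: no term occurs in at least %d documents", min_df)
  counts <- counts[, keep, drop = FALSE]
  terms <- terms[keep]
  df <- df[keep]
  n <- nrow(d)
  idf <- log(n / df)
  tfidf <- counts %*% Matrix::Diagonal(x = idf)
  tfidf <- methods::as(tfidf, "CsparseMatrix")
  tfidf <- Matrix::drop0(tfidf)
  dimnames(counts) <- dimnames(tfidf) <- list(d$doc_id, terms)
  new("TermMatrix", doc_ids = d$doc_id, terms = terms,
      counts = counts, tfidf = tfidf)
}

#' Build the bigram document-frequency index
#'
#' Bigrams are adjacent lowercased tokens after stop-word removal, without
#' stemming; they are used only to link articles to a priori concepts.
#' Per-cluster document frequencies are tallied against the final labels of
#' a [ClusterAssignment-class] (including the reserved unclustered
#' categories, which downstream filters ignore).
#'
#' @param corpus a [DocumentCorpus-class].
#' @param assignment a [ClusterAssignment-class] covering every corpus
#'   document (an uncovered document is an integrity error).
#' @param stopwords stop-word list; defaults to [defaultStopwords()].
#' @return a [BigramIndex-class].
#' @export
buildBigramIndex <- function(corpus, assignment,
                             stopwords = defaultStopwords()) {
  stopifnot(is(corpus, "DocumentCorpus"), is(assignment, "ClusterAssignment"))
  d <- corpusDocs(corpus)
  lab <- finalLabels(assignment)
  missing <- setdiff(d$doc_id, names(lab))
  if (length(missing))
    .stopf("integrity error: assignment missing documents: %s",
           paste(head(missing, 5L), collapse = ", "))
  per_doc <- lapply(seq_len(nrow(d)), function(i) {
    unique(textBigrams(paste(ifelse(is.na(d$title[i]), "", d$title[i]),
                             ifelse(is.na(d$abstract[i]), "", d$abstract[i])),
                       stopwords = stopwords))
  })
  bigrams <- sort(unique(unlist(per_doc, use.names = FALSE)))
  clusters <- sort(unique(unname(lab[d$doc_id])))
  if (!length(bigrams)) {
    return(new("BigramIndex", bigrams = character(),
               membership = structure(list(), names = character()),
               cluster_df = matrix(integer(), nrow = 0L,
                                   ncol = length(clusters),
                                   dimnames = list(character(), clusters))))
  }
  doc_idx <- rep.int(seq_len(nrow(d)), lengths(per_doc))
  bg_idx <- match(unlist(per_doc, use.names = FALSE), bigrams)
  membership <- split(d$doc_id[doc_idx], factor(bg_idx, seq_along(bigrams)))
  names(membership) <- bigrams
  membership <- lapply(membership, as.character)
  cl_idx <- match(unname(lab[d$doc_id[doc_idx]]), clusters)
  cluster_df <- matrix(0L, nrow = length(bigrams), ncol = length(clusters),
                       dimnames = list(bigrams, clusters))
  tab <- table(bg_idx, cl_idx)
  cluster_df[cbind(as.integer(rownames(tab))[row(tab)],
                   as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  new("BigramIndex", bigrams = bigrams, membership = membership,
      cluster_df = cluster_df)
}
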