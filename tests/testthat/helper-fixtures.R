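## Shared fixture builders; everything is generated in code at test time.

## small corpus with explicit texts
toy_corpus <- function(texts, ids = sprintf("d%d", seq_along(texts)),
                       years = 2015L) {
  DocumentCorpus(doc_id = ids, title = rep("", length(texts)),
                 abstract = texts, year = years)
}

## hand-built assignment over given ids
toy_assignment <- function(ids, labels, topic_names = character()) {
  cl <- setdiff(unique(labels), unclusteredLabels())
  if (!length(topic_names) && length(cl))
    topic_names <- structure(cl, names = cl)
  new("ClusterAssignment", doc_ids = ids, final = labels,
      topic_names = topic_names,
      provenance = structure(rep("test", length(cl)), names = cl),
      sweep_labels = matrix(integer(), nrow = length(ids), ncol = 0L))
}

## random small corpus over a tiny vocabulary, for oracle comparisons
random_corpus <- function(n_docs, vocab, mean_len = 12) {
  texts <- vapply(seq_len(n_docs), function(i)
    paste(sample(vocab, max(2, stats::rpois(1, mean_len)), replace = TRUE),
          collapse = " "), "")
  toy_corpus(texts)
}

## naive per-cell tf-idf: tf = raw count, idf = ln(N / df)
bruteforce_tfidf <- function(corpus, min_df = 1L) {
  d <- corpusDocs(corpus)
  txt <- paste(ifelse(is.na(d$title), "", d$title),
               ifelse(is.na(d$abstract), "", d$abstract))
  toks <- lapply(txt, preprocessText)
  terms <- sort(unique(unlist(toks)))
  n <- length(toks)
  counts <- sapply(terms, function(t)
    vapply(toks, function(tk) sum(tk == t), 1L))
  counts <- matrix(counts, nrow = n, dimnames = list(d$doc_id, terms))
  df <- colSums(counts > 0)
  keep <- df >= min_df
  counts <- counts[, keep, drop = FALSE]
  df <- df[keep]
  tfidf <- sweep(counts, 2, log(n / df), `*`)
  list(counts = counts, tfidf = tfidf, terms = terms[keep])
}

## a valid enhancement record
enh <- function(mode = "add-marks", mark = "point", aes = "color",
                structure = "structured") {
  list(mode = mode, mark = mark, aesthetics = aes, structure = structure)
}

## quick annotation builders
ann_single <- function(id, type = "bar chart", topic = "topicA",
                       concepts = character(), enhancements = list()) {
  FigureAnnotation(id, paste0("doc-", id),
                   list(list(type = type, enhancements = enhancements)),
                   combination = "Single", why_topic = topic,
                   why_concepts = concepts)
}

ann_multi <- function(id, types, combination, constituents = character(),
                      topic = "topicA") {
  FigureAnnotation(id, paste0("doc-", id),
                   lapply(types, function(t) list(type = t)),
                   combination = combination, constituents = constituents,
                   why_topic = topic)
}
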