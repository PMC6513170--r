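#' Construct a ConceptVocabulary
#'
#' @param concept character vector of unique concept names.
#' @param group character vector of groups, one of "genomic",
#'   "epidemiology", "medical".
#' @return a [ConceptVocabulary-class].
#' @export
ConceptVocabulary <- function(concept, group) {
  new("ConceptVocabulary",
      concepts = data.frame(concept = as.character(concept),
                            group = as.character(group),
                            stringsAsFactors = FALSE))
}

#' The default a priori concept vocabulary
#'
#' The 23 analyst-defined concepts in three groups used to link documents
#' to research themes: 7 genomic, 11 epidemiology (the general outbreak
#' concept plus its three level-specific variants counted separately) and
#' 5 medical.
#'
#' @return a [ConceptVocabulary-class] with exactly 23 concepts.
#' @examples
#' table(conceptTable(defaultConceptVocabulary())$group)
#' @export
defaultConceptVocabulary <- function() {
  ConceptVocabulary(
    concept = c(
      ## genomic
      "drug resistance", "genome", "genotype", "molecular biology",
      "pathogen characterization", "phylogeny", "population diversity",
      ## epidemiology
      "clusters", "disease reservoirs", "geography", "outbreaks",
      "outbreaks (international)", "outbreaks (community)",
      "outbreaks (hospital)", "surveillance", "transmission", "vaccine",
      "vectors",
      ## medical
      "clinical", "cancer", "diagnosis", "outcome", "treatment"),
    group = c(rep("genomic", 7L), rep("epidemiology", 11L),
              rep("medical", 5L)))
}

#' Construct a ConceptMap
#'
#' @param bigram character vector of bigrams (each maps to at most one
#'   concept).
#' @param concept character vector of concept names.
#' @param vocabulary optional [ConceptVocabulary-class]; when given, every
#'   concept must exist in it (validation error otherwise).
#' @return a [ConceptMap-class].
#' @export
ConceptMap <- function(bigram, concept, vocabulary = NULL) {
  cm <- new("ConceptMap",
            entries = data.frame(bigram = as.character(bigram),
                                 concept = as.character(concept),
                                 stringsAsFactors = FALSE))
  if (!is.null(vocabulary)) {
    bad <- setdiff(cm@entries$concept, conceptTable(vocabulary)$concept)
    if (length(bad))
      .stopf("validation error: concept map references unknown concepts: %s",
             paste(bad, collapse = ", "))
  }
  cm
}

#' The bundled default concept map
#'
#' Only the documented exemplar assignment ships by default (the bigram
#' "vancomycin resistance" mapped to the concept "drug resistance"); the
#' full curated map is an analyst product loaded with [readConceptMap()].
#'
#' @return a [ConceptMap-class].
#' @export
defaultConceptMap <- function() {
  ConceptMap("vancomycin resistance", "drug resistance",
             vocabulary = defaultConceptVocabulary())
}

#' Read a concept map or a plain vocabulary-term file
#'
#' `readConceptMap()` reads a two-column delimited table (bigram, concept;
#' tab or comma auto-detected). `readVocabularyTerms()` reads a plain-text
#' controlled vocabulary, one term per line (e.g. pathogen names).
#'
#' @param path file path.
#' @param vocabulary optional [ConceptVocabulary-class] to validate
#'   concepts against.
#' @return a [ConceptMap-class], or a character vector of terms.
#' @export
readConceptMap <- function(path, vocabulary = defaultConceptVocabulary()) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("bigram", "concept") %in% names(tab)))
    .stopf("format error in '%s': columns bigram, concept required",
           basename(path))
  ConceptMap(tab$bigram, tab$concept, vocabulary = vocabulary)
}

#' @rdname readConceptMap
#' @export
readVocabularyTerms <- function(path) {
  terms <- trimws(readLines(path, warn = FALSE))
  terms[nzchar(terms)]
}

#' Validate clusters against an external controlled vocabulary
#'
#' Case-insensitive whole-phrase matching of vocabulary terms (e.g. human
#' pathogen names) against raw title+abstract text, tallied per cluster.
#' Terms whose total number of matching documents falls below
#' `min_articles` are dropped. The resulting table supports the
#' small-multiples check of term distribution across clusters against
#' automatically derived cluster names.
#'
#' @param corpus a [DocumentCorpus-class].
#' @param assignment a [ClusterAssignment-class] for the corpus.
#' @param vocab_terms non-empty character vector of vocabulary terms
#'   (multi-word phrases allowed; matched unstemmed).
#' @param min_articles minimum total matching documents for a term to be
#'   kept (default 40).
#' @return data.frame with columns `term`, `cluster`, `n_docs` (a document
#'   counts once per term and cluster).
#' @export
matchExternalVocabulary <- function(corpus, assignment, vocab_terms,
                                    min_articles = 40L) {
  stopifnot(is(corpus, "DocumentCorpus"), is(assignment, "ClusterAssignment"))
  if (!length(vocab_terms)) .stopf("vocabulary terms must be non-empty")
  d <- corpusDocs(corpus)
  lab <- finalLabels(assignment)[d$doc_id]
  text <- tolower(paste(ifelse(is.na(d$title), "", d$title),
                        ifelse(is.na(d$abstract), "", d$abstract)))
  rows <- list()
  for (term in unique(vocab_terms)) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                              tolower(term)), "\\b")
    hit <- grepl(pat, text, perl = TRUE)
    if (sum(hit) < min_articles) next
    tab <- table(lab[hit])
    rows[[term]] <- data.frame(term = term, cluster = names(tab),
                               n_docs = as.integer(tab),
                               stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term = character(), cluster = character(),
                      n_docs = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$term, out$cluster), , drop = FALSE]
}

#' Simplify an assignment to large clusters plus "other"
#'
#' Clusters with at least `min_cluster_docs` member documents are retained
#' under their names; all smaller clusters are relabeled to a single
#' "other" cluster. Unclustered categories are untouched and document
#' count is conserved.
#'
#' @param assignment a named [ClusterAssignment-class].
#' @param match_table optional external-vocabulary match table (see
#'   [matchExternalVocabulary()]); when given, retention is additionally
#'   restricted to clusters that appear in it.
#' @param min_cluster_docs retention threshold (default 100).
#' @return the simplified [ClusterAssignment-class].
#' @export
simplifyClusters <- function(assignment, match_table = NULL,
                             min_cluster_docs = 100L) {
  stopifnot(is(assignment, "ClusterAssignment"))
  ids <- clusterIds(assignment)
  sizes <- vapply(ids, function(id) sum(assignment@final == id), 1L)
  keep <- sizes >= min_cluster_docs
  if (!is.null(match_table) && nrow(match_table))
    keep <- keep & ids %in% unique(match_table$cluster)
  drop_ids <- ids[!keep]
  if (!length(drop_ids)) {
    prov <- assignment@provenance
    attr(prov, "simplified") <- sprintf("min_cluster_docs=%d", min_cluster_docs)
    return(methods::initialize(assignment, provenance = prov))
  }
  final <- assignment@final
  final[final %in% drop_ids] <- "other"
  nm <- assignment@topic_names
  nm <- nm[setdiff(names(nm), drop_ids)]
  nm["other"] <- "other"
  prov <- assignment@provenance
  prov <- prov[setdiff(names(prov), drop_ids)]
  prov["other"] <- sprintf("simplify(min_cluster_docs=%d)", min_cluster_docs)
  methods::initialize(assignment, final = final, topic_names = nm,
                      provenance = prov)
}

#' Identify candidate concept bigrams
#'
#' A bigram is a candidate for manual concept assignment when it occurs in
#' at least `min_within` articles within some topic cluster and is present
#' (document frequency >= 1) in at least
#' `ceiling(min_between_frac * (C - 1))` of the other clusters, where C is
#' the number of clusters. Output is deterministic and sorted.
#'
#' @param bi a [BigramIndex-class] built against a simplified assignment.
#' @param assignment the matching [ClusterAssignment-class]; at least two
#'   clusters are required.
#' @param min_within within-cluster document-frequency threshold
#'   (default 10).
#' @param min_between_frac fraction of the other clusters the bigram must
#'   appear in (default 0.10).
#' @return sorted character vector of candidate bigrams.
#' @export
findCandidateBigrams <- function(bi, assignment, min_within = 10L,
                                 min_between_frac = 0.10) {
  stopifnot(is(bi, "BigramIndex"), is(assignment, "ClusterAssignment"))
  ids <- clusterIds(assignment)
  if (length(ids) < 2L)
    .stopf("at least two clusters are required (have %d)", length(ids))
  df <- bi@cluster_df[, intersect(colnames(bi@cluster_df), ids), drop = FALSE]
  if (!ncol(df)) .stopf("bigram index has no columns for the assignment clusters")
  need_between <- .ceil_frac(min_between_frac, length(ids) - 1L)
  keep <- vapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    anchors <- which(row >= min_within)
    if (!length(anchors)) return(FALSE)
    any(vapply(anchors, function(a) sum(row[-a] >= 1L) >= need_between,
               TRUE))
  }, TRUE)
  sort(rownames(df)[keep])
}

#' Link documents to a priori concepts through mapped bigrams
#'
#' A document is tagged with concept C when it contains any candidate
#' bigram that the curated map assigns to C. Candidates not covered by the
#' map are reported (attribute `unmapped`) for manual curation.
#'
#' @param corpus a [DocumentCorpus-class].
#' @param candidates character vector of candidate bigrams (see
#'   [findCandidateBigrams()]).
#' @param cmap a [ConceptMap-class]; referencing a concept outside
#'   `vocabulary` is a validation error.
#' @param bi the [BigramIndex-class] holding bigram membership.
#' @param vocabulary the [ConceptVocabulary-class] (default bundled).
#' @return a [ConceptLinks-class]; `attr(, "unmapped")` lists candidate
#'   bigrams with no concept assignment.
#' @export
linkConcepts <- function(corpus, candidates, cmap, bi,
                         vocabulary = defaultConceptVocabulary()) {
  stopifnot(is(corpus, "DocumentCorpus"), is(cmap, "ConceptMap"),
            is(bi, "BigramIndex"))
  entries <- conceptMapEntries(cmap)
  bad <- setdiff(entries$concept, conceptTable(vocabulary)$concept)
  if (length(bad))
    .stopf("validation error: concept map references unknown concepts: %s",
           paste(bad, collapse = ", "))
  mapped <- entries[entries$bigram %in% candidates, , drop = FALSE]
  unmapped <- setdiff(candidates, entries$bigram)
  links <- structure(vector("list", nDocs(corpus)), names = docIds(corpus))
  for (i in seq_along(links)) links[[i]] <- character()
  for (k in seq_len(nrow(mapped))) {
    docs <- intersect(bi@membership[[mapped$bigram[k]]], names(links))
    for (dc in docs)
      links[[dc]] <- union(links[[dc]], mapped$concept[k])
  }
  links <- lapply(links, function(v) sort(v))
  out <- new("ConceptLinks", links = links,
             concepts = conceptTable(vocabulary)$concept)
  attr(out, "unmapped") <- sort(unmapped)
  out
}
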