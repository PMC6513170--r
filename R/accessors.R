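#' Accessors for the core containers
#'
#' Small generic accessor layer so downstream code never touches slots.
#'
#' @param x an object of the documented class.
#' @return `docIds()` the ordered document identifiers; `nDocs()` the number
#'   of documents; `corpusDocs()` the per-document data.frame;
#'   `termCounts()` / `termTfidf()` the sparse matrices; `termNames()` the
#'   stemmed vocabulary; `embeddingCoords()` the 2-D coordinate matrix;
#'   `sweepLabels()` the per-setting label matrix; `finalLabels()` the final
#'   per-document labels; `topicNames()` the cluster-id to topic-name map;
#'   `clusterIds()` the cluster ids in use; `conceptTable()` /
#'   `conceptMapEntries()` / `conceptLinksList()` the underlying tables;
#'   `strataTable()` the stratum table; `selections()` the sampling event
#'   log; `chartTypes()` / `combinationTypes()` the schema vocabularies.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("docIds", function(x) standardGeneric("docIds"))
#' @rdname accessors
#' @export
setGeneric("nDocs", function(x) standardGeneric("nDocs"))
#' @rdname accessors
#' @export
setGeneric("corpusDocs", function(x) standardGeneric("corpusDocs"))
#' @rdname accessors
#' @export
setGeneric("termCounts", function(x) standardGeneric("termCounts"))
#' @rdname accessors
#' @export
setGeneric("termTfidf", function(x) standardGeneric("termTfidf"))
#' @rdname accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))
#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))
#' @rdname accessors
#' @export
setGeneric("sweepLabels", function(x) standardGeneric("sweepLabels"))
#' @rdname accessors
#' @export
setGeneric("finalLabels", function(x) standardGeneric("finalLabels"))
#' @rdname accessors
#' @export
setGeneric("topicNames", function(x) standardGeneric("topicNames"))
#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))
#' @rdname accessors
#' @export
setGeneric("conceptTable", function(x) standardGeneric("conceptTable"))
#' @rdname accessors
#' @export
setGeneric("conceptMapEntries", function(x) standardGeneric("conceptMapEntries"))
#' @rdname accessors
#' @export
setGeneric("conceptLinksList", function(x) standardGeneric("conceptLinksList"))
#' @rdname accessors
#' @export
setGeneric("strataTable", function(x) standardGeneric("strataTable"))
#' @rdname accessors
#' @export
setGeneric("selections", function(x) standardGeneric("selections"))
#' @rdname accessors
#' @export
setGeneric("chartTypes", function(x) standardGeneric("chartTypes"))
#' @rdname accessors
#' @export
setGeneric("combinationTypes", function(x) standardGeneric("combinationTypes"))

#' @rdname accessors
setMethod("docIds", "DocumentCorpus", function(x) x@docs$doc_id)
#' @rdname accessors
setMethod("docIds", "TermMatrix", function(x) x@doc_ids)
#' @rdname accessors
setMethod("docIds", "Embedding", function(x) x@doc_ids)
#' @rdname accessors
setMethod("docIds", "SweepResult", function(x) x@doc_ids)
#' @rdname accessors
setMethod("docIds", "ClusterAssignment", function(x) x@doc_ids)

#' @rdname accessors
setMethod("nDocs", "DocumentCorpus", function(x) nrow(x@docs))
#' @rdname accessors
setMethod("corpusDocs", "DocumentCorpus", function(x) x@docs)
#' @rdname accessors
setMethod("termCounts", "TermMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("termTfidf", "TermMatrix", function(x) x@tfidf)
#' @rdname accessors
setMethod("termNames", "TermMatrix", function(x) x@terms)
#' @rdname accessors
setMethod("embeddingCoords", "Embedding", function(x) x@coords)
#' @rdname accessors
setMethod("sweepLabels", "SweepResult", function(x) x@labels)
#' @rdname accessors
setMethod("sweepLabels", "ClusterAssignment", function(x) x@sweep_labels)
#' @rdname accessors
setMethod("finalLabels", "ClusterAssignment", function(x) {
  structure(x@final, names = x@doc_ids)
})
#' @rdname accessors
setMethod("topicNames", "ClusterAssignment", function(x) x@topic_names)
#' @rdname accessors
setMethod("clusterIds", "ClusterAssignment", function(x) {
  setdiff(unique(x@final), c(.UNCLUSTERED, .NEVER))
})
#' @rdname accessors
setMethod("conceptTable", "ConceptVocabulary", function(x) x@concepts)
#' @rdname accessors
setMethod("conceptMapEntries", "ConceptMap", function(x) x@entries)
#' @rdname accessors
setMethod("conceptLinksList", "ConceptLinks", function(x) x@links)
#' @rdname accessors
setMethod("strataTable", "StrataSet", function(x) x@strata)
#' @rdname accessors
setMethod("selections", "SampleSet", function(x) x@selections)
#' @rdname accessors
setMethod("chartTypes", "TypologySchema", function(x) x@chart_types)
#' @rdname accessors
setMethod("combinationTypes", "TypologySchema", function(x) x@combination_types)

#' Reserved final-label categories
#'
#' Documents that are noise only under the consolidated parameter settings
#' are "currently-unclustered"; documents that are noise under every swept
#' setting are "never-clustered".
#'
#' @return a named character vector of the two reserved labels.
#' @examples
#' unclusteredLabels()
#' @export
unclusteredLabels <- function() {
  c(currently_unclustered = .UNCLUSTERED, never_clustered = .NEVER)
}
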