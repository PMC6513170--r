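#' @title Core S4 containers
#' @description S4 classes for the literature-analysis and
#'   visualization-typology pipeline: document corpora, term matrices,
#'   embeddings, cluster assignments, concept structures, sampling state,
#'   the typology schema and figure annotations.
#' @name gevit-classes
NULL

#' DocumentCorpus: an ordered collection of article records
#'
#' One row per article with identifier, publication year, title, abstract,
#' MeSH terms and free-form flags. The unit of clustering and sampling.
#'
#' @slot docs data.frame with columns `doc_id` (character, unique),
#'   `year` (integer, `NA` allowed), `title`, `abstract` (character) and
#'   list-columns `mesh_terms`, `flags` (character vectors per document).
#' @slot provenance free-text description of the source queries.
#' @exportClass DocumentCorpus
setClass("DocumentCorpus",
         representation(docs = "data.frame", provenance = "character"))

setValidity("DocumentCorpus", function(object) {
  d <- object@docs
  need <- c("doc_id", "year", "title", "abstract", "mesh_terms", "flags")
  if (!all(need %in% names(d)))
    return(paste("docs must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (anyNA(d$doc_id) || !is.character(d$doc_id))
    return("doc_id must be non-missing character")
  if (anyDuplicated(d$doc_id))
    return(paste("duplicate doc_id:",
                 paste(unique(d$doc_id[duplicated(d$doc_id)]), collapse = ", ")))
  yr <- d$year[!is.na(d$year)]
  if (length(yr) && any(yr < 1000 | yr > 9999))
    return("year must be a 4-digit integer or NA")
  TRUE
})

#' TermMatrix: sparse document-by-term counts and tf-idf weights
#'
#' @slot doc_ids ordered document identifiers (matrix rows).
#' @slot terms ordered stemmed unigrams (matrix columns).
#' @slot counts sparse matrix of raw term counts.
#' @slot tfidf sparse matrix of tf-idf weights, same shape as `counts`.
#' @exportClass TermMatrix
setClass("TermMatrix",
         representation(doc_ids = "character", terms = "character",
                        counts = "Matrix", tfidf = "Matrix"))

setValidity("TermMatrix", function(object) {
  dmc <- dim(object@counts); dmt <- dim(object@tfidf)
  if (!identical(dmc, dmt)) return("counts and tfidf must have identical shape")
  if (dmc[1L] != length(object@doc_ids)) return("row count != |doc_ids|")
  if (dmc[2L] != length(object@terms)) return("column count != |terms|")
  if (any(object@counts@x < 0) || any(object@tfidf@x < 0))
    return("all entries must be >= 0")
  TRUE
})

#' BigramIndex: lowercased, unstemmed adjacent-token bigrams
#'
#' @slot bigrams bigram strings ("token token"), stop words removed,
#'   unstemmed.
#' @slot membership named list: bigram -> character vector of doc_ids
#'   containing it as adjacent tokens.
#' @slot cluster_df integer matrix bigram x cluster of per-cluster document
#'   frequencies.
#' @exportClass BigramIndex
setClass("BigramIndex",
         representation(bigrams = "character", membership = "list",
                        cluster_df = "matrix"))

setValidity("BigramIndex", function(object) {
  if (!identical(names(object@membership), object@bigrams))
    return("membership must be named by bigrams, same order")
  if (length(object@bigrams) && nrow(object@cluster_df) != length(object@bigrams))
    return("cluster_df rows != |bigrams|")
  TRUE
})

#' Embedding: 2-D t-SNE coordinates for a document set
#'
#' @slot doc_ids ordered document identifiers.
#' @slot coords numeric matrix, one row per document, two columns.
#' @slot perplexity perplexity actually used (may be auto-lowered).
#' @slot seed integer RNG seed used for the layout.
#' @exportClass Embedding
setClass("Embedding",
         representation(doc_ids = "character", coords = "matrix",
                        perplexity = "numeric", seed = "integer"))

setValidity("Embedding", function(object) {
  if (nrow(object@coords) != length(object@doc_ids))
    return("|coords| != |doc_ids|")
  if (ncol(object@coords) != 2L) return("coords must be 2-D")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  TRUE
})

#' SweepResult: density-clustering labels across a minPts sweep
#'
#' @slot doc_ids ordered document identifiers.
#' @slot min_pts the swept minimum-cluster-size values.
#' @slot labels integer matrix (document x setting); 0 encodes noise;
#'   positive integers are per-setting cluster ids in decreasing size order.
#' @exportClass SweepResult
setClass("SweepResult",
         representation(doc_ids = "character", min_pts = "integer",
                        labels = "matrix"))

setValidity("SweepResult", function(object) {
  if (nrow(object@labels) != length(object@doc_ids))
    return("labels rows != |doc_ids|")
  if (ncol(object@labels) != length(object@min_pts))
    return("labels columns != |min_pts|")
  if (anyNA(object@labels)) return("every setting must label every document")
  TRUE
})

#' ClusterAssignment: final per-document topic-cluster labels
#'
#' Final labels partition the corpus into named clusters,
#' "currently-unclustered" (noise under the consolidated settings only) and
#' "never-clustered" (noise under every swept setting).
#'
#' @slot doc_ids ordered document identifiers.
#' @slot final per-document final label: a cluster id (e.g. "C1", "other")
#'   or one of the two reserved categories.
#' @slot topic_names named character: cluster id -> hyphen-joined top-2
#'   stemmed terms (empty before [nameClusters()] is run).
#' @slot provenance named character: cluster id -> the sweep setting (or
#'   operation) that produced it.
#' @slot sweep_labels the per-setting label matrix the assignment was
#'   consolidated from (may have zero columns for hand-built assignments).
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
         representation(doc_ids = "character", final = "character",
                        topic_names = "character", provenance = "character",
                        sweep_labels = "matrix"))

setValidity("ClusterAssignment", function(object) {
  if (length(object@final) != length(object@doc_ids))
    return("final labels must cover every document")
  if (anyNA(object@final)) return("final labels must be non-missing")
  cl <- setdiff(unique(object@final), c(.UNCLUSTERED, .NEVER))
  if (length(object@topic_names) && !all(cl %in% names(object@topic_names)))
    return("every cluster id must have a topic name once named")
  if (ncol(object@sweep_labels) > 0L) {
    never <- object@final == .NEVER
    all_noise <- rowSums(object@sweep_labels != 0L) == 0L
    if (!identical(unname(never), unname(all_noise)))
      return("never-clustered must hold exactly for documents that are noise under every sweep setting")
  }
  TRUE
})

#' ConceptVocabulary: the a priori concepts and their groups
#'
#' @slot concepts data.frame with columns `concept`, `group`
#'   (group in genomic / epidemiology / medical).
#' @exportClass ConceptVocabulary
setClass("ConceptVocabulary", representation(concepts = "data.frame"))

setValidity("ConceptVocabulary", function(object) {
  d <- object@concepts
  if (!all(c("concept", "group") %in% names(d)))
    return("concepts needs columns concept, group")
  if (anyDuplicated(d$concept)) return("concept names must be unique")
  if (!all(d$group %in% c("genomic", "epidemiology", "medical")))
    return("group must be one of genomic, epidemiology, medical")
  TRUE
})

#' ConceptMap: curated bigram-to-concept assignments
#'
#' @slot entries data.frame with columns `bigram`, `concept`.
#' @exportClass ConceptMap
setClass("ConceptMap", representation(entries = "data.frame"))

setValidity("ConceptMap", function(object) {
  d <- object@entries
  if (!all(c("bigram", "concept") %in% names(d)))
    return("entries needs columns bigram, concept")
  if (anyDuplicated(d$bigram))
    return("a bigram maps to at most one concept")
  TRUE
})

#' ConceptLinks: per-document a priori concept tags
#'
#' @slot links named list: doc_id -> character vector of concept names.
#' @slot concepts the concept names the links may draw from.
#' @exportClass ConceptLinks
setClass("ConceptLinks",
         representation(links = "list", concepts = "character"))

setValidity("ConceptLinks", function(object) {
  used <- unique(unlist(object@links, use.names = FALSE))
  if (length(used) && !all(used %in% object@concepts))
    return("links reference concepts outside the vocabulary")
  TRUE
})

#' StrataSet: sampling strata over (cluster x concept) cells
#'
#' @slot strata data.frame with columns `cluster`, `concept` and list-column
#'   `doc_ids` (eligible documents per stratum).
#' @slot years named integer vector doc_id -> publication year (used by the
#'   year-constrained sampling rounds; may be empty).
#' @exportClass StrataSet
setClass("StrataSet", representation(strata = "data.frame", years = "integer"))

#' SampleSet: the stratified-sampling event log
#'
#' @slot selections data.frame, one row per selection event: `cluster`,
#'   `concept`, `doc_id`, `round`, `status` (pending / accepted / rejected),
#'   `reason` (controlled rejection code or free text; NA otherwise).
#' @slot seed integer seed of the draw that created the set.
#' @exportClass SampleSet
setClass("SampleSet", representation(selections = "data.frame", seed = "integer"))

setValidity("SampleSet", function(object) {
  d <- object@selections
  need <- c("cluster", "concept", "doc_id", "round", "status", "reason")
  if (!all(need %in% names(d)))
    return(paste("selections needs columns:", paste(need, collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (!all(d$status %in% c("pending", "accepted", "rejected", "candidate")))
    return("status must be pending, accepted, rejected or candidate")
  acc <- d[d$status == "accepted", , drop = FALSE]
  if (nrow(acc)) {
    key <- paste(acc$cluster, acc$concept, acc$round, sep = "\r")
    if (anyDuplicated(key))
      return("at most one accepted document per stratum per round")
  }
  TRUE
})

#' TypologySchema: the controlled vocabularies of the visualization typology
#'
#' @slot chart_classes the chart-type classes.
#' @slot chart_types data.frame with columns `name`, `class`, `parent`
#'   (parent chart type for special cases, NA otherwise).
#' @slot combination_types exactly six chart-combination categories.
#' @slot mark_kinds basic graphical marks (connection is a specialized line
#'   mark, containment a specialized area mark, glyph an embedded mini-chart).
#' @slot aesthetics mark aesthetic properties.
#' @slot enhancement_modes add-marks / re-encode-marks.
#' @slot enhancement_structure structured / annotation.
#' @slot core logical; TRUE for the bundled schema before any overlay.
#' @exportClass TypologySchema
setClass("TypologySchema",
         representation(chart_classes = "character", chart_types = "data.frame",
                        combination_types = "character", mark_kinds = "character",
                        aesthetics = "character",
                        enhancement_modes = "character",
                        enhancement_structure = "character",
                        core = "logical"))

setValidity("TypologySchema", function(object) {
  if (length(object@combination_types) != 6L)
    return("combination_types must have exactly 6 members")
  ct <- object@chart_types
  if (!all(c("name", "class", "parent") %in% names(ct)))
    return("chart_types needs columns name, class, parent")
  if (anyDuplicated(ct$name))
    return("every chart type belongs to exactly one class")
  if (!all(ct$class %in% object@chart_classes))
    return("chart type classes must be registered chart classes")
  par <- ct$parent[!is.na(ct$parent)]
  if (length(par) && !all(par %in% ct$name))
    return("special cases must reference a parent chart type")
  if (!all(c("connection", "line", "containment", "area") %in% object@mark_kinds))
    return("mark kinds must include line/connection and area/containment")
  TRUE
})

#' FigureAnnotation: the typology coding of one figure
#'
#' Whole figures are coded; multi-part figures are not decomposed.
#'
#' @slot figure_id unique figure identifier.
#' @slot doc_id source article identifier.
#' @slot chart_instances list; each element is `list(type =, enhancements =)`
#'   where enhancements is a list of
#'   `list(mode =, mark =, aesthetics =, structure =)`.
#' @slot combination one combination-type code.
#' @slot constituents for Complex Combination: the two constituent
#'   non-Single combination types; otherwise empty.
#' @slot why_topic the topic-cluster tag (why axis).
#' @slot why_concepts a priori concept tags (why axis).
#' @slot quality_tags optional subjective tags (good / missed-opportunity).
#' @slot caption optional caption text.
#' @exportClass FigureAnnotation
setClass("FigureAnnotation",
         representation(figure_id = "character", doc_id = "character",
                        chart_instances = "list", combination = "character",
                        constituents = "character", why_topic = "character",
                        why_concepts = "character", quality_tags = "character",
                        caption = "character"))

#' DesignSpaceStats: descriptive statistics over an annotation corpus
#'
#' All percentages are accompanied by the counts they were computed from.
#'
#' @slot n_figures number of annotated figures.
#' @slot n_instances number of chart-type instances across figures.
#' @slot chart_type_instance_share data.frame (`type`, `n`, `pct`): share of
#'   all chart-type instances.
#' @slot chart_type_presence data.frame (`level`, `name`, `n`, `pct`): per
#'   type and per class, percentage of figures containing at least one
#'   instance.
#' @slot combination_distribution data.frame (`combination`, `n`, `pct`):
#'   exclusive and exhaustive over figures.
#' @slot enhancement_rates data.frame (`measure`, `n`, `pct`) over chart
#'   instances: any-enhancement, add-marks, re-encode-marks, annotation.
#' @exportClass DesignSpaceStats
setClass("DesignSpaceStats",
         representation(n_figures = "integer", n_instances = "integer",
                        chart_type_instance_share = "data.frame",
                        chart_type_presence = "data.frame",
                        combination_distribution = "data.frame",
                        enhancement_rates = "data.frame"))

## ---- show methods -------------------------------------------------------

setMethod("show", "DocumentCorpus", function(object) {
  cat(sprintf("DocumentCorpus with %d documents\n", nrow(object@docs)))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  yr <- object@docs$year
  if (length(yr) && any(!is.na(yr)))
    cat(sprintf("  years: %d-%d (%d missing)\n", min(yr, na.rm = TRUE),
                max(yr, na.rm = TRUE), sum(is.na(yr))))
})

setMethod("show", "TermMatrix", function(object) {
  cat(sprintf("TermMatrix: %d documents x %d stemmed terms (%.2f%% nonzero)\n",
              length(object@doc_ids), length(object@terms),
              100 * length(object@counts@x) /
                max(1, length(object@doc_ids) * length(object@terms))))
})

setMethod("show", "Embedding", function(object) {
  cat(sprintf("Embedding: %d documents, perplexity %.1f, seed %d\n",
              length(object@doc_ids), object@perplexity, object@seed))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult over minPts {%s} on %d documents\n",
              paste(object@min_pts, collapse = ", "), length(object@doc_ids)))
  for (j in seq_along(object@min_pts)) {
    lb <- object@labels[, j]
    cat(sprintf("  minPts=%d: %d clusters, %d noise\n", object@min_pts[j],
                length(setdiff(unique(lb), 0L)), sum(lb == 0L)))
  }
})

setMethod("show", "ClusterAssignment", function(object) {
  cl <- setdiff(unique(object@final), c(.UNCLUSTERED, .NEVER))
  cat(sprintf("ClusterAssignment: %d documents, %d clusters, %d %s, %d %s\n",
              length(object@doc_ids), length(cl),
              sum(object@final == .UNCLUSTERED), .UNCLUSTERED,
              sum(object@final == .NEVER), .NEVER))
  if (length(object@topic_names)) {
    nm <- head(object@topic_names, 8)
    cat("  topics:", paste(sprintf("%s=%s", names(nm), nm), collapse = ", "),
        if (length(object@topic_names) > 8) "..." else "", "\n")
  }
})

setMethod("show", "TypologySchema", function(object) {
  cat(sprintf(paste0("TypologySchema: %d chart types in %d classes; ",
                     "%d combination types; %d mark kinds\n"),
              nrow(object@chart_types), length(object@chart_classes),
              length(object@combination_types), length(object@mark_kinds)))
})

setMethod("show", "FigureAnnotation", function(object) {
  cat(sprintf("FigureAnnotation %s (doc %s): %s, %d chart instance(s)\n",
              object@figure_id, object@doc_id, object@combination,
              length(object@chart_instances)))
})

setMethod("show", "DesignSpaceStats", function(object) {
  cat(sprintf("DesignSpaceStats over %d figures / %d chart instances\n",
              object@n_figures, object@n_instances))
  cat("  combination distribution (%):\n")
  d <- object@combination_distribution
  for (i in seq_len(nrow(d)))
    cat(sprintf("    %-20s %5.1f (n=%d)\n", d$combination[i], d$pct[i], d$n[i]))
})
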