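#' Load the visualization typology schema
#'
#' Returns the bundled typology — chart types grouped into classes (with
#' special cases referencing a parent type, e.g. epidemic curve under bar
#' chart), the six chart-combination categories, mark kinds (connection is
#' a specialized line mark, containment a specialized area mark), mark
#' aesthetics and the enhancement vocabularies — optionally merged with a
#' user overlay. Overlays are strictly additive: they may add chart
#' classes, chart types, special cases or glyph types, but may never
#' redefine or remove a core code (the combination taxonomy, mark kinds,
#' aesthetics and enhancement vocabularies are fixed).
#'
#' The bundled chart types are those documented for the original corpus;
#' the complete published inventory can be restored by whoever has the
#' published taxonomy figure, via an overlay file.
#'
#' @param overlay optional path to a JSON overlay file with any of the
#'   keys `chart_classes`, `chart_types` (records with `name`, `class`,
#'   optional `parent`), `glyph_types`.
#' @return a [TypologySchema-class]; ordering is stable (bundled codes
#'   first, overlay additions after, in file order).
#' @examples
#' s <- loadSchema()
#' combinationTypes(s)
#' @export
loadSchema <- function(overlay = NULL) {
  f <- system.file("extdata", "gevit_schema.json", package = "gevit",
                   mustWork = TRUE)
  raw <- jsonlite::fromJSON(f, simplifyDataFrame = TRUE)
  ct <- raw$chart_types
  ct$parent <- as.character(ct$parent)
  schema <- new("TypologySchema",
                chart_classes = raw$chart_classes,
                chart_types = ct,
                combination_types = raw$combination_types,
                mark_kinds = raw$mark_kinds,
                aesthetics = raw$aesthetics,
                enhancement_modes = raw$enhancement_modes,
                enhancement_structure = raw$enhancement_structure,
                core = TRUE)
  if (is.null(overlay)) return(schema)
  ov <- jsonlite::fromJSON(overlay, simplifyDataFrame = TRUE)
  frozen <- c("combination_types", "mark_kinds", "aesthetics",
              "enhancement_modes", "enhancement_structure")
  touched <- intersect(names(ov), frozen)
  if (length(touched))
    .stopf("validation error: overlay may not redefine core code sets: %s",
           paste(touched, collapse = ", "))
  if (!is.null(ov$chart_classes))
    schema@chart_classes <- c(schema@chart_classes,
                              setdiff(ov$chart_classes, schema@chart_classes))
  if (!is.null(ov$chart_types)) {
    add <- as.data.frame(ov$chart_types, stringsAsFactors = FALSE)
    if (is.null(add$parent)) add$parent <- NA_character_
    add$parent <- as.character(add$parent)
    clash <- intersect(add$name, schema@chart_types$name)
    if (length(clash))
      .stopf("validation error: overlay redefines core chart types: %s",
             paste(clash, collapse = ", "))
    schema@chart_types <- rbind(schema@chart_types,
                                add[, c("name", "class", "parent")])
  }
  schema@core <- FALSE
  methods::validObject(schema)
  schema
}

#' Write a schema as a machine-readable document
#'
#' Serializes a [TypologySchema-class] to the same JSON layout the bundled
#' schema ships in, so third-party validators can check annotation files;
#' `loadSchemaFile()` parses such a document back. Serialization followed
#' by parsing is the identity.
#'
#' @param schema a [TypologySchema-class].
#' @param path destination (for `writeSchema`) or source (for
#'   `loadSchemaFile`) file path.
#' @return `writeSchema` returns `path` invisibly; `loadSchemaFile` the
#'   parsed [TypologySchema-class].
#' @export
writeSchema <- function(schema, path) {
  stopifnot(is(schema, "TypologySchema"))
  ct <- schema@chart_types
  payload <- list(schema = "gevit-typology", version = 1L,
                  chart_classes = schema@chart_classes,
                  chart_types = lapply(seq_len(nrow(ct)), function(i)
                    list(name = ct$name[i], class = ct$class[i],
                         parent = if (is.na(ct$parent[i])) NULL
                                  else ct$parent[i])),
                  combination_types = schema@combination_types,
                  mark_kinds = schema@mark_kinds,
                  aesthetics = schema@aesthetics,
                  enhancement_modes = schema@enhancement_modes,
                  enhancement_structure = schema@enhancement_structure,
                  core = schema@core)
  .write_artifact_json(payload, path)
}

#' @rdname writeSchema
#' @export
loadSchemaFile <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  ct <- as.data.frame(raw$chart_types, stringsAsFactors = FALSE)
  if (is.null(ct$parent)) ct$parent <- NA_character_
  ct$parent <- as.character(ct$parent)
  new("TypologySchema", chart_classes = raw$chart_classes, chart_types = ct,
      combination_types = raw$combination_types,
      mark_kinds = raw$mark_kinds, aesthetics = raw$aesthetics,
      enhancement_modes = raw$enhancement_modes,
      enhancement_structure = raw$enhancement_structure,
      core = isTRUE(raw$core))
}

#' Construct a figure annotation
#'
#' @param figure_id unique figure identifier.
#' @param doc_id source article identifier.
#' @param chart_instances list of chart instances; each is
#'   `list(type = "heatmap", enhancements = list(...))` where every
#'   enhancement is `list(mode =, mark =, aesthetics =, structure =)`. A
#'   bare character vector of types is also accepted (no enhancements).
#' @param combination one combination-type code.
#' @param constituents the two constituent combination types when
#'   `combination` is "Complex Combination".
#' @param why_topic,why_concepts the why-axis tags (topic cluster name and
#'   a priori concepts).
#' @param quality_tags optional subjective tags ("good",
#'   "missed-opportunity").
#' @param caption optional caption text.
#' @return a [FigureAnnotation-class].
#' @examples
#' FigureAnnotation("fig1", "p1", list(list(type = "heatmap"),
#'                                     list(type = "dendrogram")),
#'                  combination = "Composite")
#' @export
FigureAnnotation <- function(figure_id, doc_id, chart_instances,
                             combination, constituents = character(),
                             why_topic = NA_character_,
                             why_concepts = character(),
                             quality_tags = character(),
                             caption = NA_character_) {
  if (is.character(chart_instances))
    chart_instances <- lapply(chart_instances, function(t) list(type = t))
  chart_instances <- lapply(chart_instances, function(ci) {
    list(type = as.character(ci$type),
         enhancements = lapply(ci$enhancements %||% list(), function(e)
           list(mode = as.character(e$mode), mark = as.character(e$mark),
                aesthetics = as.character(e$aesthetics %||% character()),
                structure = as.character(e$structure))))
  })
  new("FigureAnnotation", figure_id = as.character(figure_id),
      doc_id = as.character(doc_id), chart_instances = chart_instances,
      combination = as.character(combination),
      constituents = as.character(constituents),
      why_topic = as.character(why_topic),
      why_concepts = as.character(why_concepts),
      quality_tags = as.character(quality_tags),
      caption = as.character(caption))
}

#' Validate an annotation against the schema
#'
#' Checks every typology invariant and returns a machine-readable report;
#' an empty report means the annotation is valid. Validation never throws
#' on content.
#'
#' @param a a [FigureAnnotation-class].
#' @param s a [TypologySchema-class].
#' @return data.frame with columns `code`, `detail`; zero rows when valid.
#'   Codes: unknown-code (any code not in the schema),
#'   single-multiplicity (Single iff exactly one chart instance),
#'   small-multiples-heterogeneous (Small Multiples must repeat one type),
#'   complex-constituents (Complex Combination must record exactly two
#'   non-Single constituent combinations; others must record none).
#' @export
validateAnnotation <- function(a, s) {
  stopifnot(is(a, "FigureAnnotation"), is(s, "TypologySchema"))
  v <- list()
  bad <- function(code, detail) v[[length(v) + 1L]] <<-
    data.frame(code = code, detail = detail, stringsAsFactors = FALSE)

  if (!(a@combination %in% s@combination_types))
    bad("unknown-code", sprintf("combination '%s'", a@combination))
  types <- vapply(a@chart_instances, function(ci) ci$type[1L], "")
  for (t in unique(types))
    if (!(t %in% s@chart_types$name))
      bad("unknown-code", sprintf("chart type '%s'", t))
  n <- length(a@chart_instances)
  if (identical(a@combination, "Single") && n != 1L)
    bad("single-multiplicity",
        sprintf("Single figure with %d chart instances", n))
  if (!identical(a@combination, "Single") && n == 1L &&
      a@combination %in% s@combination_types)
    bad("single-multiplicity",
        sprintf("one chart instance coded '%s'", a@combination))
  if (identical(a@combination, "Small Multiples") &&
      length(unique(types)) > 1L)
    bad("small-multiples-heterogeneous",
        paste("types:", paste(unique(types), collapse = ", ")))
  if (identical(a@combination, "Complex Combination")) {
    okc <- length(a@constituents) == 2L &&
      all(a@constituents %in% setdiff(s@combination_types,
                                      c("Single", "Complex Combination")))
    if (!okc)
      bad("complex-constituents",
          paste("constituents:", paste(a@constituents, collapse = ", ")))
  } else if (length(a@constituents)) {
    bad("complex-constituents",
        sprintf("'%s' must not record constituents", a@combination))
  }
  for (ci in a@chart_instances) {
    for (e in ci$enhancements) {
      if (!(e$mode %in% s@enhancement_modes))
        bad("unknown-code", sprintf("enhancement mode '%s'", e$mode))
      if (!(e$mark %in% s@mark_kinds))
        bad("unknown-code", sprintf("mark kind '%s'", e$mark))
      for (ae in e$aesthetics)
        if (!(ae %in% s@aesthetics))
          bad("unknown-code", sprintf("aesthetic '%s'", ae))
      if (!(e$structure %in% s@enhancement_structure))
        bad("unknown-code", sprintf("enhancement structure '%s'", e$structure))
    }
  }
  if (!length(v))
    return(data.frame(code = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Classify how charts combine into a figure
#'
#' Rule-based classification from a figure structure descriptor. Decision
#' order: one chart instance is Single; repetition of one chart type is
#' Small Multiples; spatially aligned multiple types form a Composite;
#' visually linked (but unaligned) multiple types are Many Types Linked;
#' otherwise Many Types General. When the linked-versus-general
#' distinction is flagged ambiguous the figure is classified Many Types
#' General. When two categories apply simultaneously (e.g. a small
#' multiple of a composite) the figure is a Complex Combination and the
#' two constituent categories are recorded.
#'
#' @param n_instances number of chart instances in the figure.
#' @param n_distinct_types number of distinct chart types.
#' @param spatially_aligned are different chart types spatially aligned?
#' @param visually_linked are charts visually linked (e.g. shared color
#'   scheme) without alignment?
#' @param repeated_same_type is some chart type repeated across instances?
#'   Defaults to `n_instances > 1 && n_distinct_types == 1`.
#' @param ambiguous_linkage is the linked-vs-general distinction
#'   ambiguous?
#' @return the combination-type code (character); for Complex Combination
#'   the attribute `constituents` holds the two constituent categories.
#' @examples
#' classifyCombination(2, 2, spatially_aligned = TRUE)  # "Composite"
#' @export
classifyCombination <- function(n_instances, n_distinct_types,
                                spatially_aligned = FALSE,
                                visually_linked = FALSE,
                                repeated_same_type = NULL,
                                ambiguous_linkage = FALSE) {
  n <- as.integer(n_instances); k <- as.integer(n_distinct_types)
  if (is.na(n) || n < 1L) .stopf("n_instances must be >= 1")
  if (is.na(k) || k < 1L || k > n)
    .stopf("contradictory descriptor: n_distinct_types must be in [1, n_instances]")
  if (is.null(repeated_same_type)) repeated_same_type <- n > 1L && k == 1L
  if (n == 1L) {
    if (spatially_aligned || visually_linked || repeated_same_type)
      .stopf("contradictory descriptor: a single chart instance cannot be aligned, linked or repeated")
    return("Single")
  }
  if (repeated_same_type && k == 1L && (spatially_aligned || visually_linked))
    .stopf("contradictory descriptor: alignment/linkage flags require multiple chart types")
  applicable <- character()
  if (repeated_same_type) applicable <- c(applicable, "Small Multiples")
  if (k >= 2L) {
    if (spatially_aligned) applicable <- c(applicable, "Composite")
    if (visually_linked && !ambiguous_linkage && !spatially_aligned)
      applicable <- c(applicable, "Many Types Linked")
    if ((!spatially_aligned && !visually_linked) ||
        (ambiguous_linkage && !spatially_aligned))
      applicable <- c(applicable, "Many Types General")
  }
  if (!length(applicable)) return("Many Types General")
  if (length(applicable) == 1L) return(applicable)
  structure("Complex Combination", constituents = applicable[1:2])
}

#' Classify an enhancement as structured or annotation
#'
#' A mark addition or re-encoding applied consistently across the base
#' chart is a structured enhancement; a one-off added mark (most commonly
#' an arrow to text) is an annotation. Ambiguous cases are resolved as
#' structured.
#'
#' @param applied_consistently is the enhancement applied consistently to
#'   the base chart type?
#' @param ambiguous is the structured-vs-annotation distinction ambiguous?
#' @return "structured" or "annotation".
#' @examples
#' classifyEnhancement(applied_consistently = FALSE)           # annotation
#' classifyEnhancement(applied_consistently = FALSE, ambiguous = TRUE)
#' @export
classifyEnhancement <- function(applied_consistently, ambiguous = FALSE) {
  if (isTRUE(ambiguous) || isTRUE(applied_consistently)) "structured"
  else "annotation"
}

## ---- annotation file I/O ------------------------------------------------

.annotation_to_record <- function(a) {
  list(figure_id = a@figure_id, doc_id = a@doc_id,
       combination = a@combination, constituents = I(a@constituents),
       chart_instances = lapply(a@chart_instances, function(ci)
         list(type = ci$type,
              enhancements = lapply(ci$enhancements, function(e)
                list(mode = e$mode, mark = e$mark,
                     aesthetics = I(e$aesthetics), structure = e$structure)))),
       why_topic = a@why_topic, why_concepts = I(a@why_concepts),
       quality_tags = I(a@quality_tags), caption = a@caption)
}

.record_to_annotation <- function(rec) {
  chr0 <- function(x) if (is.null(x)) character() else as.character(unlist(x))
  na1 <- function(x) if (is.null(x) || !length(x)) NA_character_
                     else as.character(x)[1L]
  FigureAnnotation(
    figure_id = rec$figure_id, doc_id = rec$doc_id,
    chart_instances = lapply(rec$chart_instances, function(ci)
      list(type = ci$type,
           enhancements = lapply(ci$enhancements %||% list(), function(e)
             list(mode = e$mode, mark = e$mark,
                  aesthetics = chr0(e$aesthetics), structure = e$structure)))),
    combination = rec$combination, constituents = chr0(rec$constituents),
    why_topic = na1(rec$why_topic), why_concepts = chr0(rec$why_concepts),
    quality_tags = chr0(rec$quality_tags), caption = na1(rec$caption))
}

#' Read and write figure-annotation files
#'
#' Annotations are stored as line-delimited records (one JSON object per
#' figure) and round-trip exactly.
#'
#' @param annotations list of [FigureAnnotation-class] objects.
#' @param path file path.
#' @return `writeAnnotations` returns `path` invisibly; `readAnnotations`
#'   a list of [FigureAnnotation-class] objects.
#' @export
writeAnnotations <- function(annotations, path) {
  .atomic_write(path, function(tmp)
    .write_ndjson(lapply(annotations, .annotation_to_record), tmp))
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  recs <- .read_ndjson(path, simplify = FALSE)
  lapply(recs, .record_to_annotation)
}
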