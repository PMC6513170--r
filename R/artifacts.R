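#' Write and read pipeline run artifacts
#'
#' Every pipeline product serializes to a plain-text format and round-trips
#' exactly: `readRunArtifact(writeRunArtifact(x, path))` reconstructs `x`.
#' A [DocumentCorpus-class] is written in the canonical line-delimited
#' record format (readable by [readCorpus()]); other artifacts are written
#' as a single tagged JSON document. Doubles are serialized at 17
#' significant digits so they survive the round trip bit-exactly. Writing
#' is atomic: on failure no partial file is left behind.
#'
#' @param obj a pipeline product: [DocumentCorpus-class],
#'   [TermMatrix-class], [BigramIndex-class], [Embedding-class],
#'   [SweepResult-class], [ClusterAssignment-class],
#'   [ConceptVocabulary-class], [ConceptMap-class], [ConceptLinks-class],
#'   [StrataSet-class], [SampleSet-class] or [DesignSpaceStats-class].
#' @param path destination file path.
#' @return `writeRunArtifact()` returns `path` invisibly;
#'   `readRunArtifact()` returns the reconstructed object.
#' @examples
#' co <- DocumentCorpus(c("a", "b"), c("t1", "t2"), c("x", "y"), 2019L)
#' f <- tempfile(fileext = ".ndjson")
#' writeRunArtifact(co, f)
#' identical(corpusDocs(readRunArtifact(f)), corpusDocs(co))
#' @export
setGeneric("writeRunArtifact", function(obj, path)
  standardGeneric("writeRunArtifact"))

.atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    .stopf("I/O error: cannot write to '%s'", path)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) .stopf("I/O error: cannot write to '%s'", path)
  ok <- TRUE
  invisible(path)
}

.write_artifact_json <- function(payload, path) {
  .atomic_write(path, function(tmp) {
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                                digits = NA),
               tmp, useBytes = TRUE)
  })
}

.sparse_to_triplets <- function(m) {
  tm <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  o <- order(tm@j, tm@i)
  list(i = tm@i[o] + 1L, j = tm@j[o] + 1L, x = tm@x[o])
}

.triplets_to_sparse <- function(tr, nrow, ncol) {
  Matrix::sparseMatrix(i = as.integer(tr$i), j = as.integer(tr$j),
                       x = as.numeric(tr$x), dims = c(nrow, ncol))
}

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "DocumentCorpus", function(obj, path) {
  d <- obj@docs
  recs <- c(list(list(`_type` = "corpus_header", artifact = "DocumentCorpus",
                      provenance = obj@provenance)),
            lapply(seq_len(nrow(d)), function(i)
              list(doc_id = d$doc_id[i], year = d$year[i], title = d$title[i],
                   abstract = d$abstract[i],
                   mesh_terms = I(d$mesh_terms[[i]]), flags = I(d$flags[[i]]))))
  .atomic_write(path, function(tmp) .write_ndjson(recs, tmp))
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "TermMatrix", function(obj, path) {
  cnt <- .sparse_to_triplets(obj@counts)
  tf <- .sparse_to_triplets(obj@tfidf)
  tf$x <- .num2chr(tf$x)
  .write_artifact_json(list(`_artifact` = "TermMatrix", doc_ids = I(obj@doc_ids),
                            terms = I(obj@terms), counts = lapply(cnt, I),
                            tfidf = lapply(tf, I)), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "BigramIndex", function(obj, path) {
  .write_artifact_json(list(`_artifact` = "BigramIndex", bigrams = I(obj@bigrams),
                            membership = lapply(obj@membership, I),
                            clusters = I(colnames(obj@cluster_df)),
                            cluster_df = I(as.integer(obj@cluster_df))), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "Embedding", function(obj, path) {
  .write_artifact_json(list(`_artifact` = "Embedding", doc_ids = I(obj@doc_ids),
                            x = I(.num2chr(obj@coords[, 1L])),
                            y = I(.num2chr(obj@coords[, 2L])),
                            perplexity = obj@perplexity, seed = obj@seed), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "SweepResult", function(obj, path) {
  .write_artifact_json(list(`_artifact` = "SweepResult", doc_ids = I(obj@doc_ids),
                            min_pts = I(obj@min_pts),
                            labels = I(as.integer(obj@labels))), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "ClusterAssignment", function(obj, path) {
  sw <- obj@sweep_labels
  .write_artifact_json(list(`_artifact` = "ClusterAssignment",
                            doc_ids = I(obj@doc_ids), final = I(obj@final),
                            topic_names = as.list(obj@topic_names),
                            provenance = as.list(obj@provenance),
                            sweep_min_pts = I(colnames(sw) %||% character()),
                            sweep_labels = I(as.integer(sw))), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "ConceptVocabulary", function(obj, path) {
  .write_artifact_json(list(`_artifact` = "ConceptVocabulary",
                            concept = I(obj@concepts$concept),
                            group = I(obj@concepts$group)), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "ConceptMap", function(obj, path) {
  .write_artifact_json(list(`_artifact` = "ConceptMap",
                            bigram = I(obj@entries$bigram),
                            concept = I(obj@entries$concept)), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "ConceptLinks", function(obj, path) {
  .write_artifact_json(list(`_artifact` = "ConceptLinks",
                            concepts = I(obj@concepts),
                            links = lapply(obj@links, I)), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "StrataSet", function(obj, path) {
  s <- obj@strata
  .write_artifact_json(list(`_artifact` = "StrataSet",
                            cluster = I(s$cluster), concept = I(s$concept),
                            doc_ids = lapply(s$doc_ids, I),
                            year_doc = I(names(obj@years)),
                            year_val = I(unname(obj@years))), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "SampleSet", function(obj, path) {
  s <- obj@selections
  .write_artifact_json(list(`_artifact` = "SampleSet", seed = obj@seed,
                            cluster = I(s$cluster), concept = I(s$concept),
                            doc_id = I(s$doc_id), round = I(s$round),
                            status = I(s$status), reason = I(s$reason)), path)
})

#' @rdname writeRunArtifact
setMethod("writeRunArtifact", "DesignSpaceStats", function(obj, path) {
  .write_artifact_json(list(`_artifact` = "DesignSpaceStats",
                            n_figures = obj@n_figures,
                            n_instances = obj@n_instances,
                            chart_type_instance_share = obj@chart_type_instance_share,
                            chart_type_presence = obj@chart_type_presence,
                            combination_distribution = obj@combination_distribution,
                            enhancement_rates = obj@enhancement_rates), path)
})

.df_from_json <- function(x) as.data.frame(x, stringsAsFactors = FALSE)

#' @rdname writeRunArtifact
#' @export
readRunArtifact <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  head_obj <- tryCatch(jsonlite::fromJSON(first), error = function(e)
    .stopf("format error in '%s': not a run artifact", path))
  if (identical(head_obj$`_type`, "corpus_header"))
    return(readCorpus(path, "record-lines", provenance = head_obj$provenance))
  p <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                          simplifyVector = TRUE, simplifyDataFrame = FALSE)
  kind <- p$`_artifact`
  chr <- function(x) {
    if (is.null(x)) return(character())
    if (is.list(x))
      return(vapply(x, function(v) if (is.null(v) || !length(v)) NA_character_
                    else as.character(v), "", USE.NAMES = FALSE))
    unname(as.character(x))
  }
  int <- function(x) {
    if (is.null(x)) return(integer())
    if (is.list(x))
      return(vapply(x, function(v) if (is.null(v) || !length(v)) NA_integer_
                    else as.integer(v), 1L, USE.NAMES = FALSE))
    unname(as.integer(x))
  }
  switch(kind,
    TermMatrix = {
      nd <- length(p$doc_ids); nt <- length(p$terms)
      cnt <- .triplets_to_sparse(list(i = int(p$counts$i), j = int(p$counts$j),
                                      x = as.numeric(int(p$counts$x))), nd, nt)
      tf <- .triplets_to_sparse(list(i = int(p$tfidf$i), j = int(p$tfidf$j),
                                     x = .chr2num(chr(p$tfidf$x))), nd, nt)
      dimnames(cnt) <- dimnames(tf) <- list(chr(p$doc_ids), chr(p$terms))
      new("TermMatrix", doc_ids = chr(p$doc_ids), terms = chr(p$terms),
          counts = cnt, tfidf = tf)
    },
    BigramIndex = {
      bg <- chr(p$bigrams)
      mem <- lapply(p$membership, function(v) chr(v))
      names(mem) <- bg
      df <- matrix(int(p$cluster_df), nrow = length(bg),
                   dimnames = list(bg, chr(p$clusters)))
      new("BigramIndex", bigrams = bg, membership = mem, cluster_df = df)
    },
    Embedding = new("Embedding", doc_ids = chr(p$doc_ids),
                    coords = cbind(.chr2num(chr(p$x)), .chr2num(chr(p$y))),
                    perplexity = as.numeric(p$perplexity),
                    seed = as.integer(p$seed)),
    SweepResult = {
      mp <- int(p$min_pts)
      lb <- matrix(int(p$labels), ncol = length(mp),
                   dimnames = list(NULL, as.character(mp)))
      new("SweepResult", doc_ids = chr(p$doc_ids), min_pts = mp, labels = lb)
    },
    ClusterAssignment = {
      mp <- chr(p$sweep_min_pts)
      sw <- matrix(int(p$sweep_labels), ncol = length(mp),
                   dimnames = if (length(mp)) list(NULL, mp) else NULL)
      if (!length(mp))
        sw <- matrix(integer(), nrow = length(p$doc_ids), ncol = 0L)
      new("ClusterAssignment", doc_ids = chr(p$doc_ids), final = chr(p$final),
          topic_names = unlist2chr(p$topic_names),
          provenance = unlist2chr(p$provenance), sweep_labels = sw)
    },
    ConceptVocabulary = ConceptVocabulary(chr(p$concept), chr(p$group)),
    ConceptMap = ConceptMap(chr(p$bigram), chr(p$concept)),
    ConceptLinks = {
      links <- lapply(p$links, function(v) chr(v))
      new("ConceptLinks", links = links, concepts = chr(p$concepts))
    },
    StrataSet = {
      s <- data.frame(cluster = chr(p$cluster), concept = chr(p$concept),
                      stringsAsFactors = FALSE)
      s$doc_ids <- lapply(p$doc_ids, function(v) chr(v))
      yrs <- int(p$year_val); names(yrs) <- chr(p$year_doc)
      new("StrataSet", strata = s, years = yrs)
    },
    SampleSet = new("SampleSet", seed = as.integer(p$seed),
                    selections = data.frame(cluster = chr(p$cluster),
                                            concept = chr(p$concept),
                                            doc_id = chr(p$doc_id),
                                            round = int(p$round),
                                            status = chr(p$status),
                                            reason = chr(p$reason),
                                            stringsAsFactors = FALSE)),
    DesignSpaceStats = new("DesignSpaceStats",
                           n_figures = as.integer(p$n_figures),
                           n_instances = as.integer(p$n_instances),
                           chart_type_instance_share =
                             .df_from_json(p$chart_type_instance_share),
                           chart_type_presence =
                             .df_from_json(p$chart_type_presence),
                           combination_distribution =
                             .df_from_json(p$combination_distribution),
                           enhancement_rates =
                             .df_from_json(p$enhancement_rates)),
    .stopf("format error in '%s': unknown artifact kind '%s'", path, kind))
}

unlist2chr <- function(x) {
  if (is.null(x) || !length(x)) return(character())
  out <- vapply(x, as.character, "")
  names(out) <- names(x)
  out
}
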