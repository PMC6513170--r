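#' Construct a DocumentCorpus
#'
#' @param doc_id character vector of unique document identifiers (e.g.
#'   PubMed IDs).
#' @param title,abstract character vectors (recycled NA allowed; missing
#'   values are kept as explicit `NA`).
#' @param year integer publication years; `NA` marks an explicitly missing
#'   year (such documents are excluded from year-constrained sampling).
#' @param mesh_terms list of character vectors of MeSH terms, one element
#'   per document.
#' @param flags list of character vectors of free-form markers (e.g.
#'   "manually-added").
#' @param provenance free-text description of the source queries.
#' @return a [DocumentCorpus-class] object.
#' @examples
#' DocumentCorpus(doc_id = c("p1", "p2"), title = c("A", "B"),
#'                abstract = c("first text", "second text"),
#'                year = c(2015L, NA))
#' @export
DocumentCorpus <- function(doc_id = character(), title = character(),
                           abstract = character(), year = NA_integer_,
                           mesh_terms = NULL, flags = NULL,
                           provenance = "") {
  n <- length(doc_id)
  blank2na <- function(x) {
    x <- rep_len(as.character(x), max(n, 0L))[seq_len(n)]
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    x
  }
  docs <- data.frame(doc_id = as.character(doc_id),
                     year = rep_len(suppressWarnings(as.integer(year)), n),
                     title = blank2na(title),
                     abstract = blank2na(abstract),
                     stringsAsFactors = FALSE)
  if (n == 0L) {
    docs <- data.frame(doc_id = character(), year = integer(),
                       title = character(), abstract = character())
  }
  docs$mesh_terms <- if (is.null(mesh_terms)) rep(list(character()), n)
                     else mesh_terms
  docs$flags <- if (is.null(flags)) rep(list(character()), n) else flags
  new("DocumentCorpus", docs = docs, provenance = as.character(provenance))
}

#' The published literature-search query strings
#'
#' The two PubMed queries whose combined, de-duplicated results formed the
#' original infectious-disease genomic-epidemiology corpus. Shipped as
#' documented constants only: the package performs no live querying.
#'
#' @return character vector of length two.
#' @examples
#' pubmedQueries()
#' @export
pubmedQueries <- function() {
  c(q1 = "(genome AND (outbreak OR pandemic OR epidemic) OR 'genomic epidemiology'",
    q2 = "(genomic epidemiology OR molecular epidemiology) AND (bacteri* OR vir* OR pathogen) AND Genome")
}

.as_chr_vec <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) character()
  else as.character(unlist(x, use.names = FALSE))
}

.canon_record <- function(rec, where, quiet = FALSE) {
  for (f in c("doc_id", "title", "abstract")) {
    v <- as.character(rec[[f]])[1L]
    if (is.null(rec[[f]]) || is.na(v) || !nzchar(trimws(v))) {
      if (f == "doc_id")
        .stopf("format error at %s: required field 'doc_id' missing", where)
      if (!quiet)
        .warnf("%s: field '%s' missing for document '%s'; marked missing",
               where, f, rec$doc_id)
      rec[[f]] <- NA_character_
    }
  }
  yr <- suppressWarnings(as.integer(rec$year))
  list(doc_id = as.character(rec$doc_id)[1L],
       year = if (length(yr)) yr[1L] else NA_integer_,
       title = as.character(rec$title)[1L],
       abstract = as.character(rec$abstract)[1L],
       mesh_terms = .as_chr_vec(rec$mesh_terms),
       flags = .as_chr_vec(rec$flags))
}

.records_to_corpus <- function(recs, provenance) {
  ids <- vapply(recs, `[[`, "", "doc_id")
  if (anyDuplicated(ids))
    .stopf("integrity error: duplicate doc_id within one file: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  DocumentCorpus(doc_id = ids,
                 title = vapply(recs, `[[`, "", "title"),
                 abstract = vapply(recs, `[[`, "", "abstract"),
                 year = vapply(recs, `[[`, NA_integer_, "year"),
                 mesh_terms = lapply(recs, `[[`, "mesh_terms"),
                 flags = lapply(recs, `[[`, "flags"),
                 provenance = provenance)
}

.read_record_lines <- function(path) {
  recs <- .read_ndjson(path)
  is_meta <- vapply(recs, function(r) !is.null(r$`_type`), TRUE)
  ## canonical files written by the package carry a header record; their
  ## missing markers are deliberate, so reading them back stays silent
  quiet <- any(is_meta)
  recs <- recs[!is_meta]
  lapply(seq_along(recs), function(i)
    .canon_record(recs[[i]], sprintf("%s line %d", basename(path), i),
                  quiet = quiet))
}

.read_delimited <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character")
  if (!all(c("doc_id", "title", "abstract") %in% names(tab)))
    .stopf("format error in '%s': header must name doc_id, title, abstract",
           basename(path))
  lapply(seq_len(nrow(tab)), function(i) {
    rec <- as.list(tab[i, , drop = FALSE])
    if (!is.null(rec$mesh_terms))
      rec$mesh_terms <- strsplit(rec$mesh_terms[[1L]], ";", fixed = TRUE)[[1L]]
    if (!is.null(rec$flags))
      rec$flags <- strsplit(rec$flags[[1L]], ";", fixed = TRUE)[[1L]]
    .canon_record(rec, sprintf("%s row %d", basename(path), i))
  })
}

## Standard PubMed MEDLINE flat-file tags; continuation lines start with
## six spaces.
.read_medline <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  recs <- list(); cur <- NULL; tag <- ""
  flush_rec <- function(cur) {
    if (is.null(cur)) return(NULL)
    yr <- NA_integer_
    if (!is.null(cur$DP)) {
      m <- regmatches(cur$DP[1L], regexpr("\\d{4}", cur$DP[1L]))
      if (length(m)) yr <- as.integer(m)
    }
    list(doc_id = cur$PMID[1L], year = yr,
         title = if (is.null(cur$TI)) NA_character_ else paste(cur$TI, collapse = " "),
         abstract = if (is.null(cur$AB)) NA_character_ else paste(cur$AB, collapse = " "),
         mesh_terms = if (is.null(cur$MH)) character() else cur$MH,
         flags = character())
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^ {6}", ln)) {                 # continuation of previous tag
      if (!is.null(cur) && nzchar(tag)) {
        k <- length(cur[[tag]])
        cur[[tag]][k] <- paste(cur[[tag]][k], trimws(ln))
      }
      next
    }
    if (!grepl("^[A-Z0-9]{1,4} *- ", ln))
      .stopf("format error in '%s': unparseable MEDLINE line: %s",
             basename(path), ln)
    tag <- trimws(sub("^([A-Z0-9]{1,4}) *- .*$", "\\1", ln))
    val <- sub("^[A-Z0-9]{1,4} *- ", "", ln)
    if (tag == "PMID") {
      r <- flush_rec(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- list()
    }
    if (!is.null(cur)) cur[[tag]] <- c(cur[[tag]], val)
  }
  r <- flush_rec(cur)
  if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  lapply(seq_along(recs), function(i)
    .canon_record(recs[[i]], sprintf("%s record %d", basename(path), i)))
}

#' Read a document corpus from disk
#'
#' The canonical corpus format is line-delimited records (one JSON object
#' per line with fields `doc_id`, `year`, `title`, `abstract`,
#' `mesh_terms`, `flags`). A delimited table (comma or tab, auto-detected
#' from the header line) and PubMed MEDLINE flat files (tags PMID, DP, TI,
#' AB, MH) are convenience readers mapped onto it.
#'
#' @param path path to the corpus file.
#' @param format one of "record-lines", "delimited-table", "medline".
#' @param provenance optional free-text provenance; defaults to the file
#'   name.
#' @return a [DocumentCorpus-class] preserving input order. Missing optional
#'   fields are kept as explicit `NA` (with a warning for missing
#'   title/abstract); duplicate `doc_id` within one file is an integrity
#'   error.
#' @seealso [mergeCorpora()], [writeRunArtifact()]
#' @export
readCorpus <- function(path,
                       format = c("record-lines", "delimited-table", "medline"),
                       provenance = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  recs <- switch(format,
                 "record-lines" = .read_record_lines(path),
                 "delimited-table" = .read_delimited(path),
                 "medline" = .read_medline(path))
  .records_to_corpus(recs, provenance %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge two corpora, retaining only unique records
#'
#' Union keyed by `doc_id`; on a shared id the first occurrence wins (a
#' conflicting title triggers a warning).
#'
#' @param a,b [DocumentCorpus-class] objects.
#' @return merged [DocumentCorpus-class] of size `|ids(a) u ids(b)|`.
#' @examples
#' a <- DocumentCorpus("p1", "t1", "a1", 2014L)
#' b <- DocumentCorpus(c("p1", "p2"), c("t1", "t2"), c("a1", "a2"), 2015L)
#' nDocs(mergeCorpora(a, b))  # 2
#' @export
mergeCorpora <- function(a, b) {
  stopifnot(is(a, "DocumentCorpus"), is(b, "DocumentCorpus"))
  dup <- intersect(docIds(b), docIds(a))
  if (length(dup)) {
    ta <- a@docs$title[match(dup, a@docs$doc_id)]
    tb <- b@docs$title[match(dup, b@docs$doc_id)]
    bad <- dup[!is.na(ta) & !is.na(tb) & ta != tb]
    if (length(bad))
      .warnf("conflicting titles for shared doc_id (first occurrence kept): %s",
             paste(bad, collapse = ", "))
  }
  keep <- !(docIds(b) %in% docIds(a))
  docs <- rbind(a@docs, b@docs[keep, , drop = FALSE])
  rownames(docs) <- NULL
  prov <- paste(unique(c(a@provenance, b@provenance)), collapse = " + ")
  new("DocumentCorpus", docs = docs, provenance = prov)
}
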