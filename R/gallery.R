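## Static gallery export: one machine-readable index (line-delimited
## records) plus standalone hypertext pages with client-side facet
## filtering. No server, no network assets; rebuilding from the same
## inputs is byte-identical.

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.fig_slug <- function(id) gsub("[^A-Za-z0-9_-]", "_", id)

.source_link <- function(doc_id) {
  if (grepl("^[0-9]+$", doc_id))
    sprintf("https://pubmed.ncbi.nlm.nih.gov/%s/", doc_id)
  else doc_id
}

#' Export a browsable static gallery of the design space
#'
#' Emits a machine-readable index (`index.ndjson`, one record per figure
#' with all typology codes and tags, sorted by figure id) and static pages:
#' `index.html` with facet filters over topic, concept, chart type,
#' combination and enhancement mode, plus one page per figure showing its
#' typology decomposition and a link back to the source publication.
#' Missing image assets degrade to metadata-only cards. Deterministic:
#' rebuilding from the same inputs is byte-identical.
#'
#' @param annotations list of [FigureAnnotation-class] objects (duplicate
#'   figure ids are an error).
#' @param stats the matching [DesignSpaceStats-class] (shown on the index
#'   page).
#' @param figure_assets optional named character vector figure_id -> image
#'   path (copied as-is into page references).
#' @param out_dir writable output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
exportGallery <- function(annotations, stats, figure_assets = NULL,
                          out_dir) {
  ids <- vapply(annotations, function(a) a@figure_id, "")
  if (anyDuplicated(ids))
    .stopf("duplicate figure_id: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  annotations <- annotations[order(ids)]
  ids <- sort(ids)

  recs <- lapply(annotations, function(a) {
    r <- .annotation_to_record(a)
    r$asset <- if (!is.null(figure_assets) && a@figure_id %in%
                   names(figure_assets))
      unname(figure_assets[[a@figure_id]]) else NULL
    r
  })
  index_path <- file.path(out_dir, "index.ndjson")
  .write_ndjson(recs, index_path)

  card <- function(a) {
    types <- unique(vapply(a@chart_instances, function(ci) ci$type[1L], ""))
    modes <- unique(unlist(lapply(a@chart_instances, function(ci)
      vapply(ci$enhancements, function(e) e$mode, "")), use.names = FALSE))
    sprintf(paste0(
      '<div class="card" data-topic="%s" data-concepts="%s"',
      ' data-types="%s" data-combination="%s" data-modes="%s">',
      '<a href="fig_%s.html">%s</a><br/><small>%s | %s</small></div>'),
      .html_escape(ifelse(is.na(a@why_topic), "", a@why_topic)),
      .html_escape(paste(a@why_concepts, collapse = ";")),
      .html_escape(paste(types, collapse = ";")),
      .html_escape(a@combination),
      .html_escape(paste(modes, collapse = ";")),
      .fig_slug(a@figure_id), .html_escape(a@figure_id),
      .html_escape(a@combination), .html_escape(paste(types, collapse = ", ")))
  }
  facet_values <- function(get) {
    sort(unique(unlist(lapply(annotations, get), use.names = FALSE)))
  }
  facet_block <- function(attr, label, values) {
    if (!length(values)) return("")
    opts <- paste(sprintf('<option value="%s">%s</option>',
                          .html_escape(values), .html_escape(values)),
                  collapse = "")
    sprintf('<label>%s <select data-facet="%s"><option value="">all</option>%s</select></label>',
            label, attr, opts)
  }
  comb <- stats@combination_distribution
  stats_rows <- paste(sprintf("<tr><td>%s</td><td>%d</td><td>%.1f%%</td></tr>",
                              .html_escape(comb$combination), comb$n,
                              comb$pct), collapse = "\n")
  js <- paste(
    "document.querySelectorAll('select[data-facet]').forEach(function(s){",
    "s.addEventListener('change', function(){",
    "var want={};document.querySelectorAll('select[data-facet]').forEach(function(q){want[q.dataset.facet]=q.value;});",
    "document.querySelectorAll('.card').forEach(function(c){",
    "var show=true;for(var f in want){if(!want[f])continue;",
    "var hay=(c.dataset[f]||'').split(';');if(hay.indexOf(want[f])<0)show=false;}",
    "c.style.display=show?'':'none';});});});", sep = "\n")
  index_html <- paste(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'/><title>Design-space gallery</title>",
    "<style>.card{border:1px solid #ccc;margin:4px;padding:6px;display:inline-block;width:240px}</style>",
    "</head><body>",
    "<h1>Visualization design-space gallery</h1>",
    sprintf("<p>%d figures, %d chart instances.</p>",
            stats@n_figures, stats@n_instances),
    "<table border='1'><tr><th>combination</th><th>n</th><th>share</th></tr>",
    stats_rows, "</table>",
    "<p>",
    facet_block("topic", "Topic",
                facet_values(function(a) a@why_topic[!is.na(a@why_topic)])),
    facet_block("concepts", "Concept",
                facet_values(function(a) a@why_concepts)),
    facet_block("types", "Chart type",
                facet_values(function(a)
                  vapply(a@chart_instances, function(ci) ci$type[1L], ""))),
    facet_block("combination", "Combination",
                facet_values(function(a) a@combination)),
    facet_block("modes", "Enhancement",
                facet_values(function(a)
                  unlist(lapply(a@chart_instances, function(ci)
                    vapply(ci$enhancements, function(e) e$mode, ""))))),
    "</p><div id='cards'>",
    paste(vapply(annotations, card, ""), collapse = "\n"),
    "</div><script>", js, "</script></body></html>", sep = "\n")
  index_html_path <- file.path(out_dir, "index.html")
  writeLines(index_html, index_html_path, useBytes = TRUE)

  fig_paths <- character()
  for (a in annotations) {
    asset <- if (!is.null(figure_assets) && a@figure_id %in%
                 names(figure_assets))
      sprintf('<img src="%s" alt="%s"/>',
              .html_escape(unname(figure_assets[[a@figure_id]])),
              .html_escape(a@figure_id))
    else "<p><em>No image asset; metadata-only card.</em></p>"
    inst_rows <- vapply(seq_along(a@chart_instances), function(i) {
      ci <- a@chart_instances[[i]]
      enh <- if (length(ci$enhancements))
        paste(vapply(ci$enhancements, function(e)
          sprintf("%s %s [%s] (%s)", e$mode, e$mark,
                  paste(e$aesthetics, collapse = ","), e$structure), ""),
          collapse = "; ")
      else "none"
      sprintf("<tr><td>%d</td><td>%s</td><td>%s</td></tr>", i,
              .html_escape(ci$type), .html_escape(enh))
    }, "")
    page <- paste(
      "<!DOCTYPE html>",
      sprintf("<html><head><meta charset='utf-8'/><title>%s</title></head><body>",
              .html_escape(a@figure_id)),
      sprintf("<h1>%s</h1>", .html_escape(a@figure_id)), asset,
      sprintf("<p>Combination: <b>%s</b>%s</p>", .html_escape(a@combination),
              if (length(a@constituents))
                sprintf(" (constituents: %s)",
                        .html_escape(paste(a@constituents, collapse = " + ")))
              else ""),
      sprintf("<p>Why: topic <b>%s</b>; concepts: %s</p>",
              .html_escape(ifelse(is.na(a@why_topic), "-", a@why_topic)),
              .html_escape(paste(a@why_concepts, collapse = ", "))),
      if (length(a@quality_tags))
        sprintf("<p>Quality tags: %s</p>",
                .html_escape(paste(a@quality_tags, collapse = ", ")))
      else "",
      "<table border='1'><tr><th>#</th><th>chart type</th><th>enhancements</th></tr>",
      paste(inst_rows, collapse = "\n"), "</table>",
      sprintf('<p><a href="%s">Source publication (%s)</a></p>',
              .html_escape(.source_link(a@doc_id)), .html_escape(a@doc_id)),
      if (!is.na(a@caption))
        sprintf("<blockquote>%s</blockquote>", .html_escape(a@caption))
      else "",
      '<p><a href="index.html">Back to gallery</a></p>',
      "</body></html>", sep = "\n")
    p <- file.path(out_dir, sprintf("fig_%s.html", .fig_slug(a@figure_id)))
    writeLines(page, p, useBytes = TRUE)
    fig_paths <- c(fig_paths, p)
  }
  invisible(c(index_path, index_html_path, fig_paths))
}
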