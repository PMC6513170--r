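#' Descriptive statistics over an annotation corpus
#'
#' The how-axis summary of a design space: chart-type frequencies,
#' combination distribution and enhancement rates. Two denominators are
#' deliberately distinguished and both counts and percentages are emitted
#' so either reading can be audited: instance share is computed over all
#' chart-type instances across figures, presence over figures (so a class
#' may be present in more figures than any single member type's instance
#' share suggests), and enhancement rates over chart instances.
#'
#' @param annotations non-empty list of valid [FigureAnnotation-class]
#'   objects.
#' @param s a [TypologySchema-class]; invalid annotations are an error.
#' @return a [DesignSpaceStats-class].
#' @export
computeStats <- function(annotations, s) {
  if (!length(annotations)) .stopf("empty annotation set")
  stopifnot(is(s, "TypologySchema"))
  for (a in annotations) {
    rep <- validateAnnotation(a, s)
    if (nrow(rep))
      .stopf("invalid annotation '%s': %s", a@figure_id,
             paste(sprintf("%s (%s)", rep$code, rep$detail), collapse = "; "))
  }
  n_fig <- length(annotations)
  inst_types <- lapply(annotations, function(a)
    vapply(a@chart_instances, function(ci) ci$type[1L], ""))
  all_inst <- unlist(inst_types, use.names = FALSE)
  n_inst <- length(all_inst)

  tab <- table(all_inst)
  share <- data.frame(type = names(tab), n = as.integer(tab),
                      pct = 100 * as.integer(tab) / n_inst,
                      stringsAsFactors = FALSE)
  share <- share[order(-share$n, share$type), , drop = FALSE]
  rownames(share) <- NULL

  cls <- structure(s@chart_types$class, names = s@chart_types$name)
  pres_rows <- list()
  for (t in sort(unique(all_inst))) {
    nf <- sum(vapply(inst_types, function(v) t %in% v, TRUE))
    pres_rows[[length(pres_rows) + 1L]] <-
      data.frame(level = "type", name = t, n = nf, pct = 100 * nf / n_fig,
                 stringsAsFactors = FALSE)
  }
  for (cl in sort(unique(unname(cls[unique(all_inst)])))) {
    member <- names(cls)[cls == cl]
    nf <- sum(vapply(inst_types, function(v) any(v %in% member), TRUE))
    pres_rows[[length(pres_rows) + 1L]] <-
      data.frame(level = "class", name = cl, n = nf, pct = 100 * nf / n_fig,
                 stringsAsFactors = FALSE)
  }
  presence <- do.call(rbind, pres_rows)
  rownames(presence) <- NULL

  comb <- vapply(annotations, function(a) a@combination, "")
  ctab <- table(factor(comb, levels = s@combination_types))
  comb_df <- data.frame(combination = names(ctab), n = as.integer(ctab),
                        pct = 100 * as.integer(ctab) / n_fig,
                        stringsAsFactors = FALSE)

  enh <- lapply(annotations, function(a) lapply(a@chart_instances,
                                                function(ci) ci$enhancements))
  enh <- unlist(enh, recursive = FALSE, use.names = FALSE)
  has <- function(pred) sum(vapply(enh, function(es)
    length(es) > 0L && any(vapply(es, pred, TRUE)), TRUE))
  n_any <- sum(vapply(enh, function(es) length(es) > 0L, TRUE))
  n_add <- has(function(e) identical(e$mode, "add-marks"))
  n_re <- has(function(e) identical(e$mode, "re-encode-marks"))
  n_ann <- has(function(e) identical(e$structure, "annotation"))
  rates <- data.frame(
    measure = c("any-enhancement", "add-marks", "re-encode-marks",
                "annotation"),
    n = c(n_any, n_add, n_re, n_ann),
    pct = 100 * c(n_any, n_add, n_re, n_ann) / n_inst,
    stringsAsFactors = FALSE)

  new("DesignSpaceStats", n_figures = n_fig, n_instances = n_inst,
      chart_type_instance_share = share, chart_type_presence = presence,
      combination_distribution = comb_df, enhancement_rates = rates)
}

#' Cross-tabulate the why and how axes
#'
#' Contingency counts of annotations by a why-axis variable (topic cluster
#' or a priori concept) against a how-axis variable (chart type or
#' combination). An annotation carrying several concepts (or several chart
#' types) counts once per pair. Annotations lacking the requested why-tag
#' are excluded with a warning, and the number excluded is reported as an
#' attribute.
#'
#' @param annotations list of [FigureAnnotation-class] objects.
#' @param axis_why "topic" or "concept".
#' @param axis_how "chart_type" or "combination".
#' @return an integer matrix (why levels x how levels) with
#'   `attr(, "n_excluded")`.
#' @export
crosstabWhyHow <- function(annotations, axis_why = c("topic", "concept"),
                           axis_how = c("chart_type", "combination")) {
  axis_why <- match.arg(axis_why)
  axis_how <- match.arg(axis_how)
  why_of <- function(a) {
    v <- if (axis_why == "topic") a@why_topic else a@why_concepts
    v[!is.na(v)]
  }
  how_of <- function(a) {
    if (axis_how == "combination") a@combination
    else unique(vapply(a@chart_instances, function(ci) ci$type[1L], ""))
  }
  tagged <- vapply(annotations, function(a) length(why_of(a)) > 0L, TRUE)
  if (any(!tagged))
    .warnf("%d annotation(s) lack %s tags and were excluded",
           sum(!tagged), axis_why)
  pairs_w <- character(); pairs_h <- character()
  for (a in annotations[tagged]) {
    w <- why_of(a); h <- how_of(a)
    grid <- expand.grid(w = w, h = h, stringsAsFactors = FALSE)
    pairs_w <- c(pairs_w, grid$w)
    pairs_h <- c(pairs_h, grid$h)
  }
  tab <- table(why = pairs_w, how = pairs_h)
  out <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  attr(out, "n_excluded") <- sum(!tagged)
  out
}
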