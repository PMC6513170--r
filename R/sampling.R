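#' Controlled rejection-reason codes
#'
#' The standard reasons a sampled article is rejected during the manual
#' screen; most articles are rejected because they contain no figures.
#' Free-text reasons are also accepted by the event log.
#'
#' @return character vector of codes.
#' @export
rejectionReasons <- function() {
  c("no-figures", "no-full-text", "not-English", "technique-only",
    "no-human-data", "review")
}

#' Build sampling strata over (cluster x concept) cells
#'
#' One stratum per (retained cluster, concept) pair with at least one
#' eligible document; a document is eligible when it carries both the
#' cluster label and the concept tag. Empty pairs are omitted (logged via
#' message). Documents carrying several concepts are eligible for several
#' strata.
#'
#' @param assignment a (typically simplified) [ClusterAssignment-class].
#' @param links a [ConceptLinks-class] sharing document ids.
#' @param corpus optional [DocumentCorpus-class]; when supplied,
#'   publication years are recorded so that year-constrained sampling
#'   rounds can filter eligibility.
#' @return a [StrataSet-class].
#' @export
buildStrata <- function(assignment, links, corpus = NULL) {
  stopifnot(is(assignment, "ClusterAssignment"), is(links, "ConceptLinks"))
  lab <- finalLabels(assignment)
  ll <- conceptLinksList(links)
  common <- intersect(names(lab), names(ll))
  clusters <- sort(clusterIds(assignment))
  concepts <- sort(unique(unlist(ll, use.names = FALSE)))
  rows <- list()
  n_empty <- 0L
  for (cl in clusters) {
    members <- common[lab[common] == cl]
    for (cc in concepts) {
      elig <- members[vapply(ll[members], function(v) cc %in% v, TRUE)]
      if (length(elig)) {
        rows[[length(rows) + 1L]] <-
          list(cluster = cl, concept = cc, doc_ids = elig)
      } else n_empty <- n_empty + 1L
    }
  }
  if (n_empty)
    message(sprintf("buildStrata: %d empty (cluster x concept) pairs omitted",
                    n_empty))
  strata <- data.frame(
    cluster = vapply(rows, `[[`, "", "cluster"),
    concept = vapply(rows, `[[`, "", "concept"),
    stringsAsFactors = FALSE)
  strata$doc_ids <- lapply(rows, `[[`, "doc_ids")
  years <- integer()
  if (!is.null(corpus)) {
    d <- corpusDocs(corpus)
    years <- structure(d$year, names = d$doc_id)
  }
  new("StrataSet", strata = strata, years = years)
}

#' Draw one document per stratum
#'
#' A uniform draw of one eligible document per stratum, deterministic for a
#' fixed seed. With `min_year` set, documents with an older or missing
#' publication year are ineligible; a stratum emptied by the filter is
#' skipped with a warning. A document eligible in several strata may be
#' drawn for each (reported via message).
#'
#' @param strata a [StrataSet-class].
#' @param seed integer RNG seed.
#' @param min_year optional minimum publication year (e.g. 2011 for a
#'   figure-oriented second round).
#' @param round round number recorded in the event log (default 1).
#' @return a [SampleSet-class] whose selections have status "pending",
#'   awaiting the human accept/reject decision.
#' @export
drawSample <- function(strata, seed, min_year = NULL, round = 1L) {
  stopifnot(is(strata, "StrataSet"))
  s <- strataTable(strata)
  if (!nrow(s)) .stopf("strata must be non-empty")
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(s))) {
      elig <- s$doc_ids[[i]]
      if (!is.null(min_year)) {
        if (!length(strata@years))
          .stopf("min_year filtering requires strata built with a corpus")
        yr <- strata@years[elig]
        elig <- elig[!is.na(yr) & yr >= min_year]
      }
      if (!length(elig)) {
        .warnf("stratum (%s, %s) emptied by the year filter; skipped",
               s$cluster[i], s$concept[i])
        next
      }
      pick <- elig[[sample.int(length(elig), 1L)]]
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = s$cluster[i], concept = s$concept[i],
                   doc_id = pick, round = as.integer(round),
                   status = "pending", reason = NA_character_,
                   stringsAsFactors = FALSE)
    }
    sel <- if (length(rows)) do.call(rbind, rows)
           else data.frame(cluster = character(), concept = character(),
                           doc_id = character(), round = integer(),
                           status = character(), reason = character(),
                           stringsAsFactors = FALSE)
    dup <- unique(sel$doc_id[duplicated(sel$doc_id)])
    if (length(dup))
      message(sprintf("drawSample: drawn for multiple strata: %s",
                      paste(dup, collapse = ", ")))
    new("SampleSet", selections = sel, seed = as.integer(seed))
  })
}

#' Record the human decision on a selection
#'
#' @param sample a [SampleSet-class].
#' @param doc_id the selected document.
#' @param status "accepted" or "rejected".
#' @param reason rejection reason (controlled code from
#'   [rejectionReasons()] or free text); required when rejecting.
#' @return the updated [SampleSet-class].
#' @export
decideSelection <- function(sample, doc_id, status = c("accepted", "rejected"),
                            reason = NA_character_) {
  stopifnot(is(sample, "SampleSet"))
  status <- match.arg(status)
  if (status == "rejected" && is.na(reason))
    .stopf("a rejection requires a reason")
  sel <- selections(sample)
  idx <- which(sel$doc_id == doc_id & sel$status %in% c("pending", "candidate"))
  if (!length(idx)) .stopf("no pending selection for document '%s'", doc_id)
  sel$status[idx[1L]] <- status
  sel$reason[idx[1L]] <- reason
  methods::initialize(sample, selections = sel)
}

#' Resample replacement candidates after a rejection
#'
#' For a rejected article, `k` distinct replacement candidates are drawn
#' uniformly without replacement from the stratum's remaining eligible
#' documents (all previously drawn documents excluded); fewer are returned
#' with a warning when the stratum is nearly exhausted, and an empty draw
#' marks the stratum unfillable. The caller then accepts one candidate via
#' [decideSelection()].
#'
#' @param sample a [SampleSet-class] in which `rejected_doc` has been
#'   marked rejected (see [decideSelection()]).
#' @param strata the [StrataSet-class] the sample was drawn from.
#' @param cluster,concept the stratum of the rejected selection.
#' @param rejected_doc the rejected document id.
#' @param k number of replacement candidates (default 2).
#' @param seed integer RNG seed for the candidate draw.
#' @param min_year optional minimum publication year, as in [drawSample()].
#' @return list with `sample` (updated event log, candidates appended with
#'   status "candidate") and `candidates` (character vector, possibly
#'   shorter than `k`).
#' @export
resampleAfterRejection <- function(sample, strata, cluster, concept,
                                   rejected_doc, k = 2L, seed,
                                   min_year = NULL) {
  stopifnot(is(sample, "SampleSet"), is(strata, "StrataSet"))
  sel <- selections(sample)
  hit <- sel$cluster == cluster & sel$concept == concept &
    sel$doc_id == rejected_doc
  if (!any(hit))
    .stopf("document '%s' was not a selection of stratum (%s, %s)",
           rejected_doc, cluster, concept)
  if (!any(sel$status[hit] == "rejected"))
    .stopf("document '%s' must be marked rejected before resampling",
           rejected_doc)
  s <- strataTable(strata)
  row <- which(s$cluster == cluster & s$concept == concept)
  if (!length(row)) .stopf("unknown stratum (%s, %s)", cluster, concept)
  drawn <- sel$doc_id[sel$cluster == cluster & sel$concept == concept]
  elig <- setdiff(s$doc_ids[[row]], drawn)
  if (!is.null(min_year) && length(elig)) {
    yr <- strata@years[elig]
    elig <- elig[!is.na(yr) & yr >= min_year]
  }
  round_no <- max(sel$round[hit])
  if (!length(elig)) {
    .warnf("stratum (%s, %s) unfillable: no remaining eligible documents",
           cluster, concept)
    return(list(sample = sample, candidates = character()))
  }
  if (length(elig) < k)
    .warnf("stratum (%s, %s) nearly exhausted: only %d candidate(s)",
           cluster, concept, length(elig))
  cand <- withSeed(seed, {
    elig[sample.int(length(elig), min(k, length(elig)))]
  })
  add <- data.frame(cluster = cluster, concept = concept, doc_id = cand,
                    round = round_no, status = "candidate",
                    reason = NA_character_, stringsAsFactors = FALSE)
  list(sample = methods::initialize(sample,
                                    selections = rbind(sel, add)),
       candidates = cand)
}

#' Priority order of strata by concept under-representation
#'
#' Later sampling rounds attempt to boost a priori concepts with few
#' accepted documents so far: strata whose concept has fewer accepted
#' round-1 documents than the median concept come first. Exposed as an
#' ordering, not a hard constraint.
#'
#' @param strata a [StrataSet-class].
#' @param sample the previous round's [SampleSet-class].
#' @return integer permutation of the stratum rows (most underrepresented
#'   concepts first, ties in original order).
#' @export
orderStrataByConceptDeficit <- function(strata, sample) {
  s <- strataTable(strata)
  sel <- selections(sample)
  acc <- sel[sel$status == "accepted", , drop = FALSE]
  counts <- table(factor(acc$concept, levels = sort(unique(s$concept))))
  order(as.integer(counts[s$concept]), seq_len(nrow(s)))
}
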