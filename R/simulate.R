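## Synthetic-data generators with planted ground truth. Documents are
## pseudo-word token streams from a two-component mixture (per-topic
## multinomial + shared background); concept-linked bigrams are planted
## with exact within-cluster counts and cross-cluster spread. The point is
## statistical structure (term-distinct topics, concept-linked bigrams,
## known category frequencies), not real English prose.

## deterministic pseudo-word pool: consonant-vowel syllables, filtered so
## that words are >= 6 chars, stop-word free and have unique Porter stems
.word_pool <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  words <- character(0)
  k <- length(syl)
  i <- 0L
  while (length(words) < n + 50L) {
    i <- i + 1L
    ## stride through the syllable cube so consecutive words differ in
    ## every syllable (7919 is coprime to k^3)
    j <- (i * 7919) %% (k^3)
    a <- j %% k + 1L
    b <- (j %/% k) %% k + 1L
    cc <- (j %/% (k * k)) %% k + 1L
    words <- c(words, paste0(syl[a], syl[b], syl[cc]))
    if (i > k^3) break
  }
  words <- setdiff(unique(words), defaultStopwords())
  stems <- porterStem(words)
  words <- words[!duplicated(stems)]
  if (length(words) < n) .stopf("word pool exhausted (need %d)", n)
  words[seq_len(n)]
}

#' Specify a synthetic corpus with planted structure
#'
#' The stated world of the generator: K term-distinct topics with disjoint
#' vocabularies over a shared background, a fraction of pure-background
#' noise documents, and optional planted concept-linked bigrams with exact
#' within-topic counts and cross-topic spread.
#'
#' @param n_topics number of planted topics K (default 5).
#' @param docs_per_topic documents per topic (default 200).
#' @param topic_vocab_size per-topic vocabulary size, disjoint across
#'   topics (default 30).
#' @param background_vocab_size shared background vocabulary size
#'   (default 120).
#' @param topic_weight probability that a token of a topic document is
#'   drawn from its topic vocabulary rather than the background
#'   (default 0.7).
#' @param doc_length_mean mean abstract length in tokens, geometric spread
#'   (default 120).
#' @param noise_doc_fraction noise documents (pure background) as a
#'   fraction of the topic documents (default 0.10).
#' @param planted_bigrams optional data.frame with columns `bigram` (two
#'   pool words, space-separated; auto-generated when NA), `concept`,
#'   `topic` (host topic index), `within_count` (exact number of host-topic
#'   documents containing it) and `spread_frac` (fraction of the other
#'   topics that contain it in exactly one document).
#' @param year_range publication-year range documents are drawn from
#'   (default 2008:2018).
#' @param seed integer RNG seed (default 42).
#' @return a validated spec (list, class "synthetic_corpus_spec").
#' @export
syntheticCorpusSpec <- function(n_topics = 5L, docs_per_topic = 200L,
                                topic_vocab_size = 30L,
                                background_vocab_size = 120L,
                                topic_weight = 0.7, doc_length_mean = 120,
                                noise_doc_fraction = 0.10,
                                planted_bigrams = NULL,
                                year_range = 2008:2018, seed = 42L) {
  spec <- list(n_topics = as.integer(n_topics),
               docs_per_topic = as.integer(docs_per_topic),
               topic_vocab_size = as.integer(topic_vocab_size),
               background_vocab_size = as.integer(background_vocab_size),
               topic_weight = topic_weight,
               doc_length_mean = doc_length_mean,
               noise_doc_fraction = noise_doc_fraction,
               planted_bigrams = planted_bigrams,
               year_range = year_range, seed = as.integer(seed))
  if (any(c(spec$n_topics, spec$docs_per_topic, spec$topic_vocab_size,
            spec$background_vocab_size) < 1L))
    .stopf("all counts must be positive")
  if (spec$topic_weight < 0 || spec$topic_weight > 1 ||
      spec$noise_doc_fraction < 0 || spec$noise_doc_fraction > 1)
    .stopf("fractions must lie in [0, 1]")
  pb <- spec$planted_bigrams
  if (!is.null(pb)) {
    need <- c("concept", "topic", "within_count", "spread_frac")
    if (!all(need %in% names(pb)))
      .stopf("planted_bigrams needs columns: %s", paste(need, collapse = ", "))
    if (any(pb$within_count > spec$docs_per_topic))
      .stopf("inconsistent spec: within_count exceeds docs_per_topic")
    if (any(pb$topic < 1L | pb$topic > spec$n_topics))
      .stopf("inconsistent spec: planted bigram topic out of range")
    if (any(pb$spread_frac < 0 | pb$spread_frac > 1))
      .stopf("fractions must lie in [0, 1]")
  }
  class(spec) <- "synthetic_corpus_spec"
  spec
}

#' Generate a synthetic corpus with known ground truth
#'
#' Deterministic per seed: the same spec always yields byte-identical
#' output. Non-noise documents draw each token from their topic vocabulary
#' with probability `topic_weight` and from the shared background
#' otherwise; noise documents are pure background. Planted bigrams are
#' appended to exactly `within_count` host-topic documents and to one
#' document in each of `ceiling(spread_frac * (K - 1))` other topics.
#'
#' @param spec a [syntheticCorpusSpec()].
#' @return list with `corpus` ([DocumentCorpus-class]), `topics` (named
#'   character, doc_id -> "T1"... or "noise"), `concepts` (named list,
#'   doc_id -> planted concept tags) and `spec`.
#' @export
generateCorpus <- function(spec = syntheticCorpusSpec()) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  K <- spec$n_topics
  dpt <- spec$docs_per_topic
  n_noise <- round(spec$noise_doc_fraction * K * dpt)
  n_bg_words <- if (is.null(spec$planted_bigrams)) 0L
                else 2L * nrow(spec$planted_bigrams)
  pool <- .word_pool(K * spec$topic_vocab_size +
                       spec$background_vocab_size + n_bg_words)
  topic_vocab <- split(pool[seq_len(K * spec$topic_vocab_size)],
                       rep(seq_len(K), each = spec$topic_vocab_size))
  bg <- pool[K * spec$topic_vocab_size + seq_len(spec$background_vocab_size)]
  bigram_words <- pool[K * spec$topic_vocab_size +
                         spec$background_vocab_size + seq_len(n_bg_words)]
  withSeed(spec$seed, {
    n_doc <- K * dpt + n_noise
    topic_of <- c(rep(seq_len(K), each = dpt), rep(0L, n_noise))
    ids <- sprintf("S%05d", seq_len(n_doc))
    lens <- pmax(30L, stats::rgeom(n_doc, 1 / spec$doc_length_mean))
    texts <- character(n_doc)
    titles <- character(n_doc)
    for (i in seq_len(n_doc)) {
      t <- topic_of[i]
      toks <- if (t == 0L) sample(bg, lens[i], replace = TRUE)
      else {
        from_topic <- stats::runif(lens[i]) < spec$topic_weight
        ifelse(from_topic,
               sample(topic_vocab[[t]], lens[i], replace = TRUE),
               sample(bg, lens[i], replace = TRUE))
      }
      titles[i] <- paste(toks[seq_len(min(6L, lens[i]))], collapse = " ")
      texts[i] <- paste(toks[-seq_len(min(6L, lens[i]))], collapse = " ")
    }
    concepts <- structure(rep(list(character()), n_doc), names = ids)
    pb <- spec$planted_bigrams
    if (!is.null(pb) && nrow(pb)) {
      pb$bigram <- as.character(if (is.null(pb$bigram)) NA else pb$bigram)
      for (r in seq_len(nrow(pb))) {
        if (is.na(pb$bigram[r]))
          pb$bigram[r] <- paste(bigram_words[c(2L * r - 1L, 2L * r)],
                                collapse = " ")
        host <- which(topic_of == pb$topic[r])
        chosen <- sample(host, pb$within_count[r])
        others <- setdiff(seq_len(K), pb$topic[r])
        m <- .ceil_frac(pb$spread_frac[r], K - 1L)
        spread_topics <- if (m > 0L) sample(others, m) else integer()
        spread_docs <- vapply(spread_topics, function(t)
          sample(which(topic_of == t), 1L), 1L)
        for (i in c(chosen, spread_docs)) {
          texts[i] <- paste(texts[i], pb$bigram[r])
          concepts[[i]] <- union(concepts[[i]], pb$concept[r])
        }
      }
    }
    years <- sample(spec$year_range, n_doc, replace = TRUE)
    corpus <- DocumentCorpus(
      doc_id = ids, title = titles, abstract = texts,
      year = as.integer(years),
      provenance = sprintf("synthetic corpus (K=%d, seed=%d)", K, spec$seed))
    topics <- structure(ifelse(topic_of == 0L, "noise",
                               sprintf("T%d", topic_of)), names = ids)
    list(corpus = corpus, topics = topics, concepts = concepts,
         planted_bigrams = pb, spec = spec)
  })
}

#' Generate schema-valid synthetic figure annotations
#'
#' I.i.d. draws with known category probabilities, for exercising the
#' design-space analytics. Combination categories follow `probs$combination`
#' exactly (one multinomial draw per figure); instance chart types are
#' i.i.d. from `probs$chart_type`; each instance independently receives an
#' add-marks enhancement (probability `probs$p_add`, structured), a
#' re-encoding (`probs$p_reencode`, structured) and a one-off annotation
#' (`probs$p_annotation`, an added mark coded with structure "annotation").
#'
#' @param n number of annotations.
#' @param probs list with `combination` (named probability vector over a
#'   subset of the six combination types), `chart_type` (named probability
#'   vector over schema chart types; default uniform over the bundled
#'   non-special types) and scalars `p_add`, `p_reencode`, `p_annotation`.
#' @param seed integer RNG seed.
#' @param schema a [TypologySchema-class] (default bundled).
#' @param topics,concepts optional pools of why-axis tags; each figure
#'   gets one topic and 1-2 concepts drawn uniformly when provided.
#' @return list with `annotations` (list of [FigureAnnotation-class]) and
#'   `probs` (the fully resolved generating probabilities, including the
#'   derived expected enhancement rates `exp_any` and `exp_add_marks`).
#' @export
generateAnnotations <- function(n, probs = list(), seed = 1L,
                                schema = loadSchema(), topics = NULL,
                                concepts = NULL) {
  n <- as.integer(n)
  comb_p <- probs$combination %||%
    c("Single" = 0.401, "Composite" = 0.203, "Small Multiples" = 0.173,
      "Many Types Linked" = 0.135, "Many Types General" = 0.088)
  if (any(comb_p < 0)) .stopf("probabilities must be non-negative")
  comb_p <- comb_p / sum(comb_p)
  bad <- setdiff(names(comb_p), combinationTypes(schema))
  if (length(bad)) .stopf("unknown combination type(s): %s",
                          paste(bad, collapse = ", "))
  base_types <- chartTypes(schema)
  base_types <- base_types$name[is.na(base_types$parent)]
  type_p <- probs$chart_type %||%
    structure(rep(1 / length(base_types), length(base_types)),
              names = base_types)
  type_p <- type_p / sum(type_p)
  p_add <- probs$p_add %||% 0.5
  p_re <- probs$p_reencode %||% 0.4
  p_ann <- probs$p_annotation %||% 0.3
  full_probs <- list(combination = comb_p, chart_type = type_p,
                     p_add = p_add, p_reencode = p_re, p_annotation = p_ann,
                     exp_any = 1 - (1 - p_add) * (1 - p_re) * (1 - p_ann),
                     exp_add_marks = 1 - (1 - p_add) * (1 - p_ann))
  if (n == 0L) return(list(annotations = list(), probs = full_probs))

  draw_type <- function() sample(names(type_p), 1L, prob = type_p)
  draw_enh <- function() {
    out <- list()
    if (stats::runif(1) < p_add)
      out[[length(out) + 1L]] <- list(
        mode = "add-marks", mark = sample(c("point", "line", "text"), 1L),
        aesthetics = sample(c("color", "shape"),
                            sample.int(2L, 1L)),
        structure = "structured")
    if (stats::runif(1) < p_re)
      out[[length(out) + 1L]] <- list(mode = "re-encode-marks", mark = "line",
                                      aesthetics = "color",
                                      structure = "structured")
    if (stats::runif(1) < p_ann)
      out[[length(out) + 1L]] <- list(
        mode = "add-marks", mark = sample(c("connection", "text"), 1L),
        aesthetics = character(), structure = "annotation")
    out
  }
  non_single <- setdiff(combinationTypes(schema),
                        c("Single", "Complex Combination"))
  withSeed(seed, {
    anns <- vector("list", n)
    combs <- sample(names(comb_p), n, replace = TRUE, prob = comb_p)
    for (i in seq_len(n)) {
      cb <- combs[i]
      constituents <- character()
      if (cb == "Single") {
        types <- draw_type()
      } else if (cb == "Small Multiples") {
        types <- rep(draw_type(), sample(2:4, 1L))
      } else if (cb == "Complex Combination") {
        constituents <- sample(non_single, 2L)
        types <- replicate(3L, draw_type())
        if (length(unique(types)) == 1L) types[2L] <- draw_type()
      } else {
        types <- replicate(sample(2:3, 1L), draw_type())
        if (length(unique(types)) == 1L)
          types[1L] <- sample(setdiff(names(type_p), types[1L]), 1L)
      }
      inst <- lapply(types, function(t)
        list(type = t, enhancements = draw_enh()))
      anns[[i]] <- FigureAnnotation(
        figure_id = sprintf("F%05d", i), doc_id = sprintf("S%05d", i),
        chart_instances = inst, combination = cb,
        constituents = constituents,
        why_topic = if (is.null(topics)) NA_character_
                    else sample(topics, 1L),
        why_concepts = if (is.null(concepts)) character()
                       else sample(concepts, sample.int(2L, 1L)))
    }
    list(annotations = anns, probs = full_probs)
  })
}
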