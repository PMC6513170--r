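## shared fixture: 2 clusters x up to 3 concepts with known memberships
sampling_fixture <- function() {
  ids <- sprintf("d%02d", 1:12)
  labels <- c(rep("C1", 6), rep("C2", 5), "currently-unclustered")
  asg <- toy_assignment(ids, labels)
  links <- new("ConceptLinks",
               links = list(d01 = "genome", d02 = "genome",
                            d03 = c("genome", "surveillance"),
                            d04 = "surveillance", d05 = "vaccine",
                            d06 = character(),
                            d07 = "genome", d08 = "genome",
                            d09 = "surveillance", d10 = "surveillance",
                            d11 = character(), d12 = "genome"),
               concepts = conceptTable(defaultConceptVocabulary())$concept)
  co <- DocumentCorpus(ids, paste("t", ids), paste("text for", ids),
                       year = c(2009L, 2012L, 2013L, 2010L, 2014L, 2015L,
                                2008L, 2016L, 2011L, NA, 2012L, 2013L))
  list(asg = asg, links = links, corpus = co)
}

test_that("strata are the populated (cluster x concept) cells", {
  fx <- sampling_fixture()
  expect_message(st <- buildStrata(fx$asg, fx$links, fx$corpus), "omitted")
  s <- strataTable(st)
  ## brute-force cross-tab oracle
  lab <- finalLabels(fx$asg)
  ll <- conceptLinksList(fx$links)
  for (i in seq_len(nrow(s))) {
    want <- names(ll)[vapply(names(ll), function(d)
      lab[d] == s$cluster[i] && s$concept[i] %in% ll[[d]], TRUE)]
    expect_identical(s$doc_ids[[i]], want)
  }
  expect_identical(nrow(s), 5L)  # C2 x vaccine missing; unclustered ignored
  expect_false(any(s$cluster == "C2" & s$concept == "vaccine"))

  ## fully-populated product: 2 clusters x 3 concepts -> 6 strata
  links_all <- new("ConceptLinks",
                   links = structure(rep(list(c("genome", "surveillance",
                                                "vaccine")), 12),
                                     names = sprintf("d%02d", 1:12)),
                   concepts = c("genome", "surveillance", "vaccine"))
  st_all <- buildStrata(fx$asg, links_all)
  expect_identical(nrow(strataTable(st_all)), 6L)
})

test_that("draws are uniform over eligible docs, seeded and replayable", {
  fx <- sampling_fixture()
  st <- suppressMessages(buildStrata(fx$asg, fx$links, fx$corpus))
  s1 <- drawSample(st, seed = 11L)
  s2 <- drawSample(st, seed = 11L)
  expect_identical(selections(s1), selections(s2))   # replay equality
  expect_identical(s1@seed, 11L)
  sel <- selections(s1)
  expect_true(all(sel$status == "pending"))
  ## accepted selections always belong to their stratum's eligible set
  tab <- strataTable(st)
  for (i in seq_len(nrow(sel))) {
    row <- which(tab$cluster == sel$cluster[i] &
                   tab$concept == sel$concept[i])
    expect_true(sel$doc_id[i] %in% tab$doc_ids[[row]])
  }
  ## a stratum with a single eligible doc always yields that doc
  one <- new("StrataSet",
             strata = data.frame(cluster = "C9", concept = "vaccine",
                                 doc_ids = I(list("only-doc"))),
             years = integer())
  expect_identical(selections(drawSample(one, seed = 1L))$doc_id, "only-doc")
})

test_that("the year filter restricts eligibility and can empty strata", {
  fx <- sampling_fixture()
  st <- suppressMessages(buildStrata(fx$asg, fx$links, fx$corpus))
  smp <- suppressWarnings(drawSample(st, seed = 3L, min_year = 2011L,
                                     round = 2L))
  sel <- selections(smp)
  yrs <- structure(corpusDocs(fx$corpus)$year,
                   names = docIds(fx$corpus))
  expect_true(all(!is.na(yrs[sel$doc_id]) & yrs[sel$doc_id] >= 2011L))
  expect_true(all(sel$round == 2L))
  ## (C2, surveillance) eligible docs are d09 (2011) and d10 (NA year):
  ## the missing-year document is never drawn
  hit <- sel$doc_id[sel$cluster == "C2" & sel$concept == "surveillance"]
  expect_identical(hit, "d09")
  ## strata emptied by the filter are skipped with a warning
  w <- capture_warnings(drawSample(st, seed = 3L, min_year = 2017L))
  expect_true(any(grepl("emptied", w)))
  ## without recorded years, year filtering is an error
  st2 <- suppressMessages(buildStrata(fx$asg, fx$links))
  expect_error(drawSample(st2, seed = 1L, min_year = 2011L),
               "requires strata built with a corpus")
})

test_that("rejection resampling excludes drawn docs and replays exactly", {
  fx <- sampling_fixture()
  st <- suppressMessages(buildStrata(fx$asg, fx$links, fx$corpus))
  smp <- drawSample(st, seed = 5L)
  sel <- selections(smp)
  i <- which(sel$cluster == "C1" & sel$concept == "genome")
  doc <- sel$doc_id[i]
  smp <- decideSelection(smp, doc, "rejected", reason = "no-figures")

  rs <- resampleAfterRejection(smp, st, "C1", "genome", doc, k = 2L,
                               seed = 21L)
  expect_length(rs$candidates, 2L)
  expect_false(doc %in% rs$candidates)
  expect_false(anyDuplicated(rs$candidates) > 0)
  elig <- strataTable(st)$doc_ids[[which(strataTable(st)$cluster == "C1" &
                                           strataTable(st)$concept == "genome")]]
  expect_true(all(rs$candidates %in% elig))
  ## fixed seed -> reproducible candidate lists
  rs2 <- resampleAfterRejection(smp, st, "C1", "genome", doc, k = 2L,
                                seed = 21L)
  expect_identical(rs$candidates, rs2$candidates)
  ## event log keeps rejection and candidate events
  sel2 <- selections(rs$sample)
  expect_identical(sum(sel2$status == "rejected"), 1L)
  expect_identical(sel2$reason[sel2$status == "rejected"], "no-figures")
  expect_identical(sum(sel2$status == "candidate"), 2L)

  ## exhaustion: only one remaining doc yields one candidate with warning
  one <- new("StrataSet",
             strata = data.frame(cluster = "C1", concept = "vaccine",
                                 doc_ids = I(list(c("a", "b")))),
             years = integer())
  s0 <- drawSample(one, seed = 2L)
  first <- selections(s0)$doc_id
  s0 <- decideSelection(s0, first, "rejected", reason = "review")
  expect_warning(r1 <- resampleAfterRejection(s0, one, "C1", "vaccine",
                                              first, k = 2L, seed = 1L),
                 "exhausted")
  expect_identical(r1$candidates, setdiff(c("a", "b"), first))
  ## nothing left: stratum marked unfillable
  s1 <- decideSelection(r1$sample, r1$candidates, "rejected",
                        reason = "no-full-text")
  expect_warning(r2 <- resampleAfterRejection(s1, one, "C1", "vaccine",
                                              r1$candidates, k = 2L,
                                              seed = 1L),
                 "unfillable")
  expect_length(r2$candidates, 0L)

  ## rejecting requires a recorded reason
  expect_error(decideSelection(smp, "nope", "rejected"), "reason|pending")
})

test_that("sampling history round-trips and replays identically", {
  fx <- sampling_fixture()
  st <- suppressMessages(buildStrata(fx$asg, fx$links, fx$corpus))
  smp <- drawSample(st, seed = 8L)
  f <- withr::local_tempfile(fileext = ".json")
  writeRunArtifact(smp, f)
  back <- readRunArtifact(f)
  expect_identical(selections(back), selections(smp))
  expect_identical(back@seed, smp@seed)
  ## replaying the recorded seed over the same strata reproduces the log
  expect_identical(selections(drawSample(st, seed = back@seed)),
                   selections(back))
  ## strata round-trip too
  f2 <- withr::local_tempfile(fileext = ".json")
  writeRunArtifact(st, f2)
  st2 <- readRunArtifact(f2)
  expect_identical(strataTable(st2)$doc_ids, strataTable(st)$doc_ids)
  expect_identical(st2@years, st@years)
})

test_that("round-2 priority puts underrepresented concepts first", {
  fx <- sampling_fixture()
  st <- suppressMessages(buildStrata(fx$asg, fx$links, fx$corpus))
  smp <- drawSample(st, seed = 1L)
  sel <- selections(smp)
  ## accept everything except any 'vaccine' stratum selection
  for (i in seq_len(nrow(sel)))
    if (sel$concept[i] != "vaccine")
      smp <- decideSelection(smp, sel$doc_id[i], "accepted")
  ord <- orderStrataByConceptDeficit(st, smp)
  s <- strataTable(st)
  expect_identical(s$concept[ord[1]], "vaccine")
})
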