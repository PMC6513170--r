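test_that("the bundled schema carries the core controlled vocabularies", {
  s <- loadSchema()
  expect_identical(length(combinationTypes(s)), 6L)
  expect_setequal(combinationTypes(s),
                  c("Single", "Composite", "Small Multiples",
                    "Many Types Linked", "Many Types General",
                    "Complex Combination"))
  expect_setequal(s@mark_kinds, c("point", "line", "area", "text",
                                  "connection", "containment", "glyph"))
  expect_setequal(s@aesthetics, c("size", "shape", "color", "texture"))
  expect_setequal(s@enhancement_modes, c("add-marks", "re-encode-marks"))
  expect_setequal(s@enhancement_structure, c("structured", "annotation"))
  expect_true("Other" %in% s@chart_classes)
  ct <- chartTypes(s)
  ## special cases reference their parent type
  expect_identical(ct$parent[ct$name == "epidemic curve"], "bar chart")
  expect_identical(ct$parent[ct$name == "gel image"], "image")
  ## every documented chart type validates against the schema
  documented <- c("phylogenetic tree", "dendrogram", "table", "bar chart",
                  "epidemic curve", "line chart", "pie chart", "heatmap",
                  "genomic map", "geographic map", "node-link graph",
                  "gel image", "image", "scatter chart")
  for (t in documented) {
    a <- ann_single(paste0("f-", t), type = t)
    expect_identical(nrow(validateAnnotation(a, s)), 0L)
  }
})

test_that("schema overlays are additive only", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    chart_classes = "Interactive",
    chart_types = data.frame(name = "streamgraph", class = "Temporal",
                             parent = NA_character_)), dataframe = "rows"), f)
  s <- loadSchema(overlay = f)
  expect_true("streamgraph" %in% chartTypes(s)$name)
  expect_true("Interactive" %in% s@chart_classes)
  a <- ann_single("fx", type = "streamgraph")
  expect_identical(nrow(validateAnnotation(a, s)), 0L)

  ## redefining a core chart type is a validation error
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    chart_types = data.frame(name = "heatmap", class = "Other",
                             parent = NA_character_)), dataframe = "rows"), f2)
  expect_error(loadSchema(overlay = f2), "redefines core chart types")

  ## core code sets (e.g. the combination taxonomy) are immutable
  f3 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    combination_types = c("Single", "Composite2")), auto_unbox = FALSE), f3)
  expect_error(loadSchema(overlay = f3), "core code sets")
})

test_that("schema serialization round-trips", {
  s <- loadSchema()
  f <- withr::local_tempfile(fileext = ".json")
  writeSchema(s, f)
  s2 <- loadSchemaFile(f)
  for (slot in c("chart_classes", "combination_types", "mark_kinds",
                 "aesthetics", "enhancement_modes", "enhancement_structure"))
    expect_identical(methods::slot(s2, slot), methods::slot(s, slot))
  expect_identical(chartTypes(s2), chartTypes(s))
})

test_that("annotation validation reports every violated invariant", {
  s <- loadSchema()
  ## valid composite heatmap + dendrogram
  ok <- ann_multi("f1", c("heatmap", "dendrogram"), "Composite")
  expect_identical(nrow(validateAnnotation(ok, s)), 0L)

  ## Single with two chart instances
  bad1 <- ann_multi("f2", c("heatmap", "table"), "Single")
  expect_true("single-multiplicity" %in% validateAnnotation(bad1, s)$code)

  ## unknown chart type without an overlay
  bad2 <- ann_single("f3", type = "sunburst")
  expect_true("unknown-code" %in% validateAnnotation(bad2, s)$code)

  ## Small Multiples must repeat one chart type
  bad3 <- ann_multi("f4", c("bar chart", "line chart"), "Small Multiples")
  expect_true("small-multiples-heterogeneous" %in%
                validateAnnotation(bad3, s)$code)

  ## Complex Combination needs exactly two non-Single constituents
  bad4 <- ann_multi("f5", c("heatmap", "dendrogram", "table"),
                    "Complex Combination", constituents = "Composite")
  expect_true("complex-constituents" %in% validateAnnotation(bad4, s)$code)
  bad5 <- ann_multi("f6", c("heatmap", "dendrogram", "table"),
                    "Complex Combination",
                    constituents = c("Composite", "Single"))
  expect_true("complex-constituents" %in% validateAnnotation(bad5, s)$code)
  ok2 <- ann_multi("f7", c("heatmap", "dendrogram", "table"),
                   "Complex Combination",
                   constituents = c("Composite", "Many Types Linked"))
  expect_identical(nrow(validateAnnotation(ok2, s)), 0L)

  ## non-Complex figures must not record constituents
  bad6 <- ann_multi("f8", c("heatmap", "dendrogram"), "Composite",
                    constituents = c("Composite", "Many Types Linked"))
  expect_true("complex-constituents" %in% validateAnnotation(bad6, s)$code)

  ## enhancement codes resolve against the schema
  bad7 <- ann_single("f9", enhancements = list(enh(mode = "paint-marks")))
  expect_true(any(grepl("paint-marks",
                        validateAnnotation(bad7, s)$detail)))
  bad8 <- ann_single("f10", enhancements = list(enh(mark = "blob")))
  expect_true(any(grepl("mark kind", validateAnnotation(bad8, s)$detail)))
  bad9 <- ann_single("f11", enhancements = list(enh(aes = "opacity")))
  expect_true(any(grepl("aesthetic", validateAnnotation(bad9, s)$detail)))
})

test_that("combination classification follows the published decision rules", {
  expect_identical(classifyCombination(1, 1), "Single")
  expect_identical(classifyCombination(2, 2, spatially_aligned = TRUE),
                   "Composite")
  expect_identical(classifyCombination(3, 1), "Small Multiples")
  expect_identical(classifyCombination(2, 2, visually_linked = TRUE),
                   "Many Types Linked")
  expect_identical(classifyCombination(2, 2), "Many Types General")
  ## ambiguous linked-vs-general resolves to Many Types General
  expect_identical(classifyCombination(3, 2, visually_linked = TRUE,
                                       ambiguous_linkage = TRUE),
                   "Many Types General")
  ## two applicable categories -> Complex Combination
  cc <- classifyCombination(4, 2, spatially_aligned = TRUE,
                            repeated_same_type = TRUE)
  expect_identical(as.character(cc), "Complex Combination")
  expect_identical(attr(cc, "constituents"),
                   c("Small Multiples", "Composite"))
  ## contradictory descriptors error
  expect_error(classifyCombination(1, 1, spatially_aligned = TRUE),
               "contradictory")
  expect_error(classifyCombination(2, 3), "contradictory")
})

test_that("combination classification agrees with a rule-table oracle over the descriptor lattice", {
  ## independent literal restatement of the decision rules
  oracle <- function(n, k, aligned, linked, repeated, ambiguous) {
    if (n == 1) return("Single")
    appl <- character()
    if (repeated) appl <- c(appl, "Small Multiples")
    if (k >= 2) {
      if (aligned) appl <- c(appl, "Composite")
      if (!aligned && linked && !ambiguous)
        appl <- c(appl, "Many Types Linked")
      if (!aligned && (ambiguous || !linked))
        appl <- c(appl, "Many Types General")
    }
    if (length(appl) == 0) return("Many Types General")
    if (length(appl) == 1) return(appl)
    "Complex Combination"
  }
  for (n in 1:4) for (k in 1:3) for (al in c(FALSE, TRUE))
    for (li in c(FALSE, TRUE)) for (rs in c(FALSE, TRUE))
      for (am in c(FALSE, TRUE)) {
        if (k > n) next
        contradictory <- (n == 1 && (al || li || rs)) ||
          (rs && k == 1 && (al || li))
        if (contradictory) {
          expect_error(classifyCombination(n, k, al, li, rs, am))
        } else {
          got <- as.character(classifyCombination(n, k, al, li, rs, am))
          expect_identical(got, oracle(n, k, al, li, rs, am),
                           label = sprintf("n=%d k=%d al=%d li=%d rs=%d am=%d",
                                           n, k, al, li, rs, am))
        }
      }
})

test_that("enhancement classification resolves ambiguity as structured", {
  expect_identical(classifyEnhancement(applied_consistently = TRUE),
                   "structured")
  expect_identical(classifyEnhancement(applied_consistently = FALSE),
                   "annotation")
  expect_identical(classifyEnhancement(applied_consistently = FALSE,
                                       ambiguous = TRUE), "structured")
})

test_that("annotation files round-trip exactly", {
  anns <- list(
    ann_single("fig-1", type = "phylogenetic tree",
               concepts = c("drug resistance", "surveillance"),
               enhancements = list(
                 enh("re-encode-marks", "line", "color"),
                 enh("add-marks", "text", character(), "annotation"))),
    ann_multi("fig-2", c("heatmap", "dendrogram"), "Composite"),
    FigureAnnotation("fig-3", "987", list(list(type = "geographic map",
                                               enhancements = list(
                                                 enh("add-marks", "glyph",
                                                     c("color", "size"))))),
                     combination = "Single", why_topic = "influenza-viru",
                     quality_tags = "good", caption = "A map with pie glyphs"))
  f <- withr::local_tempfile(fileext = ".ndjson")
  writeAnnotations(anns, f)
  back <- readAnnotations(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    for (sl in c("figure_id", "doc_id", "chart_instances", "combination",
                 "constituents", "why_topic", "why_concepts", "quality_tags",
                 "caption"))
      expect_identical(methods::slot(back[[i]], sl),
                       methods::slot(anns[[i]], sl))
  }
})
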