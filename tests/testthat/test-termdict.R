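test_that("term tables load with synonyms and abbreviation lexicon", {
  f <- writeTempDict(c(
    "10003481\tAspartate aminotransferase increased\t\taspartate aminotransferase=AST",
    "10019211\theadache\tcephalalgia|head pain\t"))
  d <- loadTermTable(f)
  e <- termEntries(d)
  expect_equal(nrow(e), 2L)
  expect_equal(e$preferred_name[1], "Aspartate aminotransferase increased")
  expect_length(e$synonyms[[1]], 0L)
  expect_equal(e$abbreviations[[1]],
               c("aspartate aminotransferase" = "AST"))
  expect_setequal(e$synonyms[[2]], c("cephalalgia", "head pain"))

  empty <- loadTermTable(writeTempDict(character()))
  expect_equal(nrow(termEntries(empty)), 0L)

  dup <- writeTempDict(c("T1\talpha dermatitis\t\t", "T1\tbeta dermatitis\t\t"))
  expect_error(loadTermTable(dup), "duplicate term_id")

  bad <- writeTempDict("T1\talpha dermatitis\t\tnot-a-pair")
  expect_error(loadTermTable(bad), "line 2")
})

test_that("OBO files parse into a DAG with roots, skipping obsoletes", {
  f <- writeTempObo(c("[Term]", "id: a", "name: low", "is_a: b ! mid", "",
                      "[Term]", "id: b", "name: mid", "is_a: c ! top", "",
                      "[Term]", "id: c", "name: top", "",
                      "[Term]", "id: old", "name: gone", "is_obsolete: true"))
  ont <- loadObo(f)
  expect_setequal(oboTerms(ont)$id, c("a", "b", "c"))
  expect_equal(oboRoots(ont), "c")

  multi <- loadObo(writeTempObo(c(
    "[Term]", "id: x", "name: x", "is_a: p1", "is_a: p2", "",
    "[Term]", "id: p1", "name: p1", "", "[Term]", "id: p2", "name: p2")))
  expect_setequal(termParents(multi)[["x"]], c("p1", "p2"))

  expect_error(loadObo(writeTempObo(c(
    "[Term]", "id: a", "name: a", "is_a: b", "",
    "[Term]", "id: b", "name: b", "is_a: a"))), "cycle")

  expect_error(loadObo(writeTempObo(c("[Term]", "name: anonymous"))),
               "without id")
})

test_that("singular/plural expansion covers clinical vocabulary", {
  expect_true("peripheral neuropathies" %in% expandNumber("peripheral neuropathy"))
  expect_true("rashes" %in% expandNumber("rash"))
  expect_true("pruritus" %in% expandNumber("pruritus"))
  expect_false(any(grepl("prurituss|prurituses", expandNumber("pruritus"))))
  # singular recovered from a plural-only vocabulary entry
  expect_true("night sweat" %in% expandNumber("night sweats"))
})

test_that("number expansion is closed and idempotent", {
  terms <- c("peripheral neuropathy", "rash", "rashes", "blood glucose decreased",
             "severe dermatitis", "muscle spasms", "pruritus", "seizures")
  for (t in terms) {
    out <- expandNumber(t)
    again <- unique(unlist(lapply(out, expandNumber)))
    expect_setequal(again, out)
  }
})

test_that("laboratory-finding variants follow the analyte/direction grammar", {
  v <- generateLabVariants("Aspartate aminotransferase increased",
                           c("aspartate aminotransferase" = "AST"))
  expect_true(all(c("increased AST", "AST elevated", "high AST") %in% v))
  expect_true("Aspartate aminotransferase increased" %in% v)

  expect_equal(generateLabVariants("headache"), "headache")

  # hand enumeration: analyte "blood glucose" x {decreased, reduced, low,
  # lowered} x {prefix, postfix}, plus the preferred name
  v2 <- generateLabVariants("Blood glucose decreased")
  expected <- c("Blood glucose decreased",
                as.vector(outer(c("decreased", "reduced", "low", "lowered"),
                                "Blood glucose",
                                function(d, a) paste(d, a))),
                as.vector(outer(c("decreased", "reduced", "low", "lowered"),
                                "Blood glucose",
                                function(d, a) paste(a, d))))
  expect_setequal(tolower(v2), tolower(expected))
  expect_true(all(c("decreased blood glucose", "blood glucose reduced",
                    "low blood glucose") %in% tolower(v2)))
})

test_that("compiled dictionaries index every expansion with ambiguity preserved", {
  d <- compileDictionary(makeEntry("T1", "peripheral neuropathy"))
  expect_equal(lookupSurface(d, "peripheral neuropathy"), "T1")
  expect_equal(lookupSurface(d, "Peripheral Neuropathies"), "T1")

  expect_equal(nrow(termEntries(compileDictionary(
    makeEntry("T0", "x")[0, ]))), 0L)

  two <- makeEntries(
    makeEntry("T1", "alpha finding", synonyms = "AST increased"),
    makeEntry("T2", "beta finding", synonyms = "AST increased"))
  d2 <- compileDictionary(two)
  expect_equal(lookupSurface(d2, "ast increased"), c("T1", "T2"))
})

test_that("the acronym guard indexes short forms case-sensitively with a stoplist", {
  d <- compileDictionary(astEntry())
  expect_equal(lookupSurface(d, "AST"), "10003481")
  expect_equal(lookupSurface(d, "ast"), character())   # wrong case
  trap <- makeEntry("T9", "acute lymphocytic leukaemia",
                    abbreviations = c("acute lymphocytic leukaemia" = "ALL"))
  d2 <- compileDictionary(trap)
  expect_equal(lookupSurface(d2, "all"), character())
  expect_equal(lookupSurface(d2, "ALL"), character())  # stoplisted
  expect_equal(lookupSurface(d2, "acute lymphocytic leukaemia"), "T9")
  # not stoplisted, not an abbreviation: short surfaces are not indexed
  d3 <- compileDictionary(makeEntry("T3", "rash"))
  expect_equal(lookupSurface(d3, "rash"), character())
  # lowering the guard makes short plain words matchable
  d4 <- compileDictionary(makeEntry("T3", "rash"), dictConfig(minAcronymLen = 3))
  expect_equal(lookupSurface(d4, "rash"), "T3")
})

test_that("compilation is deterministic and index closure/round-trip hold", {
  entries <- makeEntries(
    astEntry(),
    makeEntry("T2", "peripheral neuropathy"),
    makeEntry("T3", "severe dermatitis", synonyms = "grave dermatitis"))
  d1 <- compileDictionary(entries)
  d2 <- compileDictionary(entries)
  expect_identical(d1@indexCI, d2@indexCI)
  expect_identical(d1@indexCS, d2@indexCS)

  # closure: expanding any indexed surface only yields indexed surfaces
  keys <- names(d1@indexCI)
  for (k in keys) {
    for (v in expandNumber(k)) {
      expect_true(tolower(surfaceKey(v)) %in% keys,
                  label = sprintf("expansion '%s' of key '%s' indexed", v, k))
    }
  }
  # round trip: every term id appears in the index at least once
  indexed <- unique(unlist(c(d1@indexCI, d1@indexCS), use.names = FALSE))
  expect_setequal(indexed, termEntries(d1)$term_id)
})
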