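test_that("drugs are assigned the full ancestor closure of their chemical term", {
  ont <- makeOntology(list(c("chm1", "benzclass"), c("benzclass", "organic"),
                           c("organic", "root"), c("chm2", "benzclass")))
  a <- assignClasses(c(drugA = "chm1", drugB = "chm2"), ont)
  expect_setequal(a$drugA, c("benzclass", "organic", "root"))
  expect_setequal(classMembers("benzclass", a), c("drugA", "drugB"))

  expect_error(assignClasses(c(drugC = "nope"), ont), "drugC")

  # multi-parent chemical: both lineages assigned, checked against BFS oracle
  set.seed(8)
  for (i in 1:10) {
    dag <- randomDag(12)
    ids <- oboTerms(dag)$id
    t <- sample(ids, 1)
    a2 <- assignClasses(c(d = t), dag)
    expect_setequal(a2$d, oracleAncestors(dag, t))
  }
})

test_that("PCR is the fraction of class drugs carrying the ADR; effect iff 1", {
  ont <- makeOntology(list(c("c1", "cls"), c("c2", "cls"), c("c3", "cls"),
                           c("cls", "root")))
  a <- assignClasses(c(d1 = "c1", d2 = "c2", d3 = "c3"), ont)
  tab <- drugAdrTable(list(d1 = c("x", "y"), d2 = c("x", "y", "z"),
                           d3 = c("x", "w")))
  all3 <- computePcr("cls", "x", a, tab)
  expect_equal(all3$pcr, 1)
  expect_true(all3$class_effect)

  two3 <- computePcr("cls", "y", a, tab)
  expect_equal(two3$pcr, 2 / 3)
  expect_false(two3$class_effect)

  expect_equal(computePcr("cls", "absent", a, tab)$pcr, 0)
  expect_error(computePcr("emptycls", "x", a, tab), "no member")
})

test_that("PCR monotonicity under adding member drugs", {
  ont <- makeOntology(list(c("c1", "cls"), c("c2", "cls"), c("c3", "cls")))
  a2 <- assignClasses(c(d1 = "c1", d2 = "c2"), ont)
  a3 <- assignClasses(c(d1 = "c1", d2 = "c2", d3 = "c3"), ont)
  base <- drugAdrTable(list(d1 = "x", d2 = "x"))
  withAdr <- drugAdrTable(list(d1 = "x", d2 = "x", d3 = "x"))
  without <- drugAdrTable(list(d1 = "x", d2 = "x", d3 = "q"))
  p0 <- computePcr("cls", "x", a2, base)$pcr
  expect_gte(computePcr("cls", "x", a3, withAdr)$pcr, p0)
  expect_lt(computePcr("cls", "x", a3, without)$pcr, p0)
})

test_that("shared ADRs equal the intersection and the PCR=1 set", {
  ont <- makeOntology(list(c("c1", "cls"), c("c2", "cls"), c("c3", "cls")))
  a <- assignClasses(c(d1 = "c1", d2 = "c2", d3 = "c3"), ont)
  tab <- drugAdrTable(list(d1 = c("a", "b", "c"), d2 = c("b", "c"),
                           d3 = c("b", "c", "d")))
  expect_equal(sharedAdrs("cls", a, tab), c("b", "c"))

  single <- assignClasses(c(d1 = "c1"), ont)
  expect_equal(sharedAdrs("cls", single, drugAdrTable(list(d1 = c("a", "b")))),
               c("a", "b"))

  # cross-check the two code paths over random tables
  set.seed(41)
  for (i in 1:10) {
    tab2 <- drugAdrTable(setNames(tableProfiles(randomTable(3, 6)),
                                  c("d1", "d2", "d3")))
    adrs <- sort(unique(unlist(tableProfiles(tab2))))
    viaPcr <- adrs[vapply(adrs, function(ad)
      computePcr("cls", ad, a, tab2)$class_effect, logical(1L))]
    expect_equal(sharedAdrs("cls", a, tab2), viaPcr)
  }
})

test_that("pcrTable enumerates classes above the size floor", {
  ont <- makeOntology(list(c("c1", "cls"), c("c2", "cls"), c("c3", "solo"),
                           c("cls", "root"), c("solo", "root")))
  a <- assignClasses(c(d1 = "c1", d2 = "c2", d3 = "c3"), ont)
  tab <- drugAdrTable(list(d1 = c("x", "y"), d2 = c("x"), d3 = c("y")))
  p <- pcrTable(a, tab, minClassSize = 2L)
  expect_setequal(unique(p$class_id), c("cls", "root"))
  expect_true(p$class_effect[p$class_id == "cls" & p$adr_term_id == "x"])
  expect_false(any(p$class_effect[p$class_id == "root"]))
  # single-member "solo" class excluded by the floor
  expect_false("solo" %in% p$class_id)
})

test_that("computed-intermediate extraction includes connecting chains and root paths", {
  ont <- makeOntology(list(c("leaf1", "p"), c("leaf2", "p"), c("p", "root")))
  sub <- extractSubtree(ont, c("leaf1", "leaf2"))
  expect_setequal(sub@terms$id, c("leaf1", "leaf2", "p", "root"))

  one <- makeOntology(list(), extraIds = "root")
  expect_equal(extractSubtree(one, "root")@terms$id, "root")

  expect_error(extractSubtree(ont, "ghost"), "unknown selected")

  # selected terms on one chain: intermediate terms between them included
  chain <- makeOntology(list(c("a", "b"), c("b", "c"), c("c", "d")))
  sub2 <- extractSubtree(chain, c("a", "c"))
  expect_true("b" %in% sub2@terms$id)
  # reduced edges skip no included term: a->b->c->d, never a->c directly
  expect_true(all(paste(sub2@edges$child, sub2@edges$parent) %in%
                    c("a b", "b c", "c d")))
})

test_that("subtree extraction is sound on random DAGs and idempotent", {
  set.seed(17)
  for (i in 1:15) {
    dag <- randomDag(sample(8:14, 1))
    ids <- oboTerms(dag)$id
    sel <- sample(ids, sample(2:4, 1))
    sub <- extractSubtree(dag, sel)
    inc <- sub@terms$id
    # all selected present; all connecting-chain nodes present
    # (path-enumeration oracle)
    expect_true(all(sel %in% inc))
    expect_true(all(oracleBetweenTerms(dag, sel) %in% inc))
    # edges are real ancestor links with no included term skipped over
    for (r in seq_len(nrow(sub@edges))) {
      ch <- sub@edges$child[r]; pa <- sub@edges$parent[r]
      expect_true(pa %in% oracleAncestors(dag, ch))
      strictlyBetween <- vapply(setdiff(inc, c(ch, pa)), function(w)
        w %in% oracleAncestors(dag, ch) && pa %in% oracleAncestors(dag, w),
        logical(1L))
      expect_false(any(strictlyBetween))
    }
    # reduced edges preserve reachability among included terms
    for (u in inc) {
      for (v in intersect(oracleAncestors(dag, u), inc))
        expect_true(oracleReachable(sub@edges, u, v))
    }
    # idempotence: re-extracting from the extracted view changes nothing
    again <- extractSubtree(subOntologyAsOntology(sub), sel)
    expect_equal(again@terms$id, sub@terms$id)
    expect_equal(again@edges, sub@edges)
  }
})

test_that("planted class effects are recovered end-to-end with no false calls", {
  dir <- file.path(tempdir(), "ce-universe")
  unlink(dir, recursive = TRUE)
  cfg <- synthConfig(n_drugs = 9, n_adr_terms = 24, mentions_per_label = 7,
                     planted_class_specs = list(
                       list(size = 3, n_shared = 5, n_extra = 2)),
                     distractor_rate = 0, seed = 23)
  generateUniverse(cfg, dir)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  ont <- loadObo(file.path(dir, "ontology.obo"))
  dt <- read.delim(file.path(dir, "drug_terms.tsv"), colClasses = "character")
  a <- assignClasses(setNames(dt$term_id, dt$drug), ont)
  tab <- drugAdrTable(truth$profiles)
  p <- pcrTable(a, tab, minClassSize = 2L)
  eff <- p[p$class_effect, , drop = FALSE]
  planted <- truth$planted_classes[1, ]
  expect_equal(sort(eff$adr_term_id[eff$class_id == planted$class_id]),
               sort(unlist(planted$shared_adrs)))
  expect_equal(unique(eff$class_id), planted$class_id)
})
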