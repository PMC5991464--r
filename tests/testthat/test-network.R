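test_that("edge thresholds use the ceiling of fraction times drug count", {
  expect_equal(minEdgeCount(53, 0.5), 27L)
  expect_equal(minEdgeCount(10, 0.5), 5L)
  expect_equal(minEdgeCount(7, 0.5), 4L)
  expect_equal(minEdgeCount(10, 0.3), 3L)    # guards against float fuzz
  expect_error(minEdgeCount(10, 0), "fraction")
  expect_error(minEdgeCount(10, 1.2), "fraction")
})

test_that("co-occurrence networks match explicit pair counting", {
  all4 <- drugAdrTable(list(d1 = c("x", "y"), d2 = c("x", "y"),
                            d3 = c("x", "y"), d4 = c("x", "y")))
  net <- buildCooccurrenceNetwork(all4, 0.5)
  expect_equal(networkEdges(net),
               data.frame(a = "x", b = "y", weight = 4L,
                          stringsAsFactors = FALSE))

  sparse <- drugAdrTable(list(d1 = c("x", "y"), d2 = "x", d3 = "y", d4 = "z"))
  expect_equal(nrow(networkEdges(buildCooccurrenceNetwork(sparse, 0.5))), 0L)

  expect_error(buildCooccurrenceNetwork(drugAdrTable(setNames(list(), character())), 0.5),
               "empty")

  set.seed(71)
  tab <- randomTable(10, 8)
  net2 <- buildCooccurrenceNetwork(tab, 0.5)
  expect_equal(networkEdges(net2), oracleEdges(tableProfiles(tab), 0.5))
})

test_that("network invariants: weight bound and threshold monotonicity", {
  set.seed(14)
  for (i in 1:20) {
    tab <- randomTable(sample(2:10, 1), sample(2:8, 1))
    lo <- buildCooccurrenceNetwork(tab, 0.3)
    hi <- buildCooccurrenceNetwork(tab, 0.7)
    e <- networkEdges(lo); sup <- networkSupport(lo)
    if (nrow(e))
      expect_true(all(e$weight <= pmin(sup[e$a], sup[e$b])))
    # raising the fraction never adds edges
    expect_true(all(paste(networkEdges(hi)$a, networkEdges(hi)$b) %in%
                      paste(e$a, e$b)))
  }
})

test_that("degree centrality counts neighbors", {
  star <- drugAdrTable(lapply(setNames(1:5, paste0("d", 1:5)),
                              function(i) c("hub", paste0("leaf", i))))
  net <- buildCooccurrenceNetwork(star, 0.2)   # every pair with >= 1 drug
  d <- degreeCentrality(net)
  expect_equal(d$degree[d$term_id == "hub"], 5L)
  expect_true(all(d$degree[d$term_id != "hub"] == 1L))

  tri <- drugAdrTable(list(d1 = c("a", "b", "c")))
  dt <- degreeCentrality(buildCooccurrenceNetwork(tri, 0.5))
  expect_equal(dt$degree, c(2L, 2L, 2L))
})

test_that("eigenvector centrality agrees with dense eigendecomposition", {
  tri <- buildCooccurrenceNetwork(drugAdrTable(list(d1 = c("a", "b", "c"))), 0.5)
  ev <- eigenvectorCentrality(tri)
  expect_equal(ev$eigenvector, rep(1 / sqrt(3), 3), tolerance = 1e-10)

  # path a-b-c: analytic principal eigenvector (0.5, 1/sqrt(2), 0.5)
  path3 <- drugAdrTable(list(d1 = c("a", "b"), d2 = c("b", "c")))
  net3 <- buildCooccurrenceNetwork(path3, 0.5)
  ev3 <- eigenvectorCentrality(net3)
  expect_equal(ev3$eigenvector[ev3$term_id == "b"], 1 / sqrt(2),
               tolerance = 1e-8)
  expect_equal(ev3$eigenvector[ev3$term_id != "b"], c(0.5, 0.5),
               tolerance = 1e-8)

  set.seed(33)
  for (i in 1:25) {
    tab <- randomTable(sample(3:10, 1), sample(3:8, 1))
    net <- buildCooccurrenceNetwork(tab, 0.4)
    if (!length(networkNodes(net))) next
    ev <- suppressWarnings(eigenvectorCentrality(net))
    oracle <- oracleEigenvector(net)
    expect_equal(setNames(ev$eigenvector, ev$term_id), oracle[ev$term_id],
                 tolerance = 1e-8)
    expect_true(all(ev$eigenvector >= 0))
  }
})

test_that("disconnected components get zero centrality with a warning", {
  two <- drugAdrTable(list(d1 = c("a", "b"), d2 = c("a", "b"),
                           d3 = c("x", "y"), d4 = c("a", "b", "x", "y")))
  net <- buildCooccurrenceNetwork(two, 0.5)   # a-b (3 drugs), x-y (2 drugs)
  expect_warning(ev <- eigenvectorCentrality(net), "components")
  expect_equal(sort(ev$eigenvector[ev$eigenvector > 0]),
               rep(1 / sqrt(2), 2), tolerance = 1e-8)
  expect_equal(sum(ev$eigenvector == 0), 2L)
})

test_that("network comparison ranks and reports subset-specific ADRs", {
  tabA <- drugAdrTable(list(d1 = c("a", "b", "v"), d2 = c("a", "b", "v")))
  tabB <- drugAdrTable(list(d1 = c("a", "b"), d2 = c("a", "b")))
  netA <- buildCooccurrenceNetwork(tabA, 0.5)
  netB <- buildCooccurrenceNetwork(tabB, 0.5)

  same <- rankAndCompare(netA, netA)
  expect_length(same$onlyInA, 0L)

  cmp <- rankAndCompare(netA, netB)
  expect_equal(cmp$onlyInA, "v")
  expect_equal(cmp$rankingA$term_id[order(-cmp$rankingA$eigenvector,
                                          -cmp$rankingA$degree,
                                          cmp$rankingA$term_id)],
               cmp$rankingA$term_id)
  expect_type(cmp$sameRankingA, "logical")
})

test_that("synthetic universes yield networks equal to their planted truth", {
  dir <- file.path(tempdir(), "net-universe")
  unlink(dir, recursive = TRUE)
  cfg <- synthConfig(n_drugs = 8, n_adr_terms = 20, mentions_per_label = 6,
                     planted_class_specs = list(
                       list(size = 2, n_shared = 4, n_extra = 1)),
                     distractor_rate = 0, seed = 5)
  generateUniverse(cfg, dir)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  tab <- drugAdrTable(truth$profiles)
  net <- buildCooccurrenceNetwork(tab, 0.5)
  gt <- truth$expected_network$edges
  if (is.data.frame(gt) && nrow(gt)) {
    expect_equal(networkEdges(net)$a, gt$a)
    expect_equal(networkEdges(net)$b, gt$b)
    expect_equal(networkEdges(net)$weight, gt$weight)
  } else {
    expect_equal(nrow(networkEdges(net)), 0L)
  }
})
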