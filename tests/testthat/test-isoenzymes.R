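fixturePath <- system.file("extdata", "retli_isoenzymes_table.tsv",
                           package = "proTRN")

test_that("multiplicity classes follow the set rules on hand-built profiles", {
  profiles <- list(MM = c("L1", "L2", "L3", "L5"),
                   bacteroid = c("L2", "L4", "L5", "L6"))
  koMap <- data.frame(
    locus = c("L1", "L4", "L2", "L3", "L5", "L6"),
    ko = c("K1", "K1", "K2", "K3", "K4", "K4"))
  iso <- detectIsoenzymes(profiles, koMap)
  cls <- setNames(iso$multiplicity_class, iso$ko)
  expect_equal(unname(cls["K1"]), "disjoint")       # L1 vs L4
  expect_equal(unname(cls["K2"]), "identical")      # L2 in both
  expect_equal(unname(cls["K3"]), "single-condition")
  expect_equal(unname(cls["K4"]), "overlapping")    # L5 shared, L6 extra
  expect_equal(multiplicityCounts(iso)$inclusive, 2)
  expect_equal(multiplicityCounts(iso)$strict, 1)
  expect_error(detectIsoenzymes(list(MM = character()), koMap), "empty")
})

test_that("group detection is invariant to locus and condition ordering", {
  profiles <- list(MM = c("L3", "L1", "L2"), bacteroid = c("L5", "L4"))
  koMap <- data.frame(locus = c("L1", "L4", "L2", "L5", "L3"),
                      ko = c("K1", "K1", "K2", "K2", "K3"))
  a <- detectIsoenzymes(profiles, koMap)
  b <- detectIsoenzymes(lapply(rev(profiles), sample),
                        koMap[sample(nrow(koMap)), ])
  expect_equal(a$ko, b$ko)
  expect_equal(a$multiplicity_class, b$multiplicity_class)
})

test_that("the packaged R. etli table reproduces the curated classes", {
  fx <- readIsoenzymeTable(fixturePath)
  iso <- detectIsoenzymes(fx$profiles, fx$koMap)
  cls <- setNames(iso$multiplicity_class, iso$ko)
  for (ko in c("K00390", "K16147", "K01916", "K02968", "K01609"))
    expect_equal(unname(cls[ko]), "identical", label = ko)
  expect_equal(unname(cls["K00033"]), "disjoint")
  expect_equal(unname(cls["K01768"]), "overlapping")
  # the disjoint pentose-phosphate pair: one locus per condition
  k33 <- iso$loci_by_condition[[which(iso$ko == "K00033")]]
  expect_equal(k33$MM, "RHE_RS12615")
  expect_equal(k33$Bacteroid, "RHE_RS17825")
  # identical-locus KOs are excluded from the multiplicity counts
  counts <- multiplicityCounts(iso)
  expect_false(any(c("K00390", "K16147", "K01916", "K02968", "K01609")
                   %in% counts$groups$ko))
})

test_that("pathway coverage counts distinct labels over multiplicity groups", {
  groups <- data.frame(ko = c("K1", "K2", "K3"),
                       multiplicity_class = c("disjoint", "overlapping",
                                              "identical"),
                       n_conditions = 2L, n_loci = 2L)
  koPathways <- data.frame(ko = c("K1", "K1", "K2", "K3"),
                           pathway = c("glycolysis", "TCA", "glycolysis",
                                       "pentose"))
  cov <- pathwayCoverage(groups, koPathways)
  # K3 is identical and does not contribute; K1 and K2 share glycolysis
  expect_equal(cov$count, 2)
  expect_setequal(cov$table$pathway, c("glycolysis", "TCA"))
  one <- pathwayCoverage(groups[1, ], koPathways[2, , drop = FALSE])
  expect_equal(one$count, 1)
})

test_that("planted pathway labels are recovered from the synthetic KO map", {
  w <- smallWorld()
  iso <- detectIsoenzymes(w, worldKoMap(w))
  cov <- pathwayCoverage(iso, worldKoPathways(w))
  kos <- multiplicityCounts(iso)$groups$ko
  pw <- worldKoPathways(w)
  expect_equal(cov$count, length(unique(pw$pathway[pw$ko %in% kos])))
})

test_that("differential regulators are flagged when TF sets differ across conditions", {
  mkNet <- function(cond, tf, target) {
    ed <- data.frame(matrix_id = paste0(tf, "_m1"), tf = tf,
                     target = target, strand = "D", start = 1L, end = 10L,
                     site = "ACGTACGTAC", weight = 5, p_value = 1e-5,
                     significance = 5, tier = "medium",
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(ed[, c("tf", "target")])
    igraph::V(g)$isRegulator <- igraph::V(g)$name %in% tf
    new("RegNetwork", condition = cond, graph = g, edges = ed,
        provenance = "step1")
  }
  profiles <- list(MM = c("L1", "T1", "T2"), bacteroid = c("L2", "T1", "T2"))
  koMap <- data.frame(locus = c("L1", "L2"), ko = c("K1", "K1"))
  iso <- detectIsoenzymes(profiles, koMap)
  netsDiff <- list(MM = mkNet("MM", "T1", "L1"),
                   bacteroid = mkNet("bacteroid", "T2", "L2"))
  dr <- differentialRegulators(iso, netsDiff)
  expect_true(dr$differential[dr$ko == "K1"])
  netsSame <- list(MM = mkNet("MM", "T1", "L1"),
                   bacteroid = mkNet("bacteroid", "T1", "L2"))
  dr2 <- differentialRegulators(iso, netsSame)
  expect_false(dr2$differential[dr2$ko == "K1"])
  # a locus with no inferred regulator is reported uncovered
  netsPart <- list(MM = mkNet("MM", "T1", "Lx"),
                   bacteroid = mkNet("bacteroid", "T2", "L2"))
  dr3 <- differentialRegulators(iso, netsPart)
  expect_true("L1" %in% dr3$uncovered[[1]])
})

test_that("condition-specific planted regulators flag every multiplicity group", {
  # two planted groups, each regulated by a different TF per condition
  profiles <- list(MM = c("A1", "B1"), bacteroid = c("A2", "B2"))
  koMap <- data.frame(locus = c("A1", "A2", "B1", "B2"),
                      ko = c("KA", "KA", "KB", "KB"))
  iso <- detectIsoenzymes(profiles, koMap)
  ed <- function(tf, targets) {
    data.frame(matrix_id = paste0(tf, "_m2"), tf = tf, target = targets,
               strand = "D", start = 1L, end = 8L, site = "ACGTACGT",
               weight = 4, p_value = 5e-6, significance = -log10(5e-6),
               tier = "high", stringsAsFactors = FALSE)
  }
  mk <- function(cond, tf, targets) {
    e <- ed(tf, targets)
    g <- igraph::graph_from_data_frame(e[, c("tf", "target")])
    igraph::V(g)$isRegulator <- igraph::V(g)$name %in% tf
    new("RegNetwork", condition = cond, graph = g, edges = e,
        provenance = "step1")
  }
  nets <- list(MM = mk("MM", "T1", c("A1", "B1")),
               bacteroid = mk("bacteroid", "T2", c("A2", "B2")))
  dr <- differentialRegulators(iso, nets)
  expect_equal(nrow(dr), 2)
  expect_true(all(dr$differential))
})
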