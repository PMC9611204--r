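# A tiny hand-built scanning problem shared by the tests below: two TFs
# with distinctive motifs, four targets; sites planted by construction.
tinyScanWorld <- function() {
  t1site <- "AAGGCCTTAAGG"   # not reverse-complement palindromic
  t2site <- "ACGGTTCAACGG"
  bgPad <- function(left, core, len) {
    paste0(strrep("T", left), core, strrep("A", len - left - nchar(core)))
  }
  promoters <- c(
    T1 = bgPad(10, t1site, 60),            # self-site for T1
    T2 = bgPad(15, t2site, 60),            # self-site for T2
    G1 = bgPad(20, t1site, 60),            # regulated by T1
    G2 = bgPad(5, t2site, 60),             # regulated by T2
    G3 = bgPad(12, revComp(t1site), 60),   # T1 site on reverse strand
    G4 = strrep(c("T"), 60))               # no site: should drop out
  matrices <- list(T1 = list(wordPssm(t1site, id = "T1_m1")),
                   T2 = list(wordPssm(t2site, id = "T2_m1")))
  list(promoters = promoters, matrices = matrices,
       profile = list(loci = names(promoters), tfs = c("T1", "T2")))
}

test_that("network construction keeps recognised genes and drops the rest", {
  tw <- tinyScanWorld()
  net <- buildNetwork(tw$profile, tw$promoters, tw$matrices,
                      condition = "MM")
  expect_s4_class(net, "RegNetwork")
  expect_false("G4" %in% regNodes(net))      # hit by nothing
  expect_true(all(c("T1", "T2", "G1", "G2", "G3") %in% regNodes(net)))
  ed <- regEdges(net)
  expect_true(all(ed$p_value <= 9.9e-4))
  # self-sites become self-loops
  expect_true(any(ed$tf == "T1" & ed$target == "T1"))
  # the reverse-strand site is found with strand R
  g3 <- ed[ed$tf == "T1" & ed$target == "G3", ]
  expect_equal(g3$strand, "R")
  expect_error(buildNetwork(list(loci = character(), tfs = character()),
                            tw$promoters, tw$matrices), "empty")
})

test_that("a TF hitting only its own promoter is retained with a self-loop", {
  site <- "ACGTACGTACGT"
  promoters <- c(T1 = paste0(strrep("T", 10), site, strrep("T", 20)),
                 G1 = strrep("A", 42))
  net <- buildNetwork(list(loci = c("T1", "G1"), tfs = "T1"), promoters,
                      list(T1 = list(wordPssm(site, id = "T1_m1"))))
  expect_equal(regNodes(net), "T1")
  expect_equal(nrow(regEdges(net)), 1)
  expect_equal(extractRegulons(net), list(T1 = "T1"))
})

test_that("regulon extraction partitions the edges by regulator", {
  tw <- tinyScanWorld()
  net <- buildNetwork(tw$profile, tw$promoters, tw$matrices)
  regs <- extractRegulons(net)
  ed <- regEdges(net)
  expect_setequal(names(regs), unique(ed$tf))
  expect_setequal(unlist(regs, use.names = FALSE), unique(ed$target))
  expect_equal(sum(lengths(regs)), nrow(ed))
  expect_true(all(c("T1", "G1", "G3") %in% regs$T1))
})

test_that("the p-value histogram conserves the edge count", {
  tw <- tinyScanWorld()
  net <- buildNetwork(tw$profile, tw$promoters, tw$matrices)
  hist <- pvalueRangeHistogram(net)
  expect_equal(sum(hist), nrow(regEdges(net)))
  expect_length(hist, 17)
  # a single-p network concentrates in one bin
  ed <- regEdges(net)[1, ]
  ed$p_value <- 5e-5
  one <- new("RegNetwork", condition = "x",
             graph = regGraph(net), edges = ed, provenance = "step1")
  h1 <- pvalueRangeHistogram(one)
  expect_equal(sum(h1 > 0), 1)
  expect_equal(unname(h1["1e-05"]), 1)
})

test_that("the three-step method refines without inventing edges", {
  w <- smallWorld()
  profile <- worldProfiles(w)[["MM"]]
  ts <- threeStep(profile, worldPromoters(w), worldMatrices(w),
                  condition = "MM")
  expect_true(all(regNodes(ts$step3) %in% ts$retained))
  expect_true(all(ts$retained %in% regNodes(ts$step1)))
  # identical scan parameters: step-3 edges are a subset of step-1 edges
  key <- function(net) {
    ed <- regEdges(net)
    paste(ed$tf, ed$target)
  }
  expect_true(all(key(ts$step3) %in% key(ts$step1)))
  # planted-truth precision does not degrade
  truth <- truthNetwork(w)
  acc1 <- networkAccuracy(ts$step1, truth)
  acc3 <- networkAccuracy(ts$step3, truth)
  expect_gte(acc3$precision, acc1$precision)
  # the planted relations are recovered within the profile
  expect_gte(networkAccuracy(ts$step1, truth,
                             universe = profile$loci)$recall, 0.8)
})

test_that("relaxing the cutoff to a flat 1e-3 never loses edges", {
  tw <- tinyScanWorld()
  strict <- buildNetwork(tw$profile, tw$promoters, tw$matrices,
                         maxP = 1e-5)
  flat <- buildNetwork(tw$profile, tw$promoters, tw$matrices,
                       maxP = 1e-3 - 1e-12)
  expect_gte(nrow(regEdges(flat)), nrow(regEdges(strict)))
})

test_that("networks round-trip through the 12-column relation table", {
  tw <- tinyScanWorld()
  net <- buildNetwork(tw$profile, tw$promoters, tw$matrices,
                      condition = "MM")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeNetworkTsv(net, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header, proTRN:::NETWORK_COLUMNS)
  back <- readNetworkTsv(path, tfSet = c("T1", "T2"))
  edA <- regEdges(net); edA <- edA[order(edA$tf, edA$target), ]
  edB <- regEdges(back)
  expect_equal(edB[, names(edB)], edA[, names(edB)], ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(netCondition(back), "MM")
  expect_setequal(regNodes(back), regNodes(net))
})
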