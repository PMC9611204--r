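test_that("world construction honours its contract and preconditions", {
  w <- generateWorld(nGenes = 10, nTfs = 2, promoterLen = 100, seed = 7)
  expect_length(worldGenes(w), 10)
  expect_length(worldTfs(w), 2)
  expect_true(all(Biostrings::width(worldPromoters(w)) == 100))
  expect_error(generateWorld(nGenes = 10, nTfs = 0), "nTfs")
  expect_error(generateWorld(nGenes = 10, nTfs = 10), "nTfs")
  expect_error(generateWorld(nGenes = 10, nTfs = 2, promoterLen = 20),
               "twice")
})

test_that("the same seed reproduces the world bit for bit", {
  a <- generateWorld(nGenes = 30, nTfs = 4, promoterLen = 120, seed = 1)
  b <- generateWorld(nGenes = 30, nTfs = 4, promoterLen = 120, seed = 1)
  expect_identical(plantedSites(a), plantedSites(b))
  expect_identical(as.character(worldPromoters(a)),
                   as.character(worldPromoters(b)))
  expect_identical(lapply(worldMatrices(a), function(l)
    lapply(l, pssmCounts)), lapply(worldMatrices(b), function(l)
      lapply(l, pssmCounts)))
  c <- generateWorld(nGenes = 30, nTfs = 4, promoterLen = 120, seed = 2)
  expect_false(identical(as.character(worldPromoters(a)),
                         as.character(worldPromoters(c))))
})

test_that("world invariants hold: site bounds, matrix counts, self-sites", {
  w <- smallWorld()
  ps <- plantedSites(w)
  L <- Biostrings::width(worldPromoters(w))[1]
  expect_true(all(ps$start >= 1 & ps$end <= L))
  expect_true(all(ps$end - ps$start + 1 ==
                    nchar(ps$site)))
  nmat <- lengths(worldMatrices(w))
  expect_true(all(nmat >= 1 & nmat <= 5))
  # every gene has a planted self-site in its own promoter
  selfSites <- ps[ps$tf == ps$target, ]
  expect_setequal(selfSites$target, worldGenes(w))
  # truth edge count equals the sum of regulon sizes
  truth <- truthNetwork(w)
  regSizes <- table(truth$tf)
  expect_equal(nrow(truth), sum(regSizes))
  expect_true(all(truth$tf %in% worldTfs(w)))
})

test_that("planted sites are written into the promoters verbatim", {
  w <- smallWorld()
  ps <- plantedSites(w)
  proms <- as.character(worldPromoters(w))
  for (r in seq_len(min(nrow(ps), 25))) {
    sub <- substr(proms[[ps$target[r]]], ps$start[r], ps$end[r])
    want <- if (ps$strand[r] == "D") ps$site[r] else revComp(ps$site[r])
    expect_equal(sub, want)
  }
})

test_that("sampled site letter frequencies match the generating matrix (chi-square)", {
  w <- smallWorld()
  tf <- worldTfs(w)[1]
  pr <- worldMotifProbs(w)[[tf]]
  n <- 600
  sites <- proTRN:::.withSeed(99, {
    replicate(n, proTRN:::.sampleSite(pr))
  })
  # pooled goodness of fit over columns
  stat <- 0; df <- 0
  for (j in seq_len(ncol(pr))) {
    obs <- tabulate(sites[j, ], nbins = 4)
    exp <- n * pr[, j]
    keep <- exp > 1e-9
    stat <- stat + sum((obs[keep] - exp[keep])^2 / exp[keep])
    df <- df + sum(keep) - 1
  }
  expect_gt(stats::pchisq(stat, df, lower.tail = FALSE), 0.01)
})

test_that("profile overlap behaves at the boundaries and binomially in between", {
  w <- generateWorld(nGenes = 60, nTfs = 5, promoterLen = 100, seed = 21)
  all1 <- generateProfiles(w, overlap = 1)
  p1 <- profileLoci(all1)
  expect_identical(p1[[1]], p1[[2]])
  all0 <- generateProfiles(w, overlap = 0, tfRate = 0)
  p0 <- profileLoci(all0)
  expect_length(intersect(p0[[1]], p0[[2]]), 0)
  expect_error(generateProfiles(w, overlap = 1.2), "overlap")
  # binomial check at overlap 0.5 on a large world
  big <- generateWorld(nGenes = 1005, nTfs = 5, promoterLen = 60,
                       motifWidth = 12, seed = 22)
  prof <- worldProfiles(generateProfiles(big, overlap = 0.5, tfRate = 0))
  shared <- length(intersect(prof[[1]]$loci, prof[[2]]$loci))
  nNonTf <- 1000
  sigma <- sqrt(nNonTf * 0.25)
  expect_lt(abs(shared - 0.5 * nNonTf), 3 * sigma)
})

test_that("planted KO multiplicity groups are recovered exactly", {
  w <- smallWorld()  # 3 planted multiplicity groups, 2 identical KOs
  iso <- detectIsoenzymes(w, worldKoMap(w))
  counts <- multiplicityCounts(iso)
  expect_equal(counts$inclusive, 3)
  # the planted identical-locus KOs (K9 prefix) classify identical and are
  # excluded from the multiplicity count
  plantedIdentical <- grep("^K9", iso$ko)
  expect_length(plantedIdentical, 2)
  expect_true(all(iso$multiplicity_class[plantedIdentical] == "identical"))
  expect_false(any(counts$groups$multiplicity_class == "identical"))
  # zero requested groups -> none detected
  w0 <- generateWorld(nGenes = 40, nTfs = 5, promoterLen = 150, seed = 3)
  w0 <- generateProfiles(w0, overlap = 0.6)
  w0 <- generateKoMap(w0, nMultiplicityGroups = 0, nIdentical = 0)
  iso0 <- detectIsoenzymes(w0, worldKoMap(w0))
  expect_equal(multiplicityCounts(iso0)$inclusive, 0)
  # infeasible request errors
  expect_error(generateKoMap(w0, nMultiplicityGroups = 1000), "not enough")
})

test_that("a world round-trips through its external file formats", {
  w <- smallWorld()
  dir <- withr::local_tempdir()
  writeWorld(w, dir)
  back <- readWorld(dir)
  expect_identical(as.character(back$promoters),
                   as.character(worldPromoters(w)))
  expect_identical(sort(names(back$matrices)), sort(worldGenes(w)))
  orig <- worldMatrices(w)
  for (g in worldGenes(w)) {
    expect_equal(lapply(back$matrices[[g]], pssmCounts),
                 lapply(orig[[g]], pssmCounts))
  }
  expect_equal(back$truthNetwork[order(back$truthNetwork$tf,
                                       back$truthNetwork$target), ],
               truthNetwork(w), ignore_attr = TRUE)
  expect_identical(lapply(back$profiles, `[[`, "loci"), profileLoci(w))
  expect_setequal(paste(back$koMap$locus, back$koMap$ko),
                  paste(worldKoMap(w)$locus, worldKoMap(w)$ko))
})
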