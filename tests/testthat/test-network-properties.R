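test_that("canonical triads are classified correctly", {
  ffl <- igraph::graph_from_literal(A -+ B, A -+ C, B -+ C)
  expect_equal(countMotifs(ffl, "ffl"), 1)
  expect_equal(countMotifs(ffl, "fbl3"), 0)
  expect_equal(countMotifs(ffl, "complex_ffl"), 0)
  cyc <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A)
  expect_equal(countMotifs(cyc, "fbl3"), 1)
  expect_equal(countMotifs(cyc, "ffl"), 0)
  # an FFL with one extra internal edge is complex (and still an FFL)
  cffl <- igraph::graph_from_literal(A -+ B, A -+ C, B -+ C, C -+ B)
  expect_equal(countMotifs(cffl, "ffl"), 1)
  expect_equal(countMotifs(cffl, "complex_ffl"), 1)
  # self-loops are ignored for triads
  loop <- igraph::graph_from_literal(A -+ B, A -+ C, B -+ C, A -+ A)
  expect_equal(countMotifs(loop, "ffl"), 1)
})

test_that("the census equals brute-force triple enumeration on random digraphs", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(10:25, 1)
    m <- sample(2 * n + 0:n, 1)
    g <- igraph::sample_gnm(n, m, directed = TRUE)
    got <- motifCensus(g)
    want <- bruteTriads(g)
    expect_equal(got, want)
  }
})

test_that("motif counts are invariant under node relabeling", {
  set.seed(43)
  g <- igraph::sample_gnm(15, 50, directed = TRUE)
  base <- motifCensus(g)
  for (rep in 1:3) {
    perm <- sample(15)
    expect_equal(motifCensus(igraph::permute(g, perm)), base)
  }
})

test_that("potential-motif normalisation follows the closed form", {
  expect_equal(potentialMotifs(3, 3, 3, 3), 6)
  expect_equal(potentialMotifs(10, 3, 4, 2), 115.2)
  expect_equal(potentialMotifs(10, 3, 0, 3), 0)
  expect_error(potentialMotifs(2, 3, 1, 2), "n >= r")
  expect_error(potentialMotifs(5, 3, 6, 2), "TFn")
})

test_that("property profiles match closed forms on toy graphs", {
  # directed 3-cycle of regulators
  cyc <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A)
  p <- propertyProfile(cyc)
  expect_equal(unname(p["regulators_frac"]), 1)
  expect_equal(unname(p["fbl3_norm"]), 1 / 6)
  expect_equal(unname(p["giant_component_frac"]), 1)
  expect_equal(unname(p["self_reg_frac"]), 0)
  expect_equal(unname(p["diameter_norm"]), 1)  # diameter 2 > n-2, clamped
  # star: one TF regulating n-1 targets
  n <- 8
  edges <- data.frame(from = "T", to = sprintf("G%d", 1:(n - 1)))
  star <- igraph::graph_from_data_frame(edges)
  ps <- propertyProfile(star)
  expect_equal(unname(ps["max_out_frac"]), (n - 1) / n)
  expect_equal(unname(ps["giant_component_frac"]), 1)
  expect_equal(unname(ps["regulators_frac"]), 1 / n)
  expect_equal(unname(ps["avg_shortest_path"]), 1)
  expect_error(propertyProfile(igraph::make_empty_graph(5)), "edge")
  expect_error(propertyProfile(igraph::graph_from_literal(A -+ B)), "nodes")
})

test_that("the robust fit is exact on an exact power law and errors on degenerate input", {
  k <- 1:10
  y <- 0.3 * k^-2
  fit <- proTRN:::.robustLogLogFit(k, y)
  expect_equal(fit$exponent, -2, tolerance = 1e-9)
  expect_equal(fit$r2adj, 1, tolerance = 1e-9)
  # uniform degree sequence: fewer than 3 distinct degrees
  g <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A)
  expect_error(fitDegreeLaw(g, "pk"), "distinct")
})

test_that("the MLE recovers a planted degree exponent", {
  set.seed(47)
  # draw degrees directly from a discrete power law with alpha = 2.5
  kk <- sample(1:1000, 4000, replace = TRUE,
               prob = (1:1000)^(-2.5) / sum((1:1000)^(-2.5)))
  alpha <- proTRN:::.discretePowerLawMle(kk)
  expect_lt(abs(alpha - 2.5), 0.2)
  # and end to end on a configuration-model graph with that degree sequence
  degs <- sample(1:50, 500, replace = TRUE,
                 prob = (1:50)^(-2.5) / sum((1:50)^(-2.5)))
  if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1
  g <- igraph::sample_degseq(degs, method = "configuration")
  g <- igraph::as_directed(igraph::simplify(g), mode = "arbitrary")
  fit <- fitDegreeLaw(g, "pk", method = "mle")
  expect_lt(abs(-fit$exponent - 2.5), 0.6)
})

test_that("ER ensembles have exact edge counts and are seed-reproducible", {
  ens <- erEnsemble(n = 30, m = 90, reps = 25, seed = 5)
  expect_length(ens, 25)
  expect_true(all(vapply(ens, igraph::ecount, 1) == 90))
  expect_true(all(vapply(ens, igraph::vcount, 1) == 30))
  ens2 <- erEnsemble(n = 30, m = 90, reps = 25, seed = 5)
  expect_identical(lapply(ens, igraph::as_edgelist),
                   lapply(ens2, igraph::as_edgelist))
  expect_error(erEnsemble(5, 100, reps = 2), "exceeds")
  # mean regulator fraction approaches the binomial expectation
  ens3 <- erEnsemble(n = 40, m = 120, reps = 200, seed = 9)
  fr <- vapply(ens3, function(g)
    mean(igraph::degree(g, mode = "out") > 0), 1)
  expected <- 1 - (1 - 120 / (40 * 39))^39
  expect_lt(abs(mean(fr) - expected), 3 * stats::sd(fr) / sqrt(200) + 0.01)
})

test_that("min-max scaling and profile comparison behave as defined", {
  set.seed(51)
  nets <- lapply(1:5, function(i) igraph::sample_gnm(25, 70, directed = TRUE))
  profs <- lapply(nets, propertyProfile)
  cmp <- compareNetworks(profs, labels = sprintf("N%d", 1:5))
  expect_true(all(cmp$scaled >= 0 & cmp$scaled <= 1))
  nonConst <- apply(cmp$raw, 2, function(v) diff(range(v)) > 0)
  for (j in which(nonConst)) {
    expect_equal(min(cmp$scaled[, j]), 0)
    expect_equal(max(cmp$scaled[, j]), 1)
  }
  # constant columns map to zero
  expect_true(all(cmp$scaled[, !nonConst] == 0))
  # identical profiles correlate perfectly at zero dendrogram height
  two <- compareNetworks(list(profs[[1]], profs[[1]]), labels = c("a", "b"))
  expect_equal(unname(two$correlation["a", "b"]), 1)
  expect_equal(max(two$networkDendrogram$height), 0)
  expect_error(compareNetworks(profs[1]), "at least two")
})

test_that("planted networks self-regulate more than their ER nulls", {
  w <- smallWorld()
  net <- buildNetwork(worldProfiles(w)[["MM"]], worldPromoters(w),
                      worldMatrices(w), condition = "MM")
  p <- propertyProfile(regGraph(net))
  n <- attr(p, "n"); m <- attr(p, "m")
  ens <- erEnsemble(n, min(m, n * (n - 1)), reps = 50, seed = 7)
  erSelf <- vapply(ens, function(g) sum(igraph::which_loop(g)) /
                     igraph::vcount(g), 1)
  expect_gt(unname(p["self_reg_frac"]), mean(erSelf))
  expect_gt(unname(p["self_reg_frac"]), 0)
})
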