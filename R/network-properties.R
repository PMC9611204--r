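# Structural network properties: triad motif census, potential-motif
# normalisation, the 13-property profile, degree-law fits, Erdos-Renyi
# null ensembles, and min-max scaled Ward/correlation comparison.

PROPERTY_NAMES <- c(
  "regulators_frac", "self_reg_frac", "max_out_frac",
  "giant_component_frac", "density_x_regfrac", "ffl_norm",
  "complex_ffl_norm", "fbl3_norm", "avg_shortest_path", "diameter_norm",
  "avg_clustering", "r2adj_pk", "r2adj_ck")

.asIgraph <- function(net) {
  if (is(net, "RegNetwork")) regGraph(net) else net
}

# Adjacency (logical, self-loops dropped) of a directed graph.
.adjNoLoops <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  diag(A) <- FALSE
  A
}

#' Count three-node motifs
#'
#' Classifies each unordered node triple by its internal edges (self-loops
#' ignored). A triple is a 3-feedback loop (`fbl3`) if its nodes carry a
#' directed 3-cycle. A feedforward loop (`ffl`) is a triple with edges
#' X->Y, Y->Z, X->Z and no 3-cycle; a complex feedforward loop
#' (`complex_ffl`) is an FFL triple carrying at least one edge beyond the
#' three defining ones. Each triple is counted once.
#'
#' @param net a [RegNetwork-class] or directed [igraph::igraph].
#' @param kind `"ffl"`, `"complex_ffl"` or `"fbl3"`.
#' @return integer count.
#' @examples
#' g <- igraph::graph_from_literal(A -+ B, A -+ C, B -+ C)
#' countMotifs(g, "ffl")
#' @export
countMotifs <- function(net, kind = c("ffl", "complex_ffl", "fbl3")) {
  kind <- match.arg(kind)
  cen <- motifCensus(net)
  cen[[kind]]
}

#' Census of FFL, complex-FFL and 3-feedback-loop triples
#'
#' Every qualifying triple has all three node pairs connected, so the
#' candidates are exactly the triangles of the undirected skeleton; each
#' triangle is then classified from its six possible directed edges.
#'
#' @param net a [RegNetwork-class] or directed [igraph::igraph].
#' @return list with integer counts `ffl`, `complex_ffl`, `fbl3`.
#' @export
motifCensus <- function(net) {
  g <- .asIgraph(net)
  n <- igraph::vcount(g)
  if (n < 3L || igraph::ecount(g) < 3L)
    return(list(ffl = 0L, complex_ffl = 0L, fbl3 = 0L))
  A <- .adjNoLoops(g)
  gu <- igraph::graph_from_adjacency_matrix(A | t(A), mode = "undirected")
  tri <- igraph::triangles(gu)
  if (!length(tri)) return(list(ffl = 0L, complex_ffl = 0L, fbl3 = 0L))
  tm <- matrix(as.integer(tri), nrow = 3)
  i <- tm[1, ]; j <- tm[2, ]; k <- tm[3, ]
  e1 <- A[cbind(i, j)]; e2 <- A[cbind(j, i)]
  e3 <- A[cbind(i, k)]; e4 <- A[cbind(k, i)]
  e5 <- A[cbind(j, k)]; e6 <- A[cbind(k, j)]
  cyc <- (e1 & e5 & e4) | (e3 & e6 & e2)
  isFfl <- !cyc & (
    (e1 & e5 & e3) | (e3 & e6 & e1) | (e2 & e3 & e5) |
    (e5 & e4 & e2) | (e4 & e1 & e6) | (e6 & e2 & e4))
  nEdges <- e1 + e2 + e3 + e4 + e5 + e6
  list(ffl = sum(isFfl),
       complex_ffl = sum(isFfl & nEdges > 3L),
       fbl3 = sum(cyc))
}

#' Number of potential three-node motifs in a network
#'
#' The normalisation constant for motif counts:
#' `n!/(n-r)! * (TFn/n)^TFm`, i.e. the number of ordered node r-tuples
#' times the probability that the required number of slots are regulators.
#' `TFm` is 3 for 3-feedback loops and 2 for (complex) feedforward loops.
#' `0^TFm` is defined as 0 for `TFn = 0`.
#'
#' @param n node count, `n >= r`.
#' @param r motif size (default 3).
#' @param TFn regulator count, `0 <= TFn <= n`.
#' @param TFm regulators required per motif instance.
#' @return numeric(1).
#' @examples
#' potentialMotifs(10, 3, 4, 2) # 720 * 0.16 = 115.2
#' @export
potentialMotifs <- function(n, r = 3, TFn, TFm) {
  if (n < r || r < 1) stop("need n >= r >= 1")
  if (TFn < 0 || TFn > n) stop("need 0 <= TFn <= n")
  perms <- prod(seq(n, n - r + 1))
  frac <- if (TFn == 0 && TFm >= 1) 0 else (TFn / n)^TFm
  perms * frac
}

#' Fit a power law to the degree distribution or clustering spectrum
#'
#' For `which = "pk"` the fitted quantity is the empirical probability
#' `P(k)` of each positive total degree; for `which = "ck"` it is the mean
#' local clustering coefficient `C(k)` of nodes of degree `k` (undirected
#' simplification). `method = "robust"` performs an iteratively-reweighted
#' linear fit of `log10 y` on `log10 k` (Huber M-estimation) and reports
#' the adjusted coefficient of determination
#' `R2adj = 1 - (1 - R2) (N - 1)/(N - 2)`. `method = "mle"` estimates the
#' discrete power-law exponent by maximum likelihood (`xmin = 1`); the
#' `r2adj` reported alongside it still comes from the robust fit.
#'
#' @param net a [RegNetwork-class] or [igraph::igraph].
#' @param which `"pk"` or `"ck"`.
#' @param method `"robust"` or `"mle"`.
#' @param degreeMode degree used for `P(k)`: `"all"` (default), `"in"` or
#'   `"out"`.
#' @return list with `exponent` (slope; negative for a decaying law) and
#'   `r2adj`.
#' @export
fitDegreeLaw <- function(net, which = c("pk", "ck"),
                         method = c("robust", "mle"),
                         degreeMode = c("all", "in", "out")) {
  which <- match.arg(which)
  method <- match.arg(method)
  degreeMode <- match.arg(degreeMode)
  g <- .asIgraph(net)
  deg <- igraph::degree(g, mode = degreeMode, loops = FALSE)
  if (which == "pk") {
    tab <- table(deg[deg > 0])
    k <- as.numeric(names(tab))
    y <- as.numeric(tab) / sum(tab)
  } else {
    gu <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
    cc <- igraph::transitivity(gu, type = "local", isolates = "zero")
    ks <- igraph::degree(gu)
    keep <- ks > 0
    agg <- tapply(cc[keep], ks[keep], mean)
    k <- as.numeric(names(agg))
    y <- as.numeric(agg)
    pos <- y > 0
    k <- k[pos]; y <- y[pos]
  }
  fit <- .robustLogLogFit(k, y)
  exponent <- fit$exponent
  if (method == "mle") {
    if (which == "ck")
      stop("maximum-likelihood fitting applies to the degree distribution only")
    exponent <- -.discretePowerLawMle(deg[deg > 0])
  }
  list(exponent = exponent, r2adj = fit$r2adj)
}

# Huber-robust linear fit of log10 y on log10 k with adjusted R2.
.robustLogLogFit <- function(k, y) {
  if (length(unique(k)) < 3L)
    stop("fewer than 3 distinct degree values with positive mass: fit undefined")
  lx <- log10(k); ly <- log10(y)
  rfit <- MASS::rlm(ly ~ lx, maxit = 100)
  res <- ly - stats::fitted(rfit)
  r2 <- 1 - sum(res^2) / sum((ly - mean(ly))^2)
  N <- length(ly)
  list(exponent = unname(stats::coef(rfit)[2]),
       r2adj = 1 - (1 - r2) * (N - 1) / (N - 2))
}

# Discrete power-law exponent alpha (P(k) ~ k^-alpha, xmin = 1) by maximum
# likelihood; the zeta normalisation uses a truncated sum with an integral
# tail correction.
.discretePowerLawMle <- function(kk) {
  slog <- sum(log(kk))
  n <- length(kk)
  negll <- function(a) {
    K <- 10000
    z <- sum((1:K)^(-a)) + K^(1 - a) / (a - 1)
    a * slog + n * log(z)
  }
  stats::optimize(negll, c(1.01, 8))$minimum
}

#' The 13 normalized structural properties of a directed network
#'
#' Computes: fraction of regulators (out-connectivity > 0), fraction of
#' self-regulations, maximum out-connectivity over n, weakly-connected
#' giant component fraction, density times regulator fraction, FFL /
#' complex-FFL / 3-feedback-loop counts normalised by the potential-motif
#' number, average directed shortest path over reachable ordered pairs,
#' diameter normalised by (n - 2) and clamped at 1, average clustering
#' coefficient of the undirected simplification, and the adjusted R2 of
#' the robust power-law fits to P(k) and C(k) (0 when the fit is
#' undefined, i.e. no power-law signal to speak of).
#'
#' @param net a [RegNetwork-class] or directed [igraph::igraph] with at
#'   least 3 nodes and 1 edge.
#' @param label optional network label attached as attribute.
#' @return named numeric vector of the 13 properties, with attributes
#'   `n`, `m`, `TFn` and `label`.
#' @export
propertyProfile <- function(net, label = NULL) {
  g <- .asIgraph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n < 3L) stop("property profile requires at least 3 nodes")
  if (m < 1L) stop("property profile requires at least 1 edge")
  kout <- igraph::degree(g, mode = "out", loops = TRUE)
  TFn <- sum(kout > 0)
  selfLoops <- sum(igraph::which_loop(g))
  density <- m / (n * (n - 1))
  comp <- igraph::components(g, mode = "weak")
  census <- motifCensus(g)
  potFfl <- potentialMotifs(n, 3, TFn, 2)
  potFbl <- potentialMotifs(n, 3, TFn, 3)
  dists <- igraph::distances(g, mode = "out")
  finite <- is.finite(dists) & dists > 0
  avgPath <- if (any(finite)) mean(dists[finite]) else 0
  diam <- if (any(finite)) max(dists[finite]) else 0
  gu <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  avgCc <- igraph::transitivity(gu, type = "localaverage", isolates = "zero")
  r2pk <- tryCatch(fitDegreeLaw(g, "pk", "robust")$r2adj,
                   error = function(e) 0)
  r2ck <- tryCatch(fitDegreeLaw(g, "ck", "robust")$r2adj,
                   error = function(e) 0)
  vals <- c(
    regulators_frac = TFn / n,
    self_reg_frac = selfLoops / n,
    max_out_frac = max(kout) / n,
    giant_component_frac = max(comp$csize) / n,
    density_x_regfrac = density * (TFn / n),
    ffl_norm = if (potFfl > 0) census$ffl / potFfl else 0,
    complex_ffl_norm = if (potFfl > 0) census$complex_ffl / potFfl else 0,
    fbl3_norm = if (potFbl > 0) census$fbl3 / potFbl else 0,
    avg_shortest_path = avgPath,
    diameter_norm = min(diam / (n - 2), 1),
    avg_clustering = avgCc,
    r2adj_pk = r2pk,
    r2adj_ck = r2ck)
  attr(vals, "n") <- n
  attr(vals, "m") <- m
  attr(vals, "TFn") <- TFn
  attr(vals, "label") <- label
  vals
}

#' Erdos-Renyi G(n, m) null ensemble
#'
#' Uniform random simple directed graphs (no self-loops, no multi-edges)
#' with exactly `n` nodes and `m` edges, matching the node and edge counts
#' of a biological network. Reproducible under `seed`.
#'
#' @param n node count.
#' @param m edge count, at most `n (n - 1)`.
#' @param reps number of replicates (default 1000).
#' @param seed integer seed.
#' @return list of directed [igraph::igraph] objects.
#' @export
erEnsemble <- function(n, m, reps = 1000, seed = 1L) {
  if (m > n * (n - 1)) stop("m exceeds the number of possible directed edges")
  if (reps < 1L) stop("reps must be positive")
  .withSeed(as.integer(seed), {
    lapply(seq_len(reps), function(i)
      igraph::sample_gnm(n, m, directed = TRUE, loops = FALSE))
  })
}

#' Min-max scale, cluster and correlate property profiles
#'
#' Scales each property across networks to \[0, 1\] (a constant property
#' maps to all zeros), clusters networks and properties with Ward's method
#' on Euclidean distances, and computes the pairwise Pearson correlation
#' matrix of the profiles (scaled profiles by default).
#'
#' @param profiles list of [propertyProfile()] vectors (>= 2).
#' @param labels optional network labels (defaults to profile labels or
#'   `net1`, `net2`, ...).
#' @param correlateScaled correlate scaled (default) or raw profiles.
#' @return list with `raw` and `scaled` (networks x properties matrices),
#'   `networkDendrogram` and `propertyDendrogram` (hclust, Ward), and
#'   `correlation` (networks x networks Pearson matrix).
#' @export
compareNetworks <- function(profiles, labels = NULL,
                            correlateScaled = TRUE) {
  if (length(profiles) < 2L) stop("need at least two profiles")
  if (is.null(labels)) {
    labels <- vapply(seq_along(profiles), function(i) {
      lb <- attr(profiles[[i]], "label")
      if (is.null(lb)) sprintf("net%d", i) else lb
    }, "")
  }
  raw <- do.call(rbind, lapply(profiles, as.numeric))
  colnames(raw) <- PROPERTY_NAMES
  rownames(raw) <- labels
  scaled <- apply(raw, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  })
  rownames(scaled) <- labels
  netH <- stats::hclust(stats::dist(scaled), method = "ward.D2")
  propH <- stats::hclust(stats::dist(t(scaled)), method = "ward.D2")
  base <- if (correlateScaled) scaled else raw
  cmat <- suppressWarnings(stats::cor(t(base)))
  cmat[!is.finite(cmat)] <- 1
  list(raw = raw, scaled = scaled, networkDendrogram = netH,
       propertyDendrogram = propH, correlation = cmat)
}
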