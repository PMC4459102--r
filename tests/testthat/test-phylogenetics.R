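test_that("alignment masking removes excluded regions, gap columns and low-coverage columns", {
  set.seed(71)
  aln <- matrix(sample(c("A", "C", "G", "T"), 4 * 20, replace = TRUE),
                4, 20, dimnames = list(c("w", "x", "y", "z"), NULL))
  full <- maskAlignment(aln)
  expect_equal(full$nRetained, 20)

  gappy <- aln
  gappy[2, 8] <- "-"
  expect_equal(maskAlignment(gappy)$nRetained, 19)
  expect_false(8 %in% maskAlignment(gappy)$retainedColumns)

  # 20 columns, a 5-column excluded region, 1 gap column elsewhere -> 14
  res <- maskAlignment(gappy,
                       excludeRegions = data.frame(start = 0, end = 5))
  expect_equal(res$nRetained, 14)

  # ancient-taxon coverage mask at the 3-fold threshold
  cov <- rep(5L, 20); cov[15:16] <- 2L
  res2 <- maskAlignment(aln, coverageMasks = list(ancient = cov))
  expect_equal(res2$nRetained, 18)

  expect_error(maskAlignment(aln, excludeRegions = data.frame(start = 0,
                                                              end = 25)),
               "out of")
})

test_that("pruning likelihood reduces to stationary frequencies at zero branch length", {
  m <- PhyloModel(baseFreqs = c(A = 0.4, C = 0.1, G = 0.2, T = 0.3),
                  nCategories = 1, gammaShape = 1)
  tr <- ape::read.tree(text = "(a:0,b:0);")
  aln <- matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(gtrGammaLogLik(aln, tr, m), log(0.4))
})

test_that("two-taxon JC likelihood matches the closed form", {
  jc <- PhyloModel(nCategories = 1, gammaShape = 1)
  t <- 0.2
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
  same <- matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL))
  diff <- matrix(c("A", "G"), 2, 1, dimnames = list(c("a", "b"), NULL))
  p_same <- 0.25 * (0.25 + 0.75 * exp(-4 * t / 3))
  p_diff <- 0.25 * (0.25 - 0.25 * exp(-4 * t / 3))
  expect_equal(gtrGammaLogLik(same, tr, jc), log(p_same), tolerance = 1e-8)
  expect_equal(gtrGammaLogLik(diff, tr, jc), log(p_diff), tolerance = 1e-8)
})

test_that("pruning equals brute-force summation over internal states", {
  skip_if_not_installed("Matrix")
  set.seed(72)
  tr <- ape::rtree(4, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  m <- PhyloModel(rates = c(AC = 1.5, AG = 3, AT = 0.7, CG = 1.2,
                            CT = 4, GT = 1),
                  baseFreqs = c(A = 0.35, C = 0.15, G = 0.2, T = 0.3),
                  gammaShape = 0.6, nCategories = 3, pInvariant = 0.15)
  aln <- simulateAlignmentOnTree(tr, m, 10, seed = 73)
  expect_equal(gtrGammaLogLik(aln, tr, m), loglik_oracle(aln, tr, m),
               tolerance = 1e-6)
})

test_that("likelihood is invariant to the root placement (pulley principle)", {
  set.seed(74)
  tr <- ape::rtree(6, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.3)
  m <- PhyloModel(gammaShape = 0.3366, nCategories = 5, pInvariant = 0.1)
  aln <- simulateAlignmentOnTree(tr, m, 300, seed = 75)
  ll <- gtrGammaLogLik(aln, tr, m)
  for (og in tr$tip.label[1:3]) {
    rerooted <- ape::root(tr, outgroup = og, resolve.root = FALSE)
    expect_equal(gtrGammaLogLik(aln, rerooted, m), ll, tolerance = 1e-8)
  }
})

test_that("GTR generator satisfies detailed balance and P(t) is stochastic", {
  m <- PhyloModel(rates = c(AC = 2, AG = 5, AT = 1, CG = 0.5, CT = 6,
                            GT = 1.3),
                  baseFreqs = c(A = 0.31, C = 0.18, G = 0.22, T = 0.29))
  Q <- gtrRateMatrix(m)
  pi <- m@baseFreqs
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pi * Q, t(pi * Q), tolerance = 1e-12)  # pi_i Q_ij = pi_j Q_ji
  expect_equal(sum(pi * -diag(Q)), 1, tolerance = 1e-12)
  eig <- ancientMito:::gtrEigen(m)
  for (t in c(0, 0.01, 0.5, 10)) {
    P <- ancientMito:::gtrTransition(eig, t)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("gamma category rates have mean one, also after the +I adjustment", {
  r <- gammaCategoryRates(0.3366, 5)
  expect_equal(mean(r), 1, tolerance = 1e-10)
  expect_true(all(diff(r) > 0))
  m <- PhyloModel(gammaShape = 0.3366, nCategories = 5, pInvariant = 0.3)
  radj <- ancientMito:::modelRates(m)
  expect_equal(0.3 * 0 + 0.7 * mean(radj), 1, tolerance = 1e-10)
})

test_that("Fitch parsimony matches enumeration and is invariant to rooting and order", {
  # identical sequences need no steps
  same <- matrix("A", 4, 5, dimnames = list(letters[1:4], NULL))
  tr4 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(fitchParsimony(same, tr4)$steps, 0)

  # one AACC site: 1 step on the matching topology, 2 on the others
  site <- matrix(c("A", "A", "C", "C"), 4, 1,
                 dimnames = list(letters[1:4], NULL))
  tops <- list(ab = ape::read.tree(text = "((a,b),(c,d));"),
               ac = ape::read.tree(text = "((a,c),(b,d));"),
               ad = ape::read.tree(text = "((a,d),(b,c));"))
  steps <- vapply(tops, function(t) fitchParsimony(site, t)$steps,
                  numeric(1))
  expect_equal(unname(steps), c(1, 2, 2))

  # random 6-taxon alignments match the exhaustive minimum
  set.seed(76)
  tr6 <- ape::rtree(6, rooted = FALSE)
  aln6 <- matrix(sample(c("A", "C", "G", "T"), 6 * 8, replace = TRUE), 6, 8,
                 dimnames = list(tr6$tip.label, NULL))
  fp <- fitchParsimony(aln6, tr6, perBranch = TRUE)
  expect_equal(fp$steps, parsimony_oracle(aln6, tr6))
  expect_equal(sum(fp$branchSteps), fp$steps)

  # root placement and taxon order do not change the score
  expect_equal(fitchParsimony(aln6, ape::root(tr6, "t1",
                                              resolve.root = TRUE))$steps,
               fp$steps)
  expect_equal(fitchParsimony(aln6[sample(6), ], tr6)$steps, fp$steps)
})

test_that("4-taxon searches find the exhaustive optimum for both criteria", {
  set.seed(77)
  true <- ape::read.tree(text = "((a:0.05,b:0.05):0.08,(c:0.05,d:0.05):0.08);")
  m <- PhyloModel(gammaShape = 1, nCategories = 2)
  aln <- simulateAlignmentOnTree(ape::unroot(true), m, 2000, seed = 78)
  tops <- list(ape::unroot(ape::read.tree(text = "((a,b),(c,d));")),
               ape::unroot(ape::read.tree(text = "((a,c),(b,d));")),
               ape::unroot(ape::read.tree(text = "((a,d),(b,c));")))
  # MP: searched tree achieves the minimum over all 3 topologies
  mp <- searchTree(aln, m, "MP")
  mp_scores <- vapply(tops, function(t) fitchParsimony(aln, t)$steps,
                      numeric(1))
  expect_equal(attr(mp, "objective"), min(mp_scores))
  expect_equal(ape::dist.topo(mp, tops[[which.min(mp_scores)]]), 0,
               ignore_attr = TRUE)
  # ML: likewise under optimized branch lengths
  ml <- searchTree(aln, m, "ML")
  expect_equal(ape::dist.topo(ml, tops[[1]]), 0, ignore_attr = TRUE)
})

test_that("taxon input order does not change the searched topology", {
  set.seed(79)
  true <- ape::rtree(6, rooted = FALSE)
  true$edge.length <- runif(nrow(true$edge), 0.03, 0.12)
  m <- PhyloModel(gammaShape = 1, nCategories = 1)
  aln <- simulateAlignmentOnTree(true, m, 3000, seed = 80)
  t1 <- searchTree(aln, m, "MP")
  t2 <- searchTree(aln[rev(seq_len(nrow(aln))), ], m, "MP")
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap supports behave at the degenerate extremes and reproduce", {
  set.seed(81)
  true <- ape::rtree(6, rooted = FALSE)
  true$edge.length <- runif(nrow(true$edge), 0.05, 0.2)
  m <- PhyloModel(gammaShape = 1, nCategories = 1)
  aln <- simulateAlignmentOnTree(true, m, 1500, seed = 82)

  b1 <- bootstrapTree(aln, m, "MP", nReplicates = 1, seed = 5)
  expect_true(all(attr(b1, "supports") %in% c(0, 100)))

  b <- bootstrapTree(aln, m, "MP", nReplicates = 50, seed = 6)
  internal <- attr(b, "supports")[-1]  # root pseudo-node excluded
  expect_true(all(internal >= 90))     # clean strong signal

  b2 <- bootstrapTree(aln, m, "MP", nReplicates = 50, seed = 6)
  expect_identical(attr(b, "supports"), attr(b2, "supports"))
})

test_that("outgroup rooting is idempotent and invertible", {
  set.seed(83)
  tr <- ape::rtree(6, rooted = FALSE)
  rooted <- rootWithOutgroup(tr, "t3")
  expect_true(ape::is.rooted(rooted))
  # the outgroup attaches at the root
  root_children <- rooted$edge[rooted$edge[, 1] ==
                                 length(rooted$tip.label) + 1, 2]
  expect_true(match("t3", rooted$tip.label) %in% root_children)
  # unrooting recovers the original topology; rooting again is stable
  expect_equal(ape::dist.topo(ape::unroot(rooted), tr), 0,
               ignore_attr = TRUE)
  again <- rootWithOutgroup(rooted, "t3")
  expect_equal(ape::dist.topo(ape::unroot(again), ape::unroot(rooted)), 0,
               ignore_attr = TRUE)
  expect_error(rootWithOutgroup(tr, "nope"), "outgroup")
})

test_that("mismatch counting separates differences from unresolved sites", {
  expect_equal(unname(countMismatches("ACGTN", "ACTTA")), c(1, 4, 1))
  s <- random_seq(80, seed = 84)
  expect_equal(unname(countMismatches(s, s)), c(0, 80, 0))
  expect_error(countMismatches("ACGT", "ACG"), "equal length")
  # gaps are unresolved, not mismatches
  expect_equal(unname(countMismatches("AC-T", "ACGT")), c(0, 3, 1))
})

test_that("annotated regions are recovered by alignment and compared correctly", {
  ref <- simulateReference(3000, 0.4, seed = 85, annotations = data.frame(
    name = c("D-loop", "cytb"), start = c(0L, 1000L), end = c(400L, 2140L)))
  cytb <- decodeFragment(ref, 1000, 2140)
  # a reconstructed genome: cytb with 3 substitutions and 7 N positions
  v <- strsplit(cytb, "")[[1]]
  subs <- c(100, 500, 900)
  for (i in subs) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  v[201:207] <- "N"
  recon <- paste0(strrep("A", 50), paste(v, collapse = ""), strrep("T", 50))
  ext <- extractRegionByAlignment(recon, ref, "cytb")
  counts <- countMismatches(ext$ref, ext$query)
  expect_equal(unname(counts["mismatches"]), 3)
  expect_equal(unname(counts["unresolvedSites"]), 7)

  tab <- pairwiseMismatchMatrix(c(recon_cytb = paste(v, collapse = "")),
                                c(published = cytb))
  expect_equal(tab$mismatches, 3)
  expect_equal(tab$unresolvedSites, 7)
})
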