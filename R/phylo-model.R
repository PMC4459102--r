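# GTR+G+I machinery: rate matrix construction, discrete-gamma rates, and
# sequence simulation along trees (the test harness for the placement code).

#' Discrete gamma category rates
#'
#' Mean-of-quantile discretization: K equal-probability categories of a
#' Gamma(shape, rate = shape) distribution, each represented by its
#' conditional mean, so the category rates average exactly 1.
#'
#' @param alpha gamma shape parameter.
#' @param K number of categories.
#' @return numeric(K) category rates with mean 1.
#' @export
gammaCategoryRates <- function(alpha, K) {
  if (K == 1) return(1)
  b <- qgamma((0:K) / K, shape = alpha, rate = alpha)
  K * (pgamma(b[-1], shape = alpha + 1, rate = alpha) -
       pgamma(b[-(K + 1)], shape = alpha + 1, rate = alpha))
}

# Category rates including the invariant-sites adjustment: variable
# categories are inflated by 1/(1 - pInv) so the overall mean rate is 1.
modelRates <- function(model) {
  gammaCategoryRates(model@gammaShape, as.integer(model@nCategories)) /
    (1 - model@pInvariant)
}

#' GTR rate matrix
#'
#' Builds the reversible generator Q with off-diagonals
#' `rates[ij] * baseFreqs[j]`, scaled so the expected substitution rate at
#' stationarity is 1.
#'
#' @param model a [PhyloModel-class].
#' @return 4x4 rate matrix (rows/cols A, C, G, T).
#' @export
gtrRateMatrix <- function(model) {
  pi <- model@baseFreqs
  r <- model@rates
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  pairs <- rbind(c(1, 2, "AC"), c(1, 3, "AG"), c(1, 4, "AT"),
                 c(2, 3, "CG"), c(2, 4, "CT"), c(3, 4, "GT"))
  for (k in seq_len(nrow(pairs))) {
    i <- as.integer(pairs[k, 1]); j <- as.integer(pairs[k, 2])
    Q[i, j] <- r[pairs[k, 3]] * pi[j]
    Q[j, i] <- r[pairs[k, 3]] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

# Eigen-decomposition of the (reversible) GTR generator in its symmetrized
# form; used to compute transition matrices P(t) = exp(Qt).
gtrEigen <- function(model) {
  Q <- gtrRateMatrix(model)
  pi <- model@baseFreqs
  sq <- sqrt(pi)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / sq) %*% e$vectors,
       left = t(e$vectors) %*% diag(sq))
}

gtrTransition <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an alignment on a tree under GTR+G+I
#'
#' Sites are i.i.d.: each draws a rate category (invariant with probability
#' `pInvariant`, otherwise one of the equal-probability gamma categories),
#' root states come from the stationary frequencies, and states evolve down
#' each branch with the model's transition matrices.
#'
#' @param tree an [ape::phylo] binary tree with branch lengths (in expected
#'   substitutions per site).
#' @param model a [PhyloModel-class].
#' @param nSites number of alignment columns.
#' @param seed integer seed.
#' @return character matrix (taxa x sites) over A/C/G/T with taxon rownames.
#' @export
simulateAlignmentOnTree <- function(tree, model, nSites, seed) {
  if (!ape::is.binary(tree)) stop("tree must be binary")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("branch lengths must be >= 0")
  eig <- gtrEigen(model)
  rates <- modelRates(model)
  K <- length(rates)
  with_seed(seed, {
    cat <- ifelse(runif(nSites) < model@pInvariant, 0L,
                  sample.int(K, nSites, replace = TRUE))
    siteRate <- ifelse(cat == 0L, 0, rates[pmax(cat, 1L)])
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    states <- matrix(0L, nnode, nSites)
    tr <- reorder(tree, "postorder")
    root <- tr$edge[nrow(tr$edge), 1]
    states[root, ] <- sample.int(4, nSites, replace = TRUE,
                                 prob = model@baseFreqs)
    for (k in rev(seq_len(nrow(tr$edge)))) {   # preorder
      par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      len <- tr$edge.length[k]
      states[child, ] <- states[par, ]
      for (g in seq_len(K)) {
        idx <- which(cat == g)
        if (!length(idx)) next
        P <- gtrTransition(eig, len * rates[g])
        from <- states[par, idx]
        for (s in 1:4) {
          sel <- idx[from == s]
          if (length(sel))
            states[child, sel] <- sample.int(4, length(sel), replace = TRUE,
                                             prob = P[s, ])
        }
      }
    }
    aln <- matrix(BASES[states[seq_len(ntip), , drop = FALSE]], ntip, nSites)
    rownames(aln) <- tree$tip.label
    aln
  })
}
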