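# Tree search: distance starting trees (NJ), NNI hill climbing under ML
# (GTR+G+I pruning likelihood) or MP (Fitch), bootstrap supports and
# outgroup rooting.

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites over columns where both sequences are
#' unambiguous A/C/G/T.
#'
#' @param aln character matrix (taxa x sites).
#' @return a `dist` object.
#' @export
pDistance <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  ok <- matrix(aln %in% BASES, n, ncol(aln))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- if (any(use))
      mean(aln[i, use] != aln[j, use]) else 0
  }
  stats::as.dist(d)
}

#' Pairwise log-det (paralinear) distance matrix
#'
#' Consistent under general time-reversible (indeed general Markov)
#' substitution; used for likelihood starting trees. Falls back to adding a
#' small pseudocount when the divergence matrix is singular.
#'
#' @param aln character matrix (taxa x sites).
#' @return a `dist` object.
#' @export
logdetDistance <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- aln[i, ] %in% BASES & aln[j, ] %in% BASES
    F <- unclass(table(factor(aln[i, use], BASES),
                       factor(aln[j, use], BASES))) + 0.1
    F <- F / sum(F)
    val <- -0.25 * (log(det(F)) -
                      0.5 * sum(log(rowSums(F))) -
                      0.5 * sum(log(colSums(F))))
    d[i, j] <- d[j, i] <- max(val, 0)
  }
  stats::as.dist(d)
}

# All nearest-neighbour-interchange neighbours of an unrooted binary tree.
nniNeighbors <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  E <- tree$edge
  internal <- which(E[, 1] > ntip & E[, 2] > ntip)
  out <- list()
  for (k in internal) {
    u <- E[k, 1]; v <- E[k, 2]
    vkids <- which(E[, 1] == v)
    ukids <- setdiff(which(E[, 1] == u), k)
    if (length(vkids) < 2 || length(ukids) < 1) next
    w <- ukids[1]
    for (ck in vkids[1:2]) {
      nt <- tree
      nt$edge[ck, 1] <- u
      nt$edge[w, 1] <- v
      nt <- reorder(nt, "cladewise")
      out[[length(out) + 1]] <- nt
    }
  }
  out
}

# Cycle single-branch Brent optimizations of the edge lengths under the
# pruning likelihood until the improvement falls below `tol`.
optimizeBranchLengths <- function(tree, engine, maxPasses = 5, tol = 1e-4,
                                  upper = 5) {
  ll <- engine(tree)
  for (pass in seq_len(maxPasses)) {
    before <- ll
    for (i in seq_along(tree$edge.length)) {
      f <- function(x) {
        t2 <- tree
        t2$edge.length[i] <- x
        engine(t2)
      }
      opt <- optimize(f, c(1e-8, upper), maximum = TRUE, tol = 1e-6)
      if (opt$objective > ll) {
        tree$edge.length[i] <- opt$maximum
        ll <- opt$objective
      }
    }
    if (ll - before < tol) break
  }
  list(tree = tree, loglik = ll)
}

#' Search for the best tree by NNI hill climbing
#'
#' Builds a neighbour-joining starting tree (log-det distances for ML,
#' p-distances for MP) and improves it by nearest-neighbour interchanges
#' under the chosen objective, accepting the first improving move
#' (deterministic order) until no neighbour improves. ML branch lengths are
#' optimized by cycled single-branch Brent steps; MP edge lengths are set
#' to per-branch Fitch step counts.
#'
#' @param aln character matrix (taxa x sites) or [maskAlignment()] result.
#' @param model a [PhyloModel-class] (ML only).
#' @param method `"ML"` or `"MP"`.
#' @param seed integer seed (recorded; the search itself is deterministic).
#' @return an [ape::phylo] tree (unrooted) with `attr(, "objective")` the
#'   final log-likelihood (ML) or parsimony steps (MP).
#' @export
searchTree <- function(aln, model = PhyloModel(), method = c("ML", "MP"),
                       seed = 1) {
  method <- match.arg(method)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 4) {
    warning("fewer than 4 taxa: returning the trivial tree")
    tr <- ape::stree(n, type = "star", tip.label = rownames(aln))
    tr$edge.length <- rep(0, nrow(tr$edge))
    return(tr)
  }
  d <- if (method == "ML") logdetDistance(aln) else pDistance(aln)
  start <- ape::unroot(ape::nj(d))
  start$edge.length <- pmax(start$edge.length, 1e-6)
  cp <- compressPatterns(aln)

  if (method == "MP") {
    score <- function(t) fitchParsimony(aln, t)$steps
    cur <- start; curScore <- score(cur)
    repeat {
      improved <- FALSE
      for (nb in nniNeighbors(cur)) {
        s <- score(nb)
        if (s < curScore) { cur <- nb; curScore <- s; improved <- TRUE; break }
      }
      if (!improved) break
    }
    fp <- fitchParsimony(aln, cur, perBranch = TRUE)
    cur <- fp$tree
    cur$edge.length <- fp$branchSteps
    attr(cur, "objective") <- fp$steps
    attr(cur, "method") <- "MP"
    return(cur)
  }

  engine <- makeLikEngine(cp$aln, cp$weights, model)
  opt <- optimizeBranchLengths(start, engine)
  cur <- opt$tree; curLL <- opt$loglik
  repeat {
    improved <- FALSE
    for (nb in nniNeighbors(cur)) {
      o <- optimizeBranchLengths(nb, engine, maxPasses = 1)
      if (o$loglik > curLL + 1e-6) {
        o <- optimizeBranchLengths(o$tree, engine)
        cur <- o$tree; curLL <- o$loglik; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  attr(cur, "objective") <- curLL
  attr(cur, "method") <- "ML"
  cur
}

#' Bootstrap supports for a point-estimate tree
#'
#' Resamples alignment columns with replacement, reruns the tree search on
#' each replicate, and reports for every internal edge of the point
#' estimate the percentage of replicates containing the same bipartition.
#'
#' @param aln character matrix (taxa x sites) or [maskAlignment()] result.
#' @param model a [PhyloModel-class].
#' @param method `"ML"` or `"MP"`.
#' @param nReplicates number of bootstrap replicates (default 1000).
#' @param seed integer seed; replicate resampling is reproducible.
#' @param tree optional precomputed point-estimate tree.
#' @return the point-estimate tree with `node.label` set to supports (in
#'   percent) and `attr(, "supports")` the numeric vector.
#' @export
bootstrapTree <- function(aln, model = PhyloModel(),
                          method = c("ML", "MP"), nReplicates = 1000,
                          seed = 1, tree = NULL) {
  method <- match.arg(method)
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  aln <- as_alignment(aln)
  if (is.null(tree)) tree <- searchTree(aln, model, method, seed)
  reps <- lapply(seq_len(nReplicates), function(r) {
    cols <- with_seed(derive_seed(seed, 100 + r),
                      sample.int(ncol(aln), ncol(aln), replace = TRUE))
    searchTree(aln[, cols, drop = FALSE], model, method, seed)
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- 100 * counts / nReplicates
  tree$node.label <- as.character(round(supports))
  attr(tree, "supports") <- supports
  tree
}

#' Root a tree on its outgroup
#'
#' Places the root on the outgroup's pendant edge. Rooting is idempotent
#' and unrooting recovers the original unrooted topology.
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup tip label of the outgroup taxon.
#' @return rooted [ape::phylo] tree.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' not present in the tree")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
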