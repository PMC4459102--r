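# Felsenstein pruning likelihood under GTR+G+I.
#
# Site likelihood = pInv * I(site can be constant) * pi(base)
#                 + (1 - pInv) * mean over gamma categories of the pruned
#                   category likelihood; gaps/N are treated as fully
#                   ambiguous (missing data).

# Compress an alignment (character matrix taxa x sites) into site patterns.
compressPatterns <- function(aln) {
  pat <- apply(aln, 2, paste, collapse = "")
  tab <- table(pat)
  first <- match(names(tab), pat)
  list(aln = aln[, first, drop = FALSE], weights = as.numeric(tab))
}

# Tip likelihood codes: 4 x nsite indicator matrices; non-ACGT = all ones.
tipLikelihood <- function(chars) {
  m <- matrix(0, 4, length(chars))
  for (b in 1:4) m[b, chars == BASES[b]] <- 1
  m[, !(chars %in% BASES)] <- 1
  m
}

# Build a reusable likelihood evaluator for one alignment + model: tip
# indicator matrices, the invariant-site vector and the eigensystem are
# computed once; the returned function re-evaluates only the pruning pass
# for a given tree.
makeLikEngine <- function(aln, weights, model) {
  nsite <- ncol(aln)
  eig <- gtrEigen(model)
  rates <- modelRates(model)
  pInv <- model@pInvariant
  pi <- model@baseFreqs
  tips <- lapply(rownames(aln), function(tx) tipLikelihood(aln[tx, ]))
  names(tips) <- rownames(aln)
  invLik <- vapply(seq_len(nsite), function(j) {
    obs <- aln[, j]
    obs <- obs[obs %in% BASES]
    if (!length(obs)) return(1)
    u <- unique(obs)
    if (length(u) == 1) pi[[u]] else 0
  }, numeric(1))

  function(tree) {
    if (is.null(tree$edge.length) || any(tree$edge.length < 0))
      stop("tree must have non-negative branch lengths")
    tr <- reorder(tree, "postorder")
    ntip <- length(tr$tip.label)
    nnode <- ntip + tr$Nnode
    root <- tr$edge[nrow(tr$edge), 1]
    varLik <- numeric(nsite)
    for (g in seq_along(rates)) {
      acc <- vector("list", nnode)
      for (k in seq_len(nrow(tr$edge))) {
        par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
        P <- gtrTransition(eig, tr$edge.length[k] * rates[g])
        msg <- P %*% (if (child <= ntip) tips[[tr$tip.label[child]]]
                      else acc[[child]])
        acc[[par]] <- if (is.null(acc[[par]])) msg else acc[[par]] * msg
      }
      varLik <- varLik + colSums(pi * acc[[root]])
    }
    varLik <- varLik / length(rates)
    sum(weights * log(pInv * invLik + (1 - pInv) * varLik))
  }
}

#' GTR+G+I log-likelihood by Felsenstein pruning
#'
#' Site likelihood = `pInvariant * I(site can be constant) * pi(base)` plus
#' `(1 - pInvariant)` times the mean over the equal-probability gamma
#' categories of the pruned category likelihood; gaps and N are treated as
#' missing data.
#'
#' @param aln character matrix (taxa x sites) over A/C/G/T/N/-, or the
#'   result of [maskAlignment()] (its retained columns are used).
#' @param tree an [ape::phylo] tree covering all alignment taxa, with
#'   non-negative branch lengths.
#' @param model a [PhyloModel-class].
#' @param weights optional per-column weights (e.g. pattern counts).
#' @return total log-likelihood (sum over sites).
#' @export
gtrGammaLogLik <- function(aln, tree, model, weights = NULL) {
  aln <- as_alignment(aln)
  if (!all(tree$tip.label %in% rownames(aln)))
    stop("alignment missing taxa present in the tree")
  if (is.null(weights)) {
    cp <- compressPatterns(aln)
    aln <- cp$aln; weights <- cp$weights
  }
  makeLikEngine(aln, weights, model)(tree)
}

as_alignment <- function(aln) {
  if (is.list(aln) && !is.null(aln$alignment)) aln <- aln$alignment
  if (is(aln, "DNAStringSet")) {
    aln <- t(vapply(as.character(aln),
                    function(s) strsplit(s, "")[[1]],
                    character(Biostrings::width(aln)[1])))
  }
  if (!is.matrix(aln)) stop("alignment must be a taxa x sites matrix")
  toupper(aln)
}

#' Read a FASTA multiple alignment as a character matrix
#'
#' @param path FASTA file with equal-length aligned sequences.
#' @return character matrix (taxa x sites).
#' @export
readAlignmentFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1) stop("alignment rows must have equal length")
  m <- t(vapply(as.character(x), function(s) strsplit(s, "")[[1]],
                character(w[1])))
  rownames(m) <- names(x)
  toupper(m)
}
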