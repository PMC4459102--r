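# Fitch parsimony with per-branch step counts from one most-parsimonious
# ancestral reconstruction.

# bit codes A=1, C=2, G=4, T=8; anything else fully ambiguous
fitch_code <- function(chars) {
  code <- rep(15L, length(chars))
  code[chars == "A"] <- 1L; code[chars == "C"] <- 2L
  code[chars == "G"] <- 4L; code[chars == "T"] <- 8L
  code
}

#' Fitch parsimony score and per-branch step counts
#'
#' Bottom-up Fitch pass per site (gaps/N fully ambiguous), summed over
#' sites. Per-branch counts come from one most-parsimonious reconstruction:
#' the root takes the lowest-index base in its state set and each child
#' keeps its parent's state when compatible, otherwise the lowest-index
#' base of its own set (a deterministic tie-break).
#'
#' @param aln character matrix (taxa x sites) or [maskAlignment()] result.
#' @param tree an [ape::phylo] topology (branch lengths ignored).
#' @param perBranch logical; also compute per-branch step counts.
#' @return list with `steps` (total), `branchSteps` (numeric per edge of
#'   `reorder(tree, "postorder")`, NULL unless requested) and `tree` (the
#'   postorder tree the counts refer to).
#' @export
fitchParsimony <- function(aln, tree, perBranch = FALSE) {
  aln <- as_alignment(aln)
  if (!all(tree$tip.label %in% rownames(aln)))
    stop("alignment missing taxa present in the tree")
  cp <- compressPatterns(aln)
  pat <- cp$aln; w <- cp$weights
  nsite <- ncol(pat)
  tr <- reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]

  state <- matrix(0L, nnode, nsite)
  for (i in seq_len(ntip)) state[i, ] <- fitch_code(pat[tr$tip.label[i], ])
  steps <- numeric(nsite)
  seen <- logical(nnode)
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    if (!seen[par]) { state[par, ] <- state[child, ]; seen[par] <- TRUE }
    else {
      inter <- bitwAnd(state[par, ], state[child, ])
      un <- bitwOr(state[par, ], state[child, ])
      hit <- inter == 0L
      steps <- steps + as.numeric(hit)
      state[par, ] <- ifelse(hit, un, inter)
    }
  }
  total <- sum(w * steps)

  branchSteps <- NULL
  if (perBranch) {
    # exact per-branch counts from a unit-cost Sankoff pass: bottom-up
    # minimal-cost matrices, then a top-down assignment preferring the
    # parent's state and breaking remaining ties toward the lowest base
    # index (deterministic)
    BIG <- 1e9
    cost <- vector("list", nnode)
    for (i in seq_len(ntip)) {
      code <- fitch_code(pat[tr$tip.label[i], ])
      m <- matrix(BIG, 4, nsite)
      for (b in 1:4) m[b, bitwAnd(code, bitwShiftL(1L, b - 1L)) > 0L] <- 0
      cost[[i]] <- m
    }
    child_contrib <- function(cc) {
      # min over child state t of cost[t] + (t != s), per parent state s
      low <- apply(cc, 2, min)
      pmin_mat <- pmin(cc, rep(low + 1, each = 4) * 1)
      matrix(pmin_mat, 4, ncol(cc))
    }
    for (k in seq_len(nrow(tr$edge))) {
      par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      contrib <- child_contrib(cost[[child]])
      if (is.null(cost[[par]])) cost[[par]] <- contrib
      else cost[[par]] <- cost[[par]] + contrib
    }
    assign_state <- matrix(0L, nnode, nsite)
    assign_state[root, ] <- apply(cost[[root]], 2, which.min)
    branchSteps <- numeric(nrow(tr$edge))
    for (k in rev(seq_len(nrow(tr$edge)))) {   # preorder
      par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      cc <- cost[[child]]
      ps <- assign_state[par, ]
      pcost <- cc[cbind(ps, seq_len(nsite))]
      best <- apply(cc, 2, min)
      takePar <- pcost <= best + 1  # staying costs at most one extra step
      st <- ifelse(takePar, ps, apply(cc, 2, which.min))
      assign_state[child, ] <- st
      branchSteps[k] <- sum(w * (st != ps))
    }
  }
  list(steps = total, branchSteps = branchSteps, tree = tr)
}
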