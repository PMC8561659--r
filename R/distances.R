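#' @include AllClasses.R utils.R feature-table.R
NULL

#' Construct a distance matrix
#'
#' @param m square symmetric numeric matrix (or \code{dist}) with sample
#'   names.
#' @return a validated \linkS4class{DistanceMatrix}.
#' @export
distanceMatrix <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("distance input must be a square symmetric matrix")
  m <- (m + t(m)) / 2                     # absorb round-off asymmetry
  diag(m) <- 0
  new("DistanceMatrix", m)
}

countsFrom <- function(x) {
  if (is(x, "FeatureTable")) t(counts(x)) else as.matrix(x)
}

#' Centred log-ratio transform
#'
#' Per sample, \code{log(count + pseudocount)} minus its mean over taxa,
#' mapping compositions into unconstrained real space.  Scale-invariant:
#' multiplying a zero-free sample by a constant leaves its clr row unchanged
#' (with pseudocount 0).
#'
#' @param x a \linkS4class{FeatureTable} or a samples x taxa matrix.
#' @param pseudocount added to every count before the log; must be positive
#'   when zeros are present.
#' @return samples x taxa real matrix.
#' @export
clrTransform <- function(x, pseudocount = 1) {
  m <- countsFrom(x)
  if (any(rowSums(m) == 0)) stop("zero-sum sample(s): clr undefined")
  if (pseudocount <= 0 && any(m == 0))
    stop("zeros present: a positive pseudocount is required")
  lm_ <- log(m + pseudocount)
  sweep(lm_, 1, rowMeans(lm_), "-")
}

#' Aitchison distance
#'
#' Euclidean distance between clr-transformed samples; the scale-invariant
#' compositional distance.
#'
#' @inheritParams clrTransform
#' @return a \linkS4class{DistanceMatrix}.
#' @export
aitchisonDistance <- function(x, pseudocount = 1) {
  distanceMatrix(dist(clrTransform(x, pseudocount)))
}

# tips x edges incidence: inc[t, e] is TRUE when tip t descends through edge
# e.  Built in postorder so each internal node's tip set is available when
# its parent edge is processed.
edgeTipIncidence <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  ne <- nrow(po$edge)
  nodeTips <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) nodeTips[[i]] <- i
  inc <- matrix(FALSE, nt, ne)
  for (e in seq_len(ne)) {
    child <- po$edge[e, 2]
    inc[nodeTips[[child]], e] <- TRUE
    parent <- po$edge[e, 1]
    nodeTips[[parent]] <- c(nodeTips[[parent]], nodeTips[[child]])
  }
  list(inc = inc, lengths = po$edge.length,
       tipLabels = po$tip.label)
}

presenceMatrix <- function(x, tree) {
  m <- countsFrom(x)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  m > 0
}

#' Unweighted UniFrac distance
#'
#' Presence/absence phylogenetic distance between samples: the branch length
#' leading only to taxa present in exactly one of the two samples, divided by
#' the branch length leading to taxa present in either.  Presence is count
#' greater than zero.  Two samples with no observed taxa are at distance 0.
#'
#' @param x a \linkS4class{FeatureTable} or samples x taxa matrix whose taxa
#'   all appear as tree tips.
#' @param tree rooted \code{phylo} with non-negative branch lengths.
#' @return a \linkS4class{DistanceMatrix}.
#' @export
unweightedUnifrac <- function(x, tree) {
  pres <- presenceMatrix(x, tree)
  et <- edgeTipIncidence(tree)
  tipIdx <- match(colnames(pres), et$tipLabels)
  # edges x samples: does any descendant tip of the edge occur in the sample
  occ <- crossprod(et$inc[tipIdx, , drop = FALSE], t(pres)) > 0
  n <- nrow(pres)
  d <- matrix(0, n, n, dimnames = list(rownames(pres), rownames(pres)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      either <- occ[, i] | occ[, j]
      denom <- sum(et$lengths[either])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else
        sum(et$lengths[xor(occ[, i], occ[, j])]) / denom
    }
  }
  distanceMatrix(d)
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the root and all
#' taxa present in a sample.
#'
#' @param presence logical/numeric vector named by taxon (present when
#'   greater than zero), or a character vector of present taxon names.
#' @param tree rooted \code{phylo}.
#' @return branch-length units.
#' @export
faithPD <- function(presence, tree) {
  present <- if (is.character(presence)) presence
             else names(presence)[presence > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  if (!length(present)) return(0)
  et <- edgeTipIncidence(tree)
  tipIdx <- match(present, et$tipLabels)
  onPath <- colSums(et$inc[tipIdx, , drop = FALSE]) > 0
  sum(et$lengths[onPath])
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: double-centre \eqn{-D^2/2}, eigendecompose, and
#' scale eigenvectors by the square root of their (positive) eigenvalues.
#' Negative eigenvalues are discarded without correction; proportion
#' explained is relative to the positive eigenvalue mass.
#'
#' @param dm a \linkS4class{DistanceMatrix} (or symmetric matrix/dist).
#' @return an \linkS4class{OrdinationResult}.
#' @export
pcoa <- function(dm) {
  if (!is(dm, "DistanceMatrix")) dm <- distanceMatrix(dm)
  m <- dm@.Data
  n <- nrow(m)
  res <- suppressWarnings(cmdscale(m, k = max(n - 1, 1), eig = TRUE))
  eig <- res$eig
  tol <- if (all(eig == 0)) 0 else max(abs(eig)) * 1e-9
  keep <- which(eig[seq_len(max(ncol(res$points), 1))] > tol)
  if (!length(keep)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(m), "PC1"))
    return(new("OrdinationResult", coordinates = coords, eigenvalues = 0,
               proportionExplained = 0))
  }
  coords <- res$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("PC", seq_along(keep))
  rownames(coords) <- rownames(m)
  new("OrdinationResult", coordinates = coords, eigenvalues = eig[keep],
      proportionExplained = eig[keep] / sum(eig[keep]))
}
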