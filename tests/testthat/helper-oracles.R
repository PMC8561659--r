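# Independent oracles used across test files.  These deliberately share no
# code with the package implementations they check.

# Convex hull volume by brute-force supporting-plane enumeration: every
# point triple whose plane has all points on one side is a hull facet
# (general position assumed); the volume is the divergence-theorem sum of
# outward-oriented signed tetrahedra around the centroid.
bruteHullVolume <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  ctr <- colMeans(P)
  tol <- 1e-9 * max(dist(P))
  tri <- utils::combn(n, 3)
  A <- P[tri[1, ], , drop = FALSE]
  B <- P[tri[2, ], , drop = FALSE]
  C <- P[tri[3, ], , drop = FALSE]
  U <- B - A
  V <- C - A
  N <- cbind(U[, 2] * V[, 3] - U[, 3] * V[, 2],
             U[, 3] * V[, 1] - U[, 1] * V[, 3],
             U[, 1] * V[, 2] - U[, 2] * V[, 1])
  D <- N %*% t(P) - rowSums(N * A)        # signed side of every point
  supporting <- which(rowSums(D > tol) == 0 | rowSums(D < -tol) == 0)
  vol <- 0
  for (s in supporting) {
    a <- P[tri[1, s], ]; b <- P[tri[2, s], ]; c3 <- P[tri[3, s], ]
    m <- rbind(a - ctr, b - ctr, c3 - ctr)
    v <- det(m) / 6
    # orient outward: normal away from centroid
    if (sum(N[s, ] * (ctr - a)) > 0) v <- -v
    vol <- vol + v
  }
  vol
}

# Unweighted UniFrac by explicit branch-set enumeration: walk every edge,
# collect the tips below it by recursive descent on the edge matrix, and
# accumulate shared/unique branch length.
tipsBelow <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tipsBelow, tree = tree))
}

unifracOracle <- function(presA, presB, tree) {
  either <- 0; unique_ <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[tipsBelow(tree, tree$edge[e, 2])]
    inA <- any(presA[tips]); inB <- any(presB[tips])
    if (inA || inB) either <- either + tree$edge.length[e]
    if (xor(inA, inB)) unique_ <- unique_ + tree$edge.length[e]
  }
  if (either == 0) 0 else unique_ / either
}

# 3-D rotation matrix from an axis and angle (for hull invariance checks).
rotationMatrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Small cohorts reused across files.
smallDailyCohort <- function(seed = 42, ...) {
  simulateCohort(cohortConfig("daily_dynamics", nParticipants = 4L,
                              timepoints = paste0("T", 1:5), nTaxa = 30L,
                              seed = seed, ...))
}

noiseFreeAcuteCohort <- function(seed = 7, treatments = NULL, n = 4L, ...) {
  participants <- sprintf("P%02d", seq_len(n))
  if (is.null(treatments)) treatments <- rep("alcohol_free", n)
  simulateCohort(cohortConfig(
    "acute_perturbation", nParticipants = n,
    treatmentAssignments = setNames(treatments, participants),
    baselineLoadLog10Sd = 0, withinDayLoadLog10Sd = 0, seed = seed, ...))
}
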