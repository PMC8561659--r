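#' @include AllClasses.R utils.R distances.R
NULL

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convex hull volume of a 3-D point set
#'
#' Volume of the convex hull, computed with an incremental (beneath-beyond)
#' hull construction: facets visible from each new point are replaced by the
#' fan over its horizon edges, and the enclosed volume is the sum of
#' outward-oriented tetrahedra around an interior reference point.  Point
#' sets with fewer than four points, or that are affinely dependent
#' (coincident, collinear or coplanar), have zero volume and are flagged
#' degenerate rather than raising an error, so participants with few samples
#' remain comparable.
#'
#' @param points n x 3 numeric matrix of coordinates (finite).
#' @return list with \code{volume} (non-negative) and \code{degenerate}
#'   (logical).
#' @export
convexHullVolume <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must have exactly 3 coordinates")
  if (any(!is.finite(pts))) stop("non-finite coordinates")
  degenerate <- list(volume = 0, degenerate = TRUE)
  n <- nrow(pts)
  if (n < 4L) return(degenerate)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[1] == 0 || sv[3] <= sv[1] * 1e-10) return(degenerate)
  diam <- 2 * sv[1]
  eps <- 1e-9 * diam

  # initial simplex: spread-out affinely independent quadruple
  i1 <- which.max(rowSums(X^2))
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  ab <- pts[i2, ] - pts[i1, ]
  areas <- apply(pts, 1, function(p) sum(cross3(ab, p - pts[i1, ])^2))
  i3 <- which.max(areas)
  nrm0 <- cross3(ab, pts[i3, ] - pts[i1, ])
  vols <- abs(as.numeric((pts - matrix(pts[i1, ], n, 3, byrow = TRUE)) %*% nrm0))
  i4 <- which.max(vols)
  simplex <- c(i1, i2, i3, i4)
  inner <- colMeans(pts[simplex, ])

  makeFacet <- function(i, j, k) {
    a <- pts[i, ]
    nrm <- cross3(pts[j, ] - a, pts[k, ] - a)
    len <- sqrt(sum(nrm^2))
    if (len > 0 && sum(nrm * (inner - a)) > 0) {
      tmp <- j; j <- k; k <- tmp
      nrm <- -nrm
    }
    list(v = c(i, j, k), n = nrm, a = a, len = len)
  }
  facets <- list(makeFacet(i1, i2, i3), makeFacet(i1, i2, i4),
                 makeFacet(i1, i3, i4), makeFacet(i2, i3, i4))

  for (p in setdiff(seq_len(n), simplex)) {
    x <- pts[p, ]
    vis <- vapply(facets, function(f) {
      f$len > 0 && sum(f$n * (x - f$a)) / f$len > eps
    }, logical(1))
    if (!any(vis)) next
    edges <- do.call(rbind, lapply(facets[vis], function(f) {
      rbind(sort(f$v[c(1, 2)]), sort(f$v[c(2, 3)]), sort(f$v[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    facets <- facets[!vis]
    for (e in seq_len(nrow(horizon)))
      facets[[length(facets) + 1L]] <-
        makeFacet(horizon[e, 1], horizon[e, 2], p)
  }
  vol <- sum(vapply(facets, function(f) {
    det(rbind(pts[f$v[1], ] - inner, pts[f$v[2], ] - inner,
              pts[f$v[3], ] - inner)) / 6
  }, numeric(1)))
  list(volume = max(vol, 0), degenerate = FALSE)
}

#' Per-group convex hull volumes in ordination space
#'
#' The temporal-dispersion statistic: for each group (normally a
#' participant), the convex hull volume of its samples in the first
#' \code{nAxes} principal coordinates.  A larger hull means the group's
#' composition moved more across timepoints.
#'
#' @param ord an \linkS4class{OrdinationResult}.
#' @param metadata data.frame indexed by the ordination's sample names.
#' @param groupField metadata column defining groups (default
#'   "participant").
#' @param nAxes number of leading axes (default 3).
#' @return data.frame with group, n_points, volume and degenerate flag.
#' @export
participantHulls <- function(ord, metadata, groupField = "participant",
                             nAxes = 3L) {
  coords <- coordinates(ord)
  if (!all(rownames(coords) %in% rownames(metadata)))
    stop("every ordinated sample needs metadata")
  groups <- metadata[rownames(coords), groupField]
  if (any(is.na(groups))) stop("every sample needs a group label")
  if (ncol(coords) < nAxes)
    coords <- cbind(coords, matrix(0, nrow(coords), nAxes - ncol(coords)))
  coords <- coords[, seq_len(nAxes), drop = FALSE]
  out <- lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    if (!length(idx)) {
      msg("group ", g, " has no samples; skipped")
      return(NULL)
    }
    h <- convexHullVolume(coords[idx, , drop = FALSE])
    data.frame(group = g, n_points = length(idx), volume = h$volume,
               degenerate = h$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Group pairwise distances for dispersion testing
#'
#' Labels unordered sample pairs of a distance matrix by scheme:
#' \describe{
#'   \item{within_vs_between}{pairs sharing a participant at different
#'     timepoints ("within_participant") versus pairs sharing a timepoint
#'     across participants ("between_participant"); all other pairs are
#'     excluded.}
#'   \item{timepoint_pairs}{within-participant pairs labelled by their
#'     timepoint combination (e.g. "T1-T2").}
#'   \item{treatment_over_time}{within-participant pairs labelled by the
#'     participant's treatment group.}
#' }
#' No pair is counted twice and no sample is paired with itself.
#'
#' @param dm a \linkS4class{DistanceMatrix}.
#' @param metadata data.frame indexed by sample name with participant,
#'   timepoint and (for treatment_over_time) treatment columns.
#' @param scheme grouping scheme.
#' @return data.frame with group, distance, sample1, sample2.
#' @export
groupDistances <- function(dm, metadata,
                           scheme = c("within_vs_between", "timepoint_pairs",
                                      "treatment_over_time")) {
  scheme <- match.arg(scheme)
  ids <- rownames(dm)
  if (!all(ids %in% rownames(metadata)))
    stop("metadata missing for some samples")
  meta <- metadata[ids, ]
  need <- c("participant", "timepoint",
            if (scheme == "treatment_over_time") "treatment")
  missingCols <- setdiff(need, colnames(meta))
  if (length(missingCols))
    stop("metadata lacks column(s): ", paste(missingCols, collapse = ", "))
  n <- length(ids)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      samePart <- meta$participant[i] == meta$participant[j]
      sameTime <- meta$timepoint[i] == meta$timepoint[j]
      label <- switch(scheme,
        within_vs_between = if (samePart && !sameTime) "within_participant"
          else if (!samePart && sameTime) "between_participant"
          else NA_character_,
        timepoint_pairs = if (samePart && !sameTime)
          paste(sort(c(as.character(meta$timepoint[i]),
                       as.character(meta$timepoint[j]))), collapse = "-")
          else NA_character_,
        treatment_over_time = if (samePart && !sameTime)
          as.character(meta$treatment[i]) else NA_character_)
      if (is.na(label)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = label, distance = dm[i, j], sample1 = ids[i],
        sample2 = ids[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no pairs matched the grouping scheme")
  do.call(rbind, rows)
}

#' Kruskal-Wallis H statistic with tie correction
#'
#' \eqn{H = \frac{12}{N(N+1)} \sum_i n_i \bar R_i^2 - 3(N+1)} on average
#' ranks, divided by the tie-correction factor
#' \eqn{1 - \sum_t (t^3 - t) / (N^3 - N)}.  All-identical values give H = 0.
#'
#' @param values numeric observations.
#' @param labels group labels (>= 2 non-empty groups).
#' @return the H statistic.
#' @export
kwStatistic <- function(values, labels) {
  g <- as.integer(factor(labels))
  ns <- tabulate(g)
  if (length(ns) < 2L || any(ns == 0L)) stop("need >= 2 non-empty groups")
  N <- length(values)
  r <- rank(values)
  S <- rowsum(r, g)
  H <- 12 / (N * (N + 1)) * sum(S^2 / ns) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) return(0)
  H / C
}

#' Permutation Kruskal-Wallis test
#'
#' Distance observations are not independent, so instead of the chi-squared
#' reference the group labels are shuffled uniformly \code{nPermutations}
#' times, H is recomputed for each shuffle, and the p-value is the add-one
#' exceedance proportion
#' \eqn{p = (\#\{H_{perm} \ge H_{obs}\} + 1) / (n_{perm} + 1)}.  The minimum
#' attainable p is exactly \eqn{1/(n_{perm}+1)}.
#'
#' @param values numeric observations (e.g. grouped pairwise distances).
#' @param labels group labels.
#' @param nPermutations number of label shuffles (default 1000).
#' @param seed RNG seed for the shuffles.
#' @return a \linkS4class{PermutationTestResult}.
#' @export
permutationKW <- function(values, labels, nPermutations = 1000L, seed = 1L) {
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  g <- as.integer(factor(labels))
  ns <- tabulate(g)
  if (length(ns) < 2L || any(ns == 0L)) stop("need >= 2 non-empty groups")
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  Hof <- function(gg) {
    if (C <= 0) return(0)
    S <- rowsum(r, gg)
    (12 / (N * (N + 1)) * sum(S^2 / ns) - 3 * (N + 1)) / C
  }
  hObs <- Hof(g)
  hPerm <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(b) Hof(g[sample.int(N)]),
           numeric(1))
  })
  nExceed <- sum(hPerm >= hObs - 1e-12)
  new("PermutationTestResult", kObserved = hObs,
      nPermutations = as.integer(nPermutations),
      nExceed = as.integer(nExceed),
      pValue = (nExceed + 1) / (nPermutations + 1), seed = as.integer(seed))
}

#' Paired two-sided t-test on per-participant hull volumes
#'
#' Compares matched hull volumes (e.g. each participant's raw-sample hull
#' against their PMA-sample hull) with a two-sided paired t-test.
#'
#' @param x,y paired volume vectors in the same participant order.
#' @return list with \code{t}, \code{p} and \code{meanDifference} (y - x).
#' @export
pairedHullTest <- function(x, y) {
  stopifnot(length(x) == length(y))
  tt <- t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       meanDifference = unname(tt$estimate))
}
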