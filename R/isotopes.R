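# Collagen stable-isotope quality control and isotope-space niche overlap.

#' Atomic C/N ratio from weight-percent composition
#'
#' @param pctC,pctN collagen carbon and nitrogen content in weight percent.
#' @return atomic C/N ratio `(pctC / 12.011) / (pctN / 14.007)`.
#' @export
cnAtomic <- function(pctC, pctN) (pctC / 12.011) / (pctN / 14.007)

#' Quality-filter collagen isotope records
#'
#' Retains records whose atomic C/N ratio lies inside the inclusive
#' reliability window (default 2.9-3.6). Records lacking pctC/pctN are
#' flagged unassessable. The ratio is always derived from the elemental
#' composition, never taken from the input.
#'
#' @param records data.frame with at least `pctC` and `pctN` columns.
#' @param params a [QCParams-class].
#' @return list with `retained`, `rejected` (with a `reason` column) and
#'   `unassessable` data.frames; each input row lands in exactly one.
#' @export
qcFilter <- function(records, params = QCParams()) {
  cn <- cnAtomic(records$pctC, records$pctN)
  records$cn_atomic <- cn
  una <- is.na(cn)
  low <- !una & cn < params@cnMin
  high <- !una & cn > params@cnMax
  keep <- !una & !low & !high
  rejected <- records[low | high, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- ifelse(rejected$cn_atomic < params@cnMin,
                              "cn_below_range", "cn_above_range")
  list(retained = records[keep, , drop = FALSE],
       rejected = rejected,
       unassessable = records[una, , drop = FALSE])
}

#' Per-group isotope summaries
#'
#' @param records data.frame with `d13C`, `d15N` and the grouping columns.
#' @param by character vector of grouping columns (default taxon, period).
#' @return data.frame with mean, sd and n per group and isotope; sd is NA
#'   for groups with a single record.
#' @export
groupSummary <- function(records, by = c("taxon", "period")) {
  if (!nrow(records)) stop("no records to summarize")
  key <- interaction(records[by], drop = TRUE, sep = ":")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    g <- records[key == k, , drop = FALSE]
    cbind(g[1, by, drop = FALSE],
          data.frame(n = nrow(g),
                     mean_d13C = mean(g$d13C), mean_d15N = mean(g$d15N),
                     sd_d13C = if (nrow(g) > 1) sd(g$d13C) else NA_real_,
                     sd_d15N = if (nrow(g) > 1) sd(g$d15N) else NA_real_))
  }))
  rownames(out) <- NULL
  out
}

# ---- convex polygon helpers --------------------------------------------------

# counter-clockwise convex hull of a 2-column matrix
hull_ccw <- function(pts) {
  h <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(h) >= 3 && poly_area_signed(h) < 0) h <- h[nrow(h):1, , drop = FALSE]
  h
}

poly_area_signed <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

poly_area <- function(p) if (nrow(p) < 3) 0 else abs(poly_area_signed(p))

# Sutherland-Hodgman clipping of convex polygon `subject` by convex CCW
# polygon `clip`; exact for convex inputs.
clip_convex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]; b <- clip[if (i == n) 1 else i + 1, ]
    inside <- function(p)
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2])
      d2 <- c(b[1] - a[1], b[2] - a[2])
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
      p + t * d1
    }
    res <- matrix(numeric(0), 0, 2)
    m <- nrow(out)
    for (k in seq_len(m)) {
      cur <- out[k, ]; nxt <- out[if (k == m) 1 else k + 1, ]
      if (inside(cur)) {
        res <- rbind(res, cur)
        if (!inside(nxt)) res <- rbind(res, inter(cur, nxt))
      } else if (inside(nxt)) res <- rbind(res, inter(cur, nxt))
    }
    out <- res
  }
  out
}

point_in_hull <- function(p, hull) {
  n <- nrow(hull)
  if (n < 3) return(FALSE)
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1 else i + 1, ]
    if ((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) < -1e-9)
      return(FALSE)
  }
  TRUE
}

#' Convex-hull overlap between two isotope clusters
#'
#' Overlap = area(intersection of the two groups' convex hulls in the
#' (d13C, d15N) plane) / area(union). Degenerate (collinear) hulls fall
#' back to segment intersection and are flagged. Optional query samples are
#' classified inside/outside each hull.
#'
#' @param groupA,groupB data.frames (or 2-column matrices) with `d13C` and
#'   `d15N`; each needs at least 3 records for a proper hull.
#' @param query optional data.frame of samples to classify (columns
#'   `sample`, `d13C`, `d15N`).
#' @return list with `overlap` (fraction in `[0, 1]`), `areaA`, `areaB`,
#'   `areaIntersection`, `degenerate` flag, and (when `query` is given)
#'   `classification` with logical `inA`, `inB` per query sample.
#' @export
overlapScore <- function(groupA, groupB, query = NULL) {
  as_pts <- function(g) {
    if (is.data.frame(g)) cbind(g$d13C, g$d15N) else as.matrix(g)
  }
  A <- as_pts(groupA); B <- as_pts(groupB)
  if (nrow(A) < 3 || nrow(B) < 3)
    stop("each group needs at least 3 records for hull construction")
  hA <- hull_ccw(A); hB <- hull_ccw(B)
  aA <- poly_area(hA); aB <- poly_area(hB)
  degenerate <- aA < 1e-12 || aB < 1e-12
  if (degenerate) {
    ov <- segment_overlap(A, B)
  } else {
    inter <- clip_convex(hA, hB)
    aI <- poly_area(inter)
    ov <- aI / (aA + aB - aI)
  }
  res <- list(overlap = ov, areaA = aA, areaB = aB,
              areaIntersection = if (degenerate) NA_real_ else aI,
              degenerate = degenerate)
  if (!is.null(query)) {
    res$classification <- data.frame(
      sample = if (!is.null(query$sample)) query$sample
               else seq_len(nrow(query)),
      inA = vapply(seq_len(nrow(query)), function(i)
        point_in_hull(c(query$d13C[i], query$d15N[i]), hA), logical(1)),
      inB = vapply(seq_len(nrow(query)), function(i)
        point_in_hull(c(query$d13C[i], query$d15N[i]), hB), logical(1)))
  }
  res
}

# 1D fallback for collinear clusters: fraction of overlap between the two
# point ranges projected on the dominant direction; 0 when not collinear.
segment_overlap <- function(A, B) {
  P <- rbind(A, B)
  P <- sweep(P, 2, colMeans(P))
  v <- svd(P)$v[, 1]
  resid <- P - as.numeric(P %*% v) %o% v
  if (max(abs(resid)) > 1e-6) return(0)
  a <- range(A %*% v); b <- range(B %*% v)
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  un <- max(a[2], b[2]) - min(a[1], b[1])
  if (un <= 0) return(1)  # all points identical
  inter / un
}
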