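#' Polygon utilities behind the shape features
#'
#' Region outlines are measured on a simplified crack-boundary polygon: the
#' exact polygon along pixel edges (so axis-aligned shapes keep their true
#' perimeter) is decimated with the Ramer-Douglas-Peucker algorithm at a
#' sub-pixel tolerance, which collapses the rasterisation staircase on
#' curved outlines (a digital disk recovers ~99% of the true circle
#' perimeter) while preserving genuine corners.  The same polygon feeds
#' perimeter, convex hull, lobeyness and the minimal-area oriented
#' bounding rectangle, keeping the features internally consistent.
#'
#' @name polygon-utils
#' @keywords internal
NULL

# crack-boundary polygons of a binary mask, in (y, x) pixel-centre
# coordinates (pixel (i, j) spans i +/- 0.5, j +/- 0.5).  Returns a list of
# closed polygons (outer boundaries and hole boundaries).
crack_polygons <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- (mask > 0) * 1L
  up    <- rbind(pad[-1, , drop = FALSE], 0L)[1:(nr + 2L), , drop = FALSE]
  # segments around each inside pixel whose 4-neighbour is outside
  ins <- which(pad > 0L, arr.ind = TRUE)
  if (!nrow(ins)) return(list())
  i <- ins[, 1]; j <- ins[, 2]
  get <- function(di, dj) pad[cbind(i + di, j + dj)]
  segs <- list()
  top <- get(-1L, 0L) == 0L
  if (any(top)) segs[[length(segs) + 1L]] <-
    cbind(i[top] - 0.5, j[top] - 0.5, i[top] - 0.5, j[top] + 0.5)
  bot <- get(1L, 0L) == 0L
  if (any(bot)) segs[[length(segs) + 1L]] <-
    cbind(i[bot] + 0.5, j[bot] + 0.5, i[bot] + 0.5, j[bot] - 0.5)
  lef <- get(0L, -1L) == 0L
  if (any(lef)) segs[[length(segs) + 1L]] <-
    cbind(i[lef] + 0.5, j[lef] - 0.5, i[lef] - 0.5, j[lef] - 0.5)
  rig <- get(0L, 1L) == 0L
  if (any(rig)) segs[[length(segs) + 1L]] <-
    cbind(i[rig] - 0.5, j[rig] + 0.5, i[rig] + 0.5, j[rig] + 0.5)
  segs <- do.call(rbind, segs)
  # stitch directed segments into closed loops; at corner points where two
  # segments start (diagonal pixel contact) prefer the right turn so each
  # loop stays simple
  from_key <- paste(segs[, 1], segs[, 2])
  lookup <- split(seq_len(nrow(segs)), from_key)
  used <- rep(FALSE, nrow(segs))
  polys <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    cur <- s0
    pts_i <- numeric(0); pts_j <- numeric(0)
    repeat {
      used[cur] <- TRUE
      pts_i <- c(pts_i, segs[cur, 1]); pts_j <- c(pts_j, segs[cur, 2])
      nk <- paste(segs[cur, 3], segs[cur, 4])
      cand <- lookup[[nk]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # pick the sharpest right turn relative to the incoming direction
        din <- c(segs[cur, 3] - segs[cur, 1], segs[cur, 4] - segs[cur, 2])
        cross <- vapply(cand, function(k) {
          dout <- c(segs[k, 3] - segs[k, 1], segs[k, 4] - segs[k, 2])
          din[1] * dout[2] - din[2] * dout[1]
        }, numeric(1))
        cand <- cand[which.max(cross)]
      }
      cur <- cand[1]
    }
    polys[[length(polys) + 1L]] <- cbind(y = pts_i, x = pts_j)
  }
  polys
}

# Ramer-Douglas-Peucker simplification of an open polyline (keeps ends)
rdp_polyline <- function(p, eps) {
  n <- nrow(p)
  if (n <= 2L) return(p)
  keep <- rep(FALSE, n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    a <- p[i, ]; b <- p[j, ]
    ab <- b - a
    L <- sqrt(sum(ab^2))
    idx <- (i + 1L):(j - 1L)
    d <- if (L < 1e-12) {
      sqrt((p[idx, 1] - a[1])^2 + (p[idx, 2] - a[2])^2)
    } else {
      abs((p[idx, 1] - a[1]) * ab[2] - (p[idx, 2] - a[2]) * ab[1]) / L
    }
    k <- idx[which.max(d)]
    if (max(d) > eps) {
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  p[keep, , drop = FALSE]
}

# closed-polygon RDP: anchor at the vertex farthest from the centroid and
# the vertex farthest from it, simplify the two halves
rdp_closed <- function(p, eps) {
  n <- nrow(p)
  if (n <= 4L) return(p)
  d2 <- (p[, 1] - mean(p[, 1]))^2 + (p[, 2] - mean(p[, 2]))^2
  i1 <- which.max(d2)
  p <- rbind(p[i1:n, , drop = FALSE], p[seq_len(i1 - 1L), , drop = FALSE])
  d2 <- (p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2
  i2 <- which.max(d2)
  a <- rdp_polyline(p[1:i2, , drop = FALSE], eps)
  b <- rdp_polyline(rbind(p[i2:n, , drop = FALSE], p[1, , drop = FALSE]), eps)
  rbind(a[-nrow(a), , drop = FALSE], b[-nrow(b), , drop = FALSE])
}

#' Trace the outline polygon of a binary region
#'
#' @param mask logical/0-1 matrix, one region (the largest outline is
#'   returned if several are present).
#' @param simplify_tol Douglas-Peucker tolerance in px applied to the
#'   crack-boundary polygon (default 1 px; 0 keeps the raw pixel-edge
#'   polygon).
#' @return numeric matrix with columns `y`, `x` (pixel units, closed
#'   implicitly).
#' @export
trace_region_polygon <- function(mask, simplify_tol = 1) {
  polys <- crack_polygons(mask)
  if (!length(polys)) stop("empty region")
  per <- vapply(polys, polygon_perimeter, numeric(1))
  p <- polys[[which.max(per)]]
  if (simplify_tol > 0) p <- rdp_closed(p, simplify_tol)
  p
}

#' Perimeter of a closed polygon
#' @param p two-column coordinate matrix (closed implicitly).
#' @return total edge length.
#' @export
polygon_perimeter <- function(p) {
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

#' Signed-area magnitude of a closed polygon (shoelace formula)
#' @param p two-column coordinate matrix.
#' @return area (non-negative).
#' @export
polygon_area <- function(p) {
  y <- p[, 1]; x <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - y * c(x[-1], x[1]))) / 2
}

convex_hull_polygon <- function(p) {
  p[grDevices::chull(p[, 2], p[, 1]), , drop = FALSE]
}

# minimal-area oriented bounding rectangle via rotating calipers over hull
# edges; returns list(area, length, width)
min_area_rect <- function(p) {
  h <- convex_hull_polygon(p)
  n <- nrow(h)
  if (n == 1L) return(list(area = 0, length = 0, width = 0))
  if (n == 2L) {
    L <- sqrt(sum((h[2, ] - h[1, ])^2))
    return(list(area = 0, length = L, width = 0))
  }
  best <- NULL
  for (k in seq_len(n)) {
    a <- h[k, ]; b <- h[if (k == n) 1L else k + 1L, ]
    e <- b - a
    L <- sqrt(sum(e^2))
    if (L < 1e-12) next
    u <- e / L                      # edge direction
    v <- c(-u[2], u[1])             # normal
    pu <- h[, 1] * u[1] + h[, 2] * u[2]
    pv <- h[, 1] * v[1] + h[, 2] * v[2]
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area) {
      best <- list(area = area, length = max(du, dv), width = min(du, dv))
    }
  }
  best
}
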