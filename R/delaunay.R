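# Delaunay triangulation by sorted incremental insertion and Lawson flips.
# No super-triangle is used: points are pre-sorted lexicographically, so
# each new point lies outside the convex hull of its predecessors and is
# connected to the visible hull edges, after which locally non-Delaunay
# edges are flipped. This avoids the classic finite-super-triangle failure
# for near-collinear hull triangles with huge circumcircles, and makes the
# handling of co-circular quadruples a fixed function of the sorted
# insertion order (reproducibility).

orient2d <- function(p, a, b, c) {
  (p[b, 1] - p[a, 1]) * (p[c, 2] - p[a, 2]) -
    (p[b, 2] - p[a, 2]) * (p[c, 1] - p[a, 1])
}

# incircle: for CCW triangle (a, b, c), positive when d lies strictly
# inside the circumcircle. Relative tolerance keeps co-circular quadruples
# unflipped (insertion order decides the diagonal).
incircle_excess <- function(p, a, b, c, d) {
  m <- cbind(p[c(a, b, c), 1] - p[d, 1], p[c(a, b, c), 2] - p[d, 2])
  m <- cbind(m, m[, 1]^2 + m[, 2]^2)
  pos <- m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) +
    m[1, 2] * (m[2, 3] * m[3, 1] - m[2, 1] * m[3, 3]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  mag <- max(abs(m[, 3])) * max(abs(m)) * max(abs(m))
  list(det = pos, tol = 1e-12 * max(mag, .Machine$double.xmin))
}

#' Delaunay triangulation of a planar point set
#'
#' Incremental construction with Lawson edge flips; input points are
#' processed in lexicographic order, fixing the treatment of co-circular
#' quadruples reproducibly. Returned indices refer to the original input
#' order.
#'
#' @param centers data.frame or matrix with x/y coordinates (first two
#'   columns).
#' @return list `triangles` (m x 3 integer matrix, rows sorted) and
#'   `edges` (k x 2 integer matrix, each row sorted, unique).
#' @export
delaunay_triangulate <- function(centers) {
  pts <- as.matrix(as.data.frame(centers)[, 1:2])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 4) pf_stop("degenerate_geometry", "need at least 4 points")
  if (anyDuplicated(pts)) pf_stop("degenerate_geometry", "duplicate points")

  ord <- order(pts[, 1], pts[, 2])
  p <- pts[ord, , drop = FALSE]
  span <- max(diff(range(p[, 1])), diff(range(p[, 2])))
  eps_or <- 1e-12 * max(span^2, .Machine$double.xmin)

  tris <- matrix(0L, 0, 3)
  alive <- logical(0)
  edge_map <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  reg <- function(id) {
    t <- tris[id, ]
    for (e in list(t[1:2], t[2:3], t[c(1, 3)])) {
      k <- ekey(e[1], e[2])
      cur <- if (exists(k, edge_map)) get(k, edge_map) else integer(0)
      assign(k, c(cur, id), edge_map)
    }
  }
  unreg <- function(id) {
    t <- tris[id, ]
    for (e in list(t[1:2], t[2:3], t[c(1, 3)])) {
      k <- ekey(e[1], e[2])
      assign(k, setdiff(get(k, edge_map), id), edge_map)
    }
  }
  add_tri <- function(a, b, c) {
    if (orient2d(p, a, b, c) < 0) { tmp <- b; b <- c; c <- tmp }
    tris <<- rbind(tris, c(a, b, c))
    alive <<- c(alive, TRUE)
    reg(nrow(tris))
    nrow(tris)
  }

  # Lawson flip propagation from a queue of candidate edges
  flip_from <- function(queue) {
    while (length(queue) > 0) {
      e <- queue[[1]]
      queue <- queue[-1]
      k <- ekey(e[1], e[2])
      ids <- if (exists(k, edge_map)) get(k, edge_map) else integer(0)
      ids <- ids[alive[ids]]
      if (length(ids) != 2) next
      t1 <- tris[ids[1], ]
      t2 <- tris[ids[2], ]
      c1 <- setdiff(t1, e)
      c2 <- setdiff(t2, e)
      if (length(c1) != 1 || length(c2) != 1) next
      # orient (e1, e2, c1) CCW for the incircle sign
      a <- e[1]; b <- e[2]
      if (orient2d(p, a, b, c1) < 0) { tmp <- a; a <- b; b <- tmp }
      inc <- incircle_excess(p, a, b, c1, c2)
      if (inc$det > inc$tol) {
        unreg(ids[1]); unreg(ids[2])
        alive[ids] <<- FALSE
        add_tri(c1, c2, a)
        add_tri(c1, c2, b)
        queue <- c(queue, list(c(a, c1), c(a, c2), c(b, c1), c(b, c2)))
      }
    }
  }

  # chain phase: leading points may be collinear
  chain <- c(1L, 2L)
  i <- 3L
  while (i <= n && abs(orient2d(p, chain[1], chain[2], i)) <= eps_or) {
    chain <- c(chain, i)
    i <- i + 1L
  }
  if (i > n) pf_stop("degenerate_geometry", "all points are collinear")
  # fan-triangulate the chain against the first off-line point
  for (j in seq_len(length(chain) - 1))
    add_tri(chain[j], chain[j + 1], i)
  hull <- if (orient2d(p, chain[1], chain[2], i) > 0)
    c(chain, i) else c(rev(chain), i)
  flip_from(lapply(seq_len(length(chain) - 1), function(j)
    c(chain[j], chain[j + 1])))

  for (pt in (i + 1L):n) {
    if (pt > n) break
    h <- length(hull)
    nxt <- c(2:h, 1)
    vis <- vapply(seq_len(h), function(k)
      orient2d(p, hull[k], hull[nxt[k]], pt) < -eps_or, logical(1))
    if (!any(vis)) pf_stop("degenerate_geometry",
                           "insertion point not outside hull (degenerate input)")
    newq <- list()
    for (k in which(vis)) {
      add_tri(hull[nxt[k]], hull[k], pt)
      newq <- c(newq, list(c(hull[k], hull[nxt[k]])))
    }
    # hull update: drop interior vertices of the visible chain, insert pt.
    # rotate so the visible run is contiguous and does not wrap
    first <- which(vis & !vis[c(h, seq_len(h - 1))])[1]
    run <- sum(vis)
    idx <- ((first - 1 + seq_len(h)) - 1) %% h + 1
    hull <- hull[idx]  # visible edges now occupy positions 1..run
    hull <- c(hull[1], pt, hull[(run + 1):h])
    flip_from(newq)
  }

  tri_mat <- tris[alive, , drop = FALSE]
  tri_mat[] <- ord[tri_mat]
  tri_mat <- t(apply(tri_mat, 1, sort))
  edges <- rbind(tri_mat[, 1:2], tri_mat[, 2:3], tri_mat[, c(1, 3)])
  edges <- unique(t(apply(edges, 1, sort)))
  list(triangles = tri_mat, edges = edges)
}

# Indices of points lying on the convex-hull boundary (hull vertices plus
# points collinear on hull edges, which matters for lattice patterns).
hull_boundary_points <- function(pts, tol_factor = 1e-9) {
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hv <- pts[hull, , drop = FALSE]
  m <- nrow(hv)
  diam <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  tol <- tol_factor * max(diam, 1)
  on_boundary <- rep(FALSE, nrow(pts))
  on_boundary[hull] <- TRUE
  for (k in seq_len(m)) {
    a <- hv[k, ]
    b <- hv[if (k == m) 1 else k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    on_boundary <- on_boundary | (dx^2 + dy^2 < tol^2)
  }
  which(on_boundary)
}
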