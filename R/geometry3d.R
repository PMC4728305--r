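# 3D computational geometry: incremental convex hull and exact
# point-to-facet distances.  Positions are n x 3 matrices in um.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' 3D convex hull of a point cloud
#'
#' Incremental (beneath-beyond) convex hull.  Facets are triangles oriented
#' with outward normals; surface area is the facet-area sum and volume the
#' signed tetrahedron sum about the origin.
#'
#' @param pts n x 3 numeric matrix (n >= 4, not all coplanar).
#' @param tol relative degeneracy tolerance.
#' @return list with \code{faces} (f x 3 vertex indices into \code{pts}),
#'   \code{vertices} (indices on the hull), \code{areaUm2}, \code{volumeUm3}.
#' @export
convexHull3d <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop("convex hull needs at least 4 points")
  rng <- apply(pts, 2L, range)
  diam <- sqrt(sum((rng[2L, ] - rng[1L, ])^2))
  if (diam == 0) stop("degenerate point set: all points coincide")
  eps <- tol * diam

  # initial simplex: extreme point pair, then max-area, then max-volume
  i1 <- which.min(pts[, 1L])
  d1 <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d1)
  ab <- pts[i2, ] - pts[i1, ]
  ap <- sweep(pts, 2L, pts[i1, ])
  crossn <- cbind(ap[, 2L] * ab[3L] - ap[, 3L] * ab[2L],
                  ap[, 3L] * ab[1L] - ap[, 1L] * ab[3L],
                  ap[, 1L] * ab[2L] - ap[, 2L] * ab[1L])
  dline <- rowSums(crossn^2)
  i3 <- which.max(dline)
  if (dline[i3] <= (eps * sqrt(sum(ab^2)))^2)
    stop("degenerate point set: collinear")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- abs(ap %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] <= eps)
    stop("degenerate point set: coplanar")

  verts <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[verts, ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1L], ]; nn <- cross3(pts[f[2L], ] - a, pts[f[3L], ] - a)
    if (sum(nn * (interior - a)) > 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- t(apply(faces, 1L, orient))

  faceNormals <- function(faces) {
    a <- pts[faces[, 1L], , drop = FALSE]
    b <- pts[faces[, 2L], , drop = FALSE]
    c_ <- pts[faces[, 3L], , drop = FALSE]
    u <- b - a; v <- c_ - a
    nrm <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                 u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                 u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    list(n = nrm, off = rowSums(nrm * a), len = sqrt(rowSums(nrm^2)))
  }

  fn <- faceNormals(faces)
  rest <- setdiff(seq_len(n), verts)
  # farthest-first insertion keeps the hull fat and the tolerance meaningful
  for (p in rest) {
    vis <- (fn$n %*% pts[p, ] - fn$off) > eps * fn$len
    if (!any(vis)) next
    visFaces <- faces[vis, , drop = FALSE]
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- rbind(visFaces[, c(1L, 2L)], visFaces[, c(2L, 3L)],
                   visFaces[, c(3L, 1L)])
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    newFaces <- cbind(horizon, p)
    faces <- rbind(faces[!vis, , drop = FALSE], newFaces)
    fn <- faceNormals(faces)
    bad <- fn$len <= eps * diam  # sliver faces from near-duplicates
    if (any(bad)) {
      faces <- faces[!bad, , drop = FALSE]
      fn <- faceNormals(faces)
    }
  }

  area <- sum(fn$len) / 2
  a <- pts[faces[, 1L], , drop = FALSE]
  vol <- sum(fn$n * a) / 6  # div theorem with outward normals
  list(faces = faces, vertices = sort(unique(as.vector(faces))),
       areaUm2 = area, volumeUm3 = abs(vol))
}

# Distance from each row of P to triangle (a, b, c); Ericson's closest-point
# construction, vectorized over points.
pointsTriangleDistance <- function(P, a, b, c) {
  P <- matrix(P, ncol = 3L)
  m <- nrow(P)
  ab <- b - a; ac <- c - a; bc <- c - b
  ap <- sweep(P, 2L, a)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  bp <- sweep(P, 2L, b)
  d3 <- bp %*% ab; d4 <- bp %*% ac
  cp <- sweep(P, 2L, c)
  d5 <- cp %*% ab; d6 <- cp %*% ac
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  cl <- matrix(NA_real_, m, 3L)
  done <- rep(FALSE, m)
  setcl <- function(idx, pts) {
    cl[idx, ] <<- pts
    done[idx] <<- TRUE
  }
  idx <- !done & d1 <= 0 & d2 <= 0
  if (any(idx)) setcl(idx, matrix(a, sum(idx), 3L, byrow = TRUE))
  idx <- !done & d3 >= 0 & d4 <= d3
  if (any(idx)) setcl(idx, matrix(b, sum(idx), 3L, byrow = TRUE))
  idx <- !done & d6 >= 0 & d5 <= d6
  if (any(idx)) setcl(idx, matrix(c, sum(idx), 3L, byrow = TRUE))
  idx <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(idx)) {
    v <- d1[idx] / (d1[idx] - d3[idx])
    setcl(idx, matrix(rep(a, each = sum(idx)), ncol = 3L) + outer(v, ab))
  }
  idx <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(idx)) {
    w <- d2[idx] / (d2[idx] - d6[idx])
    setcl(idx, matrix(rep(a, each = sum(idx)), ncol = 3L) + outer(w, ac))
  }
  idx <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(idx)) {
    w <- (d4[idx] - d3[idx]) / ((d4[idx] - d3[idx]) + (d5[idx] - d6[idx]))
    setcl(idx, matrix(rep(b, each = sum(idx)), ncol = 3L) + outer(w, bc))
  }
  idx <- !done
  if (any(idx)) {
    denom <- va[idx] + vb[idx] + vc[idx]
    v <- vb[idx] / denom; w <- vc[idx] / denom
    setcl(idx, matrix(rep(a, each = sum(idx)), ncol = 3L) +
            outer(v, ab) + outer(w, ac))
  }
  sqrt(rowSums((P - cl)^2))
}

#' Distance of points to a convex-hull surface
#'
#' Exact minimum Euclidean distance from each point to the triangulated hull
#' surface (interior and exterior points alike).
#'
#' @param P m x 3 matrix of query points.
#' @param pts the point matrix the hull was built from.
#' @param hull result of \code{\link{convexHull3d}}.
#' @return numeric(m) distances in um.
#' @export
pointsHullDistance <- function(P, pts, hull) {
  P <- matrix(P, ncol = 3L)
  d <- rep(Inf, nrow(P))
  for (f in seq_len(nrow(hull$faces))) {
    tri <- hull$faces[f, ]
    d <- pmin(d, pointsTriangleDistance(P, pts[tri[1L], ], pts[tri[2L], ],
                                        pts[tri[3L], ]))
  }
  d
}
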