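# Planar polygon helpers. Polygons are two-column matrices of vertices
# (x, y), not closed (first vertex not repeated), oriented counter-clockwise.

polygon_coords <- function(p) {
  if (inherits(p, "hs_polygon")) p$coords else as.matrix(p)
}

#' Polygon area (shoelace formula)
#'
#' @param poly an `hs_polygon` or a two-column vertex matrix.
#' @return Area in squared map units (m^2 on metric grids).
#' @export
polygon_area <- function(poly) {
  xy <- polygon_coords(poly)
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

signed_area <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

ensure_ccw <- function(xy) {
  if (signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

new_polygon <- function(coords, ...) {
  coords <- ensure_ccw(as.matrix(coords))
  colnames(coords) <- c("x", "y")
  structure(c(list(coords = coords), list(...)), class = "hs_polygon")
}

#' @export
print.hs_polygon <- function(x, ...) {
  cat(sprintf("<hs_polygon> %d vertices, area %.4g km^2\n",
              nrow(x$coords), polygon_area(x) / 1e6))
  invisible(x)
}

#' Test whether points fall inside a convex polygon
#'
#' Boundary points count as inside.
#'
#' @param poly convex `hs_polygon` or vertex matrix (any orientation).
#' @param x,y point coordinates.
#' @return Logical vector.
#' @export
in_convex <- function(poly, x, y) {
  xy <- ensure_ccw(polygon_coords(poly))
  n <- nrow(xy)
  inside <- rep(TRUE, length(x))
  eps <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (xy[j, 1] - xy[i, 1]) * (y - xy[i, 2]) -
      (xy[j, 2] - xy[i, 2]) * (x - xy[i, 1])
    scale <- sqrt((xy[j, 1] - xy[i, 1])^2 + (xy[j, 2] - xy[i, 2])^2)
    inside <- inside & (cross >= -eps * max(scale, 1))
  }
  inside
}

# Sutherland-Hodgman clip of a convex polygon against an axis-aligned rectangle
clip_to_rect <- function(poly, xmin, xmax, ymin, ymax) {
  xy <- ensure_ccw(polygon_coords(poly))
  clip_half <- function(pts, keep, cross_t) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), 0, 2)
    kv <- keep(pts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (kv[i]) out <- rbind(out, pts[i, ])
      if (xor(kv[i], kv[j])) {
        t <- cross_t(pts[i, ], pts[j, ])
        out <- rbind(out, pts[i, ] + t * (pts[j, ] - pts[i, ]))
      }
    }
    out
  }
  lin <- function(a, b, lim, k) (lim - a[k]) / (b[k] - a[k])
  xy <- clip_half(xy, function(p) p[, 1] >= xmin, function(a, b) lin(a, b, xmin, 1))
  xy <- clip_half(xy, function(p) p[, 1] <= xmax, function(a, b) lin(a, b, xmax, 1))
  xy <- clip_half(xy, function(p) p[, 2] >= ymin, function(a, b) lin(a, b, ymin, 2))
  xy <- clip_half(xy, function(p) p[, 2] <= ymax, function(a, b) lin(a, b, ymax, 2))
  if (nrow(xy) < 3) stop("polygon does not intersect the clipping rectangle", call. = FALSE)
  new_polygon(xy)
}

#' Axis-aligned rectangle as a polygon
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds (m).
#' @return An `hs_polygon`.
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax) {
  new_polygon(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

# distance from points to an axis-aligned segment set (matrix x0,y0,x1,y1)
dist_to_segments <- function(px, py, segs) {
  # returns, for each point, min distance over all segments; chunked so the
  # intermediate matrices stay modest
  np <- length(px)
  out <- rep(Inf, np)
  ns <- nrow(segs)
  if (ns == 0 || np == 0) return(out)
  chunk <- max(1L, floor(2e6 / ns))
  for (s in seq(1L, np, by = chunk)) {
    idx <- s:min(np, s + chunk - 1L)
    dx <- segs[, 3] - segs[, 1]
    dy <- segs[, 4] - segs[, 2]
    len2 <- dx^2 + dy^2
    # t = projection parameter clamped to [0,1]; outer over points x segments
    wx <- outer(px[idx], segs[, 1], "-")
    wy <- outer(py[idx], segs[, 2], "-")
    tt <- sweep(sweep(wx, 2, dx, "*") + sweep(wy, 2, dy, "*"), 2, pmax(len2, 1e-300), "/")
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    ex <- wx - sweep(tt, 2, dx, "*")
    ey <- wy - sweep(tt, 2, dy, "*")
    d2 <- ex^2 + ey^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}
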