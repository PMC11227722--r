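#' Canopy-cover class labels
#'
#' Quartile canopy bins used throughout: sparse (<= 25%), open (26-50%),
#' moderate (51-75%), dense (> 75%).
#' @export
canopy_levels <- c("sparse", "open", "moderate", "dense")

#' Categorize continuous canopy cover into quartile classes
#'
#' @param canopy an [hs_raster] of percent canopy cover in `[0, 100]`.
#' @return Categorical [hs_raster] with integer codes 1-4 and levels
#'   [canopy_levels].
#' @export
categorize_canopy <- function(canopy) {
  v <- raster_values(canopy)
  if (any(v < 0 | v > 100, na.rm = TRUE)) {
    stop("canopy values must lie in [0, 100]", call. = FALSE)
  }
  k <- matrix(NA_real_, nrow(v), ncol(v))
  # bins (25,50], (50,75], (75,100]: a cell at exactly 25 is sparse, 50 open
  k[!is.na(v)] <- findInterval(v[!is.na(v)], c(25, 50, 75), left.open = TRUE) + 1
  with_values(canopy, k, levels = canopy_levels)
}

square_counts <- function(ind, w) {
  # square (2w+1)^2 window sum via separable clamped prefix sums
  b <- box_from_prefix(row_prefix(ind), w)
  t(box_from_prefix(row_prefix(t(b)), w))
}

#' Majority (focal mode) smoothing of a categorical raster
#'
#' Each cell is replaced by the modal class of the square window around it
#' (window truncated at the extent edge); ties keep the center cell's value.
#' The filter is applied `passes` times.
#'
#' @param r categorical [hs_raster] with integer codes.
#' @param window odd window edge length in cells (default 3, i.e. 30 m x 30 m
#'   at 10 m resolution).
#' @param passes number of repeated applications (default 2).
#' @return Smoothed categorical [hs_raster].
#' @export
focal_mode <- function(r, window = 3L, passes = 2L) {
  if (window < 1 || window %% 2 != 1) {
    stop("`window` must be a positive odd number of cells", call. = FALSE)
  }
  if (passes < 0) stop("`passes` must be >= 0", call. = FALSE)
  v <- raster_values(r)
  codes <- sort(unique(v[!is.na(v)]))
  w <- (window - 1L) / 2L
  for (p in seq_len(passes)) {
    counts <- lapply(codes, function(k) {
      square_counts(matrix(as.numeric(!is.na(v) & v == k), nrow(v)), w)
    })
    maxc <- Reduce(pmax, counts)
    nmax <- Reduce(`+`, lapply(counts, function(cc) (cc == maxc) * 1))
    out <- v # ties and NA keep center value
    for (i in seq_along(codes)) {
      sel <- !is.na(v) & counts[[i]] == maxc & nmax == 1
      out[sel] <- codes[i]
    }
    v <- out
  }
  with_values(r, v)
}

# ---- connected components (4-connectivity) ----------------------------------

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

label_components <- function(v) {
  # v: integer category matrix (no NA); returns integer label matrix with
  # consecutive ids, rook adjacency
  n <- nrow(v); m <- ncol(v)
  runid <- matrix(0L, n, m)
  nrun <- 0L
  for (i in seq_len(n)) {
    r <- rle(v[i, ])
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    ids <- nrun + seq_along(r$lengths)
    runid[i, ] <- rep(ids, r$lengths)
    nrun <- nrun + length(r$lengths)
  }
  parent <- seq_len(nrun)
  if (n > 1) {
    same <- v[-1, , drop = FALSE] == v[-n, , drop = FALSE]
    a <- runid[-1, , drop = FALSE][same]
    b <- runid[-n, , drop = FALSE][same]
    pairs <- unique(cbind(a, b))
    for (k in seq_len(nrow(pairs))) {
      ra <- uf_find(parent, pairs[k, 1]); rb <- uf_find(parent, pairs[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nrun), function(i) uf_find(parent, i), integer(1))
  labels <- matrix(match(roots, unique(roots))[runid], n, m)
  labels
}

boundary_masks <- function(labels) {
  n <- nrow(labels); m <- ncol(labels)
  list(
    vert = if (n > 1) labels[-1, , drop = FALSE] != labels[-n, , drop = FALSE]
           else matrix(FALSE, 0, m),
    horiz = if (m > 1) labels[, -1, drop = FALSE] != labels[, -m, drop = FALSE]
            else matrix(FALSE, n, 0)
  )
}

#' Delineate canopy patches from a smoothed categorical raster
#'
#' Connected components (rook adjacency) are formed per class; components
#' smaller than `min_area_ha` are absorbed into the adjacent patch sharing the
#' longest boundary (ties broken toward the lower-numbered class, then the
#' lower patch id), so every cell ends in a retained patch. The rule is a
#' strict less-than: a 0.40-ha component is kept.
#'
#' @param catr categorical [hs_raster] (typically [categorize_canopy] then
#'   [focal_mode]).
#' @param min_area_ha minimum patch size in hectares (default 0.4).
#' @return A `patch_set`: labeled raster, per-patch table (category, area,
#'   perimeter), and internal boundary segments (extent border excluded).
#' @export
delineate_patches <- function(catr, min_area_ha = 0.4) {
  v <- raster_values(catr)
  if (length(v) == 0) stop("empty raster", call. = FALSE)
  if (any(is.na(v))) stop("categorical raster must not contain NA", call. = FALSE)
  res <- catr$res
  cell_ha <- res^2 / 1e4
  min_cells <- min_area_ha / cell_ha

  for (round in 1:50) {
    labels <- label_components(v)
    sizes <- tabulate(labels)
    small <- which(sizes < min_cells - 1e-9)
    if (length(small) == 0 || max(labels) == 1) break
    cat_of <- as.numeric(tapply(c(v), c(labels), function(z) z[1]))
    changed <- FALSE
    # absorb every sub-minimum patch into its longest-shared-boundary
    # neighbor in one sweep, then relabel; chains resolve over rounds
    for (p in small[order(sizes[small], cat_of[small], small)]) {
      nb <- neighbor_edge_counts(labels, p)
      if (nrow(nb) == 0) next # isolated patch spanning a whole stripe: keep
      nb$cat <- cat_of[nb$patch]
      nb <- nb[order(-nb$edges, nb$cat, nb$patch), , drop = FALSE]
      v[labels == p] <- nb$cat[1]
      changed <- TRUE
    }
    if (!changed) break
  }

  labels <- label_components(v)
  sizes <- tabulate(labels)
  cat_of <- as.numeric(tapply(c(v), c(labels), function(z) z[1]))

  bm <- boundary_masks(labels)
  n <- nrow(labels); m <- ncol(labels)
  xmin <- catr$xmin; ymin <- catr$ymin

  segs <- matrix(numeric(0), 0, 4)
  if (nrow(bm$vert)) {
    idx <- which(bm$vert, arr.ind = TRUE) # between rows idx[,1] and idx[,1]+1
    if (nrow(idx)) {
      x0 <- xmin + (idx[, 2] - 1) * res
      yy <- ymin + idx[, 1] * res
      segs <- rbind(segs, cbind(x0, yy, x0 + res, yy))
    }
  }
  if (ncol(bm$horiz)) {
    idx <- which(bm$horiz, arr.ind = TRUE) # between cols idx[,2] and idx[,2]+1
    if (nrow(idx)) {
      xx <- xmin + idx[, 2] * res
      y0 <- ymin + (idx[, 1] - 1) * res
      segs <- rbind(segs, cbind(xx, y0, xx, y0 + res))
    }
  }
  colnames(segs) <- c("x0", "y0", "x1", "y1")

  # per-cell internal-edge length: half of each shared boundary edge per side
  elen <- matrix(0, n, m)
  if (nrow(bm$vert)) {
    add <- matrix(0, n, m)
    add[-n, ][bm$vert] <- add[-n, ][bm$vert] + res / 2
    elen <- elen + add
    add <- matrix(0, n, m)
    add[-1, ][bm$vert] <- add[-1, ][bm$vert] + res / 2
    elen <- elen + add
  }
  if (ncol(bm$horiz)) {
    add <- matrix(0, n, m)
    add[, -m][bm$horiz] <- add[, -m][bm$horiz] + res / 2
    elen <- elen + add
    add <- matrix(0, n, m)
    add[, -1][bm$horiz] <- add[, -1][bm$horiz] + res / 2
    elen <- elen + add
  }

  # perimeter includes the extent border (true patch outline)
  per_edges <- integer(max(labels))
  lab_n <- rbind(labels[-1, , drop = FALSE], matrix(0L, 1, m))
  lab_s <- rbind(matrix(0L, 1, m), labels[-n, , drop = FALSE])
  lab_e <- cbind(labels[, -1, drop = FALSE], matrix(0L, n, 1))
  lab_w <- cbind(matrix(0L, n, 1), labels[, -m, drop = FALSE])
  for (nbm in list(lab_n, lab_s, lab_e, lab_w)) {
    per_edges <- per_edges + tabulate(labels[labels != nbm], nbins = max(labels))
  }

  patches <- tibble::tibble(
    patch_id = seq_len(max(labels)),
    category = as.integer(cat_of),
    cat_label = if (!is.null(catr$levels)) catr$levels[as.integer(cat_of)] else
      as.character(cat_of),
    n_cells = as.integer(sizes),
    area_ha = sizes * cell_ha,
    perimeter_m = per_edges * res
  )

  structure(
    list(
      labels = with_values(catr, labels, levels = NULL),
      category = with_values(catr, matrix(cat_of[labels], n, m), levels = catr$levels),
      patches = patches,
      segments = segs,
      edge_len = with_values(catr, elen, levels = NULL),
      res = res
    ),
    class = "patch_set"
  )
}

neighbor_edge_counts <- function(labels, p) {
  n <- nrow(labels); m <- ncol(labels)
  cnt <- integer(max(labels))
  mask <- labels == p
  if (n > 1) {
    up <- mask[-n, , drop = FALSE] & !mask[-1, , drop = FALSE]
    nb <- labels[-1, , drop = FALSE][up]
    cnt <- cnt + tabulate(nb, nbins = length(cnt))
    dn <- mask[-1, , drop = FALSE] & !mask[-n, , drop = FALSE]
    nb <- labels[-n, , drop = FALSE][dn]
    cnt <- cnt + tabulate(nb, nbins = length(cnt))
  }
  if (m > 1) {
    rt <- mask[, -m, drop = FALSE] & !mask[, -1, drop = FALSE]
    nb <- labels[, -1, drop = FALSE][rt]
    cnt <- cnt + tabulate(nb, nbins = length(cnt))
    lt <- mask[, -1, drop = FALSE] & !mask[, -m, drop = FALSE]
    nb <- labels[, -m, drop = FALSE][lt]
    cnt <- cnt + tabulate(nb, nbins = length(cnt))
  }
  cnt[p] <- 0L
  keep <- which(cnt > 0)
  data.frame(patch = keep, edges = cnt[keep])
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, %d boundary segments\n",
              nrow(x$patches), nrow(x$segments)))
  print(dplyr::count(x$patches, .data$cat_label, wt = .data$area_ha, name = "area_ha"))
  invisible(x)
}

#' Patch edge density within a circular neighborhood
#'
#' Total internal patch-boundary length (extent border excluded) within the
#' circular window around each cell, divided by the window area, in km/km^2.
#' Boundary length is attributed to cells (half of each shared edge to the
#' cell on either side) and summed over cells whose centers fall in the window.
#'
#' @param patches a `patch_set` from [delineate_patches].
#' @param radius window radius in m; must be at least the cell size.
#' @return An [hs_raster] of edge density (km/km^2).
#' @export
edge_density <- function(patches, radius) {
  if (radius < patches$res) stop("`radius` must be >= the cell size", call. = FALSE)
  fc <- focal_sum_count(raster_values(patches$edge_len), radius, patches$res)
  area_km2 <- pi * radius^2 / 1e6
  with_values(patches$edge_len, (fc$sum / 1000) / area_km2)
}

#' Distance from points to the nearest patch boundary
#'
#' Euclidean distance to the nearest internal patch-boundary segment; 0 on a
#' boundary, `Inf` when the patch set has no internal boundaries.
#'
#' @param patches a `patch_set`.
#' @param x,y point coordinates (m).
#' @return Numeric vector of distances (m).
#' @export
distance_to_edge <- function(patches, x, y) {
  ext <- raster_extent(patches$labels)
  if (any(x < ext[1] | x > ext[2] | y < ext[3] | y > ext[4], na.rm = TRUE)) {
    stop("points outside the raster extent", call. = FALSE)
  }
  dist_to_segments(x, y, patches$segments)
}

#' Circular neighborhood mean
#'
#' Mean over cells whose centers lie within `radius` of each focal cell's
#' center; missing cells are ignored. With `radius` smaller than the cell
#' size the window is the cell itself.
#'
#' @param r an [hs_raster].
#' @param radius window radius in m (>= 0).
#' @return An [hs_raster] of windowed means.
#' @export
neighborhood_mean <- function(r, radius) {
  if (radius < 0) stop("`radius` must be >= 0", call. = FALSE)
  fc <- focal_sum_count(raster_values(r), radius, r$res)
  out <- fc$sum / fc$count
  out[fc$count == 0] <- NA_real_
  with_values(r, out, levels = NULL)
}

#' Topographic position index
#'
#' Cell elevation minus the mean elevation of the circular neighborhood
#' (center excluded); negative in drainages, positive on ridges.
#'
#' @param elev elevation [hs_raster] (m).
#' @param radius neighborhood radius in m; must be at least the cell size.
#' @return An [hs_raster] of TPI values (m).
#' @export
tpi <- function(elev, radius) {
  if (radius < elev$res) stop("`radius` must be >= the cell size", call. = FALSE)
  v <- raster_values(elev)
  fc <- focal_sum_count(v, radius, elev$res, exclude_center = TRUE)
  nb_mean <- fc$sum / fc$count
  nb_mean[fc$count == 0] <- NA_real_
  with_values(elev, v - nb_mean, levels = NULL)
}

#' Slope and linearized aspect from elevation
#'
#' Slope (degrees) from Horn's 3x3 finite differences; aspect is folded into a
#' heat-load-style linear index `(1 - cos(aspect - fold)) / 2` in `[0, 1]`, 0
#' at the fold azimuth (default 30 degrees, i.e. NNE) and 1 opposite it. Flat
#' cells get index 0.5. Border cells are `NA`.
#'
#' @param elev elevation [hs_raster] (m).
#' @param fold_deg fold azimuth for the aspect linearization (degrees
#'   clockwise from north, default 30).
#' @return A list with [hs_raster] elements `slope` and `aspect_lin`.
#' @export
slope_linear_aspect <- function(elev, fold_deg = 30) {
  z <- raster_values(elev)
  n <- nrow(z); m <- ncol(z)
  p <- matrix(NA_real_, n, m); q <- matrix(NA_real_, n, m)
  if (n >= 3 && m >= 3) {
    i <- 2:(n - 1); j <- 2:(m - 1)
    zc <- function(di, dj) z[i + di, j + dj, drop = FALSE]
    # row + 1 is north (row 1 = south), col + 1 is east
    p[i, j] <- ((zc(1, 1) + 2 * zc(0, 1) + zc(-1, 1)) -
                (zc(1, -1) + 2 * zc(0, -1) + zc(-1, -1))) / (8 * elev$res)
    q[i, j] <- ((zc(1, -1) + 2 * zc(1, 0) + zc(1, 1)) -
                (zc(-1, -1) + 2 * zc(-1, 0) + zc(-1, 1))) / (8 * elev$res)
  }
  slope <- atan(sqrt(p^2 + q^2)) * 180 / pi
  az <- (atan2(-p, -q) * 180 / pi) %% 360 # downslope azimuth, clockwise from N
  idx <- (1 - cos((az - fold_deg) * pi / 180)) / 2
  idx[!is.na(slope) & slope == 0] <- 0.5
  list(
    slope = with_values(elev, slope, levels = NULL),
    aspect_lin = with_values(elev, idx, levels = NULL)
  )
}

#' Extract multi-scale covariates at point locations
#'
#' Builds the full covariate table for a set of points: circular-window canopy
#' means, vegetation-class proportions and TPI at each scale, elevation, slope
#' and linearized aspect at the point, and the patch covariates (category,
#' size, distance to edge, edge density at each scale).
#'
#' @param points tibble with columns `x`, `y` (m); other columns are kept.
#' @param landscape a `landscape_stack` (see [generate_landscape]).
#' @param patches optional `patch_set`; when `NULL` the patch covariates are
#'   skipped.
#' @param scales neighborhood radii in m (default `c(100, 400, 4000)`).
#' @param families which covariate families to compute, a subset of
#'   `c("canopy", "veg", "terrain", "patch")`.
#' @param disturbed optional 0/1 [hs_raster]; points on flagged cells are
#'   dropped (locations whose habitat changed after the landscape was
#'   measured).
#' @return The input tibble plus covariate columns, one row per retained
#'   point; rows outside the extent carry `NA` covariates (with a warning).
#' @export
extract_covariates <- function(points, landscape, patches = NULL,
                               scales = c(100, 400, 4000),
                               families = c("canopy", "veg", "terrain", "patch"),
                               disturbed = NULL) {
  stopifnot(all(c("x", "y") %in% names(points)))
  families <- match.arg(families, several.ok = TRUE)
  out <- tibble::as_tibble(points)

  if (!is.null(disturbed)) {
    flag <- raster_extract(disturbed, out$x, out$y)
    out <- out[is.na(flag) | flag == 0, , drop = FALSE]
  }

  idx <- cell_index(landscape$canopy, out$x, out$y)
  if (anyNA(idx$row)) {
    warning(sum(is.na(idx$row)), " point(s) outside the raster extent; covariates set to NA")
  }

  grab <- function(r) raster_extract(r, out$x, out$y)

  if ("canopy" %in% families) {
    for (s in scales) out[[paste0("canopy_", s)]] <- grab(neighborhood_mean(landscape$canopy, s))
  }
  if ("veg" %in% families && !is.null(landscape$vegclass)) {
    codes <- landscape$veg_codes %||% sort(unique(c(raster_values(landscape$vegclass))))
    for (k in codes) {
      ind <- with_values(landscape$vegclass,
                         (raster_values(landscape$vegclass) == k) * 1, levels = NULL)
      for (s in scales) out[[paste0("veg", k, "_", s)]] <- grab(neighborhood_mean(ind, s))
    }
  }
  if ("terrain" %in% families && !is.null(landscape$elevation)) {
    out$elev <- grab(landscape$elevation)
    sa <- slope_linear_aspect(landscape$elevation)
    out$slope <- grab(sa$slope)
    out$aspect_lin <- grab(sa$aspect_lin)
    for (s in scales) out[[paste0("tpi_", s)]] <- grab(tpi(landscape$elevation, s))
  }
  if ("patch" %in% families && !is.null(patches)) {
    pid <- grab(patches$labels)
    out$patch_cat <- patches$patches$cat_label[pid]
    out$patch_size_ha <- patches$patches$area_ha[pid]
    ok <- !is.na(idx$row)
    de <- rep(NA_real_, nrow(out))
    de[ok] <- distance_to_edge(patches, out$x[ok], out$y[ok])
    out$dist_edge <- de
    for (s in scales) out[[paste0("edge_density_", s)]] <- grab(edge_density(patches, s))
  }
  out
}
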