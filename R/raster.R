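#' Planar gridded raster
#'
#' A minimal matrix-backed raster on a planar metric grid. Row 1 of the value
#' matrix is the southernmost row; columns run west to east. Cell centers sit
#' at `xmin + (col - 0.5) * res`, `ymin + (row - 0.5) * res`, and a point
#' belongs to the half-open cell `[x0, x0 + res) x [y0, y0 + res)`.
#'
#' @param values numeric matrix of cell values (row 1 = south).
#' @param xmin,ymin coordinates of the grid origin (south-west corner), m.
#' @param res cell edge length, m.
#' @param levels optional character vector of category labels for integer-coded
#'   categorical rasters (value `k` means `levels[k]`).
#' @return An object of class `hs_raster`.
#' @export
hs_raster <- function(values, xmin = 0, ymin = 0, res = 10, levels = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values))
  if (!is.numeric(res) || length(res) != 1 || res <= 0) {
    stop("`res` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res, levels = levels),
    class = "hs_raster"
  )
}

#' @export
print.hs_raster <- function(x, ...) {
  e <- raster_extent(x)
  cat(sprintf(
    "<hs_raster> %d rows x %d cols, res %g m, extent [%g, %g] x [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$res, e[1], e[2], e[3], e[4]
  ))
  if (!is.null(x$levels)) {
    cat("  categorical:", paste(x$levels, collapse = ", "), "\n")
  } else {
    rng <- range(x$values, na.rm = TRUE)
    cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' @export
dim.hs_raster <- function(x) dim(x$values)

#' Raster extent
#'
#' @param r an [hs_raster].
#' @return Numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(r) {
  c(r$xmin, r$xmin + ncol(r$values) * r$res,
    r$ymin, r$ymin + nrow(r$values) * r$res)
}

#' Raster values as a matrix
#' @param r an [hs_raster].
#' @export
raster_values <- function(r) r$values

#' Row/column indices of the cells containing points
#'
#' Half-open cell convention: a point on a cell's west or south edge belongs
#' to that cell. Points outside the extent get `NA` indices.
#'
#' @param r an [hs_raster].
#' @param x,y point coordinates (m), recycled to common length.
#' @return A tibble with columns `row`, `col`.
#' @export
cell_index <- function(r, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  col <- floor((x - r$xmin) / r$res) + 1L
  row <- floor((y - r$ymin) / r$res) + 1L
  bad <- is.na(row) | is.na(col) |
    row < 1L | row > nrow(r$values) | col < 1L | col > ncol(r$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Extract cell values at point locations
#'
#' @inheritParams cell_index
#' @return Numeric vector of cell values (`NA` outside the extent).
#' @export
raster_extract <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' @export
as_tibble.hs_raster <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  xs <- x$xmin + (rep(seq_len(nc), each = nr) - 0.5) * x$res
  ys <- x$ymin + (rep(seq_len(nr), times = nc) - 0.5) * x$res
  vals <- as.vector(x$values)
  tibble::tibble(x = xs, y = ys, value = vals)
}

#' Plot a raster with ggplot2
#'
#' @param object an [hs_raster].
#' @param ... unused.
#' @export
autoplot.hs_raster <- function(object, ...) {
  df <- as_tibble.hs_raster(object)
  if (!is.null(object$levels)) {
    df$value <- factor(object$levels[df$value], levels = object$levels)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$res), c(b$xmin, b$ymin, b$res)))
}

with_values <- function(r, values, levels = r$levels) {
  hs_raster(values, xmin = r$xmin, ymin = r$ymin, res = r$res, levels = levels)
}

# ---- circular focal machinery -----------------------------------------------
# A circular window of radius `radius` (m) contains the cells whose centers lie
# within `radius` of the focal cell's center. The window sum is decomposed into
# horizontal runs: for each row offset di the run half-width is
# floor(sqrt(radius^2/res^2 - di^2)) cells, and each run sum comes from clamped
# row-prefix sums, so results are exact (no FFT round-off) in O(n*m*R).

row_prefix <- function(mat) {
  if (ncol(mat) == 1L) return(mat)
  t(apply(mat, 1L, cumsum))
}

# sum over columns j-w .. j+w, clamped to the matrix, from row-prefix sums
box_from_prefix <- function(cs, w) {
  m <- ncol(cs)
  hi <- pmin(seq_len(m) + w, m)
  lo <- seq_len(m) - w - 1L
  right <- cs[, hi, drop = FALSE]
  left <- matrix(0, nrow(cs), m)
  sel <- lo >= 1L
  if (any(sel)) left[, sel] <- cs[, lo[sel], drop = FALSE]
  right - left
}

add_row_shift <- function(acc, b, di) {
  # acc[i, ] += b[i + di, ]
  n <- nrow(acc)
  if (abs(di) >= n) return(acc)
  if (di == 0L) return(acc + b)
  if (di > 0L) {
    i <- seq_len(n - di)
    acc[i, ] <- acc[i, ] + b[i + di, , drop = FALSE]
  } else {
    i <- seq.int(1L - di, n)
    acc[i, ] <- acc[i, ] + b[i + di, , drop = FALSE]
  }
  acc
}

# Returns list(sum, count): windowed sum of non-NA values and non-NA cell count.
focal_sum_count <- function(mat, radius, res, exclude_center = FALSE) {
  n <- nrow(mat); m <- ncol(mat)
  notna <- !is.na(mat)
  v <- mat; v[!notna] <- 0
  cnt <- matrix(as.numeric(notna), n, m)
  rmax <- floor(radius / res)
  if (rmax < 1L) {
    s <- v; k <- cnt
  } else {
    csv <- row_prefix(v)
    csn <- row_prefix(cnt)
    s <- matrix(0, n, m); k <- matrix(0, n, m)
    for (di in 0:rmax) {
      w <- floor(sqrt(radius^2 / res^2 - di^2))
      bv <- box_from_prefix(csv, w)
      bn <- box_from_prefix(csn, w)
      s <- add_row_shift(s, bv, di)
      k <- add_row_shift(k, bn, di)
      if (di > 0L) {
        s <- add_row_shift(s, bv, -di)
        k <- add_row_shift(k, bn, -di)
      }
    }
  }
  if (exclude_center) {
    s <- s - v
    k <- k - cnt
  }
  list(sum = s, count = k)
}
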