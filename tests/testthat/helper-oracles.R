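# Independent brute-force oracles. These deliberately share no code with the
# package's windowed/prefix-sum implementations: everything is a direct loop
# over cells or segments.

oracle_circular_stat <- function(m, radius, res, fun = mean,
                                 exclude_center = FALSE) {
  n <- nrow(m); k <- ncol(m)
  out <- matrix(NA_real_, n, k)
  rmax <- ceiling(radius / res)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    vals <- c()
    for (di in -rmax:rmax) for (dj in -rmax:rmax) {
      if (exclude_center && di == 0 && dj == 0) next
      if ((di^2 + dj^2) * res^2 > radius^2) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= k && !is.na(m[ii, jj])) {
        vals <- c(vals, m[ii, jj])
      }
    }
    out[i, j] <- if (length(vals)) fun(vals) else NA_real_
  }
  out
}

# windowed sum of a per-cell quantity (used for the edge-length oracle)
oracle_circular_sum <- function(m, radius, res) {
  oracle_circular_stat(m, radius, res, fun = sum)
}

oracle_point_segment_dist <- function(x, y, segs) {
  best <- Inf
  for (s in seq_len(nrow(segs))) {
    ax <- segs[s, 1]; ay <- segs[s, 2]; bx <- segs[s, 3]; by <- segs[s, 4]
    dx <- bx - ax; dy <- by - ay
    tt <- ((x - ax) * dx + (y - ay) * dy) / (dx^2 + dy^2)
    tt <- min(max(tt, 0), 1)
    d <- sqrt((x - (ax + tt * dx))^2 + (y - (ay + tt * dy))^2)
    best <- min(best, d)
  }
  best
}

# Moran's I with rook weights, direct double loop over neighbor pairs
oracle_morans_i <- function(m) {
  z <- m - mean(m)
  n <- nrow(m); k <- ncol(m)
  num <- 0; w <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    if (i < n) { num <- num + 2 * z[i, j] * z[i + 1, j]; w <- w + 2 }
    if (j < k) { num <- num + 2 * z[i, j] * z[i, j + 1]; w <- w + 2 }
  }
  (length(m) / w) * num / sum(z^2)
}

make_track <- function(times_min, id = "F01", x = NULL, y = NULL,
                       activity = NULL) {
  n <- length(times_min)
  tibble::tibble(
    individual_id = id,
    timestamp = as.POSIXct("2017-02-01", tz = "UTC") + times_min * 60,
    x = x %||% seq_len(n) * 10,
    y = y %||% rep(0, n),
    activity = activity %||% rep(NA_real_, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_raster <- function(value, n = 10, m = n, res = 10) {
  hs_raster(matrix(value, n, m), res = res)
}
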