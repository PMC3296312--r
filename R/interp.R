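# Vectorized bilinear interpolation on a regular grid.
# Z has length(y) rows and length(x) columns; query points outside the grid
# are clamped to the nearest edge. x and y must be strictly increasing.
bilinear_grid <- function(x, y, Z, xp, yp) {
  nx <- length(x)
  ny <- length(y)
  i <- findInterval(xp, x, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= nx] <- nx - 1L
  j <- findInterval(yp, y, rightmost.closed = TRUE)
  j[j < 1L] <- 1L
  j[j >= ny] <- ny - 1L
  tx <- (xp - x[i]) / (x[i + 1L] - x[i])
  ty <- (yp - y[j]) / (y[j + 1L] - y[j])
  tx <- pmin(pmax(tx, 0), 1)
  ty <- pmin(pmax(ty, 0), 1)
  Z[cbind(j, i)] * (1 - tx) * (1 - ty) +
    Z[cbind(j, i + 1L)] * tx * (1 - ty) +
    Z[cbind(j + 1L, i)] * (1 - tx) * ty +
    Z[cbind(j + 1L, i + 1L)] * tx * ty
}
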