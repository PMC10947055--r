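# Cubic-convolution (Keys, a = -0.5) resampling primitives. The kernel
# reproduces constant and linear signals exactly and interpolates (h(0)=1,
# h(+-1)=h(+-2)=0), so integer-coordinate sampling is an identity.

keys_kernel <- function(s, a = -0.5) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  i2 <- !i1 & s < 2
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

#' Sample a masked image at continuous coordinates by bicubic interpolation
#'
#' Separable Keys cubic convolution over the 4x4 pixel neighbourhood of each
#' query point. No extrapolation: a query is invalid if any tap with nonzero
#' weight falls outside the image, or if any contributing source pixel is
#' invalid.
#'
#' @param values numeric matrix.
#' @param valid logical matrix, same shape.
#' @param x,y numeric vectors of 0-based column / row coordinates.
#' @return list with `values` and `valid` vectors, one entry per query.
#' @keywords internal
bicubic_sample <- function(values, valid, x, y) {
  nr <- nrow(values); nc <- ncol(values)
  n <- length(x)
  stopifnot(length(y) == n)
  v <- values
  v[!valid] <- 0  # invalid pixels contribute 0; flagged via `ok` below

  ix <- floor(pmin(pmax(x, -3), nc + 2)); iy <- floor(pmin(pmax(y, -3), nr + 2))
  fx <- x - ix;   fy <- y - iy

  wx <- lapply(-1:2, function(m) keys_kernel(fx - m))
  wy <- lapply(-1:2, function(m) keys_kernel(fy - m))

  out <- numeric(n)
  ok <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  tol <- 1e-12
  for (m in 1:4) {
    cm <- ix + (m - 2)                            # 0-based column of this tap
    wxm <- wx[[m]]
    inx <- cm >= 0 & cm <= nc - 1
    cmc <- pmin(pmax(cm, 0), nc - 1)
    for (k in 1:4) {
      w <- wxm * wy[[k]]
      use <- abs(w) > tol
      if (!any(use)) next
      rk <- iy + (k - 2)
      iny <- rk >= 0 & rk <= nr - 1
      rkc <- pmin(pmax(rk, 0), nr - 1)
      idx <- rkc + 1L + cmc * nr                  # column-major linear index
      inside <- inx & iny
      contrib <- numeric(n)
      gi <- use & inside
      contrib[gi] <- w[gi] * v[idx[gi]]
      out <- out + contrib
      ok <- ok & (!use | (inside & valid[idx]))
    }
  }
  out[!ok] <- NA_real_
  list(values = out, valid = ok)
}
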