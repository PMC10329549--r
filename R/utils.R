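# Internal numeric/image helpers shared across modules.

# Round half away from zero (symmetric under negation, unlike base round()).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Reflect an index vector into [1, n] (mirror boundary without repeating the
# edge sample twice in a row beyond one bounce; sufficient for small offsets).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  idx <- abs(idx - 1L)
  period <- 2L * (n - 1L)
  idx <- idx %% period
  ifelse(idx >= n, period - idx, idx) + 1L
}

# Shift a matrix by (dr, dc) with mirror-reflected borders:
# result[r, c] = m[reflect(r + dr), reflect(c + dc)].
shift_reflect <- function(m, dr, dc) {
  m[reflect_index(seq_len(nrow(m)) + dr, nrow(m)),
    reflect_index(seq_len(ncol(m)) + dc, ncol(m)), drop = FALSE]
}

# Mean over a (2k+1) x (2k+1) box with reflected borders.
box_mean <- function(m, half) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -half:half) {
    row_sh <- m[reflect_index(seq_len(nrow(m)) + dr, nrow(m)), , drop = FALSE]
    for (dc in -half:half) {
      acc <- acc + row_sh[, reflect_index(seq_len(ncol(m)) + dc, ncol(m)),
                          drop = FALSE]
    }
  }
  acc / (2 * half + 1)^2
}

# Separable binomial [1 4 6 4 1]/16 smoothing with reflected borders,
# the standard Gaussian-pyramid kernel.
binomial_smooth <- function(m) {
  w <- c(1, 4, 6, 4, 1) / 16
  offs <- -2:2
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(offs)) {
    acc <- acc + w[i] * m[reflect_index(seq_len(nrow(m)) + offs[i], nrow(m)), ,
                          drop = FALSE]
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(offs)) {
    out <- out + w[i] * acc[, reflect_index(seq_len(ncol(m)) + offs[i], ncol(m)),
                            drop = FALSE]
  }
  out
}

# Bilinear upsampling of a matrix to target dimensions, aligning the corner
# pixel centers of source and target grids.
bilinear_resize <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  rf <- if (nr == 1L) rep(1, nr) else seq(1, sr, length.out = nr)
  cf <- if (nc == 1L) rep(1, nc) else seq(1, sc, length.out = nc)
  r0 <- pmin(floor(rf), sr - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cf), sc - 1L); c0 <- pmax(c0, 1L)
  tr <- rf - r0; tc <- cf - c0
  if (sr == 1L) { r0 <- rep(1L, nr); tr <- rep(0, nr) }
  if (sc == 1L) { c0 <- rep(1L, nc); tc <- rep(0, nc) }
  a <- m[r0, c0, drop = FALSE]; b <- m[pmin(r0 + 1L, sr), c0, drop = FALSE]
  cc <- m[r0, pmin(c0 + 1L, sc), drop = FALSE]
  d <- m[pmin(r0 + 1L, sr), pmin(c0 + 1L, sc), drop = FALSE]
  TR <- matrix(tr, nr, nc); TC <- matrix(tc, nr, nc, byrow = TRUE)
  a * (1 - TR) * (1 - TC) + b * TR * (1 - TC) + cc * (1 - TR) * TC + d * TR * TC
}

# 4-connected component labelling of a binary matrix. Returns an integer
# matrix of labels (0 = background), labelled in raster-scan discovery order.
label_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask != 0)
  if (length(fg) == 0L) return(lab)
  cur <- 0L
  stack <- integer(nr * nc)
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      if (r > 1L) { q <- p - 1L
        if (mask[q] != 0 && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (r < nr) { q <- p + 1L
        if (mask[q] != 0 && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (cl > 1L) { q <- p - nr
        if (mask[q] != 0 && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (cl < nc) { q <- p + nr
        if (mask[q] != 0 && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
    }
  }
  lab
}

# Evaluate a polynomial given coefficients highest degree first.
polyval_desc <- function(coefs, x) {
  out <- rep(0, length(x))
  for (cf in coefs) out <- out * x + cf
  out
}

# Derivative coefficients (highest degree first).
polyderiv_desc <- function(coefs) {
  d <- length(coefs) - 1L
  if (d == 0L) return(0)
  coefs[seq_len(d)] * (d:1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
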