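# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# geodesic reconstruction by dilation: iterate pointwise min(mask, dilate8)
# until fixpoint
oracle_reconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  repeat {
    nr <- nrow(J); nc <- ncol(J)
    D <- J
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      src_r <- seq_len(nr) - dr
      src_c <- seq_len(nc) - dc
      ok_r <- src_r >= 1 & src_r <= nr
      ok_c <- src_c >= 1 & src_c <= nc
      shifted <- matrix(-Inf, nr, nc)
      shifted[ok_r, ok_c] <- J[src_r[ok_r], src_c[ok_c]]
      D <- pmax(D, shifted)
    }
    nxt <- pmin(D, mask)
    if (all(nxt == J)) return(J)
    J <- nxt
  }
}

# erosion by an arbitrary flat structuring element, reflect padding, direct
# pixel loop
oracle_erode <- function(px, se) {
  r <- (nrow(se) - 1) / 2
  mirror1 <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    j[j < 0] <- j[j < 0] + 2 * n
    ifelse(j < n, j + 1, 2 * n - j)
  }
  out <- px
  for (rr in seq_len(nrow(px))) for (cc in seq_len(ncol(px))) {
    vals <- c()
    for (dr in -r:r) for (dc in -r:r) {
      if (!se[dr + r + 1, dc + r + 1]) next
      vals <- c(vals, px[mirror1(rr + dr, nrow(px)), mirror1(cc + dc, ncol(px))])
    }
    out[rr, cc] <- min(vals)
  }
  out
}

# Otsu by exhaustive scan of all candidate thresholds on a 256-bin histogram
oracle_otsu <- function(px, mx) {
  v <- pmin(floor(px / mx * 256), 255)
  h <- tabulate(v + 1, nbins = 256) / length(v)
  lev <- (seq_len(256) - 0.5) / 256
  best <- -Inf; best_t <- 0
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * lev[1:k]) / w0
    mu1 <- sum(h[(k + 1):256] * lev[(k + 1):256]) / w1
    bc <- w0 * w1 * (mu0 - mu1)^2
    if (bc > best) { best <- bc; best_t <- lev[k] + 0.5 / 256 }
  }
  best_t * mx
}

# per-pixel coefficient of variation across a list of matrices
oracle_cov <- function(mats, epsilon, variant) {
  k <- length(mats)
  out <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    v <- vapply(mats, function(m) m[r, c], 0)
    mu <- mean(v)
    disp <- mean((v - mu)^2)
    if (variant == "std") disp <- sqrt(disp)
    out[r, c] <- disp / (mu + epsilon)
  }
  out
}

# Haralick statistics by direct GLCM accumulation at one pixel (natural log,
# 0 log 0 = 0). Returns ASM, ENT, DOE, IMOC2 only (the ones used by the
# shipped models).
oracle_haralick_pixel <- function(q, r, c, ksize, nlevels) {
  h <- ksize %/% 2
  mirror1 <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    j[j < 0] <- j[j < 0] + 2 * n
    ifelse(j < n, j + 1, 2 * n - j)
  }
  win <- matrix(NA_integer_, ksize, ksize)
  for (dr in -h:h) for (dc in -h:h)
    win[dr + h + 1, dc + h + 1] <- q[mirror1(r + dr, nrow(q)), mirror1(c + dc, ncol(q))]
  P <- matrix(0, nlevels, nlevels)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (rr in seq_len(ksize)) for (cc in seq_len(ksize)) for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    if (r2 < 1 || r2 > ksize || c2 < 1 || c2 > ksize) next
    a <- win[rr, cc] + 1; b <- win[r2, c2] + 1
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P <- P / sum(P)
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  ent <- -sum(xlx(P))
  px <- rowSums(P); py <- colSums(P)
  pd <- numeric(nlevels)
  for (a in seq_len(nlevels)) for (b in seq_len(nlevels))
    pd[abs(a - b) + 1] <- pd[abs(a - b) + 1] + P[a, b]
  doe <- -sum(xlx(pd))
  hxy2 <- -sum(xlx(outer(px, py)))
  arg <- 1 - exp(-2 * (hxy2 - ent))
  c(ASM = sum(P^2), ENT = ent, DOE = doe,
    IMOC2 = if (arg > 0) sqrt(arg) else 0)
}

# count of 2x2 all-foreground blocks
count_2x2_blocks <- function(m) {
  sum(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1])
}

# count of 8-neighbors for every pixel of a logical mask
neighbor_counts <- function(m) {
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  s <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + p[2:(nrow(m) + 1) + dr, 2:(ncol(m) + 1) + dc]
  }
  s
}

# a small deterministic cell-like test image: bright blobs on dark bg
blob_image <- function(n = 64, centers, radius = 9, fg = 3000, bg = 150,
                       bit_depth = 12) {
  m <- matrix(bg, n, n)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((row(m) - centers[i, 1])^2 + (col(m) - centers[i, 2])^2)
    m[d <= radius] <- fg
  }
  gray_image(m, bit_depth)
}
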