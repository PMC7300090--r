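# Internal numerical helpers shared across modules.

# Vectorized HSV -> RGB. h in degrees, s and v in [0,1].
# Returns an n x 3 matrix. grDevices::hsv() goes through hex strings and is
# too slow for full-frame rendering.
.hsv2rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# RGB pixel array (H x W x 3) -> list of H x W matrices h (degrees), s, v.
.rgb2hsvDeg <- function(pixels) {
  d <- dim(pixels)
  m <- rbind(as.vector(pixels[, , 1]),
             as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# Axial circular statistics on angles in degrees in [0, 180).
# Angles are doubled, vector-averaged, and the mean halved back.
.axialStats <- function(angles_deg) {
  th <- 2 * angles_deg * pi / 180
  C <- mean(cos(th))
  S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mu <- (atan2(S, C) * 180 / pi / 2) %% 180
  list(mean_deg = mu, R = R, var = 1 - R)
}

# von Mises sampler (Best & Fisher rejection scheme). mu in radians.
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# Shift a matrix by (dr, dc), padding with `fill`.
.shiftMat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbour stack in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
# with row 1 at the top of the frame.
.neighbourStack <- function(m) {
  list(p2 = .shiftMat(m,  1,  0), p3 = .shiftMat(m,  1, -1),
       p4 = .shiftMat(m,  0, -1), p5 = .shiftMat(m, -1, -1),
       p6 = .shiftMat(m, -1,  0), p7 = .shiftMat(m, -1,  1),
       p8 = .shiftMat(m,  0,  1), p9 = .shiftMat(m,  1,  1))
}

# Zhang-Suen morphological thinning of a logical matrix down to a
# 1-pixel-wide, 8-connected skeleton. Fully vectorized; the iteration count
# is bounded by the maximum object half-width.
.thinZhangSuen <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- .neighbourStack(m)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seq9 <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- 0
      for (k in 1:8) A <- A + (seq9[[k]] == 0) * (seq9[[k + 1]] == 1)
      if (sub == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          nb$p2 * nb$p4 * nb$p6 == 0 & nb$p4 * nb$p6 * nb$p8 == 0
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          nb$p2 * nb$p4 * nb$p8 == 0 & nb$p2 * nb$p6 * nb$p8 == 0
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}

# Count of 8-neighbours that are TRUE, for a logical matrix.
.neighbourCount <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  nb <- .neighbourStack(m)
  nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
}

# Crossing number: 0->1 transitions in the circular neighbour sequence.
# Line pixels have 2 (staircase included), endpoints 1, branch points >= 3.
.crossingNumber <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  nb <- .neighbourStack(m)
  seq9 <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  A <- 0
  for (k in 1:8) A <- A + (seq9[[k]] == 0) * (seq9[[k + 1]] == 1)
  A
}

# 8-connected labelling of a logical matrix. EBImage::bwlabel is
# 4-connected, which fragments diagonal skeleton chains, so components are
# taken over the 8-neighbour pixel graph instead. Labels are deterministic
# (ordered by first pixel in column-major scan order).
.label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0) return(out)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- rows + off[1]; nc <- cols + off[2]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    j <- match((nc[ok] - 1L) * H + nr[ok], idx)
    keep <- !is.na(j)
    edges <- c(edges, rbind(which(ok)[keep], j[keep]))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber so labels follow first appearance in scan order
  out[idx] <- match(memb, unique(memb))
  out
}

# Total-least-squares axial orientation (degrees in [0,180)) of a set of
# pixel coordinates given as a matrix with columns (row, col). Angle is
# measured in image convention: 0 = horizontal, increasing counter-clockwise
# with the y-axis pointing up (i.e. -row).
.tlsAngle <- function(coords) {
  if (nrow(coords) < 2) return(0)
  x <- coords[, 2]
  y <- -coords[, 1]
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  ang <- 0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
  ang %% 180
}

# Absolute axial angle difference in degrees, in [0, 90].
.axialDiff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Coordinates (row, col) of pixels inside a disk.
.diskCoords <- function(cr, cc, radius, H, W) {
  r0 <- max(1, floor(cr - radius)); r1 <- min(H, ceiling(cr + radius))
  c0 <- max(1, floor(cc - radius)); c1 <- min(W, ceiling(cc + radius))
  if (r0 > r1 || c0 > c1) return(cbind(integer(0), integer(0)))
  rr <- r0:r1; cc2 <- c0:c1
  g <- expand.grid(row = rr, col = cc2)
  keep <- (g$row - cr)^2 + (g$col - cc)^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
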