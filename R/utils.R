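# Geometry and image helpers shared across modules.  Pixel centres sit at
# integer coordinates (x = column, y = row); coordinates written to disk are
# 0-based (x = col - 1, y = row - 1).

#' Round half away from zero
#'
#' Fixed-point rounding in which ties go up (90.65 -> 90.7 at 1 decimal),
#' matching how per-mL values and percentages are rendered in reports.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# linear index <-> (row, col) coordinates
idxToCoord <- function(idx, dim) {
  r <- ((idx - 1L) %% dim[1]) + 1L
  c <- ((idx - 1L) %/% dim[1]) + 1L
  cbind(row = r, col = c)
}

coordToIdx <- function(rc, dim) (rc[, 2L] - 1L) * dim[1L] + rc[, 1L]

# linear indices of pixels whose centres fall inside an axis-aligned ellipse
renderEllipse <- function(cx, cy, a, b, dim) {
  cmin <- max(1L, floor(cx - a)); cmax <- min(dim[2], ceiling(cx + a))
  rmin <- max(1L, floor(cy - b)); rmax <- min(dim[1], ceiling(cy + b))
  if (cmin > cmax || rmin > rmax) return(integer())
  cc <- cmin:cmax; rr <- rmin:rmax
  g <- expand.grid(row = rr, col = cc)
  inside <- ((g$col - cx) / a)^2 + ((g$row - cy) / b)^2 <= 1
  as.integer((g$col[inside] - 1L) * dim[1] + g$row[inside])
}

# radius of an axis-aligned ellipse along direction theta
radiusAtAngle <- function(a, b, theta) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# boundary pixels of a mask given as linear indices: any 4-neighbour outside
boundaryPixels <- function(idx, dim) {
  if (!length(idx)) return(idx)
  m <- logical(prod(dim)); m[idx] <- TRUE
  rc <- idxToCoord(idx, dim)
  nb <- function(dr, dc) {
    r <- rc[, 1] + dr; c <- rc[, 2] + dc
    ok <- r >= 1 & r <= dim[1] & c >= 1 & c <= dim[2]
    out <- !ok
    out[ok] <- !m[(c[ok] - 1L) * dim[1] + r[ok]]
    out
  }
  onb <- nb(1, 0) | nb(-1, 0) | nb(0, 1) | nb(0, -1)
  idx[onb]
}

# minimum pixel-centre distance between two masks (linear indices); Inf when
# either is empty, 0 when they share a pixel
maskMinDistance <- function(idxA, idxB, dim, boundary = TRUE) {
  if (!length(idxA) || !length(idxB)) return(Inf)
  if (any(idxA %in% idxB)) return(0)
  if (boundary) {
    idxA <- boundaryPixels(idxA, dim)
    idxB <- boundaryPixels(idxB, dim)
  }
  a <- idxToCoord(idxA, dim); b <- idxToCoord(idxB, dim)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}

#' Foreground detection for one channel image
#'
#' Otsu's threshold on the min-max normalised image, accepted only when the
#' resulting foreground/background mean contrast reaches `minContrast`
#' (otherwise the image is treated as signal-free), followed by removal of
#' components smaller than `minSize` pixels and hole filling.  On a
#' noiseless two-level image this recovers the rendered masks exactly.
#'
#' @param img numeric matrix
#' @param minContrast minimum foreground-background mean intensity difference
#' @param minSize smallest component retained, in pixels
#' @return logical matrix
#' @export
foregroundMask <- function(img, minContrast = 40, minSize = 4) {
  rng <- range(img)
  if (diff(rng) < minContrast) return(matrix(FALSE, nrow(img), ncol(img)))
  nrm <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(nrm), range = c(0, 1))
  fg <- nrm > th
  if (!any(fg) || all(fg)) return(matrix(FALSE, nrow(img), ncol(img)))
  if (mean(img[fg]) - mean(img[!fg]) < minContrast)
    return(matrix(FALSE, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(fg)
  sz <- tabulate(lab)
  keep <- which(sz >= minSize)
  fg <- matrix(lab %in% keep, nrow(img), ncol(img))
  if (any(fg)) {
    # fill holes per labelled object so nearby objects are never bridged
    lab <- EBImage::bwlabel(fg)
    fg <- EBImage::fillHull(lab) > 0
  }
  fg
}

# pixel-count solidity: mask area / pixels inside the convex hull of the
# mask's pixel centres
maskSolidity <- function(idx, dim) {
  n <- length(idx)
  if (n <= 3) return(1)
  rc <- idxToCoord(idx, dim)
  h <- grDevices::chull(rc[, 2], rc[, 1])
  hx <- rc[h, 2]; hy <- rc[h, 1]
  if (length(h) <= 2) return(1)
  # count pixels of the bounding box inside the hull polygon (convex: all
  # cross products with consistent sign, boundary included)
  rr <- range(rc[, 1]); cc <- range(rc[, 2])
  g <- expand.grid(row = rr[1]:rr[2], col = cc[1]:cc[2])
  inside <- rep(TRUE, nrow(g))
  k <- length(h)
  # chull returns vertices clockwise in plot coords; orientation handled by sign
  x2 <- c(hx[-1], hx[1]); y2 <- c(hy[-1], hy[1])
  or <- sum((x2 - hx) * (y2 + hy))  # >0 clockwise
  s <- if (or > 0) -1 else 1
  for (j in seq_len(k)) {
    cr <- (x2[j] - hx[j]) * (g$row - hy[j]) - (y2[j] - hy[j]) * (g$col - hx[j])
    inside <- inside & (s * cr >= -1e-9)
  }
  n / sum(inside)
}

# derive a child seed from a base seed, staying inside 32-bit integer range
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
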