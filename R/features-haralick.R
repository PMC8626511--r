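# Per-pixel Haralick GLCM statistics over sliding square windows.
#
# For every pixel, a gray-level co-occurrence matrix is accumulated over the
# square window of side 2r+1 centered on it (reflect-padded at borders), at
# unit offset in each of the four directions of 8-connectivity; both pixels of
# a pair must lie inside the window. The GLCM is symmetrized and normalized to
# sum 1, and four statistics are retained: angular second moment, correlation,
# contrast and variance.
#
# Implementation: for each direction a single "pair code" image is built on
# the padded luminance; windowed co-occurrence counts are then rectangle sums
# of per-code indicator images, obtained from integral images. Counts are
# small integers, so the rectangle sums are exact and tiled computation
# matches whole-image computation bit for bit.

# direction -> (row, col) unit offset; rows increase downward
.haralick_offsets <- list(
  "0"   = c(0L, 1L),
  "45"  = c(-1L, 1L),
  "90"  = c(-1L, 0L),
  "135" = c(-1L, -1L)
)

.haralick_stats <- c("A", "Corr", "Con", "V")

#' Haralick GLCM feature maps
#'
#' Computes, for each configured window radius and each of the four
#' 8-connectivity directions, the angular second moment, correlation,
#' contrast and variance of the per-pixel windowed GLCM. Maps are named
#' `H<stat><radius>_<angle>` (e.g. `HCon11_0`) and ordered by statistic
#' (A, Corr, Con, V), then radius, then direction.
#'
#' @param gray `H x W` numeric matrix with values in \[0, 1\].
#' @param config a [feature_bank_config()]; `glcm_levels` gray levels are
#'   obtained by fixed binning of the full \[0, 1\] intensity range.
#' @return Named list of `4 * 4 * length(radii)` matrices.
#' @export
haralick_bank <- function(gray, config) {
  stopifnot(is.matrix(gray), config$glcm_levels >= 2)
  radii <- as.integer(config$haralick_radii_px)
  if (any(2L * radii + 1L > 2L * min(dim(gray))))
    stop("GLCM window exceeds the image even after padding")
  L <- as.integer(config$glcm_levels)
  h <- nrow(gray); w <- ncol(gray)
  pad <- max(radii) + 1L
  lv <- matrix(pmin(as.integer(floor(pmax(pmin(gray, 1), 0) * L)), L - 1L),
               h, w)
  lvp <- pad_reflect(lv, pad)

  # per (stat, radius, direction) accumulators
  acc <- list()
  for (dir in names(.haralick_offsets)) {
    o <- .haralick_offsets[[dir]]
    res <- haralick_direction(lvp, o, radii, L, h, w, pad)
    for (r_i in seq_along(radii))
      for (st in .haralick_stats)
        acc[[sprintf("H%s%s_%s", st, format(radii[r_i]), dir)]] <-
          res[[r_i]][[st]]
  }
  # canonical order: statistic, then radius, then direction
  ord <- as.vector(vapply(.haralick_stats, function(st)
    as.vector(vapply(radii, function(r)
      sprintf("H%s%s_%s", st, format(r), names(.haralick_offsets)),
      character(4L))), character(4L * length(radii))))
  acc[ord]
}

#' All four statistics for one direction at every radius
#' @noRd
haralick_direction <- function(lvp, offset, radii, L, h, w, pad) {
  dr <- offset[1L]; dc <- offset[2L]
  np <- nrow(lvp); mp <- ncol(lvp)
  # pair-code image on the padded grid, defined wherever both the pixel and
  # its offset partner fall inside the padded image
  rows_a <- seq_len(np); cols_a <- seq_len(mp)
  rows_b <- rows_a + dr; cols_b <- cols_a + dc
  keep_r <- rows_b >= 1L & rows_b <= np
  keep_c <- cols_b >= 1L & cols_b <= mp
  A <- lvp[rows_a[keep_r], cols_a[keep_c], drop = FALSE]
  B <- lvp[rows_b[keep_r], cols_b[keep_c], drop = FALSE]
  code <- A * L + B  # in 0 .. L^2 - 1
  # padded-grid row/col index of the first valid pair-code entry
  row0 <- rows_a[keep_r][1L]
  col0 <- cols_a[keep_c][1L]

  # rectangle of first-pixel positions for the window at output pixel (i, j):
  # rows [i - r + max(0,-dr), i + r - max(0,dr)], analogous for columns
  N_of <- function(r) 2 * ((2 * r + 1 - abs(dr)) * (2 * r + 1 - abs(dc)))

  zero <- matrix(0, h, w)
  st <- lapply(seq_along(radii), function(i)
    list(asm = zero, con = zero, mu = zero, sq = zero, eab = zero))

  box <- vector("list", length(radii))
  for (ab in 0:(L * L - 1L)) {
    a <- ab %/% L; b <- ab %% L
    if (a > b) next
    ii_ab <- integral_image(code == ab)
    ii_ba <- if (a == b) ii_ab else integral_image(code == (b * L + a))
    for (r_i in seq_along(radii)) {
      r <- radii[r_i]
      rl <- -r + max(0L, -dr); rh <- r - max(0L, dr)
      cl <- -r + max(0L, -dc); ch <- r - max(0L, dc)
      # output pixel (i, j) sits at padded coords (i + pad, j + pad);
      # convert to pair-code grid coords by subtracting (row0-1, col0-1)
      oy <- pad - (row0 - 1L); ox <- pad - (col0 - 1L)
      c_ab <- box_sum(ii_ab, h, w, oy + rl, oy + rh, ox + cl, ox + ch)
      t_ab <- if (a == b) c_ab else c_ab +
        box_sum(ii_ba, h, w, oy + rl, oy + rh, ox + cl, ox + ch)
      # symmetrized GLCM: C(a,b) = c(a,b) + c(b,a), total mass N2 = 2n;
      # q is the combined normalized mass at cells (a,b) and (b,a)
      N2 <- N_of(r)
      q <- 2 * t_ab / N2
      st[[r_i]]$asm <- st[[r_i]]$asm + (if (a == b) q^2 else q^2 / 2)
      st[[r_i]]$con <- st[[r_i]]$con + (a - b)^2 * q
      st[[r_i]]$mu  <- st[[r_i]]$mu + ((a + b) / 2) * q
      st[[r_i]]$sq  <- st[[r_i]]$sq + ((a * a + b * b) / 2) * q
      st[[r_i]]$eab <- st[[r_i]]$eab + (a * b) * q
    }
  }

  lapply(st, function(s) {
    v <- pmax(s$sq - s$mu^2, 0)
    corr <- ifelse(v > 1e-12, (s$eab - s$mu^2) / v, 0)
    list(A = s$asm, Corr = corr, Con = s$con, V = v)
  })
}

#' Integral image with a leading zero row/column
#' @noRd
integral_image <- function(m) {
  m <- apply(m, 2L, cumsum)
  m <- t(apply(m, 1L, cumsum))
  rbind(0, cbind(0, m))
}

#' Per-output-pixel rectangle sums from an integral image
#'
#' Output pixel (i, j) (1-based, i in 1..h) reads the rectangle
#' rows (i + rl)..(i + rh), cols (j + cl)..(j + ch) of the source grid.
#' @noRd
box_sum <- function(ii, h, w, rl, rh, cl, ch) {
  r1 <- (1:h) + rl; r2 <- (1:h) + rh
  c1 <- (1:w) + cl; c2 <- (1:w) + ch
  ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
    ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}
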