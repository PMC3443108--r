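# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Logical disk mask of given radius (pixels) centred on a matrix of size
# (2*ceiling(r)+1)^2; used for bead stamps and focus footprints.
disk_mask <- function(radius_px) {
  r <- max(radius_px, 0)
  n <- as.integer(ceiling(r))
  d <- seq(-n, n)
  outer(d, d, function(i, j) sqrt(i^2 + j^2) <= r + 1e-9)
}

# Stamp a disk of `radius_px` centred at continuous pixel coordinates
# (x_px, y_px) into matrix `img`, setting covered pixels to
# max(current, value). Coordinates are 0-based with pixel centres at k - 0.5.
stamp_disk <- function(img, x_px, y_px, radius_px, value) {
  nr <- nrow(img); nc <- ncol(img)
  i0 <- max(1L, floor(y_px - radius_px) + 1L)
  i1 <- min(nr, ceiling(y_px + radius_px) + 1L)
  j0 <- max(1L, floor(x_px - radius_px) + 1L)
  j1 <- min(nc, ceiling(x_px + radius_px) + 1L)
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  dy <- (ii - 0.5) - y_px
  dx <- (jj - 0.5) - x_px
  hit <- outer(dy^2, dx^2, "+") <= radius_px^2 + 1e-9
  patch <- img[ii, jj, drop = FALSE]
  patch[hit] <- pmax(patch[hit], value)
  img[ii, jj] <- patch
  img
}

# 8-connected labelling. EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass, then renumber densely.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow = nrow(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  pair_a <- c(a1[a1 > 0 & b1 > 0 & a1 != b1], a2[a2 > 0 & b2 > 0 & a2 != b2])
  pair_b <- c(b1[a1 > 0 & b1 > 0 & a1 != b1], b2[a2 > 0 & b2 > 0 & a2 != b2])
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(pair_a)) {
    for (k in seq_along(pair_a)) {
      ra <- find(pair_a[k]); rb <- find(pair_b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Median-filter local background. EBImage::medianFilter operates on [0, 1];
# rescale around the image maximum, then restore the original scale.
local_background <- function(image, radius_px) {
  radius_px <- max(1L, as.integer(round(radius_px)))
  mx <- max(image)
  if (mx <= 0) return(matrix(0, nrow(image), ncol(image)))
  EBImage::medianFilter(image / mx, radius_px) * mx
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
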