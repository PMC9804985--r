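# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a label path
#'
#' Hashes `master_seed` together with an arbitrary sequence of labels
#' (group name, animal index, image index, ...) into an integer seed in
#' `[1, 2^31 - 2]`. Adding a new label path never perturbs the seed of an
#' existing one, so e.g. appending a group to a cohort leaves previously
#' generated animals untouched.
#'
#' @param master_seed integer master seed.
#' @param ... labels (coerced to character) identifying the child stream.
#' @return a single integer seed.
#' @keywords internal
seed_chain <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% m
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 2) + 1)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# all TRUE pixels of a are also TRUE in b
mask_is_subset <- function(a, b) !any(a & !b)

# strictly binary logical matrix from any numeric/Image input
as_mask <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "logical"
  m
}

# EBImage wrappers returning plain matrices -------------------------------

ebi_blur <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  as.matrix(EBImage::gblur(x, sigma = sigma_px))
}

# binary closing with a disc brush of the given radius (px); radius 0 = no-op
ebi_close <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  size <- 2L * as.integer(ceiling(radius_px)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  as_mask(EBImage::closing(mask * 1, brush) > 0.5)
}

ebi_fill_holes <- function(mask) {
  as_mask(EBImage::fillHull(mask * 1) > 0.5)
}

# drop connected components smaller than min_px pixels
drop_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- as.matrix(lab)
  n <- max(lab)
  if (n == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow = nrow(mask))
}

# one-pixel-wide inner boundary of a binary mask
mask_boundary <- function(mask) {
  if (!any(mask)) return(mask)
  brush <- EBImage::makeBrush(3L, shape = "box")
  eroded <- as_mask(EBImage::erode(mask * 1, brush) > 0.5)
  mask & !eroded
}

# Thresholding ------------------------------------------------------------

#' Otsu threshold of a numeric vector
#'
#' Maximises between-class variance on an `nbins`-bin histogram over the
#' data range. Returns a threshold value; pixels strictly above it are
#' foreground. Degenerate input (constant values) returns `Inf` so the
#' resulting mask is empty.
#' @keywords internal
otsu_threshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || diff(rng) == 0) return(Inf)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[nbins]
  mu_t <- mu[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mu_t * w0[valid] - n * mu[-nbins][valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  # the maximum is a plateau across any empty histogram gap: take its
  # centre so the threshold bisects the gap instead of hugging one class
  peak <- which(between >= max(between) * (1 - 1e-12))
  th <- mids[peak[ceiling(length(peak) / 2)]]
  th
}

# Separation of an automatic threshold in background-sd units:
# (mean above - mean below) / sd(below). An Otsu split carved out of a
# single background mode scores ~2-3; a genuine marker-positive class
# sits tens of sds above the autofluorescence background. Unlike Otsu's
# effectiveness ratio this does not degrade when the positive class is a
# tiny fraction of the pixels (sparse islets).
class_separation <- function(values, th) {
  lo <- values[values <= th]
  hi <- values[values > th]
  if (!length(hi) || !length(lo)) return(0)
  s <- stats::sd(lo)
  if (!is.finite(s) || s == 0) return(Inf)
  (mean(hi) - mean(lo)) / s
}

#' Triangle threshold of a numeric vector
#'
#' Geometric triangle method on an `nbins`-bin histogram: a line is drawn
#' from the histogram peak to the far end of the longer tail and the
#' threshold is placed at the bin with maximal perpendicular distance from
#' that line. Suited to strongly skewed histograms (a dominant background
#' peak with a long foreground tail), the typical shape of a tissue scan
#' over bare glass.
#' @keywords internal
triangle_threshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || diff(rng) == 0) return(Inf)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # walk toward the longer tail
  if ((hi - peak) >= (peak - lo)) { a <- peak; b <- hi } else { a <- peak; b <- lo }
  idx <- a:b
  # perpendicular distance of (i, h[i]) from the line (a, h[a]) -- (b, h[b])
  x1 <- a; y1 <- h[a]; x2 <- b; y2 <- h[b]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (denom == 0) return(mids[peak])
  d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1) / denom
  mids[idx[which.max(d)]]
}

# dispatch on a SegmentationConfig method name
threshold_values <- function(values, method, fixed = NA_real_) {
  switch(method,
    otsu = otsu_threshold(values),
    triangle = triangle_threshold(values),
    fixed = {
      if (!is.finite(fixed)) stop("fixed threshold method requires a finite threshold value")
      fixed
    },
    stop("unknown threshold method: ", method)
  )
}
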