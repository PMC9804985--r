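#' Sample the ground-truth geometry of a synthetic pancreas field
#'
#' Draws a smooth tissue blob covering >= 60% of the frame, places
#' non-overlapping elliptical islets inside it until the achieved islet
#' area fraction is within +/-10% (relative) of
#' `params$islet_area_fraction_target`, and marks an insulin-positive
#' (beta-cell) subset of islet pixels at `params$beta_fraction`.
#'
#' Islet equivalent radii are lognormal; each islet is an ellipse with a
#' random axis ratio in `[1, 2]` and random orientation, area-preserving so
#' ground-truth areas are analytic. A candidate islet is rejected if it
#' leaves the tissue, touches an existing islet, or would overshoot the
#' target fraction by more than 10%; after `max_placement_attempts`
#' rejections the generator aborts with an error naming the achieved versus
#' requested fraction.
#'
#' The beta-cell subset is, per islet, the connected set of pixels nearest
#' a random interior seed pixel (`beta_layout = "blob"`, mimicking the
#' clustering of beta cells in islet cores), or an independent Bernoulli
#' subsample (`"bernoulli"`).
#'
#' @param params a [generator_params()] object.
#' @param seed optional integer overriding `params$seed`.
#' @return an object of class `islet_ground_truth`: list with
#'   `islet_label_map` (integer matrix, 0 = non-islet), `tissue_mask`,
#'   `beta_mask` (logical matrices), `true_islet_fraction` (% of tissue),
#'   `true_beta_fraction_of_islet` (% of islet), and
#'   `true_mean_insulin_intensity` (the generator's insulin signal level).
#' @export
sample_islet_geometry <- function(params, seed = NULL) {
  validate_generator_params(params)
  seed <- as.integer(seed %||% params$seed)
  withr::with_seed(seed, .sample_islet_geometry(params))
}

.sample_islet_geometry <- function(params) {
  nr <- params$image_shape[1]; nc <- params$image_shape[2]

  tissue <- sample_tissue_blob(nr, nc)
  tissue_px <- sum(tissue)

  label <- matrix(0L, nr, nc)
  target_px <- round(params$islet_area_fraction_target * tissue_px)

  if (target_px > 0) {
    label <- place_islets(label, tissue, target_px, params)
  }

  beta <- sample_beta_mask(label, params$beta_fraction, params$beta_layout)

  islet_px <- sum(label > 0L)
  structure(list(
    islet_label_map = label,
    tissue_mask = tissue,
    beta_mask = beta,
    true_islet_fraction = 100 * islet_px / tissue_px,
    true_beta_fraction_of_islet =
      if (islet_px > 0) 100 * sum(beta) / islet_px else NA_real_,
    true_mean_insulin_intensity = params$insulin_intensity,
    pixel_size = params$pixel_size
  ), class = "islet_ground_truth")
}

# Sequential islet placement to a pixel-count target.
#
# Radii are drawn from the lognormal truncated to [min_islet_radius, radius
# that would exactly exhaust the remaining deficit], so no placement can
# overshoot the target and every placement is a biologically plausible
# islet (at least min_islet_radius). Once the remaining deficit drops
# below the smallest admissible islet, the last-placed islet is removed
# and replaced by one whose analytic area equals the enlarged deficit, so
# the achieved fraction lands on the target up to rasterisation error
# (far inside the +/-10% relative band). Candidate ellipses that leave
# the tissue or touch an existing islet are rejected; after
# max_placement_attempts rejections the generator aborts, naming the
# achieved vs requested fraction.
place_islets <- function(label, tissue, target_px, params) {
  nr <- nrow(label); nc <- ncol(label)
  tissue_px <- sum(tissue)
  mu <- params$islet_radius_lognormal[1]
  sdlog <- params$islet_radius_lognormal[2]
  r_min_um <- params$min_islet_radius
  min_area_px <- pi * (r_min_um / params$pixel_size)^2
  tissue_idx <- which(tissue)
  px_of <- list()   # pixels of each placed islet, by id
  achieved <- 0
  attempts <- 0L
  next_id <- 1L

  fail <- function() stop(sprintf(paste0(
    "islet placement failed after %d attempts: achieved fraction %.4f%% ",
    "of tissue vs requested %.4f%% (islets too large for the frame or ",
    "target unreachable)"), attempts,
    100 * achieved / tissue_px,
    100 * params$islet_area_fraction_target), call. = FALSE)

  # place one ellipse of equivalent radius r_px (rejection-sampled pose)
  try_place <- function(r_px) {
    while (attempts < params$max_placement_attempts) {
      axis_ratio <- stats::runif(1, 1, 2)
      phi <- stats::runif(1, 0, pi)
      centre <- arrayInd(sample(tissue_idx, 1), c(nr, nc))
      px <- ellipse_pixels(centre[1], centre[2], r_px, axis_ratio, phi,
                           nr, nc)
      if (length(px) && all(tissue[px]) && all(label[px] == 0L)) return(px)
      attempts <<- attempts + 1L
    }
    fail()
  }

  if (target_px < min_area_px) {
    # Sub-islet target: the requested area is less than one minimum-size
    # islet, so the field holds either zero islets or one -- exactly what
    # sparse diabetic pancreas fields look like. Round stochastically
    # (probability target/min_area of one islet) so the expected fraction
    # is unbiased across fields; the +/-10% band is meaningless here.
    if (stats::runif(1) < target_px / min_area_px) {
      px <- try_place(r_min_um / params$pixel_size)
      label[px] <- 1L
    }
    return(label)
  }

  while (achieved < 0.95 * target_px) {
    deficit <- target_px - achieved
    if (deficit >= min_area_px) {
      r_cap_um <- sqrt(deficit / pi) * params$pixel_size
      f_lo <- stats::plnorm(r_min_um, log(mu), sdlog)
      f_hi <- stats::plnorm(r_cap_um, log(mu), sdlog)
      r_um <- stats::qlnorm(stats::runif(1, f_lo, f_hi), log(mu), sdlog)
      r_px <- r_um / params$pixel_size
    } else {
      # swap the last islet for one that exactly exhausts the deficit
      last <- px_of[[next_id - 1L]]
      label[last] <- 0L
      achieved <- achieved - length(last)
      px_of[[next_id - 1L]] <- NULL
      next_id <- next_id - 1L
      r_px <- sqrt((target_px - achieved) / pi)
    }
    if (r_px < 1.5) r_px <- 1.5
    px <- try_place(r_px)
    label[px] <- next_id
    px_of[[next_id]] <- px
    next_id <- next_id + 1L
    achieved <- achieved + length(px)
  }
  # rasterisation slack on top of the 10% relative band: tiny targets are
  # quantised by whole-pixel ellipse rasterisation
  slack <- 3 * sqrt(target_px)
  if (achieved > 1.1 * target_px + slack ||
      achieved < 0.9 * target_px - slack) fail()
  label
}

# A single smooth blob: a circle of radius 0.46*min(dim) whose boundary is
# perturbed by a few random low-order harmonics (total relative amplitude
# <= ~0.15), guaranteeing a connected region covering >= 60% of the frame.
sample_tissue_blob <- function(nr, nc) {
  cy <- nr / 2 + stats::runif(1, -0.02, 0.02) * nr
  cx <- nc / 2 + stats::runif(1, -0.02, 0.02) * nc
  r0 <- 0.46 * min(nr, nc)
  k <- 2:5
  amp <- stats::runif(4, 0, 0.05)
  pha <- stats::runif(4, 0, 2 * pi)
  dy <- matrix(seq_len(nr) - cy, nr, nc)
  dx <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
  theta <- atan2(dy, dx)
  rmax <- r0 * (1 + Reduce(`+`, lapply(seq_along(k), function(i)
    amp[i] * cos(k[i] * theta + pha[i]))))
  dy * dy + dx * dx <= rmax * rmax
}

# Pixel indices (column-major, 1-based) of an area-preserving ellipse with
# equivalent radius r_px: semi-axes a = r*sqrt(q), b = r/sqrt(q), rotated
# by phi. Returns integer(0) if the ellipse leaves the frame.
ellipse_pixels <- function(row0, col0, r_px, axis_ratio, phi, nr, nc) {
  a <- r_px * sqrt(axis_ratio)
  b <- r_px / sqrt(axis_ratio)
  half <- ceiling(a)
  rows <- (row0 - half):(row0 + half)
  cols <- (col0 - half):(col0 + half)
  if (rows[1] < 1 || cols[1] < 1 || rows[length(rows)] > nr ||
      cols[length(cols)] > nc) return(integer(0))
  dy <- matrix(rows - row0, length(rows), length(cols))
  dx <- matrix(cols - col0, length(rows), length(cols), byrow = TRUE)
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  inside <- which(u * u + v * v <= 1)
  if (!length(inside)) return(integer(0))
  rr <- ((inside - 1) %% length(rows)) + rows[1]
  cc <- ((inside - 1) %/% length(rows)) + cols[1]
  (cc - 1L) * nr + rr
}

# Insulin-positive subset of each labelled islet at the requested fraction.
sample_beta_mask <- function(label, beta_fraction, layout) {
  beta <- matrix(FALSE, nrow(label), ncol(label))
  n_islets <- max(label)
  if (n_islets == 0L || beta_fraction <= 0) return(beta)
  nr <- nrow(label)
  for (i in seq_len(n_islets)) {
    idx <- which(label == i)
    k <- round(beta_fraction * length(idx))
    if (k == 0) next
    if (layout == "bernoulli") {
      beta[sample(idx, k)] <- TRUE
    } else {
      seed_px <- sample(idx, 1)
      sr <- ((seed_px - 1) %% nr) + 1
      sc <- ((seed_px - 1) %/% nr) + 1
      rr <- ((idx - 1) %% nr) + 1
      cc <- ((idx - 1) %/% nr) + 1
      d2 <- (rr - sr)^2 + (cc - sc)^2
      beta[idx[order(d2, idx)[seq_len(k)]]] <- TRUE
    }
  }
  beta
}
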