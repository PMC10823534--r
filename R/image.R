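#' Construct a three-channel fluorescence image
#'
#' Channels are numeric matrices of identical shape with values in
#' \[0, 1\] (rescale 8/16-bit data before constructing). Green is the
#' endothelial surface stain (PECAM1), blue the nuclear stain (DAPI) and
#' red the scenario marker (Ki67, PDGFRA or PLVAP).
#'
#' @param red,green,blue numeric matrices (height x width) in \[0, 1\].
#' @param red_role one of "Ki67", "PDGFRA", "PLVAP".
#' @return object of class `csa_image`.
#' @export
fluor_image <- function(red, green, blue,
                        red_role = c("Ki67", "PDGFRA", "PLVAP")) {
  red_role <- match.arg(red_role)
  red <- as.matrix(red); green <- as.matrix(green); blue <- as.matrix(blue)
  if (!identical(dim(red), dim(green)) ||
      !identical(dim(red), dim(blue))) {
    stop("channel shapes differ")
  }
  for (ch in list(red, green, blue)) {
    if (any(ch < 0 | ch > 1)) stop("channel values must lie in [0, 1]")
  }
  structure(list(red = red, green = green, blue = blue,
                 red_role = red_role), class = "csa_image")
}

#' Multi-level Otsu thresholding of one channel
#'
#' Exhaustive maximization of between-class variance over a 256-bin
#' intensity histogram: all (n_classes - 1)-subsets of bin boundaries are
#' scored via cumulative sums and the best is kept. The returned
#' foreground mask is "above the lowest threshold". A constant channel
#' yields an empty mask with a warning.
#'
#' @param channel numeric matrix in \[0, 1\].
#' @param n_classes number of intensity classes (>= 2; default 2).
#' @param n_bins histogram resolution (default 256).
#' @return object of class `csa_mask`: list(mask, thresholds, n_classes).
#' @export
multi_threshold <- function(channel, n_classes = 2, n_bins = 256) {
  stopifnot(n_classes >= 2)
  channel <- as.matrix(channel)
  if (max(channel) == min(channel)) {
    warning("constant channel: empty foreground")
    return(structure(list(mask = matrix(FALSE, nrow(channel),
                                        ncol(channel)),
                          thresholds = numeric(0),
                          n_classes = n_classes), class = "csa_mask"))
  }
  bin <- pmin(floor(channel * n_bins), n_bins - 1)  # 0 .. n_bins-1
  h <- tabulate(as.vector(bin) + 1L, nbins = n_bins)
  thr_bins <- .otsu_search(h, n_classes)
  thresholds <- (thr_bins + 1) / n_bins   # upper edge of the cut bin
  mask <- channel > thresholds[1]
  structure(list(mask = mask, thresholds = thresholds,
                 n_classes = n_classes), class = "csa_mask")
}

# Exhaustive between-class-variance search on a histogram. Thresholds
# are bin indices t (0-based): class c spans bins (t_{c-1}, t_c]. Uses
# prefix sums so each candidate costs O(n_classes).
.otsu_search <- function(h, n_classes) {
  n_bins <- length(h)
  w <- cumsum(h)
  m <- cumsum(h * (seq_len(n_bins) - 1))
  seg <- function(a, b) {       # bins a..b (0-based, inclusive)
    ww <- w[b + 1] - if (a == 0) 0 else w[a]
    mm <- m[b + 1] - if (a == 0) 0 else m[a]
    if (ww == 0) 0 else mm^2 / ww
  }
  cand <- which(h > 0) - 1L                 # cuts at occupied bins only
  cand <- cand[cand < n_bins - 1]
  if (length(cand) < n_classes - 1) cand <- 0:(n_bins - 2)
  combs <- utils::combn(cand, n_classes - 1)
  best <- -Inf; best_t <- combs[, 1]
  for (i in seq_len(ncol(combs))) {
    t <- combs[, i]
    bounds <- c(-1L, t, n_bins - 1L)
    s <- 0
    for (c in seq_len(n_classes)) {
      s <- s + seg(bounds[c] + 1L, bounds[c + 1])
    }
    if (s > best) { best <- s; best_t <- t }
  }
  as.numeric(best_t)
}

#' Vessel density: percent of image area in the green foreground
#' @param green_mask a [multi_threshold()] mask (or logical matrix).
#' @return percentage in \[0, 100\].
#' @export
vessel_density <- function(green_mask) {
  m <- if (inherits(green_mask, "csa_mask")) green_mask$mask else green_mask
  100 * mean(m)
}

#' Label 8-connected foreground components
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- if (inherits(mask, "csa_mask")) mask$mask else mask
  lab <- matrix(0L, nrow(m), ncol(m))
  idx <- which(m)
  if (length(idx) == 0) return(lab)
  nr <- nrow(m)
  lut <- integer(length(m)); lut[idx] <- seq_along(idx)
  r <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  edges <- list()
  # half of the 8-neighborhood; the other half is covered by symmetry
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(m)
    j <- (c2[ok] - 1) * nr + r2[ok]
    hit <- lut[j] > 0
    if (any(hit)) {
      edges[[length(edges) + 1]] <-
        cbind(which(ok)[hit], lut[j[hit]])
    }
  }
  g <- igraph::make_empty_graph(length(idx), directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Count blocks of one mask overlapping another
#'
#' 8-connected components of `mask_a` with at least `min_block_px`
#' pixels that share at least one pixel with `mask_b`.
#'
#' @param mask_a,mask_b logical matrices (or `csa_mask`) of equal shape.
#' @param min_block_px minimum component area (default 20).
#' @return integer count.
#' @export
count_overlap_blocks <- function(mask_a, mask_b, min_block_px = 20) {
  a <- if (inherits(mask_a, "csa_mask")) mask_a$mask else mask_a
  b <- if (inherits(mask_b, "csa_mask")) mask_b$mask else mask_b
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  lab <- label_components(a)
  if (max(lab) == 0) return(0L)
  sizes <- tabulate(lab[lab > 0])
  overlap <- unique(lab[lab > 0 & b])
  sum(sizes[overlap] >= min_block_px)
}

#' Image quantification metrics for one three-channel image
#'
#' Segments each channel with multi-level Otsu (2 classes for red/green,
#' 3 for the nuclear channel by default), then computes: vessel density
#' (percent green-foreground area), the number of EC nuclei (blue blocks
#' overlapping green), the number of proliferating ECs (red blocks
#' overlapping green; with `strict = TRUE` the red block must also touch
#' a nucleus block), their ratio as a percentage, and the mean raw red
#' intensity over the green foreground.
#'
#' @param img a [fluor_image()].
#' @param min_block_px minimum block area in pixels (default 20).
#' @param n_classes_nuclei Otsu classes for the blue channel (default 3).
#' @param strict require red blocks to overlap both green and blue.
#' @return data.frame with vessel_density_pct, n_ec_nuclei,
#'   n_ki67_pos_ec, ki67_pct, mean_red_over_green (NA where undefined).
#' @export
image_metrics <- function(img, min_block_px = 20, n_classes_nuclei = 3,
                          strict = FALSE) {
  stopifnot(inherits(img, "csa_image"))
  g <- multi_threshold(img$green, 2)
  b <- multi_threshold(img$blue, n_classes_nuclei)
  r <- multi_threshold(img$red, 2)
  n_ec <- count_overlap_blocks(b, g, min_block_px)
  red_target <- if (strict) g$mask & .dilate1(b$mask) else g$mask
  n_pos <- count_overlap_blocks(r, red_target, min_block_px)
  ki67 <- if (n_ec == 0) NA_real_ else 100 * n_pos / n_ec
  mrg <- mean_intensity_over_mask(img$red, g)
  data.frame(vessel_density_pct = vessel_density(g),
             n_ec_nuclei = n_ec, n_ki67_pos_ec = n_pos, ki67_pct = ki67,
             mean_red_over_green = mrg)
}

# one-pixel 8-neighborhood dilation (allows "adjacent to nucleus")
.dilate1 <- function(m) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    src_r <- max(1, 1 - dr):min(nr, nr - dr)
    src_c <- max(1, 1 - dc):min(nc, nc - dc)
    out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] |
      m[src_r, src_c]
  }
  out
}

#' Mean raw intensity of a channel over a mask
#'
#' @param channel numeric matrix (unthresholded intensities).
#' @param mask logical matrix or `csa_mask`.
#' @return mean intensity, or NA (with a warning) for an empty mask.
#' @export
mean_intensity_over_mask <- function(channel, mask) {
  m <- if (inherits(mask, "csa_mask")) mask$mask else mask
  if (!any(m)) {
    warning("empty mask: mean intensity undefined")
    return(NA_real_)
  }
  mean(channel[m])
}

#' PLVAP visualization composite
#'
#' Amplifies red and green by `amplification` (clipped at 1) and removes
#' red signal outside the green foreground, enhancing vessel-associated
#' PLVAP for counting; blue is unchanged.
#'
#' @param img a [fluor_image()].
#' @param amplification positive gain (default 2).
#' @return a new [fluor_image()].
#' @export
plvap_composite <- function(img, amplification = 2) {
  stopifnot(inherits(img, "csa_image"), amplification > 0)
  g_mask <- multi_threshold(img$green, 2)$mask
  red <- pmin(img$red * amplification, 1) * g_mask
  green <- pmin(img$green * amplification, 1)
  fluor_image(red, green, img$blue, red_role = img$red_role)
}

#' Synthesize a three-channel fluorescence scene with ground truth
#'
#' Vessels are smooth sinusoidal ribbons in green; nuclei are ellipses
#' in blue, a controlled fraction of them centered on vessels (the EC
#' nuclei); red depends on the scenario: Ki67 dots on a subset of the EC
#' nuclei, a smooth PDGFRA intensity field, or PLVAP signal along a
#' subset of vessels plus off-vessel speckle. Gaussian noise of s.d.
#' `noise_sd` is added to every channel (clipped to \[0, 1\]).
#'
#' @param width,height canvas size in pixels (defaults mirror a typical
#'   microscope frame, 1360 x 1024; tests use smaller canvases).
#' @param n_vessels number of ribbons.
#' @param vessel_width ribbon thickness in pixels.
#' @param n_nuclei number of nuclei.
#' @param frac_ec fraction of nuclei placed on vessels.
#' @param frac_positive fraction of EC nuclei that are Ki67-positive
#'   (Ki67 scenario).
#' @param scenario "ki67", "pdgfra" or "plvap".
#' @param noise_sd Gaussian noise s.d. (0 = clean scene).
#' @param seed integer seed.
#' @param max_tries placement retries before giving up.
#' @return list(image, truth): a [fluor_image()] and a list with the
#'   planted vessel mask, nucleus masks/centers and counts
#'   (n_nuclei, n_ec_nuclei, n_positive, vessel_density_pct,
#'   mean_red_over_vessel).
#' @export
synthesize_fluor_image <- function(width = 1360, height = 1024,
                                   n_vessels = 4, vessel_width = 14,
                                   n_nuclei = 30, frac_ec = 0.6,
                                   frac_positive = 0.25,
                                   scenario = c("ki67", "pdgfra",
                                                "plvap"),
                                   noise_sd = 0, seed = 1L,
                                   max_tries = 2000) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  nr <- height; nc <- width
  colx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rowy <- matrix(rep(seq_len(nr), nc), nr, nc)

  vessel <- matrix(FALSE, nr, nc)
  vessel_id <- matrix(0L, nr, nc)
  for (v in seq_len(n_vessels)) {
    y0 <- stats::runif(1, 0.15, 0.85) * nr
    amp <- stats::runif(1, 0.03, 0.10) * nr
    per <- stats::runif(1, 0.8, 1.6) * nc
    phase <- stats::runif(1, 0, 2 * pi)
    yc <- y0 + amp * sin(2 * pi * colx / per + phase)
    band <- abs(rowy - yc) <= vessel_width / 2
    vessel <- vessel | band
    vessel_id[band] <- v
  }

  # nuclei: ellipses with centers kept apart and away from the border
  rx <- 6; ry <- 4
  centers <- matrix(NA_real_, n_nuclei, 2)
  on_vessel <- logical(n_nuclei)
  n_ec_target <- round(frac_ec * n_nuclei)
  margin <- 12
  placed <- 0; tries <- 0
  while (placed < n_nuclei) {
    tries <- tries + 1
    if (tries > max_tries) stop("could not place all nuclei; relax spec")
    want_ec <- placed < n_ec_target
    x <- stats::runif(1, margin, nc - margin)
    y <- stats::runif(1, margin, nr - margin)
    iy <- round(y); ix <- round(x)
    is_on <- vessel[iy, ix]
    if (want_ec != is_on) next
    if (!want_ec) {
      # off-vessel nuclei must clear the vessel by the nucleus radius
      ys <- max(1, iy - ry - 2):min(nr, iy + ry + 2)
      xs <- max(1, ix - rx - 2):min(nc, ix + rx + 2)
      if (any(vessel[ys, xs])) next
    }
    if (placed > 0) {
      d2 <- (centers[seq_len(placed), 1] - x)^2 +
        (centers[seq_len(placed), 2] - y)^2
      if (min(d2) < (4 * rx)^2) next
    }
    placed <- placed + 1
    centers[placed, ] <- c(x, y)
    on_vessel[placed] <- want_ec
  }
  nuc_mask <- matrix(FALSE, nr, nc)
  nuc_id <- matrix(0L, nr, nc)
  for (i in seq_len(n_nuclei)) {
    e <- ((colx - centers[i, 1]) / rx)^2 + ((rowy - centers[i, 2]) / ry)^2
    nuc_mask <- nuc_mask | (e <= 1)
    nuc_id[e <= 1] <- i
  }

  green <- ifelse(vessel, 0.8, 0.05)
  blue <- ifelse(nuc_mask, 0.85, 0.05)
  n_positive <- 0L
  red <- matrix(0.02, nr, nc)
  if (scenario == "ki67") {
    ec_idx <- which(on_vessel)
    n_positive <- round(frac_positive * length(ec_idx))
    pos <- if (n_positive > 0) ec_idx[seq_len(n_positive)] else integer(0)
    for (i in pos) {
      e <- ((colx - centers[i, 1]) / (rx - 1))^2 +
        ((rowy - centers[i, 2]) / (ry - 1))^2
      red[e <= 1] <- 0.9
    }
  } else if (scenario == "pdgfra") {
    # smooth positive field: sum of broad Gaussians
    for (k in 1:6) {
      cx <- stats::runif(1, 0, nc); cy <- stats::runif(1, 0, nr)
      s <- stats::runif(1, 0.1, 0.25) * max(nr, nc)
      red <- red + 0.25 * exp(-(((colx - cx)^2 + (rowy - cy)^2) /
                                  (2 * s^2)))
    }
    red <- pmin(red, 1)
  } else {   # plvap: along a subset of vessels, plus off-vessel speckle
    chosen <- seq_len(max(1, floor(n_vessels / 2)))
    red[vessel_id %in% chosen] <- 0.45
    spk <- matrix(stats::runif(nr * nc) < 0.002, nr, nc) & !vessel
    red[spk] <- 0.5
  }
  truth <- list(vessel = vessel, nucleus_id = nuc_id, centers = centers,
                on_vessel = on_vessel, n_nuclei = n_nuclei,
                n_ec_nuclei = sum(on_vessel), n_positive = n_positive,
                vessel_density_pct = 100 * mean(vessel),
                mean_red_over_vessel = mean(red[vessel]))
  if (noise_sd > 0) {
    red <- red + stats::rnorm(nr * nc, 0, noise_sd)
    green <- green + stats::rnorm(nr * nc, 0, noise_sd)
    blue <- blue + stats::rnorm(nr * nc, 0, noise_sd)
  }
  clip <- function(m) pmin(pmax(m, 0), 1)
  role <- c(ki67 = "Ki67", pdgfra = "PDGFRA", plvap = "PLVAP")[[scenario]]
  img <- fluor_image(clip(red), clip(green), clip(blue), red_role = role)
  list(image = img, truth = truth)
}
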