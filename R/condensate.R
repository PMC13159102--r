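#' Otsu threshold of an intensity image
#'
#' Maximizes between-class variance over a 256-bin histogram of the
#' image's intensity range.  Invariant to multiplicative rescaling on
#' bimodal images.
#'
#' @param image numeric matrix.
#' @param n_bins histogram bins.
#' @return threshold value on the image's intensity scale.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("image has no intensity contrast", call. = FALSE)
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1L, 1L),
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

#' Detect condensate droplets in a single-channel image
#'
#' Re-implementation of the usual particle-analysis workflow: global
#' threshold (Otsu by default), 8-connected component labelling, and a
#' minimum-area filter.  The dilute phase is the complement of the
#' droplet mask dilated by 2 px (to avoid edge bleed).  Droplets
#' touching the image border are counted for density but excluded from
#' the size statistics.
#'
#' @param image numeric matrix (rows x cols), single channel.
#' @param pixel_size pixel edge length in um.
#' @param threshold_method `"otsu"` or a numeric threshold value.
#' @param min_area_px minimum droplet area in pixels.
#' @param max_fg_fraction with automatic thresholding, a foreground
#'   covering more than this fraction of the frame means the image has
#'   no droplet/dilute bimodality (Otsu then splits the noise in half);
#'   such images report zero droplets.
#' @return a `droplet_table`: data frame (one droplet per row: `id`,
#'   `area_um2`, `equiv_diameter_um`, `mean_intensity`, `touches_border`)
#'   with attributes `n_droplets`, `density_per_100um2`,
#'   `dilute_mean_intensity`, `mask` (logical matrix), `labels`,
#'   `threshold`.
#' @export
detect_droplets <- function(image, pixel_size, threshold_method = "otsu",
                            min_area_px = 4L, max_fg_fraction = 0.3) {
  image <- as.matrix(image)
  if (!length(image)) stop("empty image", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (max(image) <= min(image))
    stop("image is flat or saturated; cannot threshold", call. = FALSE)
  auto <- identical(threshold_method, "otsu")
  thr <- if (auto) otsu_threshold(image) else as.numeric(threshold_method)
  mask <- image > thr
  if (auto && mean(mask) > max_fg_fraction)
    mask[] <- FALSE  # unimodal image: no droplet phase present
  labels <- cx_label_components(mask)
  n_raw <- max(labels)
  keep <- integer(0)
  rows <- nrow(image); cols <- ncol(image)
  droplets <- NULL
  if (n_raw > 0) {
    areas <- tabulate(labels[labels > 0], n_raw)
    keep <- which(areas >= min_area_px)
    droplets <- do.call(rbind, lapply(seq_along(keep), function(i) {
      l <- keep[i]
      px <- which(labels == l)
      ri <- ((px - 1L) %% rows) + 1L
      ci <- ((px - 1L) %/% rows) + 1L
      data.frame(
        id = i,
        area_um2 = areas[l] * pixel_size^2,
        equiv_diameter_um = 2 * sqrt(areas[l] / pi) * pixel_size,
        mean_intensity = mean(image[px]),
        touches_border = any(ri == 1L | ri == rows | ci == 1L | ci == cols),
        in_counting_frame = !any(ri == rows | ci == cols))
    }))
  }
  if (is.null(droplets))
    droplets <- data.frame(id = integer(0), area_um2 = numeric(0),
                           equiv_diameter_um = numeric(0),
                           mean_intensity = numeric(0),
                           touches_border = logical(0),
                           in_counting_frame = logical(0))
  # rebuild mask/labels with only the kept droplets
  final_mask <- matrix(FALSE, rows, cols)
  if (length(keep)) final_mask[labels %in% keep] <- TRUE
  dilute <- !dilate_mask(final_mask, 2L)
  area_um2 <- rows * cols * pixel_size^2
  out <- droplets
  class(out) <- c("droplet_table", class(out))
  attr(out, "n_droplets") <- nrow(droplets)
  # unbiased counting frame: droplets touching the right/bottom border
  # are excluded so that densities add over tiled sub-images
  attr(out, "density_per_100um2") <-
    100 * sum(droplets$in_counting_frame) / area_um2
  attr(out, "dilute_mean_intensity") <-
    if (any(dilute)) mean(image[dilute]) else NA_real_
  attr(out, "mask") <- final_mask
  attr(out, "labels") <- labels
  attr(out, "threshold") <- thr
  out
}

# square (Chebyshev) dilation by `r` pixels
dilate_mask <- function(mask, r = 2L) {
  if (!any(mask) || r < 1L) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (di in -r:r) {
    si <- max(1, 1 + di):min(nr, nr + di)
    ti <- max(1, 1 - di):min(nr, nr - di)
    for (dj in -r:r) {
      if (di == 0 && dj == 0) next
      sj <- max(1, 1 + dj):min(nc, nc + dj)
      tj <- max(1, 1 - dj):min(nc, nc - dj)
      out[ti, tj] <- out[ti, tj] | mask[si, sj]
    }
  }
  out
}

#' Partition coefficient of condensates
#'
#' Ratio of the mean intensity inside the droplet mask to the mean in
#' the dilute phase (the complement of the mask dilated by 2 px), after
#' subtracting a camera background.  Intensities in offset-free images
#' are proportional to concentration, so the default background is 0;
#' pass `background = "percentile"` to estimate a camera offset as the
#' 1st percentile of the image (only sensible when the frame contains
#' true dark pixels), or a numeric dark level.  The coefficient is
#' invariant to multiplicative intensity rescaling.
#'
#' @param image numeric matrix.
#' @param droplet_mask logical matrix, e.g. `attr(detect_droplets(...),
#'   "mask")`.
#' @param background camera dark level: a number, or `"percentile"`.
#' @return dimensionless enrichment ratio.
#' @export
partition_coefficient <- function(image, droplet_mask, background = 0) {
  image <- as.matrix(image)
  droplet_mask <- as.matrix(droplet_mask)
  stopifnot(identical(dim(image), dim(droplet_mask)))
  if (!any(droplet_mask)) stop("droplet mask is empty", call. = FALSE)
  dilute <- !dilate_mask(droplet_mask, 2L)
  if (!any(dilute)) stop("droplet mask covers the whole frame",
                         call. = FALSE)
  bg <- if (identical(background, "percentile"))
    stats::quantile(image, 0.01, names = FALSE)
  else as.numeric(background)
  num <- mean(image[droplet_mask]) - bg
  den <- mean(image[dilute]) - bg
  if (den <= 0) stop("dilute-phase mean is non-positive after background ",
                     "subtraction", call. = FALSE)
  num / den
}

#' Classify a condensate phase diagram
#'
#' Cells of a (protein concentration x salt concentration) grid are
#' classified as droplet-positive when their droplet count reaches
#' `min_count`; boundary cells are droplet cells 4-adjacent to at least
#' one no-droplet cell.
#'
#' @param grid data frame with columns `protein_conc`, `salt_mM`,
#'   `n_droplets` covering a complete rectangular grid.
#' @param min_count minimum droplet count for a droplet-positive call.
#' @return a `phase_diagram`: `grid` (with `has_droplets`, `boundary`
#'   columns), axis vectors, and the classification matrix.
#' @export
classify_phase_grid <- function(grid, min_count = 5L) {
  need <- c("protein_conc", "salt_mM", "n_droplets")
  stopifnot(all(need %in% names(grid)))
  prot <- sort(unique(grid$protein_conc))
  salt <- sort(unique(grid$salt_mM))
  expected <- expand.grid(protein_conc = prot, salt_mM = salt)
  key <- function(d) paste(d$protein_conc, d$salt_mM)
  missing <- expected[!key(expected) %in% key(grid), , drop = FALSE]
  if (nrow(missing))
    stop("incomplete phase grid; missing cells: ",
         paste(sprintf("(%g, %g)", missing$protein_conc, missing$salt_mM),
               collapse = ", "), call. = FALSE)
  cls <- matrix(FALSE, length(prot), length(salt),
                dimnames = list(as.character(prot), as.character(salt)))
  for (r in seq_len(nrow(grid)))
    cls[as.character(grid$protein_conc[r]),
        as.character(grid$salt_mM[r])] <- grid$n_droplets[r] >= min_count
  boundary <- matrix(FALSE, nrow(cls), ncol(cls), dimnames = dimnames(cls))
  for (i in seq_len(nrow(cls))) {
    for (j in seq_len(ncol(cls))) {
      if (!cls[i, j]) next
      nb <- c(if (i > 1) !cls[i - 1, j], if (i < nrow(cls)) !cls[i + 1, j],
              if (j > 1) !cls[i, j - 1], if (j < ncol(cls)) !cls[i, j + 1])
      boundary[i, j] <- any(nb)
    }
  }
  grid$has_droplets <- mapply(function(p, s)
    cls[as.character(p), as.character(s)],
    grid$protein_conc, grid$salt_mM)
  grid$boundary <- mapply(function(p, s)
    boundary[as.character(p), as.character(s)],
    grid$protein_conc, grid$salt_mM)
  out <- list(grid = grid, protein_conc = prot, salt_mM = salt,
              classification = cls, boundary = boundary,
              min_count = min_count)
  class(out) <- "phase_diagram"
  out
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram> droplet-positive cells (rows = protein, cols = salt)\n")
  print(ifelse(x$classification, ifelse(x$boundary, "B", "+"), "."))
  invisible(x)
}

#' Read or write an intensity image as plain text
#'
#' Images travel as headerless CSV matrices of intensities (one row per
#' image row), a text-only stand-in for single-channel TIFF.
#'
#' @param path file path.
#' @param image numeric matrix.
#' @return `read_image_csv` returns a numeric matrix.
#' @export
read_image_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' @rdname read_image_csv
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(as.matrix(image), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
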