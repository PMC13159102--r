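#' Pairwise Euclidean distance matrix
#'
#' @param positions a two-column matrix or data frame of 2-D points (um).
#' @return a symmetric n x n matrix with zero diagonal.
#' @examples
#' pairwise_distances(rbind(c(0, 0), c(3, 4)))
#' @export
pairwise_distances <- function(positions) {
  positions <- as_positions(positions)
  if (nrow(positions) < 1L) stop("need at least one point", call. = FALSE)
  as.matrix(stats::dist(positions))
}

as_positions <- function(positions) {
  m <- as.matrix(positions)
  if (is.null(dim(m)) || ncol(m) < 2L)
    stop("positions must have two columns (x, y)", call. = FALSE)
  storage.mode(m) <- "double"
  m[, 1:2, drop = FALSE]
}

#' Percentage of short-distance complexes
#'
#' A complex is "short-distance" when at least one other complex lies
#' strictly closer than `threshold` (default 3 um).  The per-pair
#' variant -- the percentage of all unordered pairs closer than the
#' threshold -- is returned as the attribute `pct_pairs`, since the
#' statistic can be read either way.
#'
#' @param positions two-column matrix of complex positions (um).
#' @param threshold distance threshold in um (strict `<`).
#' @return percentage in `[0, 100]` with attribute `pct_pairs`.
#' @export
short_distance_percentage <- function(positions, threshold = 3) {
  positions <- as_positions(positions)
  if (nrow(positions) < 2L)
    stop("need at least two points", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  d <- stats::dist(positions)
  n <- nrow(positions)
  short <- d < threshold
  # column-wise expansion of the dist object into per-point "has close
  # neighbour" indicators
  has_close <- logical(n)
  idx <- 0L
  for (j in seq_len(n - 1L)) {
    m <- n - j
    hit <- short[idx + seq_len(m)]
    if (any(hit)) {
      has_close[j] <- TRUE
      has_close[j + which(hit)] <- TRUE
    }
    idx <- idx + m
  }
  out <- 100 * mean(has_close)
  attr(out, "pct_pairs") <- 100 * mean(short)
  out
}

#' Clustering fold change of a simulation record
#'
#' Ratio of the short-distance percentage at the final snapshot
#' (`t_total`) to the first post-addition snapshot (`t_bundle`).  When
#' the baseline percentage is zero the fold change is undefined and
#' flagged rather than thrown.
#'
#' @param record a `sim_record` (or any list with `times` and
#'   `positions`).
#' @param threshold distance threshold in um.
#' @return a `clustering_summary`: list with `threshold`,
#'   `pct_short_t_start`, `pct_short_t_end`, `fold_change`, `undefined`,
#'   plus the per-pair analogues.
#' @export
clustering_fold_change <- function(record, threshold = 3) {
  times <- record$times
  cfg <- record$config
  t_start <- if (!is.null(cfg)) cfg$t_bundle else min(times)
  t_end <- if (!is.null(cfg)) cfg$t_total else max(times)
  i_start <- which(times >= t_start - 1e-9)[1]
  if (is.na(i_start))
    stop("record has no snapshot at or after t = ", t_start, call. = FALSE)
  i_end <- which(abs(times - t_end) < 1e-6)
  if (!length(i_end))
    stop("record has no snapshot at t = ", t_end, call. = FALSE)
  i_end <- i_end[length(i_end)]
  p_start <- short_distance_percentage(record$positions[[i_start]], threshold)
  p_end <- short_distance_percentage(record$positions[[i_end]], threshold)
  undefined <- p_start == 0
  out <- list(
    threshold = threshold,
    pct_short_t_start = as.numeric(p_start),
    pct_short_t_end = as.numeric(p_end),
    fold_change = if (undefined) NA_real_ else as.numeric(p_end) / as.numeric(p_start),
    undefined = undefined,
    pct_pairs_t_start = attr(p_start, "pct_pairs"),
    pct_pairs_t_end = attr(p_end, "pct_pairs"),
    fold_change_pairs = if (attr(p_start, "pct_pairs") == 0) NA_real_
                        else attr(p_end, "pct_pairs") / attr(p_start, "pct_pairs")
  )
  class(out) <- "clustering_summary"
  out
}

#' @export
print.clustering_summary <- function(x, ...) {
  cat("<clustering_summary>\n")
  cat(sprintf("  threshold %g um; short-distance %% %.1f -> %.1f\n",
              x$threshold, x$pct_short_t_start, x$pct_short_t_end))
  if (x$undefined) cat("  fold change undefined (baseline 0%)\n")
  else cat(sprintf("  fold change %.3f (per-pair %.3f)\n",
                   x$fold_change, x$fold_change_pairs))
  invisible(x)
}

#' Assemble a parameter-sweep heatmap of clustering fold changes
#'
#' Records must come from [sweep_experiments()] (each tagged with its
#' grid cell) and cover a complete rectangular grid over the two axis
#' variables.  Cell values are means over replicate seeds.
#'
#' @param records list of tagged `sim_record`s.
#' @param threshold distance threshold in um.
#' @param axes character vector of the two swept variable names; by
#'   default taken from the grid tags.
#' @param statistic which fold change fills the cells: `"pairs"` (the
#'   percentage of complex pairs closer than the threshold; the default
#'   because its baseline does not saturate with complex density) or
#'   `"complexes"` (the percentage of complexes with at least one close
#'   neighbour).  Both statistics are in every [clustering_fold_change]
#'   summary.
#' @return a `heatmap_grid`: list with `axes`, `values` (matrix rows =
#'   first axis), `n_replicates`, and the long-format `table`.
#' @export
build_heatmap <- function(records, threshold = 3, axes = NULL,
                          statistic = c("pairs", "complexes")) {
  statistic <- match.arg(statistic)
  cells <- lapply(records, attr, "grid_cell")
  if (any(vapply(cells, is.null, logical(1))))
    stop("all records must carry a grid_cell tag", call. = FALSE)
  vars <- setdiff(names(cells[[1]]), "replicate")
  if (is.null(axes)) axes <- vars
  if (length(axes) == 1L) axes <- c(axes, "replicate")
  tab <- do.call(rbind, lapply(seq_along(records), function(i) {
    cell <- cells[[i]]
    cs <- clustering_fold_change(records[[i]], threshold)
    out <- as.data.frame(cell)
    out$fold_change <- if (statistic == "pairs") cs$fold_change_pairs
                       else cs$fold_change
    out$record_id <- i
    out
  }))
  a1 <- sort(unique(tab[[axes[1]]]))
  a2 <- sort(unique(tab[[axes[2]]]))
  expected <- expand.grid(a1, a2)
  have <- unique(tab[, axes])
  missing <- expected[!paste(expected[[1]], expected[[2]]) %in%
                        paste(have[[1]], have[[2]]), , drop = FALSE]
  if (nrow(missing))
    stop("incomplete sweep grid; missing cells: ",
         paste(sprintf("(%s=%g, %s=%g)", axes[1], missing[[1]],
                       axes[2], missing[[2]]), collapse = ", "),
         call. = FALSE)
  values <- matrix(NA_real_, length(a1), length(a2),
                   dimnames = list(as.character(a1), as.character(a2)))
  nrep <- values
  for (i in seq_along(a1)) {
    for (j in seq_along(a2)) {
      sel <- tab[[axes[1]]] == a1[i] & tab[[axes[2]]] == a2[j]
      values[i, j] <- mean(tab$fold_change[sel], na.rm = TRUE)
      nrep[i, j] <- sum(sel)
    }
  }
  out <- list(axes = stats::setNames(list(a1, a2), axes), values = values,
              n_replicates = nrep, table = tab, threshold = threshold)
  class(out) <- "heatmap_grid"
  out
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat("<heatmap_grid> mean clustering fold change, threshold",
      x$threshold, "um\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Render a heatmap grid to PNG
#'
#' @param grid a `heatmap_grid`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_heatmap <- function(grid, path) {
  stopifnot(inherits(grid, "heatmap_grid"))
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  v <- grid$values
  nm <- names(grid$axes)
  graphics::image(seq_len(nrow(v)), seq_len(ncol(v)), v,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = nm[1], ylab = nm[2], axes = FALSE,
                  main = "Clustering fold change")
  graphics::axis(1, at = seq_len(nrow(v)), labels = rownames(v))
  graphics::axis(2, at = seq_len(ncol(v)), labels = colnames(v))
  for (i in seq_len(nrow(v)))
    for (j in seq_len(ncol(v)))
      graphics::text(i, j, sprintf("%.2f", v[i, j]), cex = 0.8)
  invisible(path)
}

#' Write clustering summaries for a set of records
#'
#' @param records list of `sim_record`s (optionally grid-tagged).
#' @param path output CSV (one row per record).
#' @param threshold distance threshold in um.
#' @return the data frame, invisibly.
#' @export
write_clustering_csv <- function(records, path, threshold = 3) {
  tab <- do.call(rbind, lapply(seq_along(records), function(i) {
    cs <- clustering_fold_change(records[[i]], threshold)
    data.frame(record_id = i, threshold = threshold,
               pct_short_t_start = cs$pct_short_t_start,
               pct_short_t_end = cs$pct_short_t_end,
               fold_change = cs$fold_change,
               fold_change_pairs = cs$fold_change_pairs)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
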