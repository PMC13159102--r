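# Independent brute-force oracles, deliberately naive: these implement
# the statistics by direct definition so that the package's vectorized /
# compiled paths can be checked against them exactly.

oracle_pairwise <- function(pos) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt((pos[i, 1] - pos[j, 1])^2 + (pos[i, 2] - pos[j, 2])^2)
  d
}

oracle_short_pct <- function(pos, threshold) {
  n <- nrow(pos)
  close_any <- logical(n)
  npair <- 0L
  nshort <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d < threshold) close_any[i] <- TRUE
      if (j > i) {
        npair <- npair + 1L
        if (d < threshold) nshort <- nshort + 1L
      }
    }
  }
  list(pct_complex = 100 * mean(close_any), pct_pairs = 100 * nshort / npair)
}

# recursive-free flood fill, 8-connectivity
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i < 1 || i > nr || j < 1 || j > nc) next
        if (mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- nxt
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
  }
  lab
}

oracle_track_summary <- function(t, x, y = rep(0, length(x))) {
  len <- 0
  for (i in seq_len(length(x) - 1))
    len <- len + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  n <- length(x)
  list(track_length = len,
       displacement = sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2))
}

# fake minimal sim_record from two point sets (for clustering tests)
fake_record <- function(p_start, p_end, t_start = 100, t_end = 500) {
  rec <- list(config = list(t_bundle = t_start, t_total = t_end),
              times = c(t_start, t_end),
              positions = list(p_start, p_end))
  class(rec) <- "sim_record"
  rec
}

# small fast configs for simulator tests
tiny_config <- function(...) {
  sim_config(n_filaments = 4, filament_length = 4, n_hset = 6,
             n_complexes = 5, t_bundle = 1, t_total = 2,
             snapshot_interval = 1, seed = 42, ...)
}
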