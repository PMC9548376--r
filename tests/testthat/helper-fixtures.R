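# Shared fixtures: small deterministic models, tiny imaging configs, and
# independent oracles used across test files.

# fixed-duration model: every phase exactly at its median
fixed_model <- function(g1 = 300, sg2m = 450, overlap = 0, gap = 3L,
                        label = "wt") {
  cell_cycle_model(g1, 0, sg2m, 0, overlap_min = overlap,
                   dark_gap_frames = gap, genotype_label = label)
}

small_imaging <- function(n_frames = 60L, side = 96L) {
  imaging_config(n_frames = n_frames, height = side, width = side,
                 nucleus_radius_px = 5)
}

# independent flood fill (BFS) used as the oracle for select_component
flood_fill_oracle <- function(mask, seed_xy, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  col0 <- seed_xy[1] + 1L; row0 <- seed_xy[2] + 1L
  out <- matrix(FALSE, h, w)
  if (!mask[row0, col0]) return(out)
  if (connectivity == 8L) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  queue <- list(c(row0, col0))
  out[row0, col0] <- TRUE
  while (length(queue) > 0L) {
    p <- queue[[1L]]; queue <- queue[-1L]
    for (k in seq_len(nrow(nb))) {
      r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
      if (r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c] && !out[r, c]) {
        out[r, c] <- TRUE
        queue <- c(queue, list(c(r, c)))
      }
    }
  }
  out
}

# draw a hard-edged disc into a matrix (1-based centre)
disc_mask <- function(h, w, cy, cx, r) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  }
  m
}

# wrap a logical array as the binary_stack run_click_script expects
as_binary_stack <- function(masks) {
  structure(list(masks = masks, window_px = NA_integer_, k = NA_real_,
                 min_area = 0L),
            class = "binary_stack")
}

# a constant-intensity movie (both channels) for trace tests
flat_movie <- function(h, w, tn, value = 100, interval = 15) {
  structure(list(red = array(value, c(h, w, tn)),
                 green = array(value, c(h, w, tn)),
                 frame_interval_min = interval, config = NULL),
            class = "fucci_movie")
}
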