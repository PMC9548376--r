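# Nucleus segmentation: local mean + k*sd adaptive thresholding per channel,
# channel union, and seeded connected-component selection -- the headless
# analogue of click-based selection on a merged RGB stack.

# Box-filter local mean and sd with reflective padding, via integral images.
local_mean_sd <- function(img, window_px) {
  h <- nrow(img); w <- ncol(img)
  half <- (window_px - 1L) %/% 2L
  ridx <- c(rev(seq_len(min(half, h))), seq_len(h),
            rev(seq_len(h))[seq_len(min(half, h))])
  cidx <- c(rev(seq_len(min(half, w))), seq_len(w),
            rev(seq_len(w))[seq_len(min(half, w))])
  pad <- img[ridx, cidx, drop = FALSE]
  # column-wise cumsum via one global cumsum (column-major) minus per-column
  # offsets; rows handled by transposing
  col_cumsum <- function(m) {
    cs <- matrix(cumsum(m), nrow(m), ncol(m))
    if (ncol(m) > 1L)
      cs <- cs - rep(c(0, cs[nrow(m), -ncol(m)]), each = nrow(m))
    cs
  }
  boxsum <- function(m) {
    cs <- rbind(0, col_cumsum(m))
    v <- cs[(window_px + 1L):nrow(cs), , drop = FALSE] -
      cs[seq_len(nrow(cs) - window_px), , drop = FALSE]
    cs2 <- cbind(0, t(col_cumsum(t(v))))
    cs2[, (window_px + 1L):ncol(cs2), drop = FALSE] -
      cs2[, seq_len(ncol(cs2) - window_px), drop = FALSE]
  }
  n <- window_px^2
  s1 <- boxsum(pad)
  s2 <- boxsum(pad^2)
  mu <- s1 / n
  va <- pmax(0, s2 / n - mu^2)
  list(mean = mu, sd = sqrt(va))
}

#' Adaptive (local mean + k*sd) thresholding of one frame
#'
#' A pixel is foreground iff its value exceeds the mean over the surrounding
#' `window_px` x `window_px` window plus `k` times the local standard
#' deviation. Borders use reflective padding. Deterministic.
#'
#' @param frame Numeric matrix (one channel, one frame).
#' @param window_px Odd window size >= 3 and no larger than the image.
#' @param k Offset multiplier on the local sd (may be negative).
#' @return Logical matrix of the same shape.
#' @export
adaptive_threshold <- function(frame, window_px, k = 3) {
  check(is.matrix(frame) && is.numeric(frame), "`frame` must be a numeric matrix")
  check_count(window_px, "window_px", min = 3L)
  check(window_px %% 2L == 1L, "`window_px` must be odd")
  check(window_px <= min(dim(frame)),
        "`window_px` must not exceed the image size")
  check(is.numeric(k) && length(k) == 1L && is.finite(k),
        "`k` must be a single finite number")
  st <- local_mean_sd(frame, as.integer(window_px))
  frame > st$mean + k * st$sd
}

#' Pixelwise union of two binary masks
#'
#' @param mask_red,mask_green Logical matrices of equal shape.
#' @return Logical matrix, the union.
#' @export
combine_masks <- function(mask_red, mask_green) {
  check(is.matrix(mask_red) && is.logical(mask_red) &&
          is.matrix(mask_green) && is.logical(mask_green),
        "masks must be logical matrices")
  check(all(dim(mask_red) == dim(mask_green)),
        "mask shapes differ")
  mask_red | mask_green
}

# Connected-component labels (4- or 8-connectivity). EBImage::bwlabel is
# 4-connected; exact 8-connectivity is obtained by adding a bridge pixel
# into every diagonal-only touch before labeling and erasing the bridges
# afterwards. A bridge can only ever merge pixels that are already
# 8-connected through the bridge location's own neighbourhood, so the
# result equals a true 8-connected labeling.
label_components <- function(mask, connectivity = 8L) {
  check(connectivity %in% c(4L, 8L), "`connectivity` must be 4 or 8")
  if (connectivity == 8L) {
    h <- nrow(mask); w <- ncol(mask)
    aug <- mask
    if (h > 1L && w > 1L) {
      # main-diagonal touches: (i, j) and (i+1, j+1) -> bridge at (i+1, j)
      d1 <- mask[-h, -w, drop = FALSE] & mask[-1, -1, drop = FALSE]
      if (any(d1)) aug[-1, -w][d1] <- TRUE
      # anti-diagonal touches: (i+1, j) and (i, j+1) -> bridge at (i, j)
      d2 <- mask[-1, -w, drop = FALSE] & mask[-h, -1, drop = FALSE]
      if (any(d2)) aug[-h, -w][d2] <- TRUE
    }
    lab <- matrix(as.integer(EBImage::bwlabel(aug)), h)
    lab[!mask] <- 0L
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) > 0L && ids[length(ids)] != length(ids)) {
      lab[lab > 0L] <- match(lab[lab > 0L], ids)
    }
    return(lab)
  }
  # 4-connectivity: label rows runs, then union-find across vertical contacts
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  nxt <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j]) next
      up <- if (i > 1L) lab[i - 1L, j] else 0L
      lt <- if (j > 1L) lab[i, j - 1L] else 0L
      if (up == 0L && lt == 0L) {
        nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
      } else if (up != 0L && lt != 0L) {
        ru <- find(up); rl <- find(lt)
        parent[max(ru, rl)] <- min(ru, rl)
        lab[i, j] <- min(ru, rl)
      } else {
        lab[i, j] <- max(up, lt)
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    remap <- match(roots, sort(unique(roots)))
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Select the connected component containing a seed point
#'
#' The headless stand-in for clicking a cell on a merged-channel image:
#' returns exactly the connected component of `mask` containing `seed`.
#'
#' @param mask Logical matrix.
#' @param seed `c(x, y)` 0-based pixel coordinates (x = column, y = row).
#' @param connectivity 4 or 8 (default 8).
#' @return Object of class `region_mask`: list with `mask` (logical matrix,
#'   single component), `seed`, `connectivity`, `area`, `centroid` (0-based
#'   `c(x, y)`).
#' @export
select_component <- function(mask, seed, connectivity = 8L) {
  check(is.matrix(mask) && is.logical(mask), "`mask` must be a logical matrix")
  check(length(seed) == 2L && all(is.finite(seed)), "`seed` must be c(x, y)")
  col <- as.integer(round(seed[1])) + 1L
  row <- as.integer(round(seed[2])) + 1L
  check(row >= 1L && row <= nrow(mask) && col >= 1L && col <= ncol(mask),
        "seed outside image bounds")
  if (!mask[row, col]) {
    fg <- which(mask, arr.ind = TRUE)
    hint <- if (nrow(fg) == 0L) "mask is empty" else {
      d2 <- (fg[, 1] - row)^2 + (fg[, 2] - col)^2
      nb <- fg[which.min(d2), ]
      sprintf("nearest foreground at x=%d, y=%d", nb[2] - 1L, nb[1] - 1L)
    }
    stop(sprintf("no object at seed (x=%d, y=%d); %s",
                 seed[1], seed[2], hint), call. = FALSE)
  }
  lab <- label_components(mask, as.integer(connectivity))
  id <- lab[row, col]
  comp <- lab == id
  idx <- which(comp, arr.ind = TRUE)
  structure(list(mask = comp, seed = c(x = seed[1], y = seed[2]),
                 connectivity = as.integer(connectivity),
                 area = nrow(idx),
                 centroid = c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)),
            class = "region_mask")
}

#' Binarize a FUCCI movie
#'
#' Per frame: adaptive-threshold each channel, take the union, and remove
#' objects below `min_area` pixels (speckle suppression that a human clicker
#' would have done implicitly).
#'
#' @param movie A `fucci_movie`.
#' @param window_px Threshold window; default `4 * nucleus_radius_px + 1`
#'   when the movie carries its imaging config, else 25.
#' @param k Threshold offset multiplier (default 1.5). A bright nucleus
#'   occupies a sizeable fraction f of its own local window and inflates the
#'   local sd to roughly `amp * sqrt(f (1 - f))`, so k must stay below
#'   `(1 - f) / sqrt(f (1 - f))` (about 2.1 at f = 0.18) for the object's
#'   own pixels to clear the threshold; 1.5 leaves headroom for touching
#'   neighbours while staying at 1.5 background sds over empty regions.
#' @param min_area Minimum object area in pixels (default 25).
#' @return Object of class `binary_stack`: list with `masks`
#'   (`[h x w x n_frames]` logical array) and the parameters used.
#' @export
binarize_movie <- function(movie, window_px = NULL, k = 1.5, min_area = 25L) {
  check(inherits(movie, "fucci_movie"), "`movie` must be a fucci_movie")
  if (is.null(window_px)) {
    r <- if (!is.null(movie$config)) movie$config$nucleus_radius_px else 6
    window_px <- 2L * ceiling(2 * r) + 1L
  }
  d <- dim(movie$red)
  masks <- array(FALSE, dim = d)
  for (f in seq_len(d[3])) {
    m <- combine_masks(adaptive_threshold(movie$red[, , f], window_px, k),
                       adaptive_threshold(movie$green[, , f], window_px, k))
    if (min_area > 0L && any(m)) {
      lab <- label_components(m, 8L)
      areas <- tabulate(lab[lab > 0L])
      small <- which(areas < min_area)
      if (length(small) > 0L) m[lab %in% small] <- FALSE
    }
    masks[, , f] <- m
  }
  structure(list(masks = masks, window_px = as.integer(window_px), k = k,
                 min_area = as.integer(min_area)),
            class = "binary_stack")
}

#' Label every frame of a binary stack
#'
#' Connected-component labels (8-connectivity) plus per-component centroid
#' and area tables for each frame; the tracking module works off this.
#'
#' @param stack A [binarize_movie()] result.
#' @return Object of class `labeled_stack`: `labels` (integer array),
#'   `components` (per-frame data.frames `label, x, y, area`; coordinates
#'   0-based), `n_frames`, `dim`.
#' @export
label_stack <- function(stack) {
  check(inherits(stack, "binary_stack"), "`stack` must be a binary_stack")
  d <- dim(stack$masks)
  labels <- array(0L, dim = d)
  comps <- vector("list", d[3])
  for (f in seq_len(d[3])) {
    lab <- label_components(stack$masks[, , f], 8L)
    labels[, , f] <- lab
    if (max(lab) == 0L) {
      comps[[f]] <- data.frame(label = integer(0), x = numeric(0),
                               y = numeric(0), area = integer(0))
    } else {
      pos <- lab > 0L
      l <- lab[pos]
      xs <- col(lab)[pos] - 1
      ys <- row(lab)[pos] - 1
      area <- tabulate(l)
      comps[[f]] <- data.frame(
        label = seq_along(area),
        x = as.vector(rowsum(xs, l)) / area,
        y = as.vector(rowsum(ys, l)) / area,
        area = area)
    }
  }
  structure(list(labels = labels, components = comps,
                 n_frames = d[3], dim = d[1:2]),
            class = "labeled_stack")
}
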