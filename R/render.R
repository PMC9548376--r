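# Synthetic FUCCI microscope: turns a truth_lineage into a two-channel
# time-lapse with exported ground-truth transition frames.
#
# Reporter timeline of one complete cycle (times in minutes, frame f is
# acquired at t = f * frame_interval, 0-based):
#   birth B (= mother's division) .. B + gap : both reporters dark
#   B + gap .. G1 end G                      : red ramps up, holds
#   G .. G + overlap                         : green ramps up, red decays
#   G + overlap .. division D               : green high, red off
#   D ..                                     : cell replaced by 2 daughters
# so green onset marks the G1/S transition and green collapse marks
# division, which is exactly what the trace analysis measures.

frame_at <- function(t_min, interval) as.integer(ceiling(t_min / interval))

# Ground-truth frame indices of every reporter transition, one row per cell.
truth_frame_table <- function(truth, imaging) {
  cells <- truth$cells
  dt <- imaging$frame_interval_min
  t_last <- (imaging$n_frames - 1L) * dt
  div_parent <- cells$division_min[match(cells$parent_id, cells$cell_id)]
  g1_start <- ifelse(is.na(cells$parent_id), NA_integer_,
                     frame_at(div_parent, dt))
  onset <- frame_at(cells$g1_end_min, dt)
  onset[cells$g1_end_min > t_last | cells$g1_end_min < 0] <- NA_integer_
  division <- ifelse(cells$censored_end, NA_integer_,
                     frame_at(cells$division_min, dt) - 1L)
  division[!is.na(division) & division > imaging$n_frames - 1L] <- NA_integer_
  data.frame(cell_id = cells$cell_id, parent_id = cells$parent_id,
             genotype = cells$genotype,
             g1_start_frame = as.integer(g1_start),
             green_onset_frame = as.integer(onset),
             division_frame = as.integer(division),
             censored_start = cells$censored_start,
             censored_end = cells$censored_end)
}

# Reporter intensity (above background) of one cell at time t_min.
reporter_intensity <- function(t_min, birth, g1_end, division, gap_min,
                               overlap_min, rep) {
  red <- 0; green <- 0
  if (t_min >= birth + gap_min && t_min < g1_end) {
    red <- rep$red_amp * min(1, (t_min - birth - gap_min) / rep$red_ramp_min)
  } else if (t_min >= g1_end && overlap_min > 0 &&
             t_min < g1_end + overlap_min) {
    red <- rep$red_amp * max(0, 1 - (t_min - g1_end) / overlap_min)
  }
  if (t_min >= g1_end && t_min < division) {
    green <- rep$green_amp * min(1, (t_min - g1_end) / rep$green_ramp_min)
  }
  c(red = red, green = green)
}

# Persistent random walk with soft pairwise repulsion and border reflection.
# Returns x/y matrices [n_frames x n_cells] (0-based pixel coordinates, NA
# when the cell does not exist) plus per-cell shape parameters.
layout_positions <- function(truth, imaging, rep) {
  cells <- truth$cells
  n <- nrow(cells)
  dt <- imaging$frame_interval_min
  t_frames <- (seq_len(imaging$n_frames) - 1) * dt
  r <- imaging$nucleus_radius_px
  div_parent <- cells$division_min[match(cells$parent_id, cells$cell_id)]
  start_f <- ifelse(is.na(cells$parent_id), 0L,
                    pmin(imaging$n_frames - 1L, frame_at(div_parent, dt)))
  end_f <- ifelse(cells$censored_end, imaging$n_frames - 1L,
                  pmax(0L, frame_at(cells$division_min, dt) - 1L))
  end_f <- pmin(end_f, imaging$n_frames - 1L)
  X <- matrix(NA_real_, imaging$n_frames, n)
  Y <- matrix(NA_real_, imaging$n_frames, n)
  vx <- numeric(n); vy <- numeric(n)
  shapes <- data.frame(
    cell_id = cells$cell_id,
    rx = r * stats::runif(n, 0.9, 1.1),
    ry = r * stats::runif(n, 0.7, 0.9),
    theta = stats::runif(n, 0, pi))
  margin <- r + 2
  lo_x <- margin; hi_x <- imaging$width - 1 - margin
  lo_y <- margin; hi_y <- imaging$height - 1 - margin
  # mirror reflection at the borders (clamping would pin cells in corners)
  reflect <- function(p, lo, hi) {
    p <- ifelse(p < lo, 2 * lo - p, p)
    p <- ifelse(p > hi, 2 * hi - p, p)
    pmin(hi, pmax(lo, p))
  }
  for (f in seq_len(imaging$n_frames) - 1L) {
    born <- which(start_f == f & end_f >= f)
    for (i in born) {
      if (is.na(cells$parent_id[i])) {
        X[f + 1L, i] <- stats::runif(1, lo_x, hi_x)
        Y[f + 1L, i] <- stats::runif(1, lo_y, hi_y)
      } else {
        p <- cells$parent_id[i]
        pf <- max(1L, f)            # mother's last occupied frame (1-based)
        px <- X[pf, p]; py <- Y[pf, p]
        if (is.na(px)) { px <- stats::runif(1, lo_x, hi_x); py <- stats::runif(1, lo_y, hi_y) }
        sibs <- which(!is.na(cells$parent_id) & cells$parent_id == p)
        side <- if (match(i, sibs) == 1L) 1 else -1
        # daughters share one division axis, derived from the mother's id so
        # the pair lands on opposite sides deterministically
        ang <- (p * 2.399963) %% (2 * pi)
        X[f + 1L, i] <- reflect(px + side * 1.4 * r * cos(ang), lo_x, hi_x)
        Y[f + 1L, i] <- reflect(py + side * 1.4 * r * sin(ang), lo_y, hi_y)
      }
      vx[i] <- stats::rnorm(1, 0, rep$motion_step_px)
      vy[i] <- stats::rnorm(1, 0, rep$motion_step_px)
    }
    alive <- which(start_f <= f & end_f >= f)
    if (f > 0L) {
      old <- alive[!(alive %in% born)]
      if (length(old) > 0L) {
        vx[old] <- rep$motion_persistence * vx[old] +
          stats::rnorm(length(old), 0, rep$motion_step_px)
        vy[old] <- rep$motion_persistence * vy[old] +
          stats::rnorm(length(old), 0, rep$motion_step_px)
        X[f + 1L, old] <- reflect(X[f, old] + vx[old], lo_x, hi_x)
        Y[f + 1L, old] <- reflect(Y[f, old] + vy[old], lo_y, hi_y)
      }
    }
    # soft repulsion, a few relaxation passes: keep centres >= 3 nucleus
    # radii apart so nuclei neither merge into one component nor pack the
    # local threshold window
    if (length(alive) > 1L) {
      minsep <- 3 * r
      for (pass in 1:3) {
        xs <- X[f + 1L, alive]; ys <- Y[f + 1L, alive]
        dmat <- as.matrix(stats::dist(cbind(xs, ys)))
        pairs <- which(dmat < minsep & upper.tri(dmat), arr.ind = TRUE)
        if (nrow(pairs) == 0L) break
        for (kk in seq_len(nrow(pairs))) {
          a <- pairs[kk, 1L]; b <- pairs[kk, 2L]
          dx <- xs[b] - xs[a]; dy <- ys[b] - ys[a]
          d <- sqrt(dx^2 + dy^2)
          if (d < 1e-6) { dx <- 1; dy <- 0; d <- 1 }
          push <- (minsep - d) / 2
          ia <- alive[a]; ib <- alive[b]
          X[f + 1L, ia] <- reflect(X[f + 1L, ia] - push * dx / d, lo_x, hi_x)
          Y[f + 1L, ia] <- reflect(Y[f + 1L, ia] - push * dy / d, lo_y, hi_y)
          X[f + 1L, ib] <- reflect(X[f + 1L, ib] + push * dx / d, lo_x, hi_x)
          Y[f + 1L, ib] <- reflect(Y[f + 1L, ib] + push * dy / d, lo_y, hi_y)
        }
      }
    }
  }
  list(X = X, Y = Y, shapes = shapes,
       start_f = as.integer(start_f), end_f = as.integer(end_f))
}

# Add one soft-edged (optionally bent) ellipse to `img` in place-ish.
draw_nucleus <- function(img, x0, y0, rx, ry, theta, amp, psf_sigma, bend = 0) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(max(rx, ry) + 2 * psf_sigma + 2)
  cx <- x0 + 1; cy <- y0 + 1               # to 1-based continuous coords
  rows <- max(1L, floor(cy - half)):min(h, ceiling(cy + half))
  cols <- max(1L, floor(cx - half)):min(w, ceiling(cx + half))
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  dy <- rows - cy
  dx <- cols - cx
  DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
  DY <- matrix(dy, length(rows), length(cols))
  u <- (DX * cos(theta) + DY * sin(theta)) / rx
  v <- (-DX * sin(theta) + DY * cos(theta)) / ry
  if (bend > 0) u <- u - bend * (v^2 - 0.5)   # boomerang curvature
  q <- u^2 + v^2
  edge <- max(1e-6, 2 * psf_sigma / max(rx, ry))
  wgt <- pmin(1, pmax(0, (1 + edge - q) / (2 * edge)))
  img[rows, cols] <- img[rows, cols] + amp * wgt
  img
}

#' Render a truth lineage into a two-channel FUCCI movie
#'
#' Draws every cell as a soft-edged ellipse moving by a persistent random
#' walk, with red (mKO2-Cdt1, G1) and green (mAG-Geminin, S/G2/M) intensity
#' following linear-ramp kinetics; both reporters sit at background during
#' the configured post-mitosis dark gap. Poisson photon noise followed by
#' Gaussian read noise is applied when `noise = TRUE`. Ground-truth frame
#' indices of every transition (G1 start, green onset, division) are
#' exported alongside the pixel data.
#'
#' @param truth A [sample_lineages()] result.
#' @param imaging An [imaging_config()]; the lineage's `t_total_min` must
#'   fit inside `n_frames * frame_interval_min`.
#' @param rep A [reporter_params()].
#' @param seed Integer seed for cell placement, motion and noise.
#' @param noise Apply Poisson + Gaussian noise? `FALSE` gives a noiseless
#'   render (quantised to integer intensity levels only).
#' @return An object of class `fucci_render`: list with `movie` (class
#'   `fucci_movie`: `red` and `green` `[height x width x n_frames]` arrays,
#'   `frame_interval_min`, `config`), `frames` (ground-truth transition
#'   frames per cell, incl. `first_visible_frame`), `positions` (long table
#'   of 0-based per-frame centroids) and the input `truth`.
#' @export
render_movie <- function(truth, imaging, rep = reporter_params(), seed = 1L,
                         noise = TRUE) {
  check(inherits(truth, "truth_lineage"), "`truth` must be a truth_lineage")
  check(inherits(imaging, "imaging_config"), "`imaging` must be an imaging_config")
  check(inherits(rep, "reporter_params"), "`rep` must be reporter_params")
  check(truth$t_total_min <= imaging$n_frames * imaging$frame_interval_min,
        "lineage t_total_min does not fit within n_frames * frame_interval_min")
  with_seed(seed, {
    cells <- truth$cells
    model <- truth$model
    dt <- imaging$frame_interval_min
    gap_min <- model$dark_gap_frames * dt
    lay <- layout_positions(truth, imaging, rep)
    h <- imaging$height; w <- imaging$width; tn <- imaging$n_frames
    red <- array(0, dim = c(h, w, tn))
    green <- array(0, dim = c(h, w, tn))
    maxval <- 2^imaging$bit_depth - 1
    finish_frame <- function(a) {
      # Poisson shot noise then Gaussian read noise, per frame
      if (noise) {
        g <- imaging$photon_gain
        v <- stats::rpois(length(a), a * g)
        if (g != 1) v <- v / g
        if (imaging$read_noise_sd > 0)
          v <- v + stats::rnorm(length(v), 0, imaging$read_noise_sd)
        a <- v
      }
      a <- round(a)
      a[a < 0] <- 0
      a[a > maxval] <- maxval
      a
    }
    vis_level <- 0.1 * min(rep$red_amp, rep$green_amp)
    first_vis <- rep(NA_integer_, nrow(cells))
    division_eff <- ifelse(cells$censored_end, Inf, cells$division_min)
    sh_rx <- lay$shapes$rx; sh_ry <- lay$shapes$ry; sh_th <- lay$shapes$theta
    bgmat <- matrix(imaging$background_level, h, w)
    for (f in seq_len(tn) - 1L) {
      t_min <- f * dt
      alive <- which(lay$start_f <= f & lay$end_f >= f)
      rf <- bgmat; gf <- bgmat
      for (i in alive) {
        inten <- reporter_intensity(t_min, cells$birth_min[i],
                                    cells$g1_end_min[i], division_eff[i],
                                    gap_min, model$overlap_min, rep)
        if (inten[1L] < 0.5 && inten[2L] < 0.5) next
        if (is.na(first_vis[i]) && max(inten) >= vis_level)
          first_vis[i] <- f
        x0 <- lay$X[f + 1L, i]; y0 <- lay$Y[f + 1L, i]
        if (inten[1L] >= 0.5)
          rf <- draw_nucleus(rf, x0, y0, sh_rx[i], sh_ry[i], sh_th[i],
                             inten[1L], imaging$psf_sigma_px, rep$bend)
        if (inten[2L] >= 0.5)
          gf <- draw_nucleus(gf, x0, y0, sh_rx[i], sh_ry[i], sh_th[i],
                             inten[2L], imaging$psf_sigma_px, rep$bend)
      }
      red[, , f + 1L] <- finish_frame(rf)
      green[, , f + 1L] <- finish_frame(gf)
    }
    frames <- truth_frame_table(truth, imaging)
    frames$first_visible_frame <- first_vis
    keep <- !is.na(lay$X)
    positions <- data.frame(
      cell_id = rep(cells$cell_id, each = tn)[keep],
      frame = rep(seq_len(tn) - 1L, times = nrow(cells))[keep],
      x = lay$X[keep], y = lay$Y[keep])
    movie <- structure(list(red = red, green = green,
                            frame_interval_min = dt, config = imaging),
                       class = "fucci_movie")
    structure(list(movie = movie, frames = frames, positions = positions,
                   truth = truth),
              class = "fucci_render")
  })
}

#' @export
print.fucci_movie <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("<fucci_movie> %d x %d px, %d frames at %g min/frame (red + green)\n",
              d[1], d[2], d[3], x$frame_interval_min))
  invisible(x)
}

#' Oracle click script from a rendered movie's ground truth
#'
#' One click per cell at its first visible frame and true centroid, with the
#' parent link carried over -- the scripted, perfectly-informed analogue of
#' the interactive mouse clicks that seed lineage tracking.
#'
#' @param render A [render_movie()] result.
#' @return A click-script `data.frame` (`frame,x,y,cell_id,parent_id`),
#'   ordered by frame.
#' @export
oracle_clicks <- function(render) {
  check(inherits(render, "fucci_render"), "`render` must be a fucci_render")
  fr <- render$frames
  n_frames <- dim(render$movie$red)[3]
  vis <- fr[!is.na(fr$first_visible_frame) &
              fr$first_visible_frame <= n_frames - 3L, ]
  pos <- render$positions
  key <- paste(pos$cell_id, pos$frame)
  idx <- match(paste(vis$cell_id, vis$first_visible_frame), key)
  out <- data.frame(frame = vis$first_visible_frame,
                    x = round(pos$x[idx]), y = round(pos$y[idx]),
                    cell_id = vis$cell_id, parent_id = vis$parent_id)
  out <- out[order(out$frame, out$cell_id), ]
  rownames(out) <- NULL
  out
}
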