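# From tracked regions to phase durations. Per cell: mean red/green
# intensity over the tracked region per frame; green onset (the G1/S
# transition) splits G1 from S/G2/M; green collapse at a confirmed division
# closes the cycle. Red/green co-expression around G1/S counts toward G1 --
# G1 ends at green onset. Post-mitosis dark-gap frames belong to the
# daughter's G1: G1 starts the frame after the mother's last observed frame.

#' Extract mean-intensity traces for every tracked cell
#'
#' @param movie A `fucci_movie`.
#' @param tree A [run_click_script()] lineage.
#' @param lstack The [label_stack()] the tree was tracked on.
#' @return Named list (by cell id) of data.frames
#'   `frame, red, green, area, dark`; intensities are `NA` on dark frames.
#' @export
extract_traces <- function(movie, tree, lstack) {
  check(inherits(movie, "fucci_movie"), "`movie` must be a fucci_movie")
  check(inherits(tree, "lineage_tree"), "`tree` must be a lineage_tree")
  check(inherits(lstack, "labeled_stack"), "`lstack` must be a labeled_stack")
  # per-frame per-label channel means, computed once
  n_f <- lstack$n_frames
  means <- vector("list", n_f)
  for (f in seq_len(n_f)) {
    lab <- lstack$labels[, , f]
    pos <- lab > 0L
    if (!any(pos)) { means[[f]] <- NULL; next }
    l <- lab[pos]
    area <- tabulate(l)
    means[[f]] <- cbind(red = as.vector(rowsum(movie$red[, , f][pos], l)) / area,
                        green = as.vector(rowsum(movie$green[, , f][pos], l)) / area)
  }
  out <- lapply(tree$tracks, function(tr) {
    if (nrow(tr) == 0L) {
      return(data.frame(frame = integer(0), red = numeric(0),
                        green = numeric(0), area = integer(0),
                        dark = logical(0)))
    }
    red <- green <- rep(NA_real_, nrow(tr))
    obs <- which(!tr$dark)
    for (i in obs) {
      m <- means[[tr$frame[i] + 1L]]
      red[i] <- m[tr$label[i], "red"]
      green[i] <- m[tr$label[i], "green"]
    }
    data.frame(frame = tr$frame, red = red, green = green,
               area = tr$area, dark = tr$dark)
  })
  out
}

#' Extract the trace of a single cell
#'
#' @inheritParams extract_traces
#' @param cell_id Cell identifier present in the tree.
#' @return One trace data.frame (see [extract_traces()]).
#' @export
extract_trace <- function(movie, tree, cell_id, lstack) {
  check(as.character(cell_id) %in% names(tree$tracks),
        sprintf("unknown cell_id '%s'", cell_id))
  sub <- tree
  sub$tracks <- tree$tracks[as.character(cell_id)]
  extract_traces(movie, sub, lstack)[[1L]]
}

#' Estimate per-channel background statistics of a movie
#'
#' Robust location/scale (median and scaled MAD) over a pixel subsample;
#' with sparsely seeded cells the vast majority of pixels are background,
#' so the median is unaffected by foreground.
#'
#' @param movie A `fucci_movie`.
#' @param max_pixels Subsample size.
#' @return List `red = c(mean, sd)`, `green = c(mean, sd)`.
#' @export
estimate_background <- function(movie, max_pixels = 200000L) {
  check(inherits(movie, "fucci_movie"), "`movie` must be a fucci_movie")
  n <- length(movie$red)
  idx <- if (n > max_pixels) round(seq(1L, n, length.out = max_pixels)) else
    seq_len(n)
  st <- function(a) {
    v <- a[idx]
    m <- stats::median(v)
    # floor at one intensity count: a noiseless background has MAD 0, and
    # any fallback involving foreground pixels would wreck the threshold
    s <- max(stats::mad(v, center = m), 1)
    c(mean = m, sd = s)
  }
  list(red = st(movie$red), green = st(movie$green))
}

# Sustained threshold crossings of one channel. The onset is the start of
# the first run of >= min_run frames above `thr` (3-frame median-smoothed);
# the offset is the falling crossing after the LAST such run -- taking the
# last run makes the collapse marker robust to brief mid-track dropouts
# (claim conflicts, occlusions), which matters because the green offset is
# the division marker. Dark frames count as below threshold.
channel_crossings <- function(frames, values, thr, min_run) {
  ok <- !is.na(values)
  if (sum(ok) < max(3L, min_run)) {
    return(list(onset = NA_integer_, offset = NA_integer_))
  }
  v <- values
  v[!ok] <- thr - 1
  sm <- if (length(v) >= 3L) stats::runmed(v, 3L) else v
  above <- sm > thr
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= min_run)
  if (length(hit) == 0L) {
    return(list(onset = NA_integer_, offset = NA_integer_))
  }
  onset <- frames[starts[hit[1L]]]
  last_end <- ends[hit[length(hit)]]
  offset <- if (last_end < length(frames)) frames[last_end + 1L] else
    NA_integer_
  list(onset = onset, offset = offset)
}

#' Detect reporter onset/offset events in one trace
#'
#' An onset is the first frame at which the 3-frame median-smoothed channel
#' exceeds `bg_mean + k_onset * bg_sd` for at least `min_run` consecutive
#' frames; an offset is defined symmetrically (falling below, searched after
#' the onset). Dark frames count as background.
#'
#' @param trace A trace data.frame (see [extract_traces()]).
#' @param bg Background statistics as returned by [estimate_background()].
#' @param k_onset Threshold multiplier (default 5).
#' @param min_run Persistence requirement in frames (default 2).
#' @return List with `red_onset`, `red_offset`, `green_onset`,
#'   `green_offset` (0-based frame numbers, `NA` when absent) and the
#'   thresholds used.
#' @export
detect_onsets <- function(trace, bg, k_onset = 5, min_run = 2L) {
  check_count(min_run, "min_run", min = 1L)
  if (nrow(trace) < min_run) {
    warning("trace shorter than min_run; no events")
    return(list(red_onset = NA_integer_, red_offset = NA_integer_,
                green_onset = NA_integer_, green_offset = NA_integer_))
  }
  one <- function(channel) {
    thr <- bg[[channel]][["mean"]] + k_onset * bg[[channel]][["sd"]]
    ev <- channel_crossings(trace$frame, trace[[channel]], thr, min_run)
    c(ev, list(thr = thr))
  }
  r <- one("red"); g <- one("green")
  list(red_onset = r$onset, red_offset = r$offset,
       green_onset = g$onset, green_offset = g$offset,
       thr_red = r$thr, thr_green = g$thr)
}

#' Segment each tracked cell into G1 and S/G2/M intervals
#'
#' G1 runs from the frame after the mother's division (founders: from red
#' onset; start-censored when the cell is already fluorescent at its first
#' frame) to green onset; S/G2/M runs from green onset to the confirmed
#' division (green collapse with two tracked daughters). A phase missing
#' either bounding event is flagged censored on that side. Cells with a
#' green onset at or before their G1 start are flagged unresolvable and
#' excluded.
#'
#' @param tree A [run_click_script()] lineage.
#' @param traces [extract_traces()] output for the same tree.
#' @param bg Background statistics ([estimate_background()]).
#' @param k_onset,min_run Onset-detection parameters (see [detect_onsets()]).
#' @return data.frame, one row per cell: `cell_id, g1_start, green_onset,
#'   sg2m_end` (0-based frames; intervals are start-inclusive,
#'   end-exclusive), `g1_censored, sg2m_censored, unresolvable`.
#' @export
segment_phases <- function(tree, traces, bg, k_onset = 5, min_run = 2L) {
  check(inherits(tree, "lineage_tree"), "`tree` must be a lineage_tree")
  info <- tree$info
  check(all(as.character(info$cell_id) %in% names(traces)),
        "traces do not cover the tree's cells")
  events <- lapply(stats::setNames(info$cell_id, info$cell_id), function(id)
    detect_onsets(traces[[as.character(id)]], bg, k_onset, min_run))
  # division boundary of a cell: the frame of its green collapse (offset) if
  # observed, else the frame after its last tracked region; the track end
  # alone can overrun the true division when faint daughter pixels fall
  # inside the matching radius during the dark gap
  division_boundary <- function(id) {
    ev <- events[[as.character(id)]]
    if (!is.na(ev$green_offset)) ev$green_offset else
      info$last_frame[info$cell_id == id] + 1L
  }
  rows <- lapply(seq_len(nrow(info)), function(i) {
    id <- info$cell_id[i]
    tr <- traces[[as.character(id)]]
    ev <- events[[as.character(id)]]
    first_f <- info$first_frame[i]
    p <- info$parent_id[i]
    divided <- id %in% tree$edges$mother
    if (!is.na(p) && p %in% info$cell_id) {
      g1_start <- division_boundary(p)
      g1_cens_start <- FALSE
    } else {
      # founder: anchor at red onset; censored when already fluorescent at
      # its first tracked frame (movie starts mid-G1 or later)
      already_on <- (!is.na(ev$red_onset) && ev$red_onset <= first_f) ||
        (!is.na(ev$green_onset) && ev$green_onset <= first_f)
      g1_start <- ev$red_onset
      g1_cens_start <- already_on || is.na(ev$red_onset)
    }
    green_onset <- ev$green_onset
    unresolvable <- !is.na(green_onset) && !is.na(g1_start) &&
      !g1_cens_start && green_onset <= g1_start
    sg2m_end <- if (divided) division_boundary(id) else NA_integer_
    # when a bounding event is missing the phase is right-censored at the
    # end of the cell's track; the audit table carries that censoring time
    track_end <- info$last_frame[i] + 1L
    g1_end_eff <- if (!is.na(green_onset)) green_onset else track_end
    sg2m_end_eff <- if (!is.na(sg2m_end)) sg2m_end else track_end
    data.frame(cell_id = id,
               founder = is.na(p),
               g1_start = as.integer(g1_start),
               green_onset = as.integer(green_onset),
               g1_end_eff = as.integer(g1_end_eff),
               sg2m_end = as.integer(sg2m_end),
               sg2m_end_eff = as.integer(sg2m_end_eff),
               g1_censored = g1_cens_start || is.na(green_onset),
               sg2m_censored = is.na(green_onset) ||
                 (!is.na(ev$green_onset) && ev$green_onset <= first_f &&
                    is.na(p)) || !divided,
               unresolvable = unresolvable)
  })
  out <- do.call(rbind, rows)
  if (any(out$unresolvable))
    message(sprintf("%d cell(s) unresolvable (green onset precedes birth); excluded",
                    sum(out$unresolvable)))
  out
}

#' Convert phase segments into duration records
#'
#' Uncensored segments become duration records; censored or unresolvable
#' ones are excluded from the statistical table but returned in an audit
#' table.
#'
#' @param segments [segment_phases()] output.
#' @param frame_interval_min Frame interval in minutes (> 0).
#' @param genotype Genotype label stamped on every record.
#' @return List with `durations` (`cell_id, genotype, phase, duration_min,
#'   censored`, uncensored only) and `audit` (all phase rows, with censor
#'   flags).
#' @export
phase_durations <- function(segments, frame_interval_min, genotype = "wt") {
  check_scalar_pos(frame_interval_min, "frame_interval_min")
  seg <- segments[!segments$unresolvable, , drop = FALSE]
  g1 <- data.frame(cell_id = seg$cell_id, genotype = genotype, phase = "G1",
                   founder = seg$founder,
                   duration_min = (seg$g1_end_eff - seg$g1_start) *
                     frame_interval_min,
                   censored = seg$g1_censored)
  sg <- data.frame(cell_id = seg$cell_id, genotype = genotype, phase = "SG2M",
                   founder = seg$founder,
                   duration_min = (seg$sg2m_end_eff - seg$green_onset) *
                     frame_interval_min,
                   censored = seg$sg2m_censored)
  audit <- rbind(g1, sg)
  durations <- audit[!audit$censored & !is.na(audit$duration_min) &
                       audit$duration_min > 0, , drop = FALSE]
  rownames(durations) <- NULL
  list(durations = durations, audit = audit)
}

#' Full trace-to-durations pipeline for one movie
#'
#' Binarize, label, track with the given click script, extract traces,
#' detect onsets and return phase-duration records.
#'
#' @param movie A `fucci_movie`.
#' @param clicks A click script (e.g. [oracle_clicks()]).
#' @param genotype Genotype label for the duration records.
#' @param window_px,k,min_area Segmentation parameters ([binarize_movie()]).
#' @param policy Tracking [gap_policy()]; default search radius is
#'   `3 * nucleus_radius_px` of the movie's config.
#' @param k_onset,min_run Onset-detection parameters.
#' @return List with `durations`, `audit`, `segments`, `tree`.
#' @export
measure_phase_durations <- function(movie, clicks, genotype = "wt",
                                    window_px = NULL, k = 1.5, min_area = 25L,
                                    policy = NULL, k_onset = 5, min_run = 2L) {
  if (is.null(policy)) {
    r <- if (!is.null(movie$config)) movie$config$nucleus_radius_px else 6
    policy <- gap_policy(search_radius_px = 3 * r)
  }
  stack <- binarize_movie(movie, window_px = window_px, k = k,
                          min_area = min_area)
  lstack <- label_stack(stack)
  tree <- run_click_script(lstack, clicks, policy, on_unmatched = "skip")
  traces <- extract_traces(movie, tree, lstack)
  bg <- estimate_background(movie)
  segments <- segment_phases(tree, traces, bg, k_onset, min_run)
  pd <- phase_durations(segments, movie$frame_interval_min, genotype)
  list(durations = pd$durations, audit = pd$audit, segments = segments,
       tree = tree)
}
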