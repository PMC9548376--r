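# Click-scripted lineage tracking over a labeled binary stack. A click
# script is the reproducible stand-in for interactive mouse clicks: each
# record seeds (or re-seeds) one cell at one frame; frames between clicks
# are filled by nearest-centroid propagation, and the multi-frame dark gap
# after mitosis is bridged by a bounded tolerance for absent regions.

#' Gap policy for tracking
#'
#' @param max_dark_frames Frames a cell may be absent (both reporters dark)
#'   before the track is declared lost. Default 5, comfortably above the
#'   typical 3-frame post-mitosis dark window.
#' @param search_radius_px Matching radius for centroid propagation; default
#'   `3 * nucleus_radius_px` when known (pass explicitly otherwise).
#' @return A list with the two fields.
#' @export
gap_policy <- function(max_dark_frames = 5L, search_radius_px = 18) {
  check_count(max_dark_frames, "max_dark_frames")
  check_scalar_pos(search_radius_px, "search_radius_px")
  list(max_dark_frames = as.integer(max_dark_frames),
       search_radius_px = search_radius_px)
}

#' Validate a click script
#'
#' Required columns `frame, x, y, cell_id` (optional `parent_id`); frames
#' non-decreasing within a cell; a parent must be introduced before its
#' children; at most two children per parent.
#'
#' @param clicks A data.frame.
#' @return The script, normalised (integer frames, `parent_id` column
#'   present), invisibly usable downstream.
#' @export
click_script <- function(clicks) {
  check(is.data.frame(clicks), "`clicks` must be a data.frame")
  need <- c("frame", "x", "y", "cell_id")
  check(all(need %in% names(clicks)),
        "click script needs columns frame, x, y, cell_id")
  if (!"parent_id" %in% names(clicks))
    clicks$parent_id <- rep(NA_integer_, nrow(clicks))
  clicks$frame <- as.integer(clicks$frame)
  if (nrow(clicks) == 0L) return(clicks)
  for (id in unique(clicks$cell_id)) {
    fr <- clicks$frame[clicks$cell_id == id]
    check(!is.unsorted(fr),
          sprintf("frames for cell %s are not non-decreasing", id))
  }
  first_click <- tapply(clicks$frame, clicks$cell_id, min)
  with_parent <- clicks[!is.na(clicks$parent_id), ]
  if (nrow(with_parent) > 0L) {
    for (i in seq_len(nrow(with_parent))) {
      p <- as.character(with_parent$parent_id[i])
      check(p %in% names(first_click),
            sprintf("parent %s referenced before being introduced", p))
      check(first_click[[p]] <= with_parent$frame[i],
            sprintf("parent %s clicked after its child", p))
    }
    kids <- table(unique(with_parent[c("cell_id", "parent_id")])$parent_id)
    check(all(kids <= 2L), "a parent has more than 2 children")
  }
  clicks
}

# Nearest unclaimed component to (x, y) in frame f (0-based). Ties broken by
# larger area, then lower label; returns NULL if none within radius.
match_component <- function(lstack, f, x, y, radius, claimed) {
  comp <- lstack$components[[f + 1L]]
  if (nrow(comp) == 0L) return(NULL)
  free <- !(comp$label %in% claimed[[f + 1L]])
  comp <- comp[free, , drop = FALSE]
  if (nrow(comp) == 0L) return(NULL)
  d <- sqrt((comp$x - x)^2 + (comp$y - y)^2)
  ok <- d <= radius
  if (!any(ok)) return(NULL)
  comp <- comp[ok, , drop = FALSE]
  d <- d[ok]
  o <- order(round(d, 6), -comp$area, comp$label)
  comp[o[1L], ]
}

# Forward propagation of one cell between from_f and to_f (inclusive,
# 0-based), given per-cell click records for re-seeding. Mutates `claimed`
# (an environment-wrapped list) and returns the track plus an end reason.
propagate_cell <- function(lstack, clicks_cell, from_f, to_f, policy,
                           claimed_env) {
  claimed <- claimed_env$claimed
  n_max <- to_f - from_f + 1L
  t_frame <- integer(n_max); t_label <- integer(n_max)
  t_x <- numeric(n_max); t_y <- numeric(n_max)
  t_area <- rep(NA_integer_, n_max); t_dark <- logical(n_max)
  nrows <- 0L
  dark_run <- 0L
  pos <- NULL
  last_seen <- NA_integer_
  end_reason <- "end"
  for (f in from_f:to_f) {
    ci <- which(clicks_cell$frame == f)
    if (length(ci) > 0L) pos <- c(clicks_cell$x[ci[1L]], clicks_cell$y[ci[1L]])
    hit <- if (is.null(pos)) NULL else
      match_component(lstack, f, pos[1], pos[2], policy$search_radius_px,
                      claimed)
    nrows <- nrows + 1L
    t_frame[nrows] <- f
    if (is.null(hit)) {
      dark_run <- dark_run + 1L
      if (!is.na(last_seen) && dark_run > policy$max_dark_frames) {
        end_reason <- "lost"
        nrows <- nrows - 1L
        break
      }
      t_label[nrows] <- 0L; t_x[nrows] <- NA_real_; t_y[nrows] <- NA_real_
      t_dark[nrows] <- TRUE
    } else {
      dark_run <- 0L
      last_seen <- f
      pos <- c(hit$x, hit$y)
      claimed[[f + 1L]] <- c(claimed[[f + 1L]], hit$label)
      t_label[nrows] <- hit$label; t_x[nrows] <- hit$x; t_y[nrows] <- hit$y
      t_area[nrows] <- hit$area; t_dark[nrows] <- FALSE
    }
  }
  track <- if (nrows == 0L) NULL else
    data.frame(frame = t_frame[seq_len(nrows)], label = t_label[seq_len(nrows)],
               x = t_x[seq_len(nrows)], y = t_y[seq_len(nrows)],
               area = t_area[seq_len(nrows)], dark = t_dark[seq_len(nrows)])
  if (!is.null(track) && nrow(track) > 0L) {
    # a track runs from its first to its last observed region; leading and
    # trailing dark frames are not part of it
    if (is.na(last_seen)) track <- track[0, ] else {
      first_seen <- min(track$frame[!track$dark])
      track <- track[track$frame >= first_seen & track$frame <= last_seen, ,
                     drop = FALSE]
    }
  }
  claimed_env$claimed <- claimed
  list(track = track, end_reason = end_reason, last_seen = last_seen)
}

#' Reconstruct a lineage tree from a click script
#'
#' Runs every scripted cell through seeded nearest-centroid propagation over
#' the labeled stack. A mother's propagation stops before her daughters'
#' first click; her last observed frame is recorded as the division frame.
#' Clicks landing on background are deferred for up to
#' `policy$max_dark_frames` frames (dark-gap clicks); a click that never
#' acquires a region raises an error naming the frame and coordinates. No
#' region is ever assigned to two cells in one frame; ambiguous matches are
#' broken by distance, then larger area, then lower label.
#'
#' @param lstack A [label_stack()] result (build via [binarize_movie()]).
#' @param clicks A click script (see [click_script()]).
#' @param policy A [gap_policy()].
#' @param on_unmatched `"error"` (default): a click that never acquires a
#'   region raises an error naming the frame and coordinates; `"skip"`: the
#'   cell is dropped with a warning (used by batch pipelines where one
#'   unresolvable cell must not abort a whole movie).
#' @return Object of class `lineage_tree`: list with `tracks` (named list of
#'   per-cell data.frames `frame,label,x,y,area,dark`), `info` (per cell:
#'   `cell_id,parent_id,first_frame,last_frame,end_reason`), `edges`
#'   (per division: `mother,daughter1,daughter2,division_frame`; daughters
#'   ordered by x-centroid at birth).
#' @export
run_click_script <- function(lstack, clicks, policy = gap_policy(),
                             on_unmatched = c("error", "skip")) {
  check(inherits(lstack, "labeled_stack"), "`lstack` must be a labeled_stack")
  on_unmatched <- match.arg(on_unmatched)
  clicks <- click_script(clicks)
  if (nrow(clicks) == 0L) {
    return(structure(list(tracks = list(),
                          info = data.frame(cell_id = integer(0),
                                            parent_id = integer(0),
                                            first_frame = integer(0),
                                            last_frame = integer(0),
                                            end_reason = character(0)),
                          edges = data.frame(mother = integer(0),
                                             daughter1 = integer(0),
                                             daughter2 = integer(0),
                                             division_frame = integer(0))),
                     class = "lineage_tree"))
  }
  ids <- unique(clicks$cell_id)
  first_click <- vapply(ids, function(id)
    min(clicks$frame[clicks$cell_id == id]), integer(1))
  parent_of <- vapply(ids, function(id) {
    p <- clicks$parent_id[clicks$cell_id == id]
    p <- p[!is.na(p)]
    if (length(p) == 0L) NA_integer_ else as.integer(p[1L])
  }, integer(1))
  # a mother's window ends just before her earliest-clicked daughter
  window_end <- vapply(ids, function(id) {
    kids <- ids[!is.na(parent_of) & parent_of == id]
    if (length(kids) == 0L) lstack$n_frames - 1L
    else min(first_click[match(kids, ids)]) - 1L
  }, integer(1))
  claimed_env <- new.env(parent = emptyenv())
  claimed_env$claimed <- rep(list(integer(0)), lstack$n_frames)
  tracks <- list()
  info <- list()
  for (ord in order(first_click, ids)) {
    id <- ids[ord]
    ck <- clicks[clicks$cell_id == id, , drop = FALSE]
    res <- propagate_cell(lstack, ck, first_click[ord], window_end[ord],
                          policy, claimed_env)
    if (is.na(res$last_seen)) {
      msg <- sprintf(
        "click for cell %s at frame %d (x=%g, y=%g) found no object within gap tolerance",
        id, ck$frame[1L], ck$x[1L], ck$y[1L])
      if (on_unmatched == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      next
    }
    tracks[[as.character(id)]] <- res$track
    info[[length(info) + 1L]] <- data.frame(
      cell_id = id, parent_id = parent_of[ord],
      first_frame = res$track$frame[1L],
      last_frame = res$last_seen,
      end_reason = if (window_end[ord] < lstack$n_frames - 1L) "division"
                   else res$end_reason)
  }
  info <- do.call(rbind, info)
  mothers <- unique(info$parent_id[!is.na(info$parent_id)])
  edges <- lapply(mothers, function(m) {
    if (!(m %in% info$cell_id)) return(NULL)   # mother skipped/untracked
    kids <- info$cell_id[!is.na(info$parent_id) & info$parent_id == m]
    if (length(kids) != 2L) return(NULL)
    bx <- vapply(kids, function(k) {
      tr <- tracks[[as.character(k)]]
      tr$x[!tr$dark][1L]
    }, numeric(1))
    kids <- kids[order(bx)]
    data.frame(mother = m, daughter1 = kids[1L], daughter2 = kids[2L],
               division_frame = info$last_frame[info$cell_id == m])
  })
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(mother = integer(0), daughter1 = integer(0),
               daughter2 = integer(0), division_frame = integer(0))
  structure(list(tracks = tracks, info = info, edges = edges,
                 policy = policy),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %d cells, %d divisions\n",
              nrow(x$info), nrow(x$edges)))
  invisible(x)
}

#' Automatic forward propagation of a single track
#'
#' Convenience over per-frame clicking: follows the component nearest the
#' running centroid until the movie ends, the cell splits (two candidate
#' components appear within the search radius after the tracked one
#' vanishes -- a division candidate), or the cell stays dark beyond
#' `max_dark_frames`.
#'
#' @param lstack A [label_stack()] result.
#' @param seed `c(frame, x, y)`, 0-based; must land on foreground.
#' @param search_radius_px Matching radius in pixels.
#' @param max_dark_frames Dark-gap tolerance in frames.
#' @return List with `track` (as in [run_click_script()]), `halt_reason`
#'   (`"end"`, `"split"` or `"lost"`) and, for splits, `daughter_seeds`
#'   (two `c(frame, x, y)` rows ordered by x).
#' @export
auto_propagate <- function(lstack, seed, search_radius_px = 18,
                           max_dark_frames = 5L) {
  check(inherits(lstack, "labeled_stack"), "`lstack` must be a labeled_stack")
  check(length(seed) == 3L && all(is.finite(seed)), "`seed` must be c(frame, x, y)")
  f0 <- as.integer(seed[1])
  check(f0 >= 0L && f0 < lstack$n_frames, "seed frame out of range")
  lab0 <- lstack$labels[as.integer(round(seed[3])) + 1L,
                        as.integer(round(seed[2])) + 1L, f0 + 1L]
  check(lab0 > 0L, "seed does not land on foreground")
  comp0 <- lstack$components[[f0 + 1L]]
  pos <- unlist(comp0[comp0$label == lab0, c("x", "y")])
  rows <- list(data.frame(frame = f0, label = lab0, x = pos[1], y = pos[2],
                          area = comp0$area[comp0$label == lab0], dark = FALSE))
  claimed <- rep(list(integer(0)), lstack$n_frames)
  claimed[[f0 + 1L]] <- lab0
  dark_run <- 0L
  halt <- "end"
  daughter_seeds <- NULL
  f <- f0
  while (f < lstack$n_frames - 1L) {
    f <- f + 1L
    comp <- lstack$components[[f + 1L]]
    inr <- comp[sqrt((comp$x - pos[1])^2 + (comp$y - pos[2])^2) <=
                  search_radius_px, , drop = FALSE]
    if (dark_run > 0L && nrow(inr) >= 2L) {
      # the tracked component vanished and two candidates appeared: division
      inr <- inr[order(inr$x), ]
      daughter_seeds <- data.frame(frame = f, x = round(inr$x[1:2]),
                                   y = round(inr$y[1:2]))
      halt <- "split"
      break
    }
    if (nrow(inr) == 0L) {
      dark_run <- dark_run + 1L
      if (dark_run > max_dark_frames) { halt <- "lost"; break }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, label = 0L, x = NA_real_, y = NA_real_,
        area = NA_integer_, dark = TRUE)
      next
    }
    o <- order(round(sqrt((inr$x - pos[1])^2 + (inr$y - pos[2])^2), 6),
               -inr$area, inr$label)
    hit <- inr[o[1L], ]
    dark_run <- 0L
    pos <- c(hit$x, hit$y)
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f, label = hit$label, x = hit$x, y = hit$y, area = hit$area,
      dark = FALSE)
  }
  track <- do.call(rbind, rows)
  track <- track[cumsum(!track$dark) > 0 &
                   rev(cumsum(rev(!track$dark))) > 0, , drop = FALSE]
  list(track = track, halt_reason = halt, daughter_seeds = daughter_seeds)
}

#' Check the structural invariants of a lineage tree
#'
#' Reports (rather than errors on) violations: parent references that do not
#' resolve (`forest`), more than two daughters (`arity`), daughters starting
#' at or before the mother's last frame (`temporal order`), one region
#' claimed by two cells in a frame (`duplicate region`), and non-interval
#' frame sets (`frame gaps`).
#'
#' @param tree A `lineage_tree` (or a hand-built list with the same shape).
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_lineage <- function(tree) {
  v <- character(0)
  info <- tree$info
  ids <- info$cell_id
  parents <- info$parent_id[!is.na(info$parent_id)]
  bad <- setdiff(parents, ids)
  if (length(bad) > 0L)
    v <- c(v, sprintf("forest: parent %s not present as a cell", bad))
  tab <- table(info$parent_id[!is.na(info$parent_id)])
  if (any(tab > 2L))
    v <- c(v, sprintf("arity: parent %s has %d daughters",
                      names(tab)[tab > 2L], as.integer(tab[tab > 2L])))
  for (i in seq_len(nrow(info))) {
    p <- info$parent_id[i]
    if (is.na(p) || !(p %in% ids)) next
    pl <- info$last_frame[info$cell_id == p]
    if (info$first_frame[i] <= pl)
      v <- c(v, sprintf(
        "temporal order: daughter %s starts at frame %d but mother %s lasts to %d",
        info$cell_id[i], info$first_frame[i], p, pl))
  }
  seen <- list()
  for (id in names(tree$tracks)) {
    tr <- tree$tracks[[id]]
    if (is.null(tr) || nrow(tr) == 0L) next
    fr <- tr$frame
    if (!identical(as.integer(fr), seq(fr[1L], fr[length(fr)])))
      v <- c(v, sprintf("frame gaps: cell %s frames are not an interval", id))
    obs <- tr[!tr$dark, , drop = FALSE]
    key <- paste(obs$frame, obs$label)
    dup <- intersect(key, unlist(seen))
    if (length(dup) > 0L)
      v <- c(v, sprintf("duplicate region: cell %s shares frame/label %s",
                        id, dup))
    seen[[id]] <- key
  }
  v
}
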