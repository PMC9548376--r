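# Click-scripted tracking, automatic propagation, lineage validation.

# binary stack with one disc per frame at supplied centres (0-based x,y)
moving_disc_stack <- function(h, w, centres, r = 4) {
  masks <- array(FALSE, c(h, w, nrow(centres)))
  for (f in seq_len(nrow(centres))) {
    if (is.na(centres[f, 1])) next
    masks[, , f] <- disc_mask(h, w, centres[f, 2] + 1, centres[f, 1] + 1, r)
  }
  as_binary_stack(masks)
}

test_that("a cell clicked once is propagated through every frame", {
  n <- 30
  centres <- cbind(x = round(10 + 0.8 * (seq_len(n) - 1)), y = rep(20, n))
  ls <- fuccitrack:::label_stack(moving_disc_stack(48, 48, centres))
  clicks <- data.frame(frame = 0, x = 10, y = 20, cell_id = 1,
                       parent_id = NA)
  tree <- run_click_script(ls, clicks, gap_policy(search_radius_px = 6))
  expect_equal(nrow(tree$tracks[["1"]]), n)
  expect_false(any(tree$tracks[["1"]]$dark))
  expect_equal(tree$info$end_reason, "end")
})

test_that("empty click script yields an empty tree", {
  ls <- fuccitrack:::label_stack(moving_disc_stack(20, 20,
                                                   cbind(10, 10)))
  tree <- run_click_script(ls, data.frame(frame = integer(0), x = numeric(0),
                                          y = numeric(0),
                                          cell_id = integer(0)))
  expect_length(tree$tracks, 0L)
  expect_equal(nrow(tree$info), 0L)
})

test_that("click script validation catches malformed scripts", {
  expect_error(click_script(data.frame(frame = 1, x = 1)), "needs columns")
  bad_parent <- data.frame(frame = c(0, 1), x = 1, y = 1,
                           cell_id = c(2, 3), parent_id = c(NA, 9))
  expect_error(click_script(bad_parent), "parent 9")
  triplets <- data.frame(frame = c(0, 5, 5, 5), x = 1, y = 1,
                         cell_id = 1:4, parent_id = c(NA, 1, 1, 1))
  expect_error(click_script(triplets), "more than 2 children")
})

test_that("a two-division lineage is reconstructed with 4 leaves and exact division frames", {
  m <- fixed_model(g1 = 300, sg2m = 450, gap = 3L)   # cycle 750 min
  tr <- sample_lineages(m, 1, 1600, seed = 80, stagger_founders = FALSE)
  expect_equal(nrow(tr$cells), 7L)
  img <- small_imaging(108)
  r <- render_movie(tr, img, seed = 81, noise = FALSE)
  st <- binarize_movie(r$movie)
  ls <- fuccitrack:::label_stack(st)
  tree <- run_click_script(ls, oracle_clicks(r),
                           gap_policy(search_radius_px = 15))
  expect_equal(nrow(tree$info), 7L)
  # two rounds of division: founder + both daughters divide -> 3 edges
  expect_equal(nrow(tree$edges), 3L)
  leaves <- setdiff(tree$info$cell_id, tree$edges$mother)
  expect_length(leaves, 4L)
  truth_div <- r$frames$division_frame[match(tree$edges$mother,
                                             r$frames$cell_id)]
  expect_true(all(abs(tree$edges$division_frame - truth_div) <= 1))
  expect_length(validate_lineage(tree), 0L)
})

test_that("auto_propagate follows a drifting cell to the end", {
  n <- 25
  centres <- cbind(x = round(8 + 1.2 * (seq_len(n) - 1)), y = rep(15, n))
  ls <- fuccitrack:::label_stack(moving_disc_stack(40, 48, centres))
  res <- auto_propagate(ls, c(0, 8, 15), search_radius_px = 6)
  expect_equal(res$halt_reason, "end")
  expect_equal(nrow(res$track), n)
})

test_that("auto_propagate halts at a division with two daughter seeds", {
  masks <- array(FALSE, c(40, 40, 12))
  for (f in 1:5) masks[, , f] <- disc_mask(40, 40, 20, 20, 4)
  # frames 6-7 dark (gap), then two daughters flanking the old position
  for (f in 8:12) {
    masks[, , f] <- disc_mask(40, 40, 20, 13, 3) |
      disc_mask(40, 40, 20, 27, 3)
  }
  ls <- fuccitrack:::label_stack(as_binary_stack(masks))
  res <- auto_propagate(ls, c(0, 19, 19), search_radius_px = 10,
                        max_dark_frames = 5)
  expect_equal(res$halt_reason, "split")
  expect_equal(nrow(res$daughter_seeds), 2L)
  expect_lt(res$daughter_seeds$x[1], res$daughter_seeds$x[2])
})

test_that("auto_propagate reports a permanently vanishing cell as lost", {
  masks <- array(FALSE, c(30, 30, 15))
  for (f in 1:4) masks[, , f] <- disc_mask(30, 30, 15, 15, 4)
  ls <- fuccitrack:::label_stack(as_binary_stack(masks))
  res <- auto_propagate(ls, c(0, 14, 14), search_radius_px = 8,
                        max_dark_frames = 3)
  expect_equal(res$halt_reason, "lost")
  expect_equal(nrow(res$track), 4L)
  expect_error(auto_propagate(ls, c(0, 1, 1), search_radius_px = 8),
               "foreground")
})

test_that("no region is claimed by two cells in the same frame", {
  m <- fixed_model(g1 = 400, sg2m = 400, gap = 2L)
  tr <- sample_lineages(m, 3, 1190, seed = 82, stagger_founders = FALSE)
  img <- small_imaging(80)
  r <- render_movie(tr, img, seed = 83)
  st <- binarize_movie(r$movie)
  ls <- fuccitrack:::label_stack(st)
  tree <- run_click_script(ls, oracle_clicks(r),
                           gap_policy(search_radius_px = 15))
  seen <- character(0)
  for (id in names(tree$tracks)) {
    trk <- tree$tracks[[id]]
    keys <- paste(trk$frame[!trk$dark], trk$label[!trk$dark])
    expect_length(intersect(keys, seen), 0L)
    seen <- c(seen, keys)
    # frame sets are intervals (dark frames included in the run)
    expect_identical(as.integer(trk$frame),
                     seq(trk$frame[1], trk$frame[nrow(trk)]))
  }
})

test_that("validate_lineage flags arity and temporal-order violations", {
  info <- data.frame(cell_id = 1:4, parent_id = c(NA, 1, 1, 1),
                     first_frame = c(0, 11, 11, 11), last_frame = c(10, 20, 20, 20),
                     end_reason = "end")
  fake <- list(info = info, tracks = list(), edges = NULL)
  v <- validate_lineage(fake)
  expect_true(any(grepl("arity", v)))

  info2 <- data.frame(cell_id = 1:2, parent_id = c(NA, 1),
                      first_frame = c(0, 5), last_frame = c(10, 20),
                      end_reason = "end")
  v2 <- validate_lineage(list(info = info2, tracks = list(), edges = NULL))
  expect_true(any(grepl("temporal order", v2)))

  info3 <- data.frame(cell_id = 2, parent_id = 7, first_frame = 0,
                      last_frame = 3, end_reason = "end")
  v3 <- validate_lineage(list(info = info3, tracks = list(), edges = NULL))
  expect_true(any(grepl("forest", v3)))
})
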