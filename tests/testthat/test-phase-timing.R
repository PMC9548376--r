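# Trace extraction, onset detection, phase segmentation and durations.

test_that("trace mean over a uniform region is exact", {
  movie <- flat_movie(30, 30, 5, value = 100)
  movie$red[11:15, 11:15, ] <- 250
  masks <- array(FALSE, c(30, 30, 5))
  masks[11:15, 11:15, ] <- TRUE
  ls <- fuccitrack:::label_stack(as_binary_stack(masks))
  clicks <- data.frame(frame = 0, x = 12, y = 12, cell_id = 1, parent_id = NA)
  tree <- run_click_script(ls, clicks, gap_policy(search_radius_px = 5))
  trc <- extract_trace(movie, tree, 1, ls)
  expect_equal(trc$red, rep(250, 5))
  expect_equal(trc$green, rep(100, 5))
  expect_equal(trc$area, rep(25L, 5))
  expect_error(extract_trace(movie, tree, 99, ls), "unknown cell_id")
})

test_that("onset detection fires at a clean step and not on flat background", {
  bg <- list(red = c(mean = 100, sd = 2), green = c(mean = 100, sd = 2))
  flat <- data.frame(frame = 0:39, red = 100, green = 100,
                     area = 25L, dark = FALSE)
  ev <- detect_onsets(flat, bg)
  expect_true(is.na(ev$red_onset) && is.na(ev$green_onset))

  step <- flat
  step$green[step$frame >= 20] <- 100 + 10 * 2   # 10 sd step at frame 20
  ev2 <- detect_onsets(step, bg, k_onset = 5, min_run = 2)
  expect_equal(ev2$green_onset, 20L)
  expect_true(is.na(ev2$green_offset))           # stays on to the end

  pulse <- flat
  pulse$green[pulse$frame >= 10 & pulse$frame <= 25] <- 150
  ev3 <- detect_onsets(pulse, bg)
  expect_equal(ev3$green_onset, 10L)
  expect_equal(ev3$green_offset, 26L)

  short <- flat[1:1, ]
  expect_warning(detect_onsets(short, bg), "shorter than min_run")
})

test_that("offset detection survives a brief mid-track dropout", {
  bg <- list(red = c(mean = 100, sd = 2), green = c(mean = 100, sd = 2))
  tr <- data.frame(frame = 0:39, red = 100, green = 100, area = 25L,
                   dark = FALSE)
  tr$green[6:30] <- 400
  tr$green[15:16] <- 100       # two-frame dropout (e.g. claim conflict)
  ev <- detect_onsets(tr, bg)
  expect_equal(ev$green_onset, 5L)
  expect_equal(ev$green_offset, 30L)   # after the LAST sustained run
})

test_that("noiseless rendered G1 cell: red trace rises monotonically to its plateau", {
  m <- cell_cycle_model(5000, 0, 1000, 0, dark_gap_frames = 0L)
  tr <- sample_lineages(m, 1, 590, seed = 90, stagger_founders = FALSE)
  img <- small_imaging(40)
  r <- render_movie(tr, img, seed = 91, noise = FALSE)
  st <- binarize_movie(r$movie)
  ls <- fuccitrack:::label_stack(st)
  tree <- run_click_script(ls, oracle_clicks(r),
                           gap_policy(search_radius_px = 15))
  trc <- extract_trace(r$movie, tree, 1, ls)
  # the region is re-segmented every frame, so sub-pixel motion lets partial rim
  # pixels in and out: allow a few percent of the plateau as slack
  sm <- stats::runmed(trc$red, 3)
  expect_true(all(diff(sm) >= -0.03 * max(sm)))
  expect_true(all(trc$green <= img$background_level + 2))
})

test_that("phase segmentation matches truth within a frame on a noiseless render", {
  m <- fixed_model(g1 = 300, sg2m = 450, gap = 3L)
  tr <- sample_lineages(m, 1, 1600, seed = 92, stagger_founders = FALSE)
  img <- small_imaging(108)
  r <- render_movie(tr, img, seed = 93, noise = FALSE)
  res <- measure_phase_durations(r$movie, oracle_clicks(r), genotype = "det")
  d <- res$durations
  g1 <- d[d$phase == "G1" & !d$founder, ]
  sg <- d[d$phase == "SG2M", ]
  expect_gte(nrow(g1), 2L)
  expect_true(all(abs(g1$duration_min - 300) <= 15))
  expect_true(all(abs(sg$duration_min - 450) <= 15))
})

test_that("complete cycles conserve G1 + SG2M = birth-to-division", {
  m <- fixed_model(g1 = 450, sg2m = 600, gap = 3L)
  tr <- sample_lineages(m, 2, 2240, seed = 94, stagger_founders = FALSE)
  img <- small_imaging(150)
  r <- render_movie(tr, img, seed = 95, noise = FALSE)
  res <- measure_phase_durations(r$movie, oracle_clicks(r), genotype = "det")
  seg <- res$segments
  full <- seg[!seg$g1_censored & !seg$sg2m_censored & !seg$unresolvable, ]
  expect_gte(nrow(full), 1L)
  for (i in seq_len(nrow(full))) {
    cycle <- (full$sg2m_end[i] - full$g1_start[i]) * 15
    expect_lte(abs(cycle - 1050), 2 * 15)
  }
})

test_that("founder already cycling at frame 0 is start-censored but its S/G2/M is measured", {
  m <- fixed_model(g1 = 300, sg2m = 600, gap = 3L)
  # founder mid-G1 at movie start: red on at frame 0
  tr <- sample_lineages(m, 1, 1190, seed = 96, stagger_founders = FALSE)
  tr$cells$birth_min <- -150
  tr$cells$g1_end_min <- 150
  tr$cells$division_min <- 750
  tr$cells$censored_start <- TRUE
  img <- small_imaging(80)
  r <- render_movie(tr, img, seed = 97, noise = FALSE)
  res <- measure_phase_durations(r$movie, oracle_clicks(r), genotype = "det")
  seg <- res$segments[res$segments$founder, ]
  expect_true(seg$g1_censored[1])
  aud <- res$audit
  sg <- aud[aud$phase == "SG2M" & aud$founder, ]
  expect_false(sg$censored[1])
  expect_lte(abs(sg$duration_min - 600), 30)
})

test_that("phase duration arithmetic and censoring bookkeeping", {
  seg <- data.frame(cell_id = 1L, founder = FALSE, g1_start = 10L,
                    green_onset = 40L, g1_end_eff = 40L,
                    sg2m_end = NA_integer_, sg2m_end_eff = 75L,
                    g1_censored = FALSE, sg2m_censored = TRUE,
                    unresolvable = FALSE)
  pd <- phase_durations(seg, 15, genotype = "g")
  expect_equal(pd$durations$duration_min, 450)      # (40-10) * 15
  expect_equal(pd$durations$phase, "G1")
  expect_equal(nrow(pd$audit), 2L)
  # fully censored cell: empty statistical table, non-empty audit
  seg$g1_censored <- TRUE
  pd2 <- phase_durations(seg, 15)
  expect_equal(nrow(pd2$durations), 0L)
  expect_equal(nrow(pd2$audit), 2L)
})

test_that("recovered median G1 increases with the generator median", {
  meds <- vapply(c(300, 600), function(g1_med) {
    pooled <- c()
    for (s in 1:10) {
      m <- cell_cycle_model(g1_med, 0.15, 450, 0.15, dark_gap_frames = 2L,
                            genotype_label = "mc")
      tr <- sample_lineages(m, 2, 1485, seed = 700 + s,
                            stagger_founders = FALSE)
      img <- imaging_config(n_frames = 100, height = 80, width = 80,
                            nucleus_radius_px = 5)
      r <- render_movie(tr, img, seed = 800 + s)
      res <- suppressWarnings(
        measure_phase_durations(r$movie, oracle_clicks(r), genotype = "mc"))
      d <- res$durations
      pooled <- c(pooled, d$duration_min[d$phase == "G1" & !d$founder])
    }
    median(pooled)
  }, numeric(1))
  expect_gt(meds[2], meds[1])
  expect_equal(meds[1], 300, tolerance = 0.25)
  expect_equal(meds[2], 600, tolerance = 0.25)
})
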