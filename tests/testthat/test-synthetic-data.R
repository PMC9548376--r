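# Generators: lineage sampling, movie rendering, and assay fixtures.

test_that("zero-variance lineage divides exactly at its medians", {
  m <- cell_cycle_model(500, 0, 1000, 0, genotype_label = "det")
  tr <- sample_lineages(m, 1, 3000, seed = 1, stagger_founders = FALSE)
  cells <- tr$cells
  founder <- cells[is.na(cells$parent_id), ]
  expect_equal(nrow(founder), 1L)
  expect_equal(founder$division_min, 1500)
  gen2 <- cells[!is.na(cells$parent_id) & cells$parent_id == founder$cell_id, ]
  expect_equal(nrow(gen2), 2L)
  expect_equal(gen2$birth_min, c(1500, 1500))
  expect_equal(gen2$division_min, c(3000, 3000))
  expect_equal(length(lineage_leaves(tr)), 4L)
  expect_true(all(cells$g1_end_min - cells$birth_min == 500))
})

test_that("t_total = 0 gives founders only, all end-censored", {
  m <- fixed_model()
  tr <- sample_lineages(m, 5, 0, seed = 3)
  expect_equal(nrow(tr$cells), 5L)
  expect_true(all(tr$cells$censored_end))
  expect_true(all(is.na(tr$cells$parent_id)))
})

test_that("lineage sampling is deterministic given the seed", {
  m <- npc_model("wt")
  a <- sample_lineages(m, 4, 4000, seed = 42)
  b <- sample_lineages(m, 4, 4000, seed = 42)
  expect_identical(a$cells, b$cells)
  c <- sample_lineages(m, 4, 4000, seed = 43)
  expect_false(identical(a$cells, c$cells))
})

test_that("lineage invariants hold on sampled forests", {
  m <- hesc_model("mut")
  for (s in 1:5) {
    tr <- sample_lineages(m, 3, 3000, seed = 100 + s)
    cells <- tr$cells
    kids <- table(cells$parent_id[!is.na(cells$parent_id)])
    expect_true(all(kids == 2L))
    for (i in which(!is.na(cells$parent_id))) {
      p <- cells[cells$cell_id == cells$parent_id[i], ]
      expect_equal(cells$birth_min[i], p$division_min)
    }
    done <- cells[!cells$censored_end, ]
    expect_true(all(done$birth_min < done$g1_end_min))
    expect_true(all(done$g1_end_min < done$division_min))
  }
})

test_that("model validation rejects impossible parameters", {
  expect_error(cell_cycle_model(-5, 0.1, 900, 0.1), "positive")
  expect_error(cell_cycle_model(100, 0.1, 900, 0.1, overlap_min = 150),
               "overlap_min")
  expect_error(cell_cycle_model(100, 0.1, 900, 0.1, dark_gap_frames = -1),
               "dark_gap_frames")
})

test_that("faster-cycling mutant lineages produce more leaves", {
  wt <- npc_model("wt"); mut <- npc_model("mut")
  leaves <- function(model, s)
    length(lineage_leaves(sample_lineages(model, 1, 3000, seed = s)))
  n_wt <- vapply(1:100, function(s) leaves(wt, s), numeric(1))
  n_mut <- vapply(1:100, function(s) leaves(mut, 1000 + s), numeric(1))
  expect_gt(mean(n_mut), mean(n_wt))
})

test_that("lognormal calibration matches a median +/- sd target", {
  s <- lognormal_logsd(1408, 982)
  x <- exp(stats::rnorm(2e5, log(1408), s))
  expect_equal(median(x), 1408, tolerance = 0.02)
  expect_equal(sd(x), 982, tolerance = 0.03)
})

test_that("noiseless render: one G1 cell gives a flat red plateau and background green", {
  m <- cell_cycle_model(5000, 0, 1000, 0, dark_gap_frames = 0L)
  tr <- sample_lineages(m, 1, 900, seed = 5, stagger_founders = FALSE)
  img <- small_imaging(60)
  r <- render_movie(tr, img, seed = 6, noise = FALSE)
  bg <- img$background_level
  expect_true(all(r$movie$green == bg))
  # after the 120-min ramp (frame 8) the red value at the moving nucleus
  # centre is constant within quantisation
  px <- vapply(10:59, function(f) {
    p <- r$positions[r$positions$frame == f, ]
    r$movie$red[round(p$y) + 1, round(p$x) + 1, f + 1]
  }, numeric(1))
  expect_true(all(abs(px - px[1]) <= 1))
  expect_gt(px[1], bg + 1000)
})

test_that("noiseless render: both channels at background through the dark gap", {
  m <- fixed_model(g1 = 300, sg2m = 300, gap = 3L)   # division at 600 min
  tr <- sample_lineages(m, 1, 890, seed = 7, stagger_founders = FALSE)
  img <- small_imaging(60)
  r <- render_movie(tr, img, seed = 8, noise = FALSE)
  bg <- img$background_level
  div_f <- r$frames$division_frame[is.na(r$frames$parent_id)]
  gap_frames <- div_f + 1 + seq_len(3)
  for (f in gap_frames) {
    expect_true(all(r$movie$red[, , f + 1] == bg))
    expect_true(all(r$movie$green[, , f + 1] == bg))
  }
  # and the mother was bright green just before dividing
  expect_gt(max(r$movie$green[, , div_f + 1]), bg + 1000)
})

test_that("default noise yields a sane per-nucleus SNR", {
  m <- cell_cycle_model(5000, 0, 1000, 0, dark_gap_frames = 0L)
  tr <- sample_lineages(m, 1, 890, seed = 9, stagger_founders = FALSE)
  img <- small_imaging(60)
  r <- render_movie(tr, img, seed = 10, noise = TRUE)
  fr <- r$movie$red[, , 40]
  bg_px <- fr[fr < 500]
  pos <- subset(r$positions, frame == 39)
  cy <- round(pos$y) + 1; cx <- round(pos$x) + 1
  nuc <- fr[(cy - 2):(cy + 2), (cx - 2):(cx + 2)]
  snr <- (mean(nuc) - mean(bg_px)) / sd(bg_px)
  expect_gt(snr, 10)
  expect_lt(snr, 500)
})

test_that("rendering is bit-identical under a fixed seed", {
  m <- fixed_model()
  tr <- sample_lineages(m, 2, 440, seed = 11)
  img <- small_imaging(30)
  a <- render_movie(tr, img, seed = 12)
  b <- render_movie(tr, img, seed = 12)
  expect_identical(a$movie$red, b$movie$red)
  expect_identical(a$movie$green, b$movie$green)
  expect_identical(a$positions, b$positions)
})

test_that("PI event generator hits its design distribution", {
  ev <- simulate_pi_events(c(1, 0, 0), 0.05, 5000, seed = 20, mu = 200)
  expect_equal(mean(ev$intensity), 200, tolerance = 0.02)
  expect_equal(sd(ev$intensity), 10, tolerance = 0.1)

  ev0 <- simulate_pi_events(c(0.5, 0, 0.5), 0, 2000, seed = 21, mu = 200)
  expect_setequal(unique(ev0$intensity), c(200, 400))

  expect_equal(nrow(simulate_pi_events(c(1, 0, 0), 0.05, 0, seed = 22)), 0L)
  expect_error(simulate_pi_events(c(0.5, 0.2, 0.2), 0.05, 100, seed = 23),
               "summing to 1")
})

test_that("Ct table generator produces the designed shifts", {
  ct <- simulate_ct_table(c(CHD8_proximal = 0.5), noise_sd = 0, seed = 30)
  rep <- ddct_fold_change(ct, "CHD8_proximal")
  expect_equal(rep$per_experiment$ddct, rep(1, 3))
  expect_equal(rep$mean_fold, 0.5)
  ct1 <- simulate_ct_table(c(g = 1), noise_sd = 0, seed = 31)
  expect_equal(ddct_fold_change(ct1, "g")$per_experiment$ddct, rep(0, 3))
})

test_that("nuclei-field generator round-trips group means and validates counts", {
  fld <- simulate_nuclei_field(c(100, 100), c(30, 30), noise_sd = 5, seed = 40)
  qa <- quantify_rois(fld$images[[1]], fld$labels[[1]], group = "a")
  qb <- quantify_rois(fld$images[[2]], fld$labels[[2]], group = "b")
  pc <- percent_change(qa$mean_intensity, qb$mean_intensity)
  expect_lt(abs(pc$percent_decrease), 5)
  expect_error(simulate_nuclei_field(c(100, 57), c(0, 10), seed = 41),
               "positive counts")
})

test_that("allele set generator emits the exact composition, shuffled by seed", {
  ref <- paste(rep("ACGT", 30), collapse = "")
  v <- list(type = "insertion", pos = 60, seq = "C")
  set <- simulate_alleles(ref, v, n_wt = 15, n_mut = 19, seed = 50)
  expect_length(set, 34L)
  truth <- attr(set, "truth")
  expect_equal(sum(truth$class == "wt"), 15L)
  expect_equal(sum(truth$class == "insertion"), 19L)
  lens <- Biostrings::width(set)
  expect_setequal(unique(lens), c(120L, 121L))
  set2 <- simulate_alleles(ref, v, n_wt = 15, n_mut = 19, seed = 50)
  expect_identical(as.character(set), as.character(set2))
  none <- simulate_alleles(ref, v, n_wt = 5, n_mut = 0, seed = 51)
  expect_true(all(attr(none, "truth")$class == "wt"))
})
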