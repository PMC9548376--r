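# Replicate-movie cohort simulation: the study design used for genotype
# comparisons. Each replicate renders an independent movie of staggered
# founders, runs the full segmentation/tracking/trace pipeline with oracle
# clicks, and pools duration records.

#' Simulate and measure a phase-duration cohort
#'
#' Runs `n_movies` independent synthetic movies of one genotype through the
#' complete pipeline (render, binarize, track from oracle clicks, traces,
#' phase segmentation) and pools the resulting duration and audit tables.
#'
#' @param model A [cell_cycle_model()].
#' @param imaging An [imaging_config()] shared by all replicates.
#' @param n_movies Number of replicate movies.
#' @param n_founders Founder cells per movie.
#' @param seed Base seed; replicate i uses `seed + i` (lineage) and
#'   `seed + 1000 + i` (render).
#' @param rep A [reporter_params()].
#' @param noise Render with imaging noise (default TRUE).
#' @return List with `durations` (pooled uncensored records; `cell_id` is
#'   prefixed by movie), `audit` (all records incl. censored), and
#'   `g1_daughters`: a data.frame `time, event` of daughter-cell G1
#'   durations, complete (`event = TRUE`) or right-censored at track end,
#'   ready for [km_median()].
#' @export
simulate_timing_cohort <- function(model, imaging, n_movies, n_founders,
                                   seed, rep = reporter_params(),
                                   noise = TRUE) {
  check(inherits(model, "cell_cycle_model"), "`model` must be a cell_cycle_model")
  check_count(n_movies, "n_movies", min = 1L)
  check_seed(seed)
  durs <- list(); audits <- list()
  t_total <- imaging$n_frames * imaging$frame_interval_min
  for (i in seq_len(n_movies)) {
    truth <- sample_lineages(model, n_founders, t_total, seed = seed + i)
    rnd <- render_movie(truth, imaging, rep = rep, seed = seed + 1000L + i,
                        noise = noise)
    res <- suppressWarnings(
      measure_phase_durations(rnd$movie, oracle_clicks(rnd),
                              genotype = model$genotype_label))
    tag <- function(df) {
      if (nrow(df) > 0L) df$cell_id <- sprintf("m%02d_%s", i, df$cell_id)
      df
    }
    durs[[i]] <- tag(res$durations)
    audits[[i]] <- tag(res$audit)
  }
  audit <- do.call(rbind, audits)
  g1 <- audit[audit$phase == "G1" & !audit$founder &
                !is.na(audit$duration_min) & audit$duration_min > 0, ]
  structure(list(durations = do.call(rbind, durs), audit = audit,
                 g1_daughters = data.frame(time = g1$duration_min,
                                           event = !g1$censored),
                 genotype = model$genotype_label,
                 n_movies = n_movies),
            class = "timing_cohort")
}

#' @export
print.timing_cohort <- function(x, ...) {
  g1 <- x$g1_daughters
  cat(sprintf(
    "<timing_cohort '%s'> %d movies; %d complete + %d censored daughter G1 phases; KM median G1 %.0f min\n",
    x$genotype, x$n_movies, sum(g1$event), sum(!g1$event),
    km_median(g1$time, g1$event)))
  invisible(x)
}
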