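#' Simulate a ground-truth cell lineage forest
#'
#' Draws G1 and S/G2/M durations for every cell independently from the
#' model's lognormals and grows lineages forward in time until `t_total_min`.
#' Each dividing mother produces exactly two daughters born at her division
#' time. Cells whose division falls beyond `t_total_min` are flagged
#' `censored_end`; staggered founders (born before time 0 at a uniformly
#' random position within their own first cycle) are flagged
#' `censored_start`, which reproduces a culture observed mid-growth rather
#' than one synchronised at movie start.
#'
#' @param model A [cell_cycle_model()].
#' @param n_founders Number of founder cells (>= 1).
#' @param t_total_min Total simulated time in minutes (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param stagger_founders If `TRUE` (default) founders are born at
#'   `-U(0, cycle)` so the population is asynchronous; if `FALSE` all
#'   founders are born at time 0.
#' @return An object of class `truth_lineage`: a list with `cells` (one row
#'   per cell: `cell_id`, `parent_id` (`NA` for founders), `genotype`,
#'   `birth_min`, `g1_min`, `sg2m_min`, `g1_end_min`, `division_min` (`NA`
#'   when censored), `censored_start`, `censored_end`), plus the `model`,
#'   `t_total_min` and `seed` used.
#' @export
sample_lineages <- function(model, n_founders, t_total_min, seed,
                            stagger_founders = TRUE) {
  check(inherits(model, "cell_cycle_model"),
        "`model` must be a cell_cycle_model")
  check_count(n_founders, "n_founders", min = 1L)
  check_scalar_nonneg(t_total_min, "t_total_min")
  with_seed(seed, {
    draw_phase <- function(median_min, logsd) {
      if (logsd == 0) median_min else stats::rlnorm(1, log(median_min), logsd)
    }
    rows <- list()
    next_id <- 1L
    # FIFO queue of cells to realise: (parent_id, birth_min, censored_start)
    queue <- lapply(seq_len(n_founders), function(i)
      list(parent = NA_integer_, birth = 0, cens_start = TRUE))
    while (length(queue) > 0L) {
      item <- queue[[1L]]; queue <- queue[-1L]
      g1 <- draw_phase(model$g1_median_min, model$g1_logsd)
      sg2m <- draw_phase(model$sg2m_median_min, model$sg2m_logsd)
      birth <- item$birth
      cens_start <- item$cens_start
      if (is.na(item$parent)) {
        # founder: born before t=0 at a uniform position in its own cycle
        birth <- if (stagger_founders) -stats::runif(1, 0, g1 + sg2m) else 0
        cens_start <- stagger_founders
      }
      division <- birth + g1 + sg2m
      cens_end <- division > t_total_min
      rows[[next_id]] <- data.frame(
        cell_id = next_id, parent_id = item$parent,
        genotype = model$genotype_label,
        birth_min = birth, g1_min = g1, sg2m_min = sg2m,
        g1_end_min = birth + g1,
        division_min = if (cens_end) NA_real_ else division,
        censored_start = cens_start, censored_end = cens_end)
      if (!cens_end) {
        queue <- c(queue, list(
          list(parent = next_id, birth = division, cens_start = FALSE),
          list(parent = next_id, birth = division, cens_start = FALSE)))
      }
      next_id <- next_id + 1L
      check(next_id <= 100000L,
            "lineage exceeds 100000 cells; reduce t_total_min or n_founders")
    }
    structure(list(cells = do.call(rbind, rows), model = model,
                   t_total_min = t_total_min, n_founders = n_founders,
                   seed = as.integer(seed)),
              class = "truth_lineage")
  })
}

#' @export
print.truth_lineage <- function(x, ...) {
  cat(sprintf(
    "<truth_lineage '%s'> %d cells from %d founders over %g min (%d divisions observed)\n",
    x$model$genotype_label, nrow(x$cells), x$n_founders, x$t_total_min,
    sum(!x$cells$censored_end)))
  invisible(x)
}

#' Leaves of a truth lineage
#'
#' Cells with no recorded daughters (alive at movie end or never divided).
#'
#' @param truth A [sample_lineages()] result.
#' @return Integer vector of leaf `cell_id`s.
#' @export
lineage_leaves <- function(truth) {
  check(inherits(truth, "truth_lineage"), "`truth` must be a truth_lineage")
  setdiff(truth$cells$cell_id, truth$cells$parent_id[!is.na(truth$cells$parent_id)])
}
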