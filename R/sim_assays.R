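# Fixture generators for the ancillary assays: propidium-iodide DNA-content
# event lists, replicate Ct tables, two-group nuclei fields, and CRISPR
# allele sets. Each is seeded and round-trips through its analysis
# counterpart.

#' Simulate a propidium-iodide DNA-content event list
#'
#' G0/G1 events are Normal(mu, cv*mu) (2N DNA content), G2/M events
#' Normal(2*mu, 2*cv*mu) (4N), and S-phase events uniform between the two
#' peaks with Gaussian-smoothed edges.
#'
#' @param fractions Length-3 non-negative vector `(G0-G1, S, G2-M)` summing
#'   to 1.
#' @param cv Peak coefficient of variation, in (0, 0.3) (0 allowed for
#'   exact delta peaks).
#' @param n_events Number of events (0 gives an empty list).
#' @param seed Integer seed.
#' @param mu Position of the 2N peak in arbitrary PE-A-like units.
#' @param sample Sample label stamped on each event.
#' @return data.frame `intensity, phase, sample` (phase is the generating
#'   ground truth).
#' @export
simulate_pi_events <- function(fractions, cv, n_events, seed, mu = 200,
                               sample = "wt") {
  check(length(fractions) == 3L && all(fractions >= 0) &&
          abs(sum(fractions) - 1) < 1e-8,
        "`fractions` must be 3 non-negative values summing to 1")
  check(is.numeric(cv) && length(cv) == 1L && cv >= 0 && cv < 0.3,
        "`cv` must be in [0, 0.3)")
  check_count(n_events, "n_events")
  check_scalar_pos(mu, "mu")
  if (n_events == 0L) {
    return(data.frame(intensity = numeric(0), phase = character(0),
                      sample = character(0)))
  }
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_events, fractions))
    g1 <- stats::rnorm(counts[1], mu, cv * mu)
    s <- stats::runif(counts[2], mu, 2 * mu) +
      stats::rnorm(counts[2], 0, 0.5 * cv * mu)
    g2m <- stats::rnorm(counts[3], 2 * mu, 2 * cv * mu)
    out <- data.frame(
      intensity = c(g1, s, g2m),
      phase = rep(c("G0G1", "S", "G2M"), counts),
      sample = sample)
    out <- out[sample.int(nrow(out)), ]
    rownames(out) <- NULL
    out$intensity <- pmax(out$intensity, 1e-6)
    out
  })
}

#' Simulate a replicate RT-qPCR Ct table
#'
#' For each independent experiment, each target gene gets a wild-type
#' delta-Ct (target minus reference) and the mutant's target Ct is shifted
#' by `-log2(fold_change)` relative to the reference gene; the reference
#' gene (POLR2a) is included for both samples, and Gaussian replicate noise
#' is added to every well.
#'
#' @param fold_changes Named positive vector of true mutant/wild-type fold
#'   changes per target probe.
#' @param ct_ref Baseline reference-gene Ct.
#' @param n_experiments Number of independent experiments.
#' @param replicates Technical replicates per well (>= 2).
#' @param noise_sd Replicate Ct noise sd.
#' @param seed Integer seed.
#' @param reference_gene Reference gene name (default `"POLR2a"`).
#' @return data.frame `sample, gene, experiment, replicate, ct`.
#' @export
simulate_ct_table <- function(fold_changes, ct_ref = 20, n_experiments = 3L,
                              replicates = 3L, noise_sd = 0.05, seed = 1L,
                              reference_gene = "POLR2a") {
  check(is.numeric(fold_changes) && length(fold_changes) >= 1L &&
          all(fold_changes > 0) && !is.null(names(fold_changes)),
        "`fold_changes` must be a named positive vector")
  check_count(replicates, "replicates", min = 2L)
  check_count(n_experiments, "n_experiments", min = 1L)
  check_scalar_nonneg(noise_sd, "noise_sd")
  with_seed(seed, {
    rows <- list()
    for (e in seq_len(n_experiments)) {
      # experiment-wide Ct shifts (input amount differences) cancel in dCt
      shift <- stats::rnorm(2, 0, 0.5)
      names(shift) <- c("wt", "mut")
      for (s in c("wt", "mut")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = reference_gene, experiment = e,
          replicate = seq_len(replicates),
          ct = ct_ref + shift[[s]] +
            stats::rnorm(replicates, 0, noise_sd))
        for (g in names(fold_changes)) {
          dct_wt <- 3                     # targets ~8x less abundant than ref
          dct <- if (s == "wt") dct_wt else dct_wt - log2(fold_changes[[g]])
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, gene = g, experiment = e,
            replicate = seq_len(replicates),
            ct = ct_ref + shift[[s]] + dct +
              stats::rnorm(replicates, 0, noise_sd))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a two-group immunofluorescence nuclei field
#'
#' Two labeled images (one per staining group, e.g. wild type and mutant)
#' of non-overlapping elliptical nuclei; each nucleus's intensity is drawn
#' around its group mean. Label masks and a ground-truth table are exported.
#'
#' @param group_means Two positive group mean intensities.
#' @param n_cells Two positive cell counts.
#' @param noise_sd Per-cell intensity sd around the group mean (absolute
#'   units).
#' @param seed Integer seed.
#' @param radius_px Mean nucleus radius.
#' @return List with `images` (two numeric matrices), `labels` (two integer
#'   label masks) and `truth` (`group, cell, true_mean`).
#' @export
simulate_nuclei_field <- function(group_means, n_cells, noise_sd = 10,
                                  seed = 1L, radius_px = 6) {
  check(length(group_means) == 2L && all(group_means > 0),
        "`group_means` must be two positive intensities")
  check(length(n_cells) == 2L && all(n_cells == round(n_cells)) &&
          all(n_cells >= 1),
        "`n_cells` must be two positive counts")
  check_scalar_nonneg(noise_sd, "noise_sd")
  with_seed(seed, {
    images <- list(); labels <- list(); truth <- list()
    for (g in 1:2) {
      n <- n_cells[g]
      ncol_grid <- ceiling(sqrt(n))
      nrow_grid <- ceiling(n / ncol_grid)
      pitch <- ceiling(3.2 * radius_px)
      h <- nrow_grid * pitch + pitch
      w <- ncol_grid * pitch + pitch
      img <- matrix(0, h, w)
      lab <- matrix(0L, h, w)
      means <- pmax(1e-3, stats::rnorm(n, group_means[g], noise_sd))
      for (i in seq_len(n)) {
        gy <- (i - 1) %/% ncol_grid
        gx <- (i - 1) %% ncol_grid
        cy <- pitch * (gy + 1) + stats::runif(1, -2, 2)
        cx <- pitch * (gx + 1) + stats::runif(1, -2, 2)
        rx <- radius_px * stats::runif(1, 0.85, 1.1)
        ry <- radius_px * stats::runif(1, 0.7, 0.95)
        th <- stats::runif(1, 0, pi)
        rows <- max(1, floor(cy - radius_px - 2)):min(h, ceiling(cy + radius_px + 2))
        cols <- max(1, floor(cx - radius_px - 2)):min(w, ceiling(cx + radius_px + 2))
        DX <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
        DY <- matrix(rows - cy, length(rows), length(cols))
        u <- (DX * cos(th) + DY * sin(th)) / rx
        v <- (-DX * sin(th) + DY * cos(th)) / ry
        inside <- u^2 + v^2 <= 1
        img[rows, cols][inside] <- means[i]
        lab[rows, cols][inside] <- i
      }
      images[[g]] <- img
      labels[[g]] <- lab
      truth[[g]] <- data.frame(group = g, cell = seq_len(n), true_mean = means)
    }
    list(images = images, labels = labels, truth = do.call(rbind, truth))
  })
}

#' Simulate a single-allele amplicon set
#'
#' `n_wt` copies of the reference amplicon and `n_mut` copies of its edited
#' variant (a single insertion or deletion at a stated position), shuffled
#' deterministically by seed.
#'
#' @param ref_seq Reference amplicon (character, ACGT).
#' @param variant List: `type` (`"insertion"` or `"deletion"`), `pos`
#'   (1-based position in the reference after (insertion) / from (deletion)
#'   which the edit applies), and `seq` (inserted bases) or `len` (deleted
#'   length).
#' @param n_wt,n_mut Copy numbers (each >= 0, together >= 1).
#' @param seed Integer seed for the shuffle.
#' @return A [Biostrings::DNAStringSet] named `allele_###`, with the truth
#'   class in `attr(, "truth")`.
#' @export
simulate_alleles <- function(ref_seq, variant, n_wt, n_mut, seed = 1L) {
  check(is.character(ref_seq) && length(ref_seq) == 1L && nchar(ref_seq) >= 20,
        "`ref_seq` must be a single sequence of >= 20 bases")
  check_count(n_wt, "n_wt"); check_count(n_mut, "n_mut")
  check(n_wt + n_mut >= 1L, "need at least one allele")
  check(is.list(variant) && variant$type %in% c("insertion", "deletion"),
        "`variant` must be a single insertion or deletion spec")
  check_count(variant$pos, "variant$pos", min = 1L)
  check(variant$pos <= nchar(ref_seq), "`variant$pos` beyond the reference")
  mut_seq <- apply_variant(ref_seq, variant)
  seqs <- c(rep(ref_seq, n_wt), rep(mut_seq, n_mut))
  cls <- c(rep("wt", n_wt), rep(variant$type, n_mut))
  with_seed(seed, {
    o <- sample.int(length(seqs))
    set <- Biostrings::DNAStringSet(seqs[o])
    names(set) <- sprintf("allele_%03d", seq_along(seqs))
    attr(set, "truth") <- data.frame(id = names(set), class = cls[o])
    set
  })
}

apply_variant <- function(ref_seq, variant) {
  p <- variant$pos
  if (variant$type == "insertion") {
    check(is.character(variant$seq) && nchar(variant$seq) >= 1L,
          "insertion variant needs `seq`")
    paste0(substr(ref_seq, 1, p), variant$seq,
           substr(ref_seq, p + 1, nchar(ref_seq)))
  } else {
    len <- if (is.null(variant$len)) 1L else variant$len
    check(p + len - 1 <= nchar(ref_seq), "deletion runs past the reference")
    paste0(substr(ref_seq, 1, p - 1),
           substr(ref_seq, p + len, nchar(ref_seq)))
  }
}
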