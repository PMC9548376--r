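# Ancillary quantifications: DNA-content histogram gating, 2^-ddCt relative
# expression, ROI intensity quantification with nucleus/cytoplasm ratio and
# percent change.

#' Gate a propidium-iodide histogram into G0-G1, S and G2-M fractions
#'
#' Kernel-smooths the intensity histogram, takes the dominant low-intensity
#' peak as the G0-G1 (2N) mode and the peak nearest twice that position as
#' the G2-M (4N) mode, estimates each peak's CV from the events near the
#' mode, and gates G0-G1 and G2-M within +/- `gate_k` estimated sds of the
#' modes; S is everything strictly between the gates. Events below
#' `0.5 * G0-G1 mode` are excluded as debris first. Fractions are over all
#' gated events.
#'
#' @param events Numeric intensities, or a data.frame with an `intensity`
#'   column (as from [simulate_pi_events()]).
#' @param min_events Minimum number of events (default 500).
#' @param gate_k Half-width of each gate in estimated peak sds (default 2).
#' @param manual_gates Optional override: list with `g0g1 = c(lo, hi)` and
#'   `g2m = c(lo, hi)` to reproduce hand-drawn gates.
#' @return Object of class `phase_fractions`: `f_g0g1, f_s, f_g2m`,
#'   `g2m_over_g0g1`, plus the modes and gates used.
#' @export
gate_dna_content <- function(events, min_events = 500L, gate_k = 2,
                             manual_gates = NULL) {
  if (is.data.frame(events)) events <- events$intensity
  check(is.numeric(events), "`events` must be numeric intensities")
  check(all(events > 0), "PI intensities must be positive")
  check(length(events) >= min_events,
        sprintf("need at least %d events, got %d", min_events, length(events)))
  if (is.null(manual_gates)) {
    d <- stats::density(events, n = 1024)
    ispeak <- which(diff(sign(diff(d$y))) == -2) + 1L
    ispeak <- ispeak[d$y[ispeak] >= 0.05 * max(d$y)]
    check(length(ispeak) >= 1L, "no peak found in the PI histogram")
    px <- d$x[ispeak]; py <- d$y[ispeak]
    # dominant peak; if a substantial peak sits near half its position, the
    # dominant one was 4N and the half-position peak is the true 2N mode
    m1 <- px[which.max(py)]
    halfish <- which(abs(px - m1 / 2) < 0.25 * (m1 / 2))
    if (length(halfish) > 0L && max(py[halfish]) > 0.25 * max(py)) {
      m1 <- px[halfish[which.max(py[halfish])]]
    }
    # one-sided (half-normal) peak-width estimate, taken on the flank away
    # from the S-phase plateau so S events cannot inflate the peak CV
    est_sd <- function(mode, side) {
      win <- if (side == "left") {
        events[events > 0.7 * mode & events < mode]
      } else {
        events[events > mode & events < 1.3 * mode]
      }
      if (length(win) < 10L) 0.02 * mode else sqrt(mean((win - mode)^2))
    }
    sd1 <- est_sd(m1, "left")
    cand <- which(abs(px - 2 * m1) < 0.3 * m1 & abs(px - m1) > 2 * sd1)
    if (length(cand) == 0L) {
      warning("no G2-M peak found near twice the G0-G1 mode; f_g2m = 0")
      m2 <- NA_real_; sd2 <- NA_real_
    } else {
      m2 <- px[cand[which.max(py[cand])]]
      sd2 <- est_sd(m2, "right")
    }
    keep <- events >= 0.5 * m1               # debris cut
    g1_gate <- c(m1 - gate_k * sd1, m1 + gate_k * sd1)
    g2_gate <- if (is.na(m2)) c(NA_real_, NA_real_) else
      c(m2 - gate_k * sd2, m2 + gate_k * sd2)
  } else {
    g1_gate <- manual_gates$g0g1
    g2_gate <- manual_gates$g2m
    m1 <- mean(g1_gate); m2 <- mean(g2_gate)
    keep <- events >= 0.5 * m1
  }
  ev <- events[keep]
  in_g1 <- ev >= g1_gate[1] & ev <= g1_gate[2]
  in_g2 <- if (anyNA(g2_gate)) rep(FALSE, length(ev)) else
    ev >= g2_gate[1] & ev <= g2_gate[2]
  in_s <- !in_g1 & !in_g2 & ev > g1_gate[2] &
    (if (anyNA(g2_gate)) TRUE else ev < g2_gate[1])
  n_gated <- sum(in_g1) + sum(in_g2) + sum(in_s)
  check(n_gated > 0L, "no events fall inside the gates")
  f1 <- sum(in_g1) / n_gated
  f2 <- sum(in_g2) / n_gated
  fs <- sum(in_s) / n_gated
  structure(list(f_g0g1 = f1, f_s = fs, f_g2m = f2,
                 g2m_over_g0g1 = if (f1 > 0) f2 / f1 else NA_real_,
                 mode_g0g1 = m1, mode_g2m = m2,
                 gate_g0g1 = g1_gate, gate_g2m = g2_gate,
                 n_events = length(events), n_gated = n_gated),
            class = "phase_fractions")
}

#' @export
print.phase_fractions <- function(x, ...) {
  cat(sprintf(
    "G0-G1 %.1f%% | S %.1f%% | G2-M %.1f%% (G2-M/G0-G1 ratio %.3f; %d/%d events gated)\n",
    100 * x$f_g0g1, 100 * x$f_s, 100 * x$f_g2m, x$g2m_over_g0g1,
    x$n_gated, x$n_events))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged at the Ct level per (sample, gene,
#' experiment); dCt = Ct(target) - Ct(reference) per sample and experiment;
#' ddCt = dCt(mut) - dCt(wt); fold change = 2^-ddCt per experiment, then
#' mean +/- sd across experiments.
#'
#' @param ct Ct table: `sample` (wt/mut), `gene`, `experiment`, `replicate`,
#'   `ct` (as from [simulate_ct_table()]).
#' @param target_probe Target gene/probe name.
#' @param reference_gene Reference gene (default `"POLR2a"`).
#' @return Object of class `fold_change_report`: `per_experiment`
#'   (`experiment, dct_wt, dct_mut, ddct, fold`), `mean_fold`, `sd_fold`,
#'   `percent_change` (100 * (1 - mean_fold)).
#' @export
ddct_fold_change <- function(ct, target_probe, reference_gene = "POLR2a") {
  check(is.data.frame(ct) &&
          all(c("sample", "gene", "experiment", "replicate", "ct") %in% names(ct)),
        "`ct` must have columns sample, gene, experiment, replicate, ct")
  check(all(ct$ct > 0), "Ct values must be positive")
  check(target_probe %in% ct$gene,
        sprintf("target probe '%s' not in table", target_probe))
  agg <- stats::aggregate(ct ~ sample + gene + experiment, ct, mean)
  rows <- list()
  for (e in sort(unique(agg$experiment))) {
    g <- function(s, gene) {
      v <- agg$ct[agg$sample == s & agg$gene == gene & agg$experiment == e]
      check(length(v) == 1L,
            sprintf("missing %s rows for sample '%s' in experiment %s",
                    gene, s, e))
      v
    }
    dct_wt <- g("wt", target_probe) - g("wt", reference_gene)
    dct_mut <- g("mut", target_probe) - g("mut", reference_gene)
    ddct <- dct_mut - dct_wt
    rows[[length(rows) + 1L]] <- data.frame(
      experiment = e, dct_wt = dct_wt, dct_mut = dct_mut, ddct = ddct,
      fold = 2^(-ddct))
  }
  per <- do.call(rbind, rows)
  structure(list(target = target_probe, reference = reference_gene,
                 per_experiment = per,
                 mean_fold = mean(per$fold),
                 sd_fold = if (nrow(per) > 1L) stats::sd(per$fold) else NA_real_,
                 percent_change = 100 * (1 - mean(per$fold))),
            class = "fold_change_report")
}

#' @export
print.fold_change_report <- function(x, ...) {
  cat(sprintf("%s vs %s: fold change %.3f ± %.3f over %d experiment(s) (%.0f%% %s)\n",
              x$target, x$reference, x$mean_fold, x$sd_fold,
              nrow(x$per_experiment), abs(x$percent_change),
              if (x$percent_change >= 0) "decrease" else "increase"))
  invisible(x)
}

#' Mean intensity per labeled ROI
#'
#' @param image Numeric matrix.
#' @param label_mask Integer matrix of the same shape; 0 = background.
#' @param group Group label stamped on each row.
#' @param compartment Compartment label (`"nucleus"`, `"cytoplasm"` or
#'   `"whole_cell"`).
#' @return data.frame `roi, compartment, mean_intensity, area, group`
#'   (zero-area labels are absent).
#' @export
quantify_rois <- function(image, label_mask, group = "wt",
                          compartment = "nucleus") {
  check(is.matrix(image) && is.numeric(image), "`image` must be a numeric matrix")
  check(all(dim(image) == dim(label_mask)), "label mask shape must equal image")
  pos <- label_mask > 0
  if (!any(pos)) {
    warning("label mask is empty")
    return(data.frame(roi = integer(0), compartment = character(0),
                      mean_intensity = numeric(0), area = integer(0),
                      group = character(0)))
  }
  l <- as.integer(label_mask[pos])
  area <- tabulate(l)
  present <- which(area > 0L)
  sums <- rowsum(image[pos], l)          # one row per present label, sorted
  data.frame(roi = present, compartment = compartment,
             mean_intensity = sums[match(present, as.integer(rownames(sums))), 1] /
               area[present],
             area = area[present], group = group)
}

#' Nucleus / cytoplasm intensity ratio per cell
#'
#' @param roi_table A [quantify_rois()]-style table covering both
#'   compartments.
#' @param pairing data.frame `cell, nucleus_roi, cytoplasm_roi` mapping each
#'   cell to exactly one ROI of each compartment.
#' @return data.frame `cell, nucleus_mean, cytoplasm_mean, ratio`; cells
#'   with zero cytoplasm mean are flagged and excluded (with a warning).
#' @export
nc_ratio <- function(roi_table, pairing) {
  check(all(c("cell", "nucleus_roi", "cytoplasm_roi") %in% names(pairing)),
        "`pairing` needs columns cell, nucleus_roi, cytoplasm_roi")
  lookup <- function(roi, comp) {
    i <- which(roi_table$roi == roi & roi_table$compartment == comp)
    check(length(i) == 1L,
          sprintf("cell pairing: expected exactly one %s ROI %s", comp, roi))
    roi_table$mean_intensity[i]
  }
  nuc <- mapply(lookup, pairing$nucleus_roi, "nucleus")
  cyt <- mapply(lookup, pairing$cytoplasm_roi, "cytoplasm")
  bad <- cyt == 0
  if (any(bad))
    warning(sprintf("%d cell(s) with zero cytoplasm mean excluded", sum(bad)))
  data.frame(cell = pairing$cell[!bad], nucleus_mean = nuc[!bad],
             cytoplasm_mean = cyt[!bad], ratio = nuc[!bad] / cyt[!bad])
}

#' Percent decrease of group B relative to group A
#'
#' `100 * (1 - mean(B)/mean(A))`; the sd is that of the per-cell percent
#' values of group B relative to the group-A mean.
#'
#' @param group_a,group_b Per-cell mean intensities (non-empty; group A mean
#'   must be positive).
#' @return List `percent_decrease`, `sd`, `n_a`, `n_b`.
#' @export
percent_change <- function(group_a, group_b) {
  check(is.numeric(group_a) && length(group_a) >= 1L, "`group_a` is empty")
  check(is.numeric(group_b) && length(group_b) >= 1L, "`group_b` is empty")
  ma <- mean(group_a)
  check(ma > 0, "group A mean must be positive")
  per_cell <- 100 * (1 - group_b / ma)
  list(percent_decrease = 100 * (1 - mean(group_b) / ma),
       sd = if (length(group_b) > 1L) stats::sd(per_cell) else NA_real_,
       n_a = length(group_a), n_b = length(group_b))
}
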