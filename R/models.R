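#' Cell-cycle timing model for FUCCI simulations
#'
#' Describes one genotype's cell-cycle behaviour: G1 and S/G2/M durations are
#' independent lognormal random variables parameterised by their median (in
#' minutes) and log-scale standard deviation, plus the two reporter artefacts
#' every FUCCI analysis has to survive -- transient red/green co-expression
#' around the G1/S transition and a multi-frame dark window after mitosis in
#' which neither reporter is detectable.
#'
#' @param g1_median_min Median G1 duration in minutes (> 0).
#' @param g1_logsd Log-scale sd of the G1 lognormal (>= 0; 0 gives every cell
#'   exactly the median).
#' @param sg2m_median_min Median S/G2/M duration in minutes (> 0).
#' @param sg2m_logsd Log-scale sd of the S/G2/M lognormal (>= 0).
#' @param overlap_min Duration in minutes of red+green co-expression at the
#'   G1/S transition: the red reporter decays over this window after green
#'   onset. Must be shorter than `g1_median_min`.
#' @param dark_gap_frames Number of post-mitosis frames in which both
#'   reporters sit at background (non-negative integer).
#' @param genotype_label Free-text genotype tag carried into duration tables.
#' @return An object of class `cell_cycle_model`.
#' @seealso [npc_model()], [hesc_model()] for calibrated presets,
#'   [sample_lineages()] which consumes the model.
#' @export
cell_cycle_model <- function(g1_median_min, g1_logsd,
                             sg2m_median_min, sg2m_logsd,
                             overlap_min = 0, dark_gap_frames = 3L,
                             genotype_label = "wt") {
  check_scalar_pos(g1_median_min, "g1_median_min")
  check_scalar_pos(sg2m_median_min, "sg2m_median_min")
  check_scalar_nonneg(g1_logsd, "g1_logsd")
  check_scalar_nonneg(sg2m_logsd, "sg2m_logsd")
  check_scalar_nonneg(overlap_min, "overlap_min")
  check_count(dark_gap_frames, "dark_gap_frames")
  check(overlap_min < g1_median_min,
        "`overlap_min` must be smaller than `g1_median_min`")
  structure(
    list(g1_median_min = g1_median_min, g1_logsd = g1_logsd,
         sg2m_median_min = sg2m_median_min, sg2m_logsd = sg2m_logsd,
         overlap_min = overlap_min, dark_gap_frames = as.integer(dark_gap_frames),
         genotype_label = as.character(genotype_label)),
    class = "cell_cycle_model")
}

#' @export
print.cell_cycle_model <- function(x, ...) {
  cat(sprintf(
    "<cell_cycle_model '%s'> G1 ~ lognormal(median %g min, logsd %g); S/G2/M ~ lognormal(median %g min, logsd %g)\n  G1/S overlap %g min, post-mitosis dark gap %d frames\n",
    x$genotype_label, x$g1_median_min, x$g1_logsd,
    x$sg2m_median_min, x$sg2m_logsd, x$overlap_min, x$dark_gap_frames))
  invisible(x)
}

#' Log-scale sd of a lognormal from its median and sd
#'
#' For X ~ lognormal with median m and log-scale sd s,
#' sd(X) = m * sqrt(u(u-1)) with u = exp(s^2), so
#' s = sqrt(log((1 + sqrt(1 + 4 r^2)) / 2)) where r = sd/median.
#' Used to calibrate [cell_cycle_model()] duration distributions to a
#' reported median +/- sd pair.
#'
#' @param median_x,sd_x Median and standard deviation of the variable itself.
#' @return The log-scale sd.
#' @export
lognormal_logsd <- function(median_x, sd_x) {
  check_scalar_pos(median_x, "median_x")
  check_scalar_nonneg(sd_x, "sd_x")
  r2 <- (sd_x / median_x)^2
  sqrt(log((1 + sqrt(1 + 4 * r2)) / 2))
}

#' Calibrated neural-progenitor (NPC) cell-cycle models
#'
#' Presets matched to reported single-cell medians and sds for human
#' stem-cell-derived neural progenitors: wild-type G1 median 1408 min
#' (sd 982), CHD8 heterozygous-mutant G1 median 517 min (sd 410).
#' S/G2/M uses a 982-min median for both genotypes (no genotype effect on
#' S/G2/M). NPCs show a protracted G1/S transition, modelled as a 60-min
#' red/green overlap.
#'
#' @param genotype `"wt"` or `"mut"`.
#' @return A [cell_cycle_model()].
#' @export
npc_model <- function(genotype = c("wt", "mut")) {
  genotype <- match.arg(genotype)
  if (genotype == "wt") {
    cell_cycle_model(1408, lognormal_logsd(1408, 982), 982, 0.3,
                     overlap_min = 60, dark_gap_frames = 3L,
                     genotype_label = "CHD8+/+")
  } else {
    cell_cycle_model(517, lognormal_logsd(517, 410), 982, 0.3,
                     overlap_min = 60, dark_gap_frames = 3L,
                     genotype_label = "CHD8+/-")
  }
}

#' Calibrated human embryonic stem cell (hESC) cell-cycle models
#'
#' Wild-type G1 median 198 min (sd 78), mutant 153 min (sd 61); S/G2/M
#' median 900 min (hESCs spend >= 10 h there). hESCs lack a clear G1/S
#' transition, so the reporter overlap defaults to 0.
#'
#' @inheritParams npc_model
#' @return A [cell_cycle_model()].
#' @export
hesc_model <- function(genotype = c("wt", "mut")) {
  genotype <- match.arg(genotype)
  if (genotype == "wt") {
    cell_cycle_model(198, lognormal_logsd(198, 78), 900, 0.2,
                     overlap_min = 0, dark_gap_frames = 3L,
                     genotype_label = "CHD8+/+")
  } else {
    cell_cycle_model(153, lognormal_logsd(153, 61), 900, 0.2,
                     overlap_min = 0, dark_gap_frames = 3L,
                     genotype_label = "CHD8+/-")
  }
}

#' Imaging configuration for the synthetic microscope
#'
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_min Acquisition interval in minutes (> 0). Default
#'   15 min, fine enough to resolve a ~150-min G1.
#' @param height,width Field size in pixels.
#' @param nucleus_radius_px Mean nucleus semi-major axis in pixels.
#' @param psf_sigma_px Gaussian blur sigma applied to nucleus edges.
#' @param background_level Camera background offset (intensity units).
#' @param photon_gain Photons per intensity unit for Poisson shot noise.
#' @param read_noise_sd Gaussian read noise sd (intensity units).
#' @param bit_depth 8 or 16.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(n_frames, frame_interval_min = 15,
                           height = 256L, width = 256L,
                           nucleus_radius_px = 6, psf_sigma_px = 1,
                           background_level = 100, photon_gain = 1,
                           read_noise_sd = 3, bit_depth = 16L) {
  check_count(n_frames, "n_frames", min = 2L)
  check_scalar_pos(frame_interval_min, "frame_interval_min")
  check_count(height, "height", min = 8L)
  check_count(width, "width", min = 8L)
  check_scalar_pos(nucleus_radius_px, "nucleus_radius_px")
  check_scalar_nonneg(psf_sigma_px, "psf_sigma_px")
  check_scalar_nonneg(background_level, "background_level")
  check_scalar_pos(photon_gain, "photon_gain")
  check_scalar_nonneg(read_noise_sd, "read_noise_sd")
  check(bit_depth %in% c(8L, 16L), "`bit_depth` must be 8 or 16")
  structure(
    list(n_frames = as.integer(n_frames),
         frame_interval_min = frame_interval_min,
         height = as.integer(height), width = as.integer(width),
         nucleus_radius_px = nucleus_radius_px, psf_sigma_px = psf_sigma_px,
         background_level = background_level, photon_gain = photon_gain,
         read_noise_sd = read_noise_sd, bit_depth = as.integer(bit_depth)),
    class = "imaging_config")
}

#' Reporter rendering kinetics
#'
#' Linear-ramp intensity kinetics for the two FUCCI reporters. Red
#' (mKO2-Cdt1) ramps up from the end of the post-mitosis dark gap over
#' `red_ramp_min`, holds until green onset (the G1/S transition), then decays
#' linearly to background over the model's `overlap_min` (degron-mediated
#' decay after S entry -- this is what produces the transient co-expression).
#' Green (mAG-Geminin) ramps up from G1 end over `green_ramp_min`, holds
#' until division, then drops to background for the dark gap.
#'
#' @param red_amp,green_amp Peak reporter intensity above background.
#' @param red_ramp_min,green_ramp_min Ramp times to peak, minutes.
#' @param motion_step_px Per-frame sd of the persistent random walk.
#' @param motion_persistence AR(1) coefficient of the walk velocity in (0,1).
#' @param bend Curvature of the nucleus ("boomerang" shape), 0 = ellipse.
#' @return An object of class `reporter_params`.
#' @export
reporter_params <- function(red_amp = 1500, green_amp = 1500,
                            red_ramp_min = 120, green_ramp_min = 60,
                            motion_step_px = 1.2, motion_persistence = 0.7,
                            bend = 0) {
  check_scalar_pos(red_amp, "red_amp")
  check_scalar_pos(green_amp, "green_amp")
  check_scalar_pos(red_ramp_min, "red_ramp_min")
  check_scalar_pos(green_ramp_min, "green_ramp_min")
  check_scalar_nonneg(motion_step_px, "motion_step_px")
  check(motion_persistence >= 0 && motion_persistence < 1,
        "`motion_persistence` must be in [0, 1)")
  check_scalar_nonneg(bend, "bend")
  structure(list(red_amp = red_amp, green_amp = green_amp,
                 red_ramp_min = red_ramp_min, green_ramp_min = green_ramp_min,
                 motion_step_px = motion_step_px,
                 motion_persistence = motion_persistence, bend = bend),
            class = "reporter_params")
}
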