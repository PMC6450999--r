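#' Marker profile for the synthetic generator
#'
#' @param name marker role (e.g. "th", "foxa2", "sox2", "cc3").
#' @param positive_fraction expected fraction of viable cells positive for
#'   the marker, in \[0,1\].
#' @param localization "nuclear" (signal drawn on the nucleus pixel set) or
#'   "cytoplasmic+neurite" (soma disk plus a branched neurite tree).
#' @param intensity peak signal intensity on the \[0,1\] scale.
#' @return a `marker_profile` list.
#' @export
marker_profile <- function(name, positive_fraction,
                           localization = c("nuclear", "cytoplasmic+neurite"),
                           intensity = 0.6) {
  localization <- match.arg(localization)
  stopifnot(is.character(name), length(name) == 1L,
            positive_fraction >= 0, positive_fraction <= 1,
            intensity > 0)
  structure(list(name = tolower(name),
                 positive_fraction = positive_fraction,
                 localization = localization,
                 intensity = intensity),
            class = "marker_profile")
}

#' Parameters of the synthetic organoid-section generator
#'
#' Defaults emulate one imaged field of a 50-um organoid section: ~200
#' densely packed nuclei, a small condensed (pyknotic) population drawn
#' smaller and brighter, a dopaminergic (TH+) majority carrying branched
#' neurites, and a nuclear floor-plate marker (FOXA2). Identical parameter
#' sets (including `seed`) produce bit-identical images and ground truth.
#'
#' @param image_shape pixels per axis, `c(y, x)` for a single plane or
#'   `c(z, y, x)` for a thin stack.
#' @param n_cells number of cells to place.
#' @param nucleus_radius_range min/max nucleus semi-major axis in pixels.
#' @param nucleus_intensity_range per-cell Hoechst base intensity range.
#' @param pyknotic_fraction fraction of cells drawn as pyknotic.
#' @param pyknotic_intensity_gain multiplicative intensity gain (> 1) of
#'   pyknotic over normal nuclei; the generator guarantees the two
#'   populations are separable by a single intensity threshold.
#' @param marker_profiles list of [marker_profile()] objects; one image
#'   channel is emitted per profile, plus Hoechst.
#' @param neurite_params list with `mean_primary` (mean primary neurites
#'   per TH+ cell, Poisson), `branch_length_range` (pixels),
#'   `bifurcation_prob` (probability a segment bifurcates at its tip),
#'   `max_depth` (maximum bifurcation generations) and `width` (drawn
#'   neurite thickness in pixels, 1-3).
#' @param spatial_noise looseness of the spatial clustering of
#'   cytoplasmic+neurite marker positivity (fraction of the image size used
#'   as SD of the noise on the radial niche score; `Inf` disables
#'   clustering and draws positives uniformly).
#' @param section_jitter_sd SD of the per-section Gaussian jitter applied to
#'   every marker's positive fraction (organoid-to-organoid variability).
#' @param noise_sigma SD of additive Gaussian read-out noise.
#' @param psf_sigma Gaussian blur (pixels) applied to all channels,
#'   emulating the optical point-spread function.
#' @param cell_gap minimum gap (pixels) between nucleus bounding circles.
#' @param seed integer seed; part of the parameter set.
#' @return a validated `synth_params` list.
#' @export
synth_params <- function(image_shape = c(512, 512),
                         n_cells = 200,
                         nucleus_radius_range = c(8, 12),
                         nucleus_intensity_range = c(0.40, 0.50),
                         pyknotic_fraction = 0.05,
                         pyknotic_intensity_gain = 2.0,
                         marker_profiles = list(
                           marker_profile("th", 0.55, "cytoplasmic+neurite"),
                           marker_profile("foxa2", 0.75, "nuclear")
                         ),
                         neurite_params = list(mean_primary = 1.2,
                                               branch_length_range = c(8, 14),
                                               bifurcation_prob = 0.4,
                                               max_depth = 2,
                                               width = 3),
                         spatial_noise = 0.04,
                         section_jitter_sd = 0.03,
                         noise_sigma = 0.03,
                         psf_sigma = 1,
                         cell_gap = 8,
                         seed = 1L) {
  p <- list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
            nucleus_radius_range = nucleus_radius_range,
            nucleus_intensity_range = nucleus_intensity_range,
            pyknotic_fraction = pyknotic_fraction,
            pyknotic_intensity_gain = pyknotic_intensity_gain,
            marker_profiles = marker_profiles,
            neurite_params = neurite_params,
            spatial_noise = spatial_noise,
            section_jitter_sd = section_jitter_sd,
            noise_sigma = noise_sigma, psf_sigma = psf_sigma,
            cell_gap = cell_gap, seed = as.integer(seed))
  class(p) <- "synth_params"
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  stopifnot(length(p$image_shape) %in% c(2L, 3L), all(p$image_shape >= 8L),
            p$n_cells >= 0L,
            length(p$nucleus_radius_range) == 2L,
            p$nucleus_radius_range[1] > 0,
            diff(p$nucleus_radius_range) >= 0,
            p$pyknotic_fraction >= 0, p$pyknotic_fraction <= 1,
            p$pyknotic_intensity_gain > 1,
            p$noise_sigma >= 0, p$psf_sigma >= 0,
            p$neurite_params$mean_primary >= 0,
            p$neurite_params$bifurcation_prob >= 0,
            p$neurite_params$bifurcation_prob <= 1,
            p$neurite_params$width >= 1, p$neurite_params$width <= 3)
  for (mp in p$marker_profiles) {
    stopifnot(mp$positive_fraction >= 0, mp$positive_fraction <= 1)
  }
  invisible(p)
}

#' Segmentation parameters
#'
#' Houses every threshold and filter size of the mask-building stage. The
#' strict size cutoffs follow the source conventions: marker components with
#' strictly fewer than `min_component_size` pixels are removed, and nuclei
#' with strictly more than `max_nucleus_size` pixels are excluded.
#'
#' @param gaussian_sigma Gaussian smoothing (pixels) of the Hoechst channel.
#' @param median_radius marker-channel median filter half-width (window
#'   `2*radius+1`, default 3x3; 0 disables the filter).
#' @param thresholds named list of per-channel threshold specs, each
#'   `list(method = "otsu")`, `list(method = "fixed", value =)` or
#'   `list(method = "quantile", q =)`; entry `default` applies to channels
#'   without their own entry.
#' @param pyknotic_threshold threshold spec for the pyknotic (condensed,
#'   hyper-intense) nuclei on the smoothed Hoechst channel; `quantile`
#'   is computed over in-mask pixels.
#' @param pyknotic_dilate dilation radius (pixels) applied to the pyknotic
#'   mask before it is subtracted from the nuclei mask, so that a condensed
#'   nucleus is removed without leaving a ring remnant.
#' @param min_component_size marker mask small-component cutoff (strict <).
#' @param max_nucleus_size single-nucleus size exclusion (strict >).
#' @param min_nucleus_size labels below this size are dropped as segmentation
#'   debris (quality-control step; strict <).
#' @param watershed_h h-maxima suppression depth for the distance-transform
#'   watershed seeds.
#' @param connectivity 4 or 8 (2D); used for components and skeleton
#'   adjacency.
#' @param th_small_removal apply the small-component removal also to the TH
#'   mask (off by default; the cutoff is defined for the nuclear markers).
#' @return a `seg_params` list.
#' @export
seg_params <- function(gaussian_sigma = 2,
                       median_radius = 1,
                       thresholds = list(default = list(method = "otsu")),
                       pyknotic_threshold = list(method = "fixed", value = 0.6),
                       pyknotic_dilate = 2,
                       min_component_size = 100,
                       max_nucleus_size = 10000,
                       min_nucleus_size = 30,
                       watershed_h = 2,
                       connectivity = 8,
                       th_small_removal = FALSE) {
  stopifnot(gaussian_sigma >= 0, median_radius >= 0,
            max_nucleus_size > min_component_size,
            connectivity %in% c(4, 8))
  p <- list(gaussian_sigma = gaussian_sigma, median_radius = median_radius,
            thresholds = thresholds, pyknotic_threshold = pyknotic_threshold,
            pyknotic_dilate = pyknotic_dilate,
            min_component_size = min_component_size,
            max_nucleus_size = max_nucleus_size,
            min_nucleus_size = min_nucleus_size,
            watershed_h = watershed_h, connectivity = connectivity,
            th_small_removal = th_small_removal)
  class(p) <- "seg_params"
  p
}

#' Pipeline configuration
#'
#' Bundles the per-stage parameter sets; fully determines (together with the
#' input images) every numeric output of [run_pipeline()].
#'
#' @param seg [seg_params()].
#' @param skeleton list with `prune` (spur length cutoff, pixels).
#' @param scoring list with `ring_width` (perinuclear ring, pixels),
#'   `min_fraction` (positivity rule, fraction of zone area),
#'   `nuclear_markers` (markers called on the nucleus pixel set instead of
#'   the perinuclear ring) and `min_cells` (sections with fewer retained
#'   nuclei are flagged low-quality and excluded from per-cell fractions).
#' @param stats list with `features` (feature columns to test; default the
#'   three headline phenotypes), `factors` (model factors) and
#'   `double_positive_mode` ("pixel" or "cell": whether the TH/FOXA2
#'   double-positive readout is a pixel-overlap fraction or a
#'   double-positive cell fraction).
#' @param mode "mip" (analyze the maximum-intensity projection of a stack,
#'   default) or "plane" (analyze each z-plane and average).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seg = seg_params(),
                            skeleton = list(prune = 3),
                            scoring = list(ring_width = 3, min_fraction = 0.01,
                                           nuclear_markers = c("foxa2", "sox2"),
                                           min_cells = 10),
                            stats = list(
                              features = c("th_foxa2_px_fraction", "n_nodes",
                                           "foxa2_not_th_px_fraction"),
                              factors = c("group", "day"),
                              double_positive_mode = "pixel"),
                            mode = c("mip", "plane")) {
  mode <- match.arg(mode)
  cfg <- list(seg = seg, skeleton = skeleton, scoring = scoring,
              stats = stats, mode = mode)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()] and [seg_params()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @examples
#' cfg <- read_config(system.file("extdata", "default_config.yaml",
#'                                package = "organoidHCA"))
#' cfg$seg$max_nucleus_size
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seg", "skeleton", "scoring", "stats", "mode")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- pipeline_config()
  seg <- do.call(seg_params, merge_params(unclass_args(cfg$seg), raw$seg))
  pipeline_config(seg = seg,
                  skeleton = merge_params(cfg$skeleton, raw$skeleton),
                  scoring = merge_params(cfg$scoring, raw$scoring),
                  stats = merge_params(cfg$stats, raw$stats),
                  mode = raw$mode %||% cfg$mode)
}

#' Write a pipeline configuration to YAML
#' @param cfg `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- list(seg = unclass_args(cfg$seg), skeleton = cfg$skeleton,
              scoring = cfg$scoring, stats = cfg$stats, mode = cfg$mode)
  yaml::write_yaml(out, path)
  invisible(path)
}

unclass_args <- function(x) {
  x <- unclass(x)
  x
}
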