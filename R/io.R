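#' Read a multichannel TIFF as an image stack
#'
#' Pages are interpreted as channels (optionally with `n_z` planes per
#' channel, channel-major); the declared channel roles must match the page
#' count exactly.
#'
#' @param path TIFF file.
#' @param channel_roles character vector of channel roles in page order
#'   (must include "hoechst").
#' @param n_z z-planes per channel (default 1).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel_roles, n_z = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  expected <- length(channel_roles) * n_z
  if (length(pages) != expected)
    stop("channel mismatch: ", length(pages), " pages but ",
         length(channel_roles), " declared channels x ", n_z, " planes")
  channels <- list()
  for (i in seq_along(channel_roles)) {
    idx <- ((i - 1L) * n_z + 1L):(i * n_z)
    channels[[channel_roles[i]]] <-
      if (n_z == 1L) pages[[idx]] else simplify2array(pages[idx])
  }
  image_stack(channels)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Pages are channel-major (all z-planes of channel 1, then channel 2,
#' ...); intensities are clipped to \[0,1\]. Images produced by
#' [generate_section()] are already on the 16-bit grid, so a write/read
#' round trip reproduces them exactly.
#'
#' @param img [image_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(img, path) {
  pages <- list()
  for (ch in img$channels) {
    if (length(dim(ch)) == 3L)
      for (z in seq_len(dim(ch)[3])) pages[[length(pages) + 1L]] <- ch[, , z]
    else pages[[length(pages) + 1L]] <- ch
  }
  pages <- lapply(pages, function(p) pmin(pmax(p, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask or a label image as TIFF
#'
#' Masks are stored as 8-bit 0/255 images; label matrices as 16-bit
#' grayscale (label id / 65535, exact for up to 65,535 labels).
#'
#' @param mask logical/binary matrix, or a `marker_mask` /
#'   `skeleton_graph` (its mask/skeleton is written).
#' @param labels integer label matrix (0 = background).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "marker_mask")) mask <- mask$mask
  if (inherits(mask, "skeleton_graph")) mask <- mask$skeleton
  tiff::writeTIFF((mask != 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
write_labels <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) <= 65535)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Run the full phenotyping pipeline over a cohort
#'
#' For every manifest row: read (or take in-memory) the image, extract the
#' feature row ([image_features()]); then assemble the per-section feature
#' table, test the configured features by two-way ANOVA with Tukey
#' comparisons, and build the phenotype report. Per-image failures are
#' logged and skipped; the run aborts only if more than half of the images
#' fail. Outputs are a pure function of the inputs and configuration.
#'
#' @param manifest data.frame (path, line, group, day, section_id).
#' @param config [pipeline_config()].
#' @param images optional named list of in-memory [image_stack()]s keyed by
#'   section_id (e.g. from [generate_cohort()]); rows without an in-memory
#'   image are read from `path`.
#' @param channel_roles page-order channel roles for images read from disk.
#' @param outdir optional output directory: feature table and run log as
#'   CSV, ANOVA tables as CSV + JSON, the configuration as YAML.
#' @return list: `features` (feature_table), `anova` (named list of
#'   `anova_result`), `report` (`phenotype_report`), `runlog` (data.frame).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         images = NULL, channel_roles = NULL,
                         outdir = NULL) {
  stopifnot(nrow(manifest) > 0)
  per_image <- list(); logrows <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$section_id[i]
    res <- tryCatch({
      img <- if (!is.null(images) && sid %in% names(images)) images[[sid]]
      else {
        if (is.null(channel_roles))
          stop("channel_roles required to read images from disk")
        read_stack(manifest$path[i], channel_roles)
      }
      image_features(img, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      logrows[[i]] <- data.frame(section_id = sid, status = "excluded",
                                 reason = conditionMessage(res),
                                 n_cells = NA_integer_,
                                 low_quality = NA)
    } else {
      per_image[[sid]] <- res
      logrows[[i]] <- data.frame(section_id = sid, status = "ok",
                                 reason = "",
                                 n_cells = res$features$n_cells,
                                 low_quality = res$log$low_quality)
    }
  }
  runlog <- do.call(rbind, logrows)
  n_fail <- sum(runlog$status == "excluded")
  if (n_fail > nrow(manifest) / 2)
    stop("pipeline aborted: ", n_fail, "/", nrow(manifest),
         " images failed; first error: ",
         runlog$reason[runlog$status == "excluded"][1])
  ft <- assemble_features(manifest, per_image)

  results <- list()
  factors <- config$stats$factors
  can_test <- length(unique(ft[[factors[1]]])) >= 2 &&
    length(unique(ft[[factors[2]]])) >= 2
  if (can_test) {
    for (f in intersect(config$stats$features, names(ft)))
      results[[f]] <- tryCatch(two_way_anova(ft, f, factors),
        error = function(e) structure(
          list(feature = f, table = NULL, tukey = NULL, model = NULL,
               flagged = TRUE, reason = conditionMessage(e)),
          class = "anova_result"))
  }
  report <- phenotype_report(ft, results)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(ft, file.path(outdir, "features.csv"), row.names = FALSE)
    write.csv(runlog, file.path(outdir, "runlog.csv"), row.names = FALSE)
    write_config(config, file.path(outdir, "config.yaml"))
    if (length(results)) {
      at <- do.call(rbind, lapply(names(results), function(f)
        if (!results[[f]]$flagged)
          cbind(feature = f, results[[f]]$table)))
      tk <- do.call(rbind, lapply(names(results), function(f)
        if (!results[[f]]$flagged)
          cbind(feature = f, results[[f]]$tukey)))
      write.csv(at, file.path(outdir, "anova.csv"), row.names = FALSE)
      write.csv(tk, file.path(outdir, "tukey.csv"), row.names = FALSE)
      jsonlite::write_json(
        lapply(results, function(r)
          if (r$flagged) list(flagged = TRUE)
          else list(anova = r$table, tukey = r$tukey)),
        file.path(outdir, "anova.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  list(features = ft, anova = results, report = report, runlog = runlog)
}
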