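#' Pipeline configuration
#'
#' Bundles every parameter of the end-to-end analysis: input (a stack on
#' disk or a phantom simulated in place), channel roles, segmentation
#' and detection settings, the co-localization radius, the distance
#' histogram bin width, and the seed. Every random operation downstream
#' receives its seed from here, so a pipeline run is a pure function of
#' its configuration.
#'
#' @param out_dir output directory
#' @param input path of a stack written by \code{\link{write_image_stack}},
#'   or NULL to simulate the phantom in \code{phantom}
#' @param phantom \code{\link{phantom_config}} used when input is NULL
#' @param channel_roles names of the granule/rna/protein channels
#' @param segmentation_method \code{"otsu"} or \code{"fixed"}
#' @param segmentation_threshold fixed threshold (when method "fixed")
#' @param detect_threshold optional named list of manual detection
#'   thresholds per channel role (used when the plateau heuristic is
#'   inapplicable)
#' @param psf_sigma_nm PSF sigma for detection, nm (z, y, x)
#' @param max_dist_nm co-localization radius
#' @param bin_width_nm distance histogram bin width
#' @param seed integer master seed
#' @return list of class \code{PipelineConfig}
#' @export
pipeline_config <- function(out_dir,
                            input = NULL,
                            phantom = phantom_config(),
                            channel_roles = c(granule = "granule",
                                              rna = "rna",
                                              protein = "protein"),
                            segmentation_method = "otsu",
                            segmentation_threshold = NULL,
                            detect_threshold = list(),
                            psf_sigma_nm = c(300, 100, 100),
                            max_dist_nm = 400,
                            bin_width_nm = 25,
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, input = input, phantom = phantom,
              channel_roles = channel_roles,
              segmentation_method = segmentation_method,
              segmentation_threshold = segmentation_threshold,
              detect_threshold = detect_threshold,
              psf_sigma_nm = as.numeric(psf_sigma_nm),
              max_dist_nm = max_dist_nm,
              bin_width_nm = bin_width_nm,
              seed = as.integer(seed))
  stopifnot(cfg$max_dist_nm > 0, cfg$bin_width_nm > 0,
            all(cfg$psf_sigma_nm > 0))
  class(cfg) <- "PipelineConfig"
  cfg
}

detect_channel <- function(arr, spacing, psf_sigma_nm, role,
                           manual_threshold = NULL) {
  sigma_vox <- psf_sigma_nm / spacing
  thr <- if (!is.null(manual_threshold)) {
    manual_threshold
  } else {
    select_threshold(predetect(arr, psf_sigma_vox = sigma_vox))
  }
  sp <- fit_spots(arr, thr, spacing, channel = role,
                  psf_sigma_vox = sigma_vox)
  sp[sp$fit_ok, , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> segment granules -> detect and fit foci ->
#' signed distances with border exclusions -> histogram + KDE ->
#' translation calls and fractions -> write result tables and a
#' provenance record. All outputs are plain CSV/JSON under
#' \code{config$out_dir}; reruns with the same configuration are
#' byte-identical (the provenance record carries a configuration hash
#' and the seed, not a timestamp).
#'
#' @param config \code{\link{pipeline_config}}
#' @return invisible list with the in-memory results (stack, truth,
#'   labelmap, spots, records, histogram, calls, summary)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  if (is.null(config$input)) {
    sim <- step("simulate", generate_phantom(config$phantom))
    stack <- sim$stack
    truth <- sim$truth
    write_ground_truth(truth, file.path(config$out_dir, "ground_truth"))
  } else {
    stack <- step("load", read_image_stack(config$input))
  }
  spacing <- stack$spacing
  roles <- config$channel_roles

  mask <- step("segment", segment_granules(
    get_channel(stack, roles[["granule"]]),
    method = config$segmentation_method,
    threshold = config$segmentation_threshold))
  labelmap <- step("segment", label_and_classify(mask))
  utils::write.csv(granule_summary(labelmap, spacing),
                   file.path(config$out_dir, "granules.csv"),
                   row.names = FALSE)

  rna_spots <- step("detect", detect_channel(
    get_channel(stack, roles[["rna"]]), spacing, config$psf_sigma_nm,
    "rna", config$detect_threshold[["rna"]]))
  protein_spots <- step("detect", detect_channel(
    get_channel(stack, roles[["protein"]]), spacing, config$psf_sigma_nm,
    "protein", config$detect_threshold[["protein"]]))
  utils::write.csv(rna_spots, file.path(config$out_dir, "spots_rna.csv"),
                   row.names = FALSE)
  utils::write.csv(protein_spots,
                   file.path(config$out_dir, "spots_protein.csv"),
                   row.names = FALSE)

  records <- step("map-distances", apply_exclusions(
    signed_distances(rna_spots, labelmap, spacing), labelmap))
  write_distance_records(records,
                         file.path(config$out_dir, "distances.csv"))
  histogram <- step("map-distances",
                    histogram_with_kde(records, config$bin_width_nm))
  write_distance_histogram(histogram,
                           file.path(config$out_dir, "histogram.json"))

  calls <- step("call-translation",
                match_spots(rna_spots, protein_spots,
                            max_dist = config$max_dist_nm))
  utils::write.csv(calls, file.path(config$out_dir, "calls.csv"),
                   row.names = FALSE)
  frac <- step("call-translation", translating_fraction(calls))

  summary <- list(
    n_granules = nrow(labelmap$granules),
    n_border_granules = sum(labelmap$granules$touches_border),
    n_rna_spots = nrow(rna_spots),
    n_protein_spots = nrow(protein_spots),
    n_distance_excluded = sum(records$excluded),
    translating_fraction = frac$fraction,
    n_translating = frac$n_translating)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  provenance <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package = "suntagr",
    package_version = as.character(utils::packageVersion("suntagr")))
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(stack = stack, truth = truth, labelmap = labelmap,
                 rna_spots = rna_spots, protein_spots = protein_spots,
                 records = records, histogram = histogram, calls = calls,
                 summary = summary))
}

# strip classes/functions so the config serializes cleanly to YAML
serialize_config <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file with the fields of \code{\link{pipeline_config}}
#' (phantom parameters under a \code{phantom} key, placement law as
#' \code{list(type = ..., ...)}).
#' @param path YAML path
#' @return \code{PipelineConfig}
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- if (!is.null(y$phantom)) do.call(phantom_config, c(
    y$phantom[setdiff(names(y$phantom), "placement_law")],
    if (!is.null(y$phantom$placement_law))
      list(placement_law = y$phantom$placement_law)))
  else phantom_config()
  args <- y[setdiff(names(y), "phantom")]
  do.call(pipeline_config, c(args, list(phantom = ph)))
}
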