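#' Default pipeline configuration
#'
#' The fully-resolved set of parameters consumed by [run_pipeline()]:
#' per-stage profiles for preprocessing, initial segmentation of the
#' cytoplasm and nuclei channels, classification and post-processing.
#'
#' @param bit_depth declared bit depth of the input images, default 12.
#' @param nuclei_profile which built-in nuclei [segmentation_profile()] to
#'   use, \code{"nuclei-large"} (default) or \code{"nuclei-small"}.
#' @return Nested named list of class \code{pipeline_config}.
#' @export
default_pipeline_config <- function(bit_depth = 12L,
                                    nuclei_profile = "nuclei-large") {
  structure(list(
    bit_depth = as.integer(bit_depth),
    preprocess = list(tiles = 8L, clip_fraction = 0.01, radius = 5,
                      tail_fraction = 0.01),
    scalespace = list(
      cytoplasm = list(scales = 0:6, min_object_area = 600,
                       epsilon = 1, variant = "std"),
      nuclei = {
        p <- segmentation_profile(nuclei_profile)
        list(scales = p$scales, min_object_area = p$min_object_area,
             epsilon = 1, variant = "std")
      }),
    classifier = list(threshold = 0.5),
    postprocess = list(bridge_radius = 2, close_radius = 3,
                       merge_iterations = 3L, max_hole_area = 50),
    evaluate = list(fm_threshold = 0.6),
    seed = 1L
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip losslessly; unknown top-level or stage keys are
#' rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return \code{read_pipeline_config}: a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- unclass(default_pipeline_config())
  check_keys <- function(x, template, where) {
    extra <- setdiff(names(x), names(template))
    if (length(extra))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
  }
  check_keys(raw, ref, "config")
  for (stage in intersect(names(raw), names(ref))) {
    if (is.list(ref[[stage]]) && !is.null(raw[[stage]])) {
      check_keys(raw[[stage]], ref[[stage]], stage)
      for (k in names(raw[[stage]])) ref[[stage]][[k]] <- raw[[stage]][[k]]
    } else if (!is.null(raw[[stage]])) ref[[stage]] <- raw[[stage]]
  }
  # nested scale-space profiles
  if (!is.null(raw$scalespace)) {
    for (ch in intersect(names(raw$scalespace), c("cytoplasm", "nuclei"))) {
      tmpl <- unclass(default_pipeline_config())$scalespace[[ch]]
      check_keys(raw$scalespace[[ch]], tmpl, paste0("scalespace$", ch))
    }
  }
  structure(ref, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param cfg a \code{pipeline_config}.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full segmentation pipeline on one field
#'
#' Chains every stage: preprocessing of both channels, initial
#' cytoplasm/background segmentation, nuclei segmentation (the same
#' multi-scale initial segmentation applied to the DNA channel with the
#' nuclei profile, unless precomputed nuclei labels are supplied), outline
#' classification with the given model, nuclei-contextual post-processing,
#' and (optionally) evaluation against a benchmark.
#'
#' @param cyto cytoplasm channel: a [gray_image], matrix, or file path.
#' @param nuclei DNA channel, same forms as \code{cyto}.
#' @param model an [outline_model] or path to a model JSON.
#' @param cfg a [default_pipeline_config()].
#' @param nuclei_labels optional precomputed nuclei label matrix; when given
#'   the DNA channel is not segmented.
#' @param bench_cells optional benchmark cell labels; when given the result
#'   includes an \code{evaluation} report.
#' @param verbose print per-stage progress with object counts.
#' @return List of class \code{pipeline_result}: \code{cells} (label
#'   matrix), \code{nuclei_labels}, \code{initial}, \code{outlines},
#'   \code{model}, \code{config}, and optionally \code{evaluation}.
#' @export
run_pipeline <- function(cyto, nuclei, model, cfg = default_pipeline_config(),
                         nuclei_labels = NULL, bench_cells = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  load_channel <- function(x) {
    if (is.character(x)) read_image(x, bit_depth = cfg$bit_depth)
    else as_gray_image(x, cfg$bit_depth)
  }
  cyto <- load_channel(cyto)
  if (is.character(model)) model <- read_outline_model(model)

  pp <- cfg$preprocess
  cyto_pp <- preprocess_cascade(cyto, tiles = pp$tiles,
                                clip_fraction = pp$clip_fraction,
                                radius = pp$radius,
                                tail_fraction = pp$tail_fraction)
  say("preprocess: done")

  sc <- cfg$scalespace$cytoplasm
  initial <- initial_segmentation(
    cyto_pp, segmentation_profile("custom", scales = sc$scales,
                                  min_object_area = sc$min_object_area),
    epsilon = sc$epsilon, variant = sc$variant)
  say("initial segmentation: %d foreground pixels", sum(initial))

  if (is.null(nuclei_labels)) {
    nuc <- load_channel(nuclei)
    nuc_pp <- preprocess_cascade(nuc, tiles = pp$tiles,
                                 clip_fraction = pp$clip_fraction,
                                 radius = pp$radius,
                                 tail_fraction = pp$tail_fraction)
    sn <- cfg$scalespace$nuclei
    nuc_mask <- initial_segmentation(
      nuc_pp, segmentation_profile("custom", scales = sn$scales,
                                   min_object_area = sn$min_object_area),
      epsilon = sn$epsilon, variant = sn$variant)
    nuclei_labels <- label_components(nuc_mask)
  }
  say("nuclei: %d objects", max(nuclei_labels))

  outlines <- classify_outlines(model, cyto_pp)
  say("outline classification: %d outline pixels", sum(outlines))

  pcfg <- postprocess_config(bridge_radius = cfg$postprocess$bridge_radius,
                             close_radius = cfg$postprocess$close_radius,
                             merge_iterations = cfg$postprocess$merge_iterations,
                             max_hole_area = cfg$postprocess$max_hole_area)
  cells <- postprocess_cells(initial, outlines, nuclei_labels, pcfg)
  say("post-processing: %d cells", max(cells))

  out <- list(cells = cells, nuclei_labels = nuclei_labels,
              initial = initial, outlines = outlines, model = model,
              config = cfg)
  if (!is.null(bench_cells)) {
    out$evaluation <- evaluate_run(cells, bench_cells,
                                   fm_threshold = cfg$evaluate$fm_threshold)
    say("evaluation: object FM %.3f", out$evaluation$cells$fmeasure)
  }
  structure(out, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cells, %d nuclei\n",
              max(x$cells), max(x$nuclei_labels)))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
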