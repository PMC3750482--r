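#' Precision, recall and F-measure from count triples
#'
#' \eqn{PR = TP/(TP+FP)}, \eqn{RC = TP/(TP+FN)} and their harmonic mean
#' \eqn{FM = 2 / (1/PR + 1/RC)}. Degenerate 0/0 ratios are 0 by convention,
#' and FM is 0 when either PR or RC is 0. Values are returned at full
#' precision; round to 2 decimals only for display.
#'
#' @param tp,fp,fn non-negative counts.
#' @return Named numeric vector \code{c(precision, recall, fmeasure)}.
#' @examples
#' round(fmeasure(424, 23, 42), 2)  # 0.95 0.91 0.93
#' @export
fmeasure <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  fm <- if (pr > 0 && rc > 0) 2 / (1 / pr + 1 / rc) else 0
  c(precision = pr, recall = rc, fmeasure = fm)
}

#' Greedy maximum-overlap object matching
#'
#' The object-level evaluation protocol: each benchmark object (visited in
#' descending area order, ties by label id) is matched to the segmented
#' object of maximum pixel overlap; the pair's pixel-level F-measure is
#' computed on the two objects alone, and when it reaches
#' \code{fm_threshold} the match counts as a true positive and the segmented
#' object is removed from further consideration — otherwise the benchmark
#' object is a false negative. Segmented objects left unmatched at the end
#' are false positives, so only one-to-one (TP), one-to-none (FN) and
#' none-to-one (FP) correspondences result.
#'
#' @param segmented,benchmark integer label matrices (0 = background).
#' @param fm_threshold per-object F-measure acceptance threshold, default
#'   0.6.
#' @return An object of class \code{match_report}: list with \code{tp},
#'   \code{fp}, \code{fn}, \code{precision}, \code{recall}, \code{fmeasure},
#'   \code{per_object_fm} (FM of each matched pair), \code{detection_error}
#'   (FP + FN), \code{level = "object"}.
#' @export
match_objects <- function(segmented, benchmark, fm_threshold = 0.6) {
  stopifnot(all(dim(segmented) == dim(benchmark)))
  bench_ids <- setdiff(unique(as.vector(benchmark)), 0L)
  seg_ids <- setdiff(unique(as.vector(segmented)), 0L)
  if (!length(bench_ids)) {
    counts <- c(tp = 0L, fp = length(seg_ids), fn = 0L)
    return(make_match_report(counts, numeric(0)))
  }
  bench_area <- vapply(bench_ids, function(id) sum(benchmark == id), 0L)
  order_ids <- bench_ids[order(-bench_area, bench_ids)]
  # overlap table between label pairs (background excluded)
  fg <- segmented > 0L & benchmark > 0L
  ov <- table(factor(benchmark[fg], levels = bench_ids),
              factor(segmented[fg], levels = seg_ids))
  seg_area <- vapply(seg_ids, function(id) sum(segmented == id), 0L)
  names(seg_area) <- seg_ids
  available <- stats::setNames(rep(TRUE, length(seg_ids)), seg_ids)
  tp <- 0L; fn <- 0L
  per_fm <- numeric(0)
  for (bid in order_ids) {
    if (!length(seg_ids)) { fn <- fn + 1L; next }
    row <- stats::setNames(as.numeric(ov[as.character(bid), ]), colnames(ov))
    row[!available] <- 0
    if (max(row) == 0) { fn <- fn + 1L; next }
    cand <- names(row)[row == max(row)]
    sid <- cand[which.min(as.integer(cand))]   # deterministic tie-break
    inter <- row[[sid]]
    a_b <- sum(benchmark == bid)
    a_s <- seg_area[[sid]]
    fm <- fmeasure(inter, a_s - inter, a_b - inter)[["fmeasure"]]
    if (fm >= fm_threshold) {
      tp <- tp + 1L
      per_fm <- c(per_fm, fm)
      available[sid] <- FALSE
    } else fn <- fn + 1L
  }
  fp <- sum(available)
  make_match_report(c(tp = tp, fp = fp, fn = fn), per_fm)
}

make_match_report <- function(counts, per_fm, level = "object") {
  m <- fmeasure(counts[["tp"]], counts[["fp"]], counts[["fn"]])
  structure(list(tp = counts[["tp"]], fp = counts[["fp"]], fn = counts[["fn"]],
                 precision = m[["precision"]], recall = m[["recall"]],
                 fmeasure = m[["fmeasure"]], per_object_fm = per_fm,
                 detection_error = counts[["fp"]] + counts[["fn"]],
                 level = level),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> level %s: TP %d FP %d FN %d | PR %.2f RC %.2f FM %.2f\n",
              x$level, x$tp, x$fp, x$fn,
              round2(x$precision), round2(x$recall), round2(x$fmeasure)))
  if (length(x$per_object_fm))
    cat(sprintf("  mean per-object FM of matches: %.2f\n",
                round2(mean(x$per_object_fm))))
  invisible(x)
}

# round-half-up at 2 decimals (display convention for metric tables)
round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Pixel-level foreground precision / recall / F-measure
#'
#' @param segmented,benchmark label matrices or logical masks; any nonzero
#'   pixel is foreground.
#' @return A \code{match_report} with \code{level = "pixel"} (counts are
#'   pixel counts).
#' @export
pixel_fmeasure <- function(segmented, benchmark) {
  s <- segmented > 0; b <- benchmark > 0
  counts <- c(tp = sum(s & b), fp = sum(s & !b), fn = sum(!s & b))
  make_match_report(counts, numeric(0), level = "pixel")
}

#' Evaluate a segmentation run against benchmarks
#'
#' Produces the full quantitative report: object-level matching for cells
#' (and for nuclei when a nuclei benchmark is given), the mean per-object
#' F-measure of correctly detected cells, the detection error FP + FN, and
#' pixel-level foreground metrics of the cytoplasm segmentation. Cytoplasm
#' correspondence never consults the nuclei image: over-splitting at nucleus
#' level must not leak into the cytoplasm score.
#'
#' @param cells integer cell label matrix (the segmentation under test).
#' @param bench_cells integer benchmark cell label matrix.
#' @param nuclei,bench_nuclei optional nuclei label matrices.
#' @param fm_threshold per-object acceptance threshold, default 0.6.
#' @return List of class \code{evaluation_report} with components
#'   \code{cells} (object-level \code{match_report}),
#'   \code{mean_object_fm}, \code{pixel} (pixel-level report), and
#'   optionally \code{nuclei}.
#' @export
evaluate_run <- function(cells, bench_cells, nuclei = NULL,
                         bench_nuclei = NULL, fm_threshold = 0.6) {
  rep_cells <- match_objects(cells, bench_cells, fm_threshold)
  out <- list(cells = rep_cells,
              mean_object_fm = if (length(rep_cells$per_object_fm))
                mean(rep_cells$per_object_fm) else NA_real_,
              pixel = pixel_fmeasure(cells, bench_cells))
  if (!is.null(nuclei) && !is.null(bench_nuclei))
    out$nuclei <- match_objects(nuclei, bench_nuclei, fm_threshold)
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("cells:  "); print(x$cells)
  if (!is.null(x$nuclei)) { cat("nuclei: "); print(x$nuclei) }
  cat("pixel:  "); print(x$pixel)
  if (!is.na(x$mean_object_fm))
    cat(sprintf("mean per-object FM (matched cells): %.2f\n",
                round2(x$mean_object_fm)))
  invisible(x)
}

#' Write an evaluation report as JSON or CSV
#'
#' @param report an \code{evaluation_report}.
#' @param path output path ending in .json or .csv.
#' @export
write_report <- function(report, path) {
  rows <- report_rows(report)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(do.call(rbind, lapply(rows, as.data.frame)), path,
                     row.names = FALSE)
  } else stop("unsupported report format: .", ext)
  invisible(path)
}

report_rows <- function(report) {
  row <- function(r, mean_fm = NA_real_) {
    list(level = r$level, tp = r$tp, fp = r$fp, fn = r$fn,
         pr = r$precision, rc = r$recall, fm = r$fmeasure,
         mean_object_fm = mean_fm)
  }
  rows <- list(cells = row(report$cells, report$mean_object_fm),
               pixel = row(report$pixel))
  if (!is.null(report$nuclei)) rows$nuclei <- row(report$nuclei)
  rows
}
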