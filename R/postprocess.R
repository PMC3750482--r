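#' Default post-processing configuration
#'
#' @return List with the tunable structuring sizes: \code{bridge_radius}
#'   (disc radius used to dilate outline branch fragments when bridging gaps
#'   in one-to-many regions, default 2), \code{close_radius} (disc radius of
#'   the closing applied to one-to-one regions, default 3),
#'   \code{merge_iterations} (passes of nucleus-free region merging, default
#'   3), \code{max_hole_area} (holes below this area are filled, default 50).
#' @export
postprocess_config <- function(bridge_radius = 2, close_radius = 3,
                               merge_iterations = 3L, max_hole_area = 50) {
  list(bridge_radius = bridge_radius, close_radius = close_radius,
       merge_iterations = as.integer(merge_iterations),
       max_hole_area = max_hole_area)
}

# Fill enclosed background holes of a binary mask. Holes overlapping
# `always_fill` are filled regardless of size; others only when smaller than
# max_area.
fill_small_holes <- function(mask, max_area = 50, always_fill = NULL) {
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  holes <- filled & !mask
  if (!any(holes)) return(mask)
  hl <- label_components(holes)
  areas <- tabulate(hl[hl > 0L], nbins = max(hl))
  fill <- which(areas < max_area)
  if (!is.null(always_fill))
    fill <- union(fill, setdiff(unique(hl[always_fill & hl > 0L]), 0L))
  out <- mask
  out[hl %in% fill] <- TRUE
  out
}

#' Filter classified outline pixels using nuclei context
#'
#' Removes outline pixels that fall on nucleus interiors (nucleus pixels can
#' never carry a cell outline), fills small holes of the initial
#' cytoplasm/background mask (holes containing a nucleus pixel are always
#' filled), and unifies the inverted refined initial mask with the filtered
#' outlines so that the cell/background transition always counts as outline
#' evidence.
#'
#' @param outlines logical matrix from [classify_outlines()].
#' @param nuclei integer label matrix of segmented nuclei (0 = background).
#' @param initial logical initial cytoplasm mask from
#'   [initial_segmentation()].
#' @param max_hole_area holes below this area are filled, default 50.
#' @return List with \code{outlines} (the unified outline mask) and
#'   \code{initial} (the hole-filled initial mask).
#' @export
filter_outlines <- function(outlines, nuclei, initial, max_hole_area = 50) {
  stopifnot(all(dim(outlines) == dim(initial)))
  nuclei_mask <- nuclei > 0
  refined <- fill_small_holes(initial, max_area = max_hole_area,
                              always_fill = nuclei_mask)
  filtered <- outlines & !nuclei_mask
  list(outlines = filtered | !refined, initial = refined)
}

#' Skeletonize an outline mask
#'
#' Homotopy-preserving thinning of the outline set to single-pixel strokes.
#' Unlike shrinking-style thinning, line endpoints are kept, so non-connected
#' outline branches survive as branches (later used to bridge gaps between
#' touching cells). The result contains no 2x2 all-foreground block.
#'
#' @param outlines logical matrix.
#' @return Logical matrix, the skeleton.
#' @export
skeletonize_outlines <- function(outlines) {
  .cc_thin(matrix(as.integer(outlines), nrow(outlines))) > 0
}

# Make a 1-px curve an effective 8-connectivity separator: at every
# diagonal-only step of the skeleton add one off-diagonal pixel, so regions
# cannot leak through the step when components are labelled 8-connected.
fill_diagonal_steps <- function(skel) {
  repeat {
    a <- skel[-nrow(skel), -ncol(skel)]; b <- skel[-nrow(skel), -1]
    c_ <- skel[-1, -ncol(skel)]; d <- skel[-1, -1]
    step1 <- a & d & !b & !c_   # main diagonal -> add top-right
    step2 <- b & c_ & !a & !d   # anti diagonal -> add top-left
    if (!any(step1 | step2)) return(skel)
    idx1 <- which(step1, arr.ind = TRUE)
    if (nrow(idx1)) skel[idx1[, 1, drop = FALSE] + 0L +
                         (idx1[, 2, drop = FALSE]) * nrow(skel)] <- TRUE
    idx2 <- which(step2, arr.ind = TRUE)
    if (nrow(idx2)) skel[idx2[, 1, drop = FALSE] + 0L +
                         (idx2[, 2, drop = FALSE] - 1L) * nrow(skel)] <- TRUE
  }
}

#' First-stage cytoplasm segmentation
#'
#' Applies the thinned outlines on the initial cytoplasm mask: labels are the
#' 8-connected components of \code{initial & !skeleton}. Diagonal steps of
#' the 1-px skeleton are widened by one pixel for the cut, since an
#' 8-connected curve does not by itself separate an 8-connected region.
#'
#' @param initial logical initial cytoplasm mask.
#' @param skeleton logical skeletonized outline mask.
#' @return Integer label matrix.
#' @export
first_stage_segmentation <- function(initial, skeleton) {
  stopifnot(all(dim(initial) == dim(skeleton)))
  label_components(initial & !fill_diagonal_steps(skeleton))
}

# Region area / convex hull area of its pixel squares.
solidity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) return(0)
  if (n <= 2L) return(1)
  corners <- rbind(cbind(pts[, 1] - 0.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] - 0.5, pts[, 2] + 0.5),
                   cbind(pts[, 1] + 0.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] + 0.5, pts[, 2] + 0.5))
  h <- grDevices::chull(corners)
  hp <- corners[h, , drop = FALSE]
  m <- nrow(hp)
  area <- abs(sum(hp[, 1] * hp[c(2:m, 1), 2] - hp[c(2:m, 1), 1] * hp[, 2])) / 2
  if (area <= 0) return(1)
  min(1, n / area)
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  kern <- disc_brush(radius)
  pad <- (nrow(kern) - 1L) %/% 2L
  mp <- EBImage::Image(pad_reflect(mask * 1, pad))
  out <- EBImage::imageData(EBImage::dilate(mp, kern))
  out[(pad + 1):(pad + nrow(mask)), (pad + 1):(pad + ncol(mask)), drop = FALSE] > 0
}

close_mask <- function(mask, radius) {
  kern <- disc_brush(radius)
  pad <- nrow(kern)  # generous padding so closing is border-safe
  mp <- EBImage::Image(pad_reflect(mask * 1, pad))
  out <- EBImage::imageData(EBImage::closing(mp, kern))
  out[(pad + 1):(pad + nrow(mask)), (pad + 1):(pad + ncol(mask)), drop = FALSE] > 0
}

# Majority region label under each nucleus; 0 when the nucleus lies entirely
# on background.
nuclei_region_assignment <- function(labels, nuclei) {
  ks <- setdiff(unique(as.vector(nuclei)), 0L)
  out <- stats::setNames(integer(length(ks)), ks)
  for (k in ks) {
    under <- labels[nuclei == k]
    under <- under[under > 0L]
    out[as.character(k)] <- if (length(under)) {
      tab <- tabulate(under)
      which.max(tab)
    } else 0L
  }
  out
}

#' Split and merge cytoplasmic regions using nuclei
#'
#' The nuclei-contextual refinement of the first-stage segmentation:
#' \enumerate{
#'   \item Regions are partitioned by reconstruction from nucleus markers
#'     into nucleus-free, one-nucleus and multi-nuclei regions.
#'   \item One-to-one regions are morphologically closed (disc of
#'     \code{close_radius}) to smooth interiors and drop stray branches.
#'   \item One-to-many regions: skeleton branch fragments adjacent to the
#'     region are dilated by \code{bridge_radius} to bridge gaps,
#'     re-skeletonized, and the region is re-cut; pieces inherit nuclei by
#'     majority overlap. A region with several nuclei but no outline
#'     evidence is never force-split (multinuclear phenotypes are
#'     preserved).
#'   \item Nucleus-free regions are iteratively merged into the adjacent
#'     nucleus-bearing region whose union has the largest solidity
#'     (\code{merge_iterations} passes, ties to the lowest label);
#'     fragments never reached by any cell are dropped.
#'   \item Cleanup: holes below \code{max_hole_area} are filled, diagonal
#'     (h-connectivity) junctions between distinct labels are removed, and
#'     labels are compacted to 1..K in raster-scan order.
#' }
#'
#' @param first_stage integer label matrix from
#'   [first_stage_segmentation()].
#' @param nuclei integer nuclei label matrix.
#' @param skeleton logical skeletonized outline mask.
#' @param cfg a [postprocess_config()].
#' @return Integer label matrix of individual cells.
#' @export
split_merge <- function(first_stage, nuclei, skeleton,
                        cfg = postprocess_config()) {
  labels <- first_stage
  if (max(nuclei) == 0L) {
    warning("empty nuclei mask: returning first-stage segmentation after cleanup")
    return(cleanup_labels(labels, cfg$max_hole_area))
  }
  assign <- nuclei_region_assignment(labels, nuclei)
  region_ids <- setdiff(unique(as.vector(labels)), 0L)
  n_nuc <- table(factor(assign[assign > 0L], levels = region_ids))

  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 0L
  merge_pool <- list()

  for (rid in region_ids) {
    mask <- labels == rid
    k <- as.integer(n_nuc[as.character(rid)])
    if (is.na(k)) k <- 0L
    if (k == 0L) {
      merge_pool[[length(merge_pool) + 1L]] <- mask
    } else if (k == 1L) {
      closed <- close_mask(mask, cfg$close_radius)
      closed <- closed & (out == 0L) & (labels == 0L | labels == rid)
      closed <- closed | mask
      nxt <- nxt + 1L
      out[closed] <- nxt
    } else {
      pieces <- split_multinucleus(mask, nuclei, skeleton, cfg)
      for (pc in pieces$cells) {
        nxt <- nxt + 1L
        out[pc & out == 0L] <- nxt
      }
      merge_pool <- c(merge_pool, pieces$fragments)
    }
  }

  # iterative merging of nucleus-free fragments into adjacent cells
  if (length(merge_pool)) {
    pending <- merge_pool
    for (it in seq_len(cfg$merge_iterations)) {
      if (!length(pending)) break
      still <- list()
      for (frag in pending) {
        reach <- dilate_mask(frag, cfg$bridge_radius)
        cand <- setdiff(unique(out[reach]), 0L)
        if (!length(cand)) { still[[length(still) + 1L]] <- frag; next }
        sol <- vapply(cand, function(cid) solidity((out == cid) | frag), 0)
        best <- cand[which(sol == max(sol))]
        best <- min(best)   # deterministic tie-break: lowest label id
        out[frag] <- best
      }
      pending <- still
    }
  }
  cleanup_labels(out, cfg$max_hole_area)
}

# Split one multi-nucleus region along dilated skeleton branch fragments,
# re-attempting on pieces that still hold several nuclei: once a piece has
# shrunk, previously interior branch tips sit near its border and a cut
# that failed globally can complete locally. Returns cells (masks holding
# >= 1 nucleus) and fragments (nucleus-free masks for the merge pool).
split_multinucleus <- function(mask, nuclei, skeleton, cfg, depth = 3L) {
  no_split <- list(cells = list(mask), fragments = list())
  frag <- skeleton & dilate_mask(mask, 1)
  if (!any(frag)) return(no_split)
  bridged <- dilate_mask(frag, cfg$bridge_radius)
  # thin the bridged branches together with the region complement: thinning
  # preserves connectivity of the union, so a branch whose dilation reaches
  # the region border stays attached to the background and cuts through
  cut <- skeletonize_outlines(bridged | skeleton | !mask)
  pieces <- label_components(mask & !fill_diagonal_steps(cut))
  if (max(pieces) <= 1L) return(no_split)
  assign <- nuclei_region_assignment(pieces, nuclei)
  cells <- list(); fragments <- list()
  counts <- table(factor(assign[assign > 0L], levels = seq_len(max(pieces))))
  # cut pixels themselves are re-attached to the neighbouring piece with the
  # most adjacent pixels so no foreground is lost
  reclaimed <- reclaim_cut_pixels(mask, pieces)
  for (pid in seq_len(max(pieces))) {
    pm <- reclaimed == pid
    if (!any(pm)) next
    k <- counts[as.character(pid)]
    if (k >= 2L && depth > 1L) {
      sub <- split_multinucleus(pm, nuclei, skeleton, cfg, depth - 1L)
      cells <- c(cells, sub$cells)
      fragments <- c(fragments, sub$fragments)
    } else if (k >= 1L) {
      cells[[length(cells) + 1L]] <- pm
    } else {
      fragments[[length(fragments) + 1L]] <- pm
    }
  }
  if (!length(cells)) return(no_split)
  list(cells = cells, fragments = fragments)
}

# Assign foreground pixels lost to the cut (mask & piece==0) to the nearest
# piece by iterative dilation voting.
reclaim_cut_pixels <- function(mask, pieces) {
  out <- pieces
  lost <- mask & out == 0L
  guard <- 0L
  while (any(lost) && (guard <- guard + 1L) < 64L) {
    idx <- which(lost, arr.ind = TRUE)
    nr <- nrow(out); nc <- ncol(out)
    changed <- FALSE
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      rr <- max(1, r - 1):min(nr, r + 1)
      cc <- max(1, c - 1):min(nc, c + 1)
      nb <- out[rr, cc]
      nb <- nb[nb > 0L]
      if (length(nb)) {
        tab <- tabulate(nb)
        out[r, c] <- which.max(tab)
        changed <- TRUE
      }
    }
    lost <- mask & out == 0L
    if (!changed) break
  }
  out
}

# Final cleanup: fill small holes per label, break diagonal junctions
# between distinct labels, compact label ids in raster-scan order.
cleanup_labels <- function(labels, max_hole_area = 50) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  for (id in ids) {
    m <- labels == id
    filled <- fill_small_holes(m, max_area = max_hole_area)
    labels[filled & labels == 0L] <- id
  }
  labels <- break_h_connectivity(labels)
  compact_labels(labels)
}

# Remove configurations where two distinct labels meet only diagonally
# inside a 2x2 block, by clearing one of the offending pixels
# (deterministically the bottom-right-most pixel of the larger label).
break_h_connectivity <- function(labels) {
  repeat {
    a <- labels[-nrow(labels), -ncol(labels)]
    b <- labels[-nrow(labels), -1]
    c_ <- labels[-1, -ncol(labels)]
    d <- labels[-1, -1]
    diag1 <- a > 0L & d > 0L & a != d & b != a & b != d & c_ != a & c_ != d
    diag2 <- b > 0L & c_ > 0L & b != c_ & a != b & a != c_ & d != b & d != c_
    hit <- which(diag1 | diag2, arr.ind = TRUE)
    if (!nrow(hit)) break
    r <- hit[1, 1]; c2 <- hit[1, 2]
    block <- labels[r:(r + 1), c2:(c2 + 1)]
    if (diag1[r, c2]) {
      drop_lab <- max(block[1, 1], block[2, 2])
      if (block[2, 2] == drop_lab) labels[r + 1, c2 + 1] <- 0L else labels[r, c2] <- 0L
    } else {
      drop_lab <- max(block[1, 2], block[2, 1])
      if (block[2, 1] == drop_lab) labels[r + 1, c2] <- 0L else labels[r, c2 + 1] <- 0L
    }
  }
  labels
}

# Renumber labels 1..K by raster-scan (row-major) order of first pixel.
compact_labels <- function(labels) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (!length(ids)) return(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  first_pos <- vapply(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    min((w[, 1] - 1L) * nc + w[, 2])
  }, 0)
  remap <- integer(max(ids))
  remap[ids[order(first_pos)]] <- seq_along(ids)
  idx <- labels > 0L
  labels[idx] <- remap[labels[idx]]
  labels
}

#' Full post-processing chain
#'
#' Convenience wrapper chaining [filter_outlines()],
#' [skeletonize_outlines()], [first_stage_segmentation()] and
#' [split_merge()] into the final cell label image.
#'
#' @param initial logical initial cytoplasm mask.
#' @param outlines logical classified outline mask.
#' @param nuclei integer nuclei label matrix.
#' @param cfg a [postprocess_config()].
#' @return Integer label matrix of individual cells.
#' @export
postprocess_cells <- function(initial, outlines, nuclei,
                              cfg = postprocess_config()) {
  f <- filter_outlines(outlines, nuclei, initial,
                       max_hole_area = cfg$max_hole_area)
  skel <- skeletonize_outlines(f$outlines)
  first <- first_stage_segmentation(f$initial, skel)
  split_merge(first, nuclei, skel, cfg)
}
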