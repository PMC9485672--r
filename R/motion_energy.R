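#' Frame sequences
#'
#' A frame sequence is the raw video input of the pipeline: an ordered set of
#' grayscale frames sampled at a fixed rate. Frames are stored as a
#' `height x width x n_frames` array of intensities in `[0, 255]`; pixel
#' coordinates have their origin at the top-left corner, with x increasing
#' rightwards (columns) and y downwards (rows).
#'
#' @param frames A 3-d numeric array (`height x width x n_frames`) or a list
#'   of equally sized numeric matrices. Intensities must lie in `[0, 255]`.
#' @param fps Sampling rate in frames per second (default 30).
#' @return A `frame_sequence` object.
#' @seealso [compute_motion_energy()], [gen_frames()]
#' @export
frame_sequence <- function(frames, fps = 30) {
  if (is.list(frames)) {
    dims <- lapply(frames, dim)
    if (length(unique(lapply(dims, as.integer))) != 1L)
      stop("format error: frames have mismatched dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (length(dim(frames)) != 3L)
    stop("format error: frames must be a height x width x n_frames array")
  if (dim(frames)[3L] < 2L) stop("need at least 2 frames")
  if (fps <= 0) stop("fps must be positive")
  rng <- range(frames)
  if (rng[1L] < 0 || rng[2L] > 255)
    stop("format error: intensities must lie in [0, 255]")
  structure(list(frames = frames, fps = fps,
                 height = dim(frames)[1L], width = dim(frames)[2L],
                 n_frames = dim(frames)[3L]),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %dx%d px at %g fps (%.1f s)\n",
              x$n_frames, x$width, x$height, x$fps, x$n_frames / x$fps))
  invisible(x)
}

#' Regions of interest
#'
#' A region of interest (ROI) is a fixed pixel region assigned to one body
#' region of one interactant; motion energy is counted separately per ROI.
#' Rectangles are given by their top-left corner and size, polygons by their
#' vertices; both are rasterized against the frame dimensions at analysis
#' time.
#'
#' @param person Who the region belongs to, e.g. `"therapist"` or
#'   `"patient"`.
#' @param region Body region label, e.g. `"head"`, `"upper_body"`,
#'   `"lower_body"`.
#' @param x,y For `roi_rect()`: top-left corner (1-based pixel coordinates,
#'   x = column, y = row). For `roi_polygon()`: numeric vectors of vertex
#'   coordinates.
#' @param width,height Rectangle size in pixels.
#' @return An `roi` object with a `label` of the form `"person.region"`.
#' @export
roi_rect <- function(person, region, x, y, width, height) {
  if (width < 1 || height < 1) stop("ROI must be nonempty")
  structure(list(person = person, region = region,
                 label = paste(person, region, sep = "."),
                 shape = "rect", x = x, y = y,
                 width = width, height = height),
            class = "roi")
}

#' @rdname roi_rect
#' @export
roi_polygon <- function(person, region, x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("polygon needs at least 3 vertices")
  structure(list(person = person, region = region,
                 label = paste(person, region, sep = "."),
                 shape = "polygon", x = x, y = y),
            class = "roi")
}

#' Rasterize an ROI to a logical pixel mask
#'
#' @param roi An [roi_rect()] / [roi_polygon()] object.
#' @param width,height Frame dimensions in pixels.
#' @return A `height x width` logical matrix; `TRUE` marks pixels inside the
#'   region. Errors if any part of the region falls outside the frame.
#' @export
rasterize_roi <- function(roi, width, height) {
  mask <- matrix(FALSE, height, width)
  if (roi$shape == "rect") {
    x1 <- roi$x; y1 <- roi$y
    x2 <- roi$x + roi$width - 1L; y2 <- roi$y + roi$height - 1L
    if (x1 < 1 || y1 < 1 || x2 > width || y2 > height)
      stop(sprintf("bounds error: ROI '%s' outside %dx%d frame",
                   roi$label, width, height))
    mask[y1:y2, x1:x2] <- TRUE
  } else {
    if (min(roi$x) < 0.5 || max(roi$x) > width + 0.5 ||
        min(roi$y) < 0.5 || max(roi$y) > height + 0.5)
      stop(sprintf("bounds error: ROI '%s' outside %dx%d frame",
                   roi$label, width, height))
    # even-odd rule on pixel centers
    px <- rep(seq_len(width), each = height)
    py <- rep(seq_len(height), times = width)
    inside <- rep(FALSE, length(px))
    n <- length(roi$x)
    j <- n
    for (i in seq_len(n)) {
      xi <- roi$x[i]; yi <- roi$y[i]; xj <- roi$x[j]; yj <- roi$y[j]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
    mask[cbind(py[inside], px[inside])] <- TRUE
  }
  if (!any(mask)) stop(sprintf("ROI '%s' rasterizes to an empty mask", roi$label))
  mask
}

#' Motion-energy time series container
#'
#' Motion energy is the per-frame-transition count of pixels within an ROI
#' whose intensity change exceeds a noise threshold: a non-negative,
#' intermittent movement signal of length `n_frames - 1` per ROI.
#'
#' @param values Numeric matrix, one row per frame transition, one column
#'   per ROI; all values must be non-negative.
#' @param fps Sampling rate in Hz.
#' @param labels Character vector of ROI (column) labels.
#' @return An `mea_series` object.
#' @export
mea_series <- function(values, fps = 30, labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("roi", seq_len(ncol(values)))
  if (length(labels) != ncol(values)) stop("one label per column required")
  if (anyNA(values) || min(values) < 0) stop("motion energy must be non-negative")
  if (fps <= 0) stop("fps must be positive")
  colnames(values) <- labels
  structure(list(values = values, fps = fps, labels = labels),
            class = "mea_series")
}

#' @export
print.mea_series <- function(x, ...) {
  cat(sprintf("<mea_series> %d steps x %d ROIs at %g fps: %s\n",
              nrow(x$values), ncol(x$values), x$fps,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Extract per-ROI motion energy from a frame sequence
#'
#' For every pair of consecutive frames and every ROI, counts the pixels in
#' the ROI mask whose absolute intensity change exceeds `noise_threshold`.
#' The count statistic bounds each value by the ROI area and is invariant
#' under global illumination offsets.
#'
#' @param frames A [frame_sequence()].
#' @param rois A list of [roi_rect()] / [roi_polygon()] objects.
#' @param noise_threshold Minimum absolute intensity change (of 255) for a
#'   pixel to count as moved; default 10.
#' @return An [mea_series()] with `n_frames - 1` rows, one column per ROI.
#' @export
compute_motion_energy <- function(frames, rois, noise_threshold = 10) {
  if (!inherits(frames, "frame_sequence")) frames <- frame_sequence(frames)
  if (noise_threshold < 0) stop("noise_threshold must be >= 0")
  if (inherits(rois, "roi")) rois <- list(rois)
  n <- frames$n_frames
  masks <- lapply(rois, rasterize_roi,
                  width = frames$width, height = frames$height)
  p <- matrix(frames$frames, ncol = n)            # pixels x frames
  changed <- abs(p[, -1L, drop = FALSE] - p[, -n, drop = FALSE]) > noise_threshold
  vals <- vapply(masks, function(m) colSums(changed[as.vector(m), , drop = FALSE]),
                 numeric(n - 1L))
  mea_series(matrix(vals, nrow = n - 1L), fps = frames$fps,
             labels = vapply(rois, `[[`, character(1L), "label"))
}

#' Combine ROI series into per-person movement series
#'
#' Sums the motion-energy columns of each person's regions elementwise,
#' yielding one whole-body movement series per person.
#'
#' @param me An [mea_series()].
#' @param grouping Named list mapping each person to the character vector of
#'   ROI labels belonging to them; groups must be disjoint.
#' @return An [mea_series()] with one column per person.
#' @export
combine_rois <- function(me, grouping) {
  all_labels <- unlist(grouping, use.names = FALSE)
  unknown <- setdiff(all_labels, me$labels)
  if (length(unknown))
    stop(sprintf("key error: unknown ROI label(s): %s",
                 paste(unknown, collapse = ", ")))
  if (anyDuplicated(all_labels))
    stop("groups must be disjoint")
  vals <- vapply(grouping, function(lbl)
    rowSums(me$values[, lbl, drop = FALSE]), numeric(nrow(me$values)))
  mea_series(matrix(vals, nrow = nrow(me$values)), fps = me$fps,
             labels = names(grouping))
}

#' Read and write motion-energy text files
#'
#' The interchange dialect is plain text with one row per frame transition
#' and one whitespace-separated numeric column per ROI, no header. Writing
#' then reading reproduces the values exactly.
#'
#' @param path File path.
#' @param fps Sampling rate to attach on read (not stored in the file).
#' @param labels Optional column labels to attach on read.
#' @return `read_mea_text()` returns an [mea_series()]; `write_mea_text()`
#'   returns `path` invisibly.
#' @export
read_mea_text <- function(path, fps = 30, labels = NULL) {
  nf <- utils::count.fields(path)
  if (length(nf) == 0L) stop("format error: empty file")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("format error: ragged row %d in '%s' (%d fields, expected %d)",
                 bad, path, nf[bad], nf[1L]))
  }
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: non-numeric cell at row %d, column %d: '%s'",
                 bad[1L], bad[2L], raw[bad[1L], bad[2L]]))
  }
  mea_series(num, fps = fps, labels = labels)
}

#' @rdname read_mea_text
#' @param me An [mea_series()] to write.
#' @export
write_mea_text <- function(me, path) {
  txt <- apply(me$values, c(1L, 2L), function(v)
    if (v == round(v)) sprintf("%d", as.integer(v)) else sprintf("%.17g", v))
  utils::write.table(txt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a declarative ROI configuration
#'
#' The configuration is a YAML list of regions, each with `person`,
#' `region`, and either `rect: [x, y, width, height]` (top-left corner and
#' size) or `polygon: [[x1, y1], [x2, y2], ...]` vertex pairs, in pixel
#' coordinates (origin top-left, x right, y down).
#'
#' @param path Path to the YAML file.
#' @return A list of [roi_rect()] / [roi_polygon()] objects.
#' @export
read_roi_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(e) {
    if (!is.null(e$rect)) {
      roi_rect(e$person, e$region, e$rect[[1L]], e$rect[[2L]],
               e$rect[[3L]], e$rect[[4L]])
    } else if (!is.null(e$polygon)) {
      vs <- do.call(rbind, lapply(e$polygon, unlist))
      roi_polygon(e$person, e$region, vs[, 1L], vs[, 2L])
    } else {
      stop("ROI config entry needs 'rect' or 'polygon'")
    }
  })
}

#' Convert an RGB frame to grayscale
#'
#' Standard luminance weighting (0.299 R + 0.587 G + 0.114 B).
#'
#' @param rgb A `height x width x 3` array.
#' @return A `height x width` intensity matrix.
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected a height x width x 3 array")
  g <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  matrix(g, dim(rgb)[1L], dim(rgb)[2L])
}
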