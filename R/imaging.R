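as_gray <- function(frame) {
  # mean of the RGB channels; redness is reserved for the respiration signal
  if (length(dim(frame)) == 3) (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  else frame
}

#' Temporal standard-deviation projection of an image stack
#'
#' Per-pixel population standard deviation, across frames, of the
#' grayscale-converted stack (grayscale = mean of the RGB channels). Pixels
#' covered by a growing colony change over the series and light up in this
#' projection, which is the raster colony segmentation operates on.
#'
#' @param stack an image stack (list with a `frames` list of height x width
#'   x 3 arrays), or a plain list of frames.
#' @return a matrix of per-pixel standard deviations (divisor `n`, not
#'   `n - 1`).
#' @export
project_temporal_std <- function(stack) {
  frames <- if (!is.null(stack$frames)) stack$frames else stack
  n <- length(frames)
  if (n < 2) stop("need at least 2 frames")
  s1 <- 0; s2 <- 0
  for (f in frames) {
    g <- as_gray(f)
    s1 <- s1 + g
    s2 <- s2 + g * g
  }
  v <- s2 / n - (s1 / n)^2
  sqrt(pmax(v, 0))
}

#' Otsu threshold restricted to a plate mask
#'
#' Computes the Otsu threshold from the intensities of the pixels inside the
#' plate mask only (256-bin histogram over the observed range), correcting for
#' light differences between plates, and returns the binary foreground
#' (pixels strictly above the threshold, inside the mask).
#'
#' @param raster a numeric matrix.
#' @param plate_mask logical matrix of the same shape; `NULL` uses all pixels.
#' @return a logical foreground matrix with attribute `"threshold"`.
#' @export
threshold_plate <- function(raster, plate_mask = NULL) {
  if (is.null(plate_mask)) plate_mask <- matrix(TRUE, nrow(raster), ncol(raster))
  stopifnot(all(dim(raster) == dim(plate_mask)))
  v <- raster[plate_mask]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate threshold: raster is constant inside the plate mask")
  thr <- EBImage::otsu(EBImage::Image(v, dim = c(length(v), 1)),
                       range = rng, levels = 256)
  fg <- raster > thr & plate_mask
  attr(fg, "threshold") <- thr
  fg
}

#' Segment colonies by watershed on the temporal-std projection
#'
#' Splits the thresholded foreground into colony labels by flooding the
#' std-projection relief from its local maxima; maxima shallower than
#' `h` relative to their surroundings are merged (h-maxima style seeding), so
#' noise texture does not oversegment a colony while two colonies merged by a
#' thin neck, each with its own std peak, are still separated. If the std
#' relief is flat inside the mask, the distance transform of the mask is used
#' as the relief instead.
#'
#' @param std_raster the [project_temporal_std()] raster.
#' @param binary_mask logical foreground from [threshold_plate()].
#' @param h merge tolerance for adjacent maxima, in std-intensity units.
#' @return an integer label matrix (0 = background).
#' @export
segment_colonies <- function(std_raster, binary_mask, h = 0.1) {
  stopifnot(all(dim(std_raster) == dim(binary_mask)))
  if (!any(binary_mask))
    return(matrix(0L, nrow(binary_mask), ncol(binary_mask)))
  relief <- std_raster
  relief[!binary_mask] <- 0
  inside <- std_raster[binary_mask]
  if (diff(range(inside)) < 1e-12) {
    relief <- EBImage::distmap(EBImage::Image(binary_mask * 1))
    relief <- relief@.Data
  }
  lab <- EBImage::watershed(EBImage::Image(relief), tolerance = h, ext = 1)
  m <- matrix(as.integer(lab@.Data), nrow(binary_mask))
  m[!binary_mask] <- 0L
  m
}

# centroids / areas / mean RGB per label of one labelled frame
frame_stats <- function(labels, frame = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(data.frame(label = integer(0), area = numeric(0),
                      row = numeric(0), col = numeric(0),
                      mean_r = numeric(0), mean_g = numeric(0),
                      mean_b = numeric(0)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  area <- as.numeric(tapply(rep(1, length(lab)), lab, sum))
  row_m <- as.numeric(tapply(rr, lab, mean))
  col_m <- as.numeric(tapply(cc, lab, mean))
  out <- data.frame(label = as.integer(names(tapply(rr, lab, mean))),
                    area = area, row = row_m, col = col_m)
  if (!is.null(frame)) {
    npx <- nrow(labels) * ncol(labels)
    out$mean_r <- as.numeric(tapply(frame[idx], lab, mean))
    out$mean_g <- as.numeric(tapply(frame[idx + npx], lab, mean))
    out$mean_b <- as.numeric(tapply(frame[idx + 2L * npx], lab, mean))
  } else {
    out$mean_r <- out$mean_g <- out$mean_b <- NA_real_
  }
  out
}

#' Track colony labels across frames
#'
#' Links per-frame labels into colony tracks by nearest-centroid assignment:
#' each detection in a frame is matched to the closest active track, provided
#' the displacement does not exceed the gate. Unmatched detections open new
#' tracks; colonies not yet detected in early frames are recorded with zero
#' area for those frames. An ambiguous swap that would exceed the gate
#' terminates a track rather than reassigning it.
#'
#' @param labeled_frames list of integer label matrices, one per frame.
#' @param frames optional list of RGB arrays for per-label mean colour.
#' @param frame_times frame times in minutes (default `0, 1, 2, ...`).
#' @param gate maximum centroid displacement per frame step, in pixels;
#'   `NULL` sets 1.5 x the median colony radius of the final frame.
#' @return a data frame with one row per (colony, frame): `colony_id`,
#'   `frame`, `frame_time_min`, `area`, `row`, `col`, `mean_r`, `mean_g`,
#'   `mean_b`.
#' @export
track_colonies <- function(labeled_frames, frames = NULL, frame_times = NULL,
                           gate = NULL) {
  nf <- length(labeled_frames)
  if (is.null(frame_times)) frame_times <- seq_len(nf) - 1
  stats <- lapply(seq_len(nf), function(f)
    frame_stats(labeled_frames[[f]],
                if (!is.null(frames)) frames[[f]] else NULL))
  if (is.null(gate)) {
    last <- stats[[nf]]
    gate <- if (nrow(last)) 1.5 * stats::median(sqrt(last$area / pi)) else Inf
    gate <- max(gate, 3)
  }
  tracks <- list()   # per track: row/col of last seen centroid, rows of output
  out <- list()
  active_row <- numeric(0); active_col <- numeric(0)
  active_id <- integer(0)
  next_id <- 1L
  for (f in seq_len(nf)) {
    st <- stats[[f]]
    assigned <- rep(NA_integer_, nrow(st))
    if (length(active_id) && nrow(st)) {
      dmat <- outer(st$row, active_row, "-")^2 +
        outer(st$col, active_col, "-")^2
      dmat <- sqrt(dmat)
      # greedy: repeatedly take the globally closest (detection, track) pair
      repeat {
        m <- which.min(dmat)
        if (!length(m) || !is.finite(dmat[m]) || dmat[m] > gate) break
        di <- (m - 1L) %% nrow(dmat) + 1L
        tj <- (m - 1L) %/% nrow(dmat) + 1L
        assigned[di] <- tj
        dmat[di, ] <- Inf
        dmat[, tj] <- Inf
      }
    }
    new_row <- active_row; new_col <- active_col
    for (di in seq_len(nrow(st))) {
      tj <- assigned[di]
      if (is.na(tj)) {
        id <- next_id; next_id <- next_id + 1L
        active_id <- c(active_id, id)
        new_row <- c(new_row, st$row[di]); new_col <- c(new_col, st$col[di])
        tj <- length(active_id)
      } else {
        id <- active_id[tj]
        new_row[tj] <- st$row[di]; new_col[tj] <- st$col[di]
      }
      out[[length(out) + 1L]] <- data.frame(
        colony_id = id, frame = f, frame_time_min = frame_times[f],
        area = st$area[di], row = st$row[di], col = st$col[di],
        mean_r = st$mean_r[di], mean_g = st$mean_g[di],
        mean_b = st$mean_b[di])
    }
    active_row <- new_row; active_col <- new_col
  }
  if (!length(out))
    return(data.frame(colony_id = integer(0), frame = integer(0),
                      frame_time_min = numeric(0), area = numeric(0),
                      row = numeric(0), col = numeric(0),
                      mean_r = numeric(0), mean_g = numeric(0),
                      mean_b = numeric(0)))
  res <- do.call(rbind, out)
  # pre-detection frames: explicit zero-area rows so every track spans the
  # full series
  full <- do.call(rbind, lapply(split(res, res$colony_id), function(tr) {
    missing <- setdiff(seq_len(nf), tr$frame)
    missing <- missing[missing < min(tr$frame)]
    if (!length(missing)) return(tr)
    pad <- data.frame(colony_id = tr$colony_id[1], frame = missing,
                      frame_time_min = frame_times[missing], area = 0,
                      row = tr$row[1], col = tr$col[1],
                      mean_r = NA_real_, mean_g = NA_real_, mean_b = NA_real_)
    rbind(pad, tr)
  }))
  full <- full[order(full$colony_id, full$frame), ]
  rownames(full) <- NULL
  full
}

#' Quality-control filtering of colony tracks
#'
#' Removes tracks that look like scanner artifacts rather than colonies:
#' too few detections, implausible final area, centroids hugging the plate
#' rim, or area collapsing between consecutive frames (colonies do not
#' shrink).
#'
#' @param tracks data frame from [track_colonies()].
#' @param min_frames minimum number of frames with positive area.
#' @param min_area,max_area bounds on the final-frame area (pixels^2).
#' @param edge_margin minimum distance of the final centroid from the plate
#'   rim, in pixels (requires `plate_center`/`plate_radius`).
#' @param max_rel_decrease maximum tolerated relative area decrease between
#'   consecutive detected frames.
#' @param plate_center,plate_radius plate geometry for the rim rule; `NULL`
#'   disables it.
#' @return the filtered tracks data frame.
#' @export
filter_artifacts <- function(tracks, min_frames = 5, min_area = 4,
                             max_area = Inf, edge_margin = 5,
                             max_rel_decrease = 0.25,
                             plate_center = NULL, plate_radius = NULL) {
  keep <- vapply(split(tracks, tracks$colony_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    det <- tr[tr$area > 0, ]
    if (nrow(det) < min_frames) return(FALSE)
    fin <- det[nrow(det), ]
    if (fin$area < min_area || fin$area > max_area) return(FALSE)
    if (!is.null(plate_center) && !is.null(plate_radius) &&
        is.finite(edge_margin)) {
      rim <- plate_radius -
        sqrt((fin$row - plate_center[1])^2 + (fin$col - plate_center[2])^2)
      if (rim < edge_margin) return(FALSE)
    }
    if (is.finite(max_rel_decrease) && nrow(det) >= 2) {
      rel <- diff(det$area) / pmax(det$area[-nrow(det)], 1)
      if (any(rel < -max_rel_decrease)) return(FALSE)
    }
    TRUE
  }, logical(1))
  ids <- names(keep)[keep]
  tracks[tracks$colony_id %in% as.integer(ids), ]
}

#' Detect the plate circle in a frame
#'
#' Estimates the plate centre and radius from the first frame: the plate is
#' taken as the connected bright region against the (dark) scanner
#' background, its centre as the centroid and its radius from the enclosed
#' area. Intended for stacks whose metadata carries no geometry; explicit
#' configuration always takes precedence.
#'
#' @param frame an RGB array or grayscale matrix.
#' @return a list with `center` (row, col) and `radius` in pixels.
#' @export
detect_plate <- function(frame) {
  g <- as_gray(frame)
  on <- g > min(g) + 0.25 * diff(range(g))
  if (!any(on)) stop("no plate found")
  idx <- which(on)
  rr <- (idx - 1L) %% nrow(g) + 1L
  cc <- (idx - 1L) %/% nrow(g) + 1L
  list(center = c(row = mean(rr), col = mean(cc)),
       radius = sqrt(length(idx) / pi))
}

#' Segment, track and quantify a plate time-lapse
#'
#' The full imaging pipeline: temporal-std projection, plate-restricted Otsu
#' threshold of the projection, watershed segmentation into colony
#' territories, per-frame quantification (one plate-level intensity threshold
#' taken from the final frame decides which pixels of a territory are colony
#' at each frame), centroid tracking, and artifact filtering.
#'
#' @param stack an image stack, e.g. from [gen_plate_timelapse()].
#' @param h watershed merge tolerance, see [segment_colonies()].
#' @param qc list of arguments passed on to [filter_artifacts()]; `NULL`
#'   skips filtering.
#' @param erode_margin pixels to shrink the plate mask by, keeping the rim's
#'   bright meniscus out of the threshold estimate.
#' @return a tracks data frame ([track_colonies()] layout) with additional
#'   columns `x`, `y` (final centroid, col/row) and `dist_center` (pixels).
#' @export
quantify_plate <- function(stack, h = 0.1, qc = list(), erode_margin = 2) {
  stdmap <- project_temporal_std(stack)
  d <- dim(stdmap)
  ctr <- stack$plate_center
  R <- stack$plate_radius
  rowg <- matrix(seq_len(d[1]), d[1], d[2])
  colg <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  plate <- (rowg - ctr[1])^2 + (colg - ctr[2])^2 <= (R - erode_margin)^2

  fg <- tryCatch(threshold_plate(stdmap, plate), error = function(e) NULL)
  empty <- data.frame(colony_id = integer(0), frame = integer(0),
                      frame_time_min = numeric(0), area = numeric(0),
                      row = numeric(0), col = numeric(0),
                      mean_r = numeric(0), mean_g = numeric(0),
                      mean_b = numeric(0), x = numeric(0), y = numeric(0),
                      dist_center = numeric(0))
  if (is.null(fg) || !any(fg)) return(empty)
  regions <- segment_colonies(stdmap, fg, h = h)
  if (max(regions) == 0) return(empty)
  # expand labels into full plate territories so late-growing rim pixels are
  # still credited to their colony
  terr <- EBImage::propagate(EBImage::Image(stdmap),
                             seeds = EBImage::Image(regions),
                             mask = plate * 1, lambda = 1e8)
  terr <- matrix(as.integer(terr@.Data), d[1])

  # one intensity threshold per plate, from the final (highest-contrast) frame
  nf <- length(stack$frames)
  gray_last <- as_gray(stack$frames[[nf]])
  ithr <- attr(threshold_plate(gray_last, plate), "threshold")

  labeled <- lapply(seq_len(nf), function(f) {
    on <- as_gray(stack$frames[[f]]) > ithr
    lab <- terr
    lab[!on] <- 0L
    lab
  })
  tracks <- track_colonies(labeled, frames = stack$frames,
                           frame_times = stack$frame_times)
  if (!is.null(qc)) {
    tracks <- do.call(filter_artifacts,
                      c(list(tracks = tracks, plate_center = ctr,
                             plate_radius = R), qc))
  }
  if (!nrow(tracks)) return(empty)
  fin <- do.call(rbind, lapply(split(tracks, tracks$colony_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    det <- tr[tr$area > 0, ]
    last <- det[nrow(det), ]
    data.frame(colony_id = tr$colony_id[1], x = last$col, y = last$row,
               dist_center = sqrt((last$row - ctr[1])^2 +
                                    (last$col - ctr[2])^2))
  }))
  merge(tracks, fin, by = "colony_id")
}

#' Phenotype-fitting inputs for one retained track
#'
#' Extracts the per-colony series consumed by the growth-kinetics stage:
#' time (h), area, mean red intensity over the colony mask, and the distance
#' of the final centroid from the plate centre.
#'
#' @param track the rows of one colony from [quantify_plate()].
#' @param plate_center plate centre (row, col); unneeded if the track already
#'   carries `dist_center`.
#' @return a data frame with `time_h`, `area`, `red`, `dist_center`.
#' @export
extract_phenotype_inputs <- function(track, plate_center = NULL) {
  track <- track[order(track$frame), ]
  dc <- if ("dist_center" %in% names(track)) track$dist_center[1] else {
    det <- track[track$area > 0, ]
    last <- det[nrow(det), ]
    sqrt((last$row - plate_center[1])^2 + (last$col - plate_center[2])^2)
  }
  data.frame(time_h = track$frame_time_min / 60, area = track$area,
             red = track$mean_r, dist_center = dc)
}
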