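#' Read gene/pathway sets in GMT format
#'
#' @param path path to a `.gmt` file (set name, description, member ids,
#'   tab-separated).
#' @return named list of member-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene/pathway sets in GMT format
#'
#' @param sets named list of member-id vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read a TF-to-target network from a two-column TSV
#'
#' @param path TSV with columns TF, target (no header required; a header row
#'   named `tf`/`target` is tolerated).
#' @return named list: TF -> character vector of targets.
#' @export
read_tf_network <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("tf", "target"))
  if (identical(tolower(df$tf[1]), "tf")) df <- df[-1, ]
  split(df$target, df$tf)
}

#' Write an image stack as a multi-page TIFF or numbered PNG series
#'
#' @param stack an image stack (list with `frames`).
#' @param path output `.tif` path, or a directory for a PNG series
#'   (`frame_0001.png`, ...).
#' @param format `"tiff"` or `"png"`.
#' @export
write_image_stack <- function(stack, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF stacks")
    tiff::writeTIFF(stack$frames, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(stack$frames)) {
      EBImage::writeImage(
        EBImage::Image(aperm(stack$frames[[i]], c(2, 1, 3)),
                       colormode = "Color"),
        file.path(path, sprintf("frame_%04d.png", i)))
    }
  }
  invisible(path)
}

#' Write colony tracks to CSV
#'
#' One CSV per plate with the standard column layout (colony id, frame time
#' in minutes, area in pixels^2, mean RGB, final-centroid plate coordinates,
#' distance from the plate centre).
#'
#' @param tracks data frame from [quantify_plate()].
#' @param path output CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- data.frame(colony_id = tracks$colony_id,
                    frame_time_min = tracks$frame_time_min,
                    area_px2 = tracks$area,
                    mean_R = tracks$mean_r, mean_G = tracks$mean_g,
                    mean_B = tracks$mean_b,
                    x = tracks$x %||% tracks$col,
                    y = tracks$y %||% tracks$row,
                    dist_center_px = tracks$dist_center %||% NA_real_)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-colony phenotype estimate table
#'
#' Loads a deposited colony-estimate table (CSV) with at least colony growth
#' rate, lag time and respiratory rate columns; tolerant to common header
#' variants.
#'
#' @param path CSV path.
#' @return data frame with standardized columns `colony_id`, `mu_max`,
#'   `lag_h`, `resp_rate` and any further columns as-is.
#' @export
read_colony_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(...) {
    hit <- match(c(...), nm)
    hit <- hit[!is.na(hit)][1]
    if (is.na(hit)) NA_integer_ else hit
  }
  map <- c(colony_id = pick("colony_id", "colony", "id"),
           mu_max = pick("mu_max", "growth_rate", "max_growth_rate"),
           lag_h = pick("lag_h", "lag_time", "lag"),
           resp_rate = pick("resp_rate", "respiratory_rate", "alpha"))
  for (target in names(map)) {
    if (!is.na(map[[target]])) names(df)[map[[target]]] <- target
  }
  if (is.null(df$colony_id)) df$colony_id <- seq_len(nrow(df))
  df
}

#' Summaries of a colony phenotype table
#'
#' Colony counts and coefficients of variation of growth rate, lag time and
#' respiratory rate, optionally per condition/plate group.
#'
#' @param table a [read_colony_table()] / [colony_phenotypes()] data frame.
#' @param by optional column name to group by (e.g. `"condition"`).
#' @return data frame with `group`, `n_colonies`, `cv_growth`, `cv_lag`,
#'   `cv_resp`.
#' @export
summarize_colony_table <- function(table, by = NULL) {
  grp <- if (is.null(by)) rep("all", nrow(table)) else table[[by]]
  cv <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  }
  do.call(rbind, lapply(split(table, grp), function(tb) {
    data.frame(group = if (is.null(by)) "all" else tb[[by]][1],
               n_colonies = nrow(tb),
               cv_growth = cv(tb$mu_max),
               cv_lag = cv(tb$lag_h),
               cv_resp = cv(tb$resp_rate))
  }))
}
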