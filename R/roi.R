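#' Region-of-interest set
#'
#' Pairs an integer label map with region names and designates the reference
#' region. Label 0 is background; every nonzero label present in the map must
#' be named.
#'
#' @param label_map 3D integer array or NIfTI file path.
#' @param names named character vector mapping label integers (as names) to
#'   region names, e.g. `c("1" = "SC1", "2" = "SC2")`.
#' @param reference_name region name used as the reference (must appear in
#'   `names`).
#' @return An `roi_set` list.
#' @export
roi_set <- function(label_map, names, reference_name = "SC1") {
  label_map <- as_volume(label_map, "label_map")
  names <- unlist(names)
  labels <- sort(unique(as.integer(label_map)))
  labels <- labels[labels != 0L]
  known <- as.integer(base::names(names))
  if (any(is.na(known))) stop("names must be keyed by integer labels")
  missing <- setdiff(labels, known)
  if (length(missing)) {
    stop(sprintf("unnamed labels in map: %s", paste(missing, collapse = ", ")))
  }
  if (!(reference_name %in% names)) stop("reference_name not among region names")
  structure(list(label_map = label_map, names = names,
                 reference_name = reference_name),
            class = "roi_set")
}

#' Default spinal cord ROI naming scheme
#'
#' Five longitudinal cord segments — SC1 (cervical, C1–C7), SC2 (upper
#' thoracic, T1–T6), SC3 (lesion level, T7), SC4 (lower thoracic, T8–T12),
#' SC5 (lumbar, L1–L5) — plus brain stem (BS) and whole brain (WB), the
#' alternative reference regions.
#'
#' @return Named character vector usable as the `names` argument of
#'   [roi_set()].
#' @export
sc_roi_names <- function() {
  c("1" = "SC1", "2" = "SC2", "3" = "SC3", "4" = "SC4", "5" = "SC5",
    "6" = "BS", "7" = "WB")
}

#' Extract regional time-activity curves from a 4D volume
#'
#' Per region and frame, takes the unweighted mean over voxels carrying that
#' region's label (background label 0 excluded). No partial-volume weighting
#' is applied.
#'
#' @param image4d 4D array (x, y, z, frame) in kBq/mL, or NIfTI file path.
#' @param rois an [roi_set()].
#' @param schedule a [frame_schedule()]; its length must equal the 4th image
#'   dimension.
#' @return Named list of [tac()] objects, one per named region present.
#' @export
extract_tacs <- function(image4d, rois, schedule) {
  image4d <- as_volume(image4d, "image4d")
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(image4d)
  if (length(d) != 4L) stop("image4d must have 4 dimensions")
  if (!identical(d[1:3], dim(rois$label_map))) {
    stop("label map grid does not match the image grid")
  }
  if (d[4] != nrow(schedule)) {
    stop("4th image dimension does not match the number of frames")
  }
  mat <- matrix(image4d, prod(d[1:3]), d[4])
  lab <- as.integer(rois$label_map)
  out <- list()
  for (key in base::names(rois$names)) {
    region <- rois$names[[key]]
    sel <- lab == as.integer(key)
    if (!any(sel)) stop(sprintf("region '%s' has zero voxels in the label map", region))
    out[[region]] <- tac(schedule, colMeans(mat[sel, , drop = FALSE]), region = region)
  }
  out
}

#' Convert a TAC to standardized uptake values
#'
#' `SUV(t) = activity(t) [kBq/mL] / (injected dose [kBq] / body weight [g])`.
#'
#' @param x a [tac()] in kBq/mL.
#' @param injected_dose_MBq injected dose (MBq), `> 0`.
#' @param body_weight_g body weight (g), `> 0`.
#' @return A [tac()] in SUV units (same schedule).
#' @examples
#' x <- tac(frame_schedule(0, 1), 10)
#' to_suv(x, injected_dose_MBq = 18, body_weight_g = 250)$activity  # 0.1389
#' @export
to_suv <- function(x, injected_dose_MBq, body_weight_g) {
  if (injected_dose_MBq <= 0) stop("injected dose must be positive")
  if (body_weight_g <= 0) stop("body weight must be positive")
  dose_kBq <- injected_dose_MBq * 1000
  out <- tac(tac_schedule(x), x$activity / (dose_kBq / body_weight_g),
             region = tac_region(x))
  attr(out, "fine") <- NULL
  out
}

#' Windowed SUV ratio
#'
#' Duration-weighted mean of the target TAC over the frames lying fully
#' inside `[t0, t1]`, divided by the same quantity for the reference TAC.
#' Injected-dose normalization cancels, so raw-activity and SUV TACs give
#' identical ratios. With the default 60-min schedule the 30–60 min window
#' contains exactly six 5-min frames.
#'
#' @param target,reference [tac()] objects sharing a schedule.
#' @param window numeric `c(t0, t1)` in minutes.
#' @return Dimensionless scalar SUVR.
#' @export
suvr_window <- function(target, reference, window = c(30, 60)) {
  stop_if_schedule_mismatch(target, reference)
  stopifnot(length(window) == 2L, window[1] < window[2])
  tol <- 1e-9
  inside <- target$frame_start >= window[1] - tol &
    target$frame_start + target$frame_duration <= window[2] + tol
  if (!any(inside)) stop("no frame lies fully inside the window")
  w <- target$frame_duration[inside]
  num <- sum(w * target$activity[inside]) / sum(w)
  den <- sum(w * reference$activity[inside]) / sum(w)
  if (den == 0) stop("reference windowed mean is zero")
  num / den
}

#' Read / write long-format TAC tables
#'
#' Schema: `animal_id, group, region, frame_start_min, frame_duration_min,
#' activity_kBq_per_mL`. Lines starting with `#` are provenance comments.
#'
#' @param path CSV file path.
#' @return `read_tac_csv()` returns the long data frame.
#' @export
read_tac_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_tac_csv
#' @param tacs long TAC data frame.
#' @param header_comment optional provenance line written as a `#` comment.
#' @export
write_tac_csv <- function(tacs, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(tacs, con, row.names = FALSE)
  invisible(path)
}
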