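#' Ultrasound frame with an elliptical region of interest
#'
#' @param pixels Numeric matrix of grayscale intensities (>= 0). Row/column
#'   indices are 0-based in the ROI specification, matching image
#'   conventions.
#' @param roi List with `center_row`, `center_col`, `semi_row`, `semi_col`
#'   (pixels, 0-based center coordinates; semi-axes may be 0 for a
#'   degenerate point ROI).
#' @param timestamp_min Acquisition time, minutes post-injection.
#' @return An object of class `echo_frame`.
#' @export
echo_frame <- function(pixels, roi, timestamp_min = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) stop("pixels must be a numeric matrix", call. = FALSE)
  if (any(pixels < 0) || any(!is.finite(pixels))) stop("pixel intensities must be finite and >= 0", call. = FALSE)
  need <- c("center_row", "center_col", "semi_row", "semi_col")
  if (!all(need %in% names(roi))) stop("roi must have fields ", paste(need, collapse = ", "), call. = FALSE)
  if (roi$semi_row < 0 || roi$semi_col < 0) stop("semi-axes must be >= 0", call. = FALSE)
  if (roi$center_row - roi$semi_row < 0 || roi$center_row + roi$semi_row > nrow(pixels) - 1 ||
      roi$center_col - roi$semi_col < 0 || roi$center_col + roi$semi_col > ncol(pixels) - 1) {
    stop("ROI extends outside the image bounds", call. = FALSE)
  }
  structure(list(pixels = pixels, roi = roi, timestamp_min = timestamp_min),
            class = "echo_frame")
}

#' Rasterize the elliptical ROI of a frame
#'
#' Pixel (r, c) (0-based centers) is inside iff
#' `((r - cr)/ar)^2 + ((c - cc)/ac)^2 <= 1`; a zero semi-axis restricts that
#' coordinate to the center exactly.
#'
#' @param frame An [echo_frame()].
#' @return Logical matrix the size of the image.
#' @export
roi_mask <- function(frame) {
  stopifnot(inherits(frame, "echo_frame"))
  roi <- frame$roi
  r <- matrix(seq_len(nrow(frame$pixels)) - 1, nrow(frame$pixels), ncol(frame$pixels))
  c_ <- matrix(seq_len(ncol(frame$pixels)) - 1, nrow(frame$pixels), ncol(frame$pixels),
               byrow = TRUE)
  tr <- if (roi$semi_row == 0) ifelse(r == roi$center_row, 0, Inf) else ((r - roi$center_row) / roi$semi_row)^2
  tc <- if (roi$semi_col == 0) ifelse(c_ == roi$center_col, 0, Inf) else ((c_ - roi$center_col) / roi$semi_col)^2
  tr + tc <= 1
}

#' Echogenicity ratio of a frame against a reference
#'
#' Mean pixel intensity within the frame's ROI divided by the mean within
#' the reference frame's ROI. When the two ROIs are congruent (identical
#' semi-axes, hence identical mask shapes) the standard deviation of the
#' per-pixel intensity ratios is also reported.
#'
#' @param frame,reference [echo_frame()] objects. The reference may be the
#'   same animal pre-injection, the earliest timepoint, or a control animal.
#' @return List of class `echo_result` with `ratio`, `pixel_ratio_sd`
#'   (`NA` unless masks congruent), `n_pixels`.
#' @export
echogenicity_ratio <- function(frame, reference) {
  stopifnot(inherits(frame, "echo_frame"), inherits(reference, "echo_frame"))
  m1 <- roi_mask(frame); m2 <- roi_mask(reference)
  if (!any(m1) || !any(m2)) stop("empty ROI mask", call. = FALSE)
  ref_mean <- mean(reference$pixels[m2])
  if (ref_mean == 0) stop("reference ROI mean is zero", call. = FALSE)
  ratio <- mean(frame$pixels[m1]) / ref_mean
  congruent <- frame$roi$semi_row == reference$roi$semi_row &&
    frame$roi$semi_col == reference$roi$semi_col
  sd_px <- NA_real_
  if (congruent && sum(m1) == sum(m2) && sum(m1) >= 2) {
    # same mask shape: per-pixel ratios in matching raster order
    px <- frame$pixels[m1]
    ref <- reference$pixels[m2]
    ok <- ref > 0
    if (sum(ok) >= 2) sd_px <- stats::sd(px[ok] / ref[ok])
  }
  structure(list(ratio = ratio, pixel_ratio_sd = sd_px, n_pixels = sum(m1)),
            class = "echo_result")
}

#' Read a grayscale image from plain text
#'
#' Accepts ASCII PGM (`P2`) or a headerless CSV of pixel intensities.
#' (Binary image formats are intentionally unsupported; the toolchain is
#' plain-text end to end.)
#'
#' @param path File path (`.pgm` or `.csv`).
#' @return Numeric matrix of intensities.
#' @export
read_gray_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines)]
    toks <- scan(text = paste(lines[-1], collapse = " "), what = numeric(),
                 quiet = TRUE)
    if (trimws(lines[1]) != "P2") stop("only ASCII PGM (P2) is supported", call. = FALSE)
    nc <- toks[1]; nr <- toks[2]  # maxval toks[3] unused (linear intensities)
    px <- toks[-(1:3)]
    if (length(px) != nr * nc) stop("corrupt PGM: pixel count mismatch", call. = FALSE)
    matrix(px, nrow = nr, ncol = nc, byrow = TRUE)
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}

#' Write a grayscale image as ASCII PGM (P2)
#'
#' @param pixels Numeric matrix; values are rounded to integers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(pixels, path) {
  px <- round(pixels)
  maxval <- max(1, max(px))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxval)), con)
  apply(px, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
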