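# Readers and writers for short-axis stacks and analysis results.
#
# A stack is an ordered list of end-diastolic slices, base -> apex. Pixel
# intensities are kept in their native units: FD is dimensionless, so neither
# intensity scaling nor pixel spacing changes the measurement, only the
# reported geometry.

#' Construct a single short-axis slice
#'
#' @param pixels Numeric matrix of intensities (rows x cols), finite and
#'   non-negative, at least 32 x 32.
#' @param pixel_spacing Length-2 numeric, (row, col) spacing in mm.
#' @param slice_location Optional position along the LV long axis in mm.
#' @param slice_index Integer position in the stack; 0 is the most basal slice.
#' @return An object of class `lv_slice`.
#' @export
slice_image <- function(pixels, pixel_spacing = c(1, 1), slice_location = NULL,
                        slice_index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_validation("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 32 || ncol(pixels) < 32) {
    abort_validation("slice must be at least 32 x 32 pixels")
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    abort_validation("intensities must be finite and non-negative")
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    abort_validation("pixel_spacing must be two positive numbers (mm)")
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         slice_location = slice_location, slice_index = as.integer(slice_index)),
    class = "lv_slice"
  )
}

#' Construct an end-diastolic stack
#'
#' @param slices List of [slice_image()] objects ordered base to apex.
#' @param subject_id Subject identifier string.
#' @param ed_frame_index Optional integer(s): the cine frame retained per slice.
#' @return An object of class `lv_stack`.
#' @export
lv_stack <- function(slices, subject_id = "subject", ed_frame_index = NULL) {
  if (length(slices) < 3) {
    abort_validation("a stack needs at least 3 slices for the apical/basal split")
  }
  if (!all(vapply(slices, inherits, logical(1), "lv_slice"))) {
    abort_validation("all elements of `slices` must be lv_slice objects")
  }
  idx <- vapply(slices, function(s) s$slice_index, integer(1))
  if (any(diff(idx) <= 0)) {
    abort_validation("slice_index must be strictly increasing base -> apex")
  }
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_validation("all slices must share the same in-plane dimensions")
  }
  structure(
    list(slices = slices, subject_id = subject_id,
         ed_frame_index = ed_frame_index),
    class = "lv_stack"
  )
}

#' @export
print.lv_stack <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  cat(sprintf("<lv_stack> subject '%s': %d slices of %d x %d px, spacing %.3g x %.3g mm\n",
              x$subject_id, length(x$slices), d[1], d[2],
              x$slices[[1]]$pixel_spacing[1], x$slices[[1]]$pixel_spacing[2]))
  invisible(x)
}

as_gray <- function(a) {
  # PNG/TIFF readers return HxW or HxWxC in [0,1]; collapse RGB(A) by the
  # channel average (alpha dropped) and rescale to 0..255 for readability.
  if (length(dim(a)) == 3) {
    nc <- dim(a)[3]
    a <- apply(a[, , seq_len(min(nc, 3)), drop = FALSE], c(1, 2), mean)
    message("RGB image collapsed to grayscale by channel average")
  }
  a * 255
}

#' Load a short-axis stack from disk
#'
#' Supported formats: a directory of per-slice PNG/TIFF images (ordered by
#' filename), a NIfTI-1 volume (slices along the third axis, cine frames along
#' the fourth when present), or a DICOM series (one file per slice, converted
#' through the `python`/pydicom toolchain when available).
#'
#' @param path File or directory path.
#' @param format One of `"image-directory"`, `"nifti"`, `"dicom-series"`.
#' @param subject_id Subject identifier attached to the stack.
#' @return An `lv_stack` (single-frame input) or `lv_cine` (multi-frame NIfTI),
#'   whose slices are ordered base to apex.
#' @export
load_stack <- function(path, format = c("image-directory", "nifti", "dicom-series"),
                       subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_input(sprintf("path does not exist: %s", path))
  if (is.null(subject_id)) subject_id <- basename(sub("[.]nii([.]gz)?$", "", path))
  switch(format,
    "image-directory" = load_image_directory(path, subject_id),
    "nifti" = load_nifti_stack(path, subject_id),
    "dicom-series" = load_dicom_series(path, subject_id)
  )
}

load_image_directory <- function(path, subject_id) {
  if (!dir.exists(path)) abort_input("image-directory format requires a directory")
  files <- sort(list.files(path, pattern = "[.](png|tif|tiff)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) abort_input("no PNG/TIFF files found")
  mats <- lapply(files, function(f) {
    ok <- tryCatch({
      if (grepl("[.]png$", f, ignore.case = TRUE)) as_gray(png::readPNG(f))
      else as_gray(tiff::readTIFF(f))
    }, error = function(e) abort_input(sprintf("unreadable image %s: %s", f, conditionMessage(e))))
    ok
  })
  warning("pixel spacing absent from plain images; defaulting to 1.0 mm/pixel",
          call. = FALSE)
  slices <- mapply(function(m, i) slice_image(m, c(1, 1), slice_index = i),
                   mats, seq_along(mats) - 1L, SIMPLIFY = FALSE)
  lv_stack(slices, subject_id)
}

load_nifti_stack <- function(path, subject_id) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_input(sprintf("unreadable NIfTI: %s", conditionMessage(e))))
  a <- as.array(img)
  pd <- RNifti::pixdim(img)
  sp <- if (length(pd) >= 2 && all(pd[1:2] > 0)) pd[1:2] else {
    warning("pixel spacing absent from NIfTI header; defaulting to 1.0 mm/pixel",
            call. = FALSE)
    c(1, 1)
  }
  if (length(dim(a)) == 4) {
    frames <- lapply(seq_len(dim(a)[3]), function(k) a[, , k, , drop = TRUE])
    return(structure(list(frames = frames, pixel_spacing = sp,
                          subject_id = subject_id), class = "lv_cine"))
  }
  if (length(dim(a)) != 3) abort_input("NIfTI volume must be 3-D or 4-D")
  slices <- lapply(seq_len(dim(a)[3]), function(k) {
    slice_image(a[, , k], sp, slice_index = k - 1L)
  })
  lv_stack(slices, subject_id)
}

load_dicom_series <- function(path, subject_id) {
  # No native R DICOM reader is available; convert the series to NIfTI with
  # pydicom/nibabel when a python interpreter is on PATH, then reuse the
  # NIfTI reader. Slice order follows ImagePositionPatient.
  py <- Sys.which("python")
  if (!nzchar(py)) abort_input("DICOM reading requires a python interpreter with pydicom on PATH")
  out <- tempfile(fileext = ".nii")
  script <- c(
    "import sys, glob, os",
    "import numpy as np, pydicom, nibabel as nib",
    "files = sorted(glob.glob(os.path.join(sys.argv[1], '*')))",
    "ds = [pydicom.dcmread(f) for f in files if os.path.isfile(f)]",
    "ds = [d for d in ds if hasattr(d, 'pixel_array')]",
    "ds.sort(key=lambda d: float(getattr(d, 'ImagePositionPatient', [0,0,len(ds)])[2]))",
    "vol = np.stack([d.pixel_array.astype(float) for d in ds], axis=-1)",
    "sp = [float(x) for x in getattr(ds[0], 'PixelSpacing', [1.0, 1.0])]",
    "aff = np.diag([sp[0], sp[1], 1.0, 1.0])",
    "nib.save(nib.Nifti1Image(vol, aff), sys.argv[2])"
  )
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2(py, c(sf, shQuote(path), shQuote(out)), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out)) abort_input("DICOM series conversion failed")
  load_nifti_stack(out, subject_id)
}

#' Write a stack to a NIfTI-1 volume
#'
#' Slices are stored along the third axis; pixel spacing goes to the header.
#'
#' @param stack An `lv_stack`.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_stack_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "lv_stack"))
  a <- simplify2array(lapply(stack$slices, function(s) s$pixels))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(stack$slices[[1]]$pixel_spacing, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Select the end-diastolic frame of a cine stack
#'
#' Cine CMR is ECG-triggered so frame 0 is conventionally end-diastole; the
#' `max-pool-area` strategy instead picks, per slice, the frame whose bright
#' blood pool (Otsu-thresholded area) is largest, i.e. maximal filling.
#'
#' @param cine An `lv_cine` object (per-slice frame arrays) as returned by
#'   [load_stack()] for 4-D NIfTI, or an `lv_stack` (returned unchanged).
#' @param strategy `"first-frame"` (default) or `"max-pool-area"`.
#' @return An `lv_stack` with `ed_frame_index` recording the chosen frames.
#' @export
select_end_diastole <- function(cine, strategy = c("first-frame", "max-pool-area")) {
  strategy <- match.arg(strategy)
  if (inherits(cine, "lv_stack")) return(cine)
  if (!inherits(cine, "lv_cine")) abort_validation("`cine` must be an lv_cine or lv_stack")
  if (length(cine$frames) < 3) abort_validation("cine must have at least 3 slices")
  picks <- vapply(cine$frames, function(fr) {
    if (length(dim(fr)) == 2) return(1L)
    nf <- dim(fr)[3]
    if (nf < 1) abort_validation("empty frame sequence")
    if (strategy == "first-frame") return(1L)
    area <- vapply(seq_len(nf), function(t) {
      m <- fr[, , t]
      thr <- stats::quantile(m, 0.5) # split bright pool from darker tissue
      rng <- range(m)
      if (diff(rng) > 0) {
        thr <- EBImage::otsu(matrix((m - rng[1]) / diff(rng), nrow(m))) *
          diff(rng) + rng[1]
      }
      sum(m > thr)
    }, numeric(1))
    which.max(area)
  }, integer(1))
  slices <- mapply(function(fr, t, i) {
    m <- if (length(dim(fr)) == 2) fr else fr[, , t]
    slice_image(m, cine$pixel_spacing, slice_index = i)
  }, cine$frames, picks, seq_along(cine$frames) - 1L, SIMPLIFY = FALSE)
  lv_stack(slices, cine$subject_id, ed_frame_index = picks - 1L)
}

#' Write per-subject fractal results as JSON
#'
#' @param subject An `lv_subject_fd` from [analyze_stack()] or [aggregate_fds()].
#' @param path Output path.
#' @param params Optional parameter record stored for provenance.
#' @param seed Optional seed stored for provenance.
#' @return `path`, invisibly.
#' @export
write_subject_json <- function(subject, path, params = NULL, seed = NULL) {
  stopifnot(inherits(subject, "lv_subject_fd"))
  payload <- list(
    subject_id = subject$subject_id,
    per_slice = subject$per_slice,
    global_fd = subject$global_fd,
    mean_apical_fd = subject$mean_apical_fd,
    max_apical_fd = subject$max_apical_fd,
    n_slices_analyzed = subject$n_slices_analyzed,
    excluded_indices = subject$excluded_indices,
    params = params,
    seed = seed,
    software_version = as.character(utils::packageVersion("lvtrab"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a cohort of subject results as flat CSV
#'
#' @param subjects List of `lv_subject_fd` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(subjects, path) {
  rows <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, global_fd = s$global_fd,
               mean_apical_fd = s$mean_apical_fd, max_apical_fd = s$max_apical_fd,
               n_slices_analyzed = s$n_slices_analyzed)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
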