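#' Read a multi-page TIFF stack and its frame-time sidecar
#'
#' @param path stem or `.tif` path written by [write_acquisition()] (or any
#'   multi-page grayscale TIFF; without a `_times.json` sidecar, frame
#'   times default to 60 s spacing).
#' @return A list: `stack` (list of integer matrices) and `times` (s).
#' @export
read_stack <- function(path) {
  stem <- sub("\\.tif{1,2}$", "", path)
  tif <- if (file.exists(paste0(stem, ".tif"))) paste0(stem, ".tif") else path
  if (!file.exists(tif)) stop(sprintf("no TIFF found at '%s'", path))
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(stem, "_times.json")
  times <- if (file.exists(sidecar)) {
    as.numeric(jsonlite::read_json(sidecar)$times)
  } else (seq_along(pages) - 1) * 60
  list(stack = pages, times = times)
}

#' Per-frame ROI statistics of an image stack
#'
#' For every frame, the arithmetic mean and sample standard deviation
#' (n - 1 denominator) of the pixel values under each ROI mask: apical
#' channel, basolateral chamber, background region, and (optionally) each
#' azimuthal sector of the basolateral disk. The background estimate used
#' downstream is the median of the background ROI in the first frame,
#' which is tracer-free.
#'
#' @param stack list of numeric matrices (frames), or a `chip_acquisition`.
#' @param masks a [rasterize_chip()] mask set.
#' @param times frame times, s (taken from the acquisition if omitted).
#' @param sectors include per-sector basolateral means?
#' @return A data.frame of class `roi_timeseries` with columns `time_s`,
#'   `apical_mean`, `apical_sd`, `baso_mean`, `baso_sd`, `bg_mean`,
#'   `bg_sd` (and `sector_01`... when `sectors = TRUE`); attribute
#'   `background_estimate` holds the first-frame background median.
#' @export
extract_timeseries <- function(stack, masks, times = NULL, sectors = FALSE) {
  if (inherits(stack, "chip_acquisition")) {
    if (is.null(times)) times <- stack$times
    stack <- stack$stack
  }
  stopifnot(inherits(masks, "roi_masks"))
  if (is.null(times)) times <- (seq_along(stack) - 1) * 60
  if (length(times) != length(stack))
    stop("length of times must match the number of frames")
  shape <- dim(stack[[1]])
  if (!all(shape == masks$frame_shape))
    stop(sprintf("stack frames are %d x %d but masks are %d x %d",
                 shape[1], shape[2], masks$frame_shape[1], masks$frame_shape[2]))
  rois <- list(apical = which(masks$apical),
               baso = which(masks$basolateral),
               bg = which(masks$background))
  if (any(lengths(rois) == 0)) stop("empty ROI mask")
  stat1 <- function(frame, idx) {
    v <- frame[idx]
    c(mean(v), stats::sd(v))
  }
  n <- length(stack)
  out <- data.frame(time_s = times,
                    apical_mean = NA_real_, apical_sd = NA_real_,
                    baso_mean = NA_real_, baso_sd = NA_real_,
                    bg_mean = NA_real_, bg_sd = NA_real_)
  sec_idx <- if (sectors) lapply(masks$sectors, which) else NULL
  if (sectors) {
    if (any(lengths(sec_idx) == 0)) stop("empty sector mask")
    for (s in seq_along(sec_idx))
      out[[sprintf("sector_%02d", s)]] <- NA_real_
  }
  for (i in seq_len(n)) {
    f <- stack[[i]]
    if (!all(dim(f) == shape)) stop("inconsistent frame shapes within stack")
    out[i, 2:3] <- stat1(f, rois$apical)
    out[i, 4:5] <- stat1(f, rois$baso)
    out[i, 6:7] <- stat1(f, rois$bg)
    if (sectors)
      for (s in seq_along(sec_idx))
        out[i, sprintf("sector_%02d", s)] <- mean(f[sec_idx[[s]]])
  }
  attr(out, "background_estimate") <- stats::median(stack[[1]][rois$bg])
  class(out) <- c("roi_timeseries", "data.frame")
  out
}

#' Detect the frame at which the apical channel reaches equilibrium
#'
#' Frames acquired while the donor (apical) channel is still filling must
#' be excluded from slope fitting. The criterion: the first frame index
#' `f` such that frames `f .. f+window-1` all lie within `rel_tol` of the
#' median of the final quartile of the series.
#'
#' @param apical_mean per-frame apical mean intensity.
#' @param rel_tol relative tolerance band (default 2%).
#' @param window number of consecutive frames required inside the band.
#' @return The 1-based equilibrium frame index.
#' @export
detect_apical_equilibrium <- function(apical_mean, rel_tol = 0.02, window = 5) {
  n <- length(apical_mean)
  if (n < window) stop("need at least `window` frames")
  ref <- stats::median(apical_mean[ceiling(0.75 * n):n])
  inband <- abs(apical_mean - ref) <= rel_tol * abs(ref)
  for (f in seq_len(n - window + 1)) {
    if (all(inband[f:(f + window - 1)])) return(f)
  }
  stop("apical channel never reached equilibrium intensity; acquire longer")
}

#' Normalize a basolateral intensity series to the apical equilibrium
#'
#' Computes the normalized intensity
#' \eqn{I(t) = (B(t) - bg) / (A_{eq} - bg)} where \eqn{A_{eq}} is the mean
#' apical intensity over the post-equilibrium frames and `bg` the
#' background estimate, and propagates the per-frame basolateral SD as
#' `norm_sd = baso_sd / (A_eq - bg)`. Frames before the equilibrium frame
#' are flagged `excluded`. Sector columns, when present, are normalized
#' with the same constants.
#'
#' @param ts a [extract_timeseries()] result.
#' @param background background level in counts; defaults to the
#'   first-frame background-ROI median stored on `ts`. Set `background = 0`
#'   for the literal (non-subtracted) normalization.
#' @param equilibrium_frame override the detected equilibrium frame.
#' @param rel_tol,window passed to [detect_apical_equilibrium()].
#' @return A data.frame of class `intensity_profile`: `ts` plus columns
#'   `norm_I`, `norm_sd`, `excluded` (and normalized `sector_*` columns);
#'   attributes `equilibrium_frame`, `A_eq`, `background_estimate`.
#' @export
normalize_profile <- function(ts, background = NULL, equilibrium_frame = NULL,
                              rel_tol = 0.02, window = 5) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (is.null(background)) background <- attr(ts, "background_estimate")
  if (is.null(background)) background <- 0
  if (is.null(equilibrium_frame))
    equilibrium_frame <- detect_apical_equilibrium(ts$apical_mean,
                                                   rel_tol = rel_tol,
                                                   window = window)
  n <- nrow(ts)
  if (equilibrium_frame > n) stop("equilibrium_frame beyond the acquisition")
  a_eq <- mean(ts$apical_mean[equilibrium_frame:n])
  denom <- a_eq - background
  if (denom <= 0)
    stop("apical equilibrium intensity does not exceed background: no signal")
  out <- ts
  out$norm_I <- (ts$baso_mean - background) / denom
  out$norm_sd <- ts$baso_sd / denom
  out$excluded <- seq_len(n) < equilibrium_frame
  sec_cols <- grep("^sector_", names(ts), value = TRUE)
  for (sc in sec_cols) out[[sc]] <- (ts[[sc]] - background) / denom
  attr(out, "equilibrium_frame") <- equilibrium_frame
  attr(out, "A_eq") <- a_eq
  attr(out, "background_estimate") <- background
  class(out) <- c("intensity_profile", "data.frame")
  out
}

#' Write an intensity profile as CSV
#'
#' @param profile an `intensity_profile`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  df$excluded <- as.integer(df$excluded)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an intensity profile CSV written by [write_profile_csv()]
#'
#' Reconstructs the `intensity_profile` attributes from the columns
#' (equilibrium frame from the `excluded` flags; `A_eq` and the background
#' cannot be recovered from the CSV and are re-derived from the stored
#' series, so sector permeabilities computed from a round-tripped CSV use
#' the same normalization constants as the original analysis).
#'
#' @param path CSV path.
#' @return An `intensity_profile` data.frame.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  df$excluded <- df$excluded != 0
  eq <- which(!df$excluded)[1]
  attr(df, "equilibrium_frame") <- eq
  # invert norm_I = (baso - bg)/(A_eq - bg) using two frames is ill-posed
  # for noisy data; recover the denominator from the propagated sd instead
  denom <- stats::median(df$baso_sd / df$norm_sd, na.rm = TRUE)
  a_mean <- mean(df$apical_mean[eq:nrow(df)])
  attr(df, "A_eq") <- a_mean
  attr(df, "background_estimate") <- a_mean - denom
  class(df) <- c("intensity_profile", "data.frame")
  df
}
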