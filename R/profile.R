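# From per-frame masks to per-particle area series and normalized
# deformation profiles — the method's central measurement.

#' Pixel scale from horizontal field width
#'
#' @param hfw Horizontal field width in micrometres.
#' @param width Image width in pixels.
#' @return Micrometres per pixel, `hfw / width`.
#' @export
pixel_scale_from_hfw <- function(hfw, width) {
  if (!is.numeric(hfw) || hfw <= 0) stop("hfw must be positive")
  if (!is.numeric(width) || width <= 0) stop("width must be positive")
  hfw / width
}

#' Cross-sectional area of a mask
#'
#' @param mask Logical mask matrix.
#' @param pixel_scale Micrometres per pixel (> 0).
#' @return Area in square micrometres (0 for an empty mask).
#' @export
measure_area <- function(mask, pixel_scale) {
  if (pixel_scale <= 0) stop("pixel_scale must be positive")
  sum(mask > 0) * pixel_scale^2
}

component_stats <- function(mask) {
  lab <- as.matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask * 1))))
  n <- max(lab)
  if (n == 0) return(NULL)
  idx <- which(lab > 0, arr.ind = TRUE)
  comps <- lab[lab > 0]
  list(labels = lab, n = n,
       areas = tabulate(comps, nbins = n),
       cy = tapply(idx[, 1], comps, mean),
       cx = tapply(idx[, 2], comps, mean))
}

#' Track one particle through a mask sequence
#'
#' Follows the connected component with maximal pixel overlap with the
#' previously selected component (frame 0: overlap with `seed_mask`). Ties
#' are broken by larger area, then by smaller centroid distance to the
#' previous selection. Frames where no component overlaps the track carry
#' the last area forward and are flagged as dropouts, so a transient
#' segmentation failure does not register as total deformation.
#'
#' @param masks List of per-frame logical masks (>= 2 frames).
#' @param seed_mask Non-empty logical mask locating the particle in frame 1.
#' @param pixel_scale Micrometres per pixel.
#' @param frame_interval Seconds between frames.
#' @param particle_id Label carried into the output.
#' @return Object of class `area_series`: list with `particle_id`, `times`
#'   (s, starting at 0), `areas` (um^2), `pixel_scale`, and `flags` (indices
#'   of carried-forward frames).
#' @export
track_particle <- function(masks, seed_mask, pixel_scale = 1,
                           frame_interval = 1, particle_id = "particle") {
  if (length(masks) < 2L) stop("need at least 2 frames")
  if (!any(seed_mask > 0)) stop("seed_mask is empty")
  if (all(vapply(masks, function(m) !any(m > 0), logical(1))))
    stop("tracking failure: all frames segmented empty")
  ref <- seed_mask > 0
  ref_c <- c(mean(which(rowSums(ref) > 0)), mean(which(colSums(ref) > 0)))
  areas_px <- numeric(length(masks))
  flags <- integer(0)
  last_area <- NA_real_
  for (i in seq_along(masks)) {
    st <- component_stats(masks[[i]])
    picked <- FALSE
    if (!is.null(st)) {
      ov <- vapply(seq_len(st$n), function(k)
        sum(ref & (st$labels == k)), numeric(1))
      if (any(ov > 0)) {
        cand <- which(ov == max(ov))
        if (length(cand) > 1L) {
          cand <- cand[st$areas[cand] == max(st$areas[cand])]
          if (length(cand) > 1L) {
            d <- sqrt((st$cy[cand] - ref_c[1])^2 +
                        (st$cx[cand] - ref_c[2])^2)
            cand <- cand[which.min(d)]
          }
        }
        k <- cand[1L]
        sel <- st$labels == k
        areas_px[i] <- st$areas[k]
        last_area <- st$areas[k]
        ref <- sel
        ref_c <- c(st$cy[k], st$cx[k])
        picked <- TRUE
      }
    }
    if (!picked) {
      if (is.na(last_area)) {
        # no component yet: flag and wait for the first appearance
        areas_px[i] <- NA_real_
      } else {
        areas_px[i] <- last_area
      }
      flags <- c(flags, i)
    }
  }
  # leading dropouts (before any component was seen) back-fill from the
  # first successful frame
  if (anyNA(areas_px))
    areas_px[is.na(areas_px)] <- areas_px[which(!is.na(areas_px))[1L]]
  structure(list(particle_id = particle_id,
                 times = (seq_along(masks) - 1L) * frame_interval,
                 areas = areas_px * pixel_scale^2,
                 pixel_scale = pixel_scale, flags = flags),
            class = "area_series")
}

#' Normalize an area series to a deformation profile
#'
#' Expresses each area as a percentage of the initial area:
#' `percent_remaining(t) = 100 * A(t) / A(0)`. Invariant to rescaling the
#' areas by any positive constant.
#'
#' @param series An `area_series` (from [track_particle()]) or a list with
#'   `times` and `areas`.
#' @param material Optional material label.
#' @return Long-format data frame `particle_id`, `material`, `time_s`,
#'   `percent_remaining` (first value exactly 100).
#' @export
normalize_profile <- function(series, material = NA_character_) {
  if (is.null(series$areas) || is.null(series$times))
    stop("series must carry times and areas")
  if (length(series$areas) != length(series$times))
    stop("times and areas lengths differ")
  if (series$areas[1L] <= 0) stop("initial area must be positive")
  data.frame(
    particle_id = if (!is.null(series$particle_id)) series$particle_id
                  else "particle",
    material = material,
    time_s = series$times,
    percent_remaining = 100 * series$areas / series$areas[1L],
    stringsAsFactors = FALSE)
}

#' Restrict profiles to screening timepoints
#'
#' Picks, for each requested time, the nearest recorded frame (no
#' interpolation — measurements exist only on captured images). A request
#' beyond the recorded range (e.g. 40 s on a 0-39 s record) maps to the
#' nearest end and raises a clamp flag.
#'
#' @param profiles Long-format profile data frame (`particle_id`, `time_s`,
#'   `percent_remaining`, optionally `material`).
#' @param times Requested times in seconds; default screening set
#'   `c(0, 2, 4, 10, 20, 40)`.
#' @return Profile data frame restricted to the matched frames, with
#'   attribute `clamped` listing requested times that fell outside the
#'   record.
#' @export
sample_timepoints <- function(profiles, times = c(0, 2, 4, 10, 20, 40)) {
  if (length(times) == 0L) stop("empty timepoint request")
  rec <- sort(unique(profiles$time_s))
  clamped <- times[times < min(rec) | times > max(rec)]
  if (length(clamped))
    warning("requested time(s) outside the recorded range, clamped: ",
            paste(clamped, collapse = ", "))
  matched <- vapply(times, function(tt) rec[which.min(abs(rec - tt))],
                    numeric(1))
  out <- profiles[profiles$time_s %in% matched, , drop = FALSE]
  out <- out[order(out$particle_id, out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clamped") <- clamped
  out
}

profile_value_at <- function(times, values, at) {
  if (at > max(times) + 1e-9 || at < min(times) - 1e-9)
    stop(sprintf("profile does not cover t = %g s", at))
  values[which.min(abs(times - at))]
}

#' Summarize deformation profiles
#'
#' Reduces each particle's profile to the two screening summaries: the final
#' deformation `100 - percent_remaining` at `final_time` (default 39 s, the
#' last frame of a 40-frame 1 fps record indexed from 0) and the initial
#' deformation rate, the mean slope over the first `rate_window` seconds in
#' percentage points per second.
#'
#' @param profiles Long-format profile data frame.
#' @param final_time End-of-observation time in seconds (must be covered).
#' @param rate_window Initial-rate window in seconds.
#' @return Data frame `particle_id`, `material`, `final_deformation`,
#'   `initial_rate`.
#' @export
summarize_profiles <- function(profiles, final_time = 39, rate_window = 4) {
  stopifnot(rate_window > 0)
  ids <- unique(profiles$particle_id)
  rows <- lapply(ids, function(pid) {
    p <- profiles[profiles$particle_id == pid, , drop = FALSE]
    p <- p[order(p$time_s), , drop = FALSE]
    fin <- profile_value_at(p$time_s, p$percent_remaining, final_time)
    atw <- profile_value_at(p$time_s, p$percent_remaining, rate_window)
    data.frame(
      particle_id = pid,
      material = if ("material" %in% names(p)) p$material[1L]
                 else NA_character_,
      final_deformation = 100 - fin,
      initial_rate = (100 - atw) / rate_window,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Video-to-profile convenience wrapper
#'
#' Segments a video, tracks the particle seeded from the first frame's
#' segmentation (largest component), and returns its normalized deformation
#' profile.
#'
#' @param video A `synthetic_video` (or list of frames plus metadata).
#' @param params [segmentation_params()] for the classical chain.
#' @param method `"classical"` or `"model"`.
#' @param model Trained segmenter for `method = "model"`.
#' @param particle_id,material Labels carried into the profile.
#' @return Long-format profile data frame.
#' @export
video_profile <- function(video, params = segmentation_params(),
                          method = c("classical", "model"), model = NULL,
                          particle_id = NULL, material = NA_character_) {
  method <- match.arg(method)
  masks <- segment_video(video, params, method, model)
  st <- component_stats(masks[[1L]])
  if (is.null(st)) {
    # fall back to the most confident later frame for the seed
    nonempty <- which(vapply(masks, function(m) any(m > 0), logical(1)))
    if (!length(nonempty)) stop("tracking failure: no particle found")
    st <- component_stats(masks[[nonempty[1L]]])
  }
  k <- which.max(st$areas)
  seed_mask <- st$labels == k
  pid <- if (!is.null(particle_id)) particle_id
         else if (!is.null(video$particle_id)) video$particle_id
         else "particle"
  series <- track_particle(
    masks, seed_mask,
    pixel_scale = video$scene$pixel_scale,
    frame_interval = video$scene$frame_interval,
    particle_id = pid)
  normalize_profile(series, material = material)
}
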