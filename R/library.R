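#' Build direction-resolved (inhalation/exhalation) motion libraries
#'
#' Classifies every frame of the volume series by the diaphragm moving
#' direction from the previous timepoint: inhale when the position
#' decreases (diaphragm moving inferior), exhale when it increases; a
#' zero change inherits the previous label, and the first frame of each
#' series (no previous timepoint) inherits the label of the second. The
#' estimated displacement interval is the total motion range divided by
#' the mean number of entries per library.
#'
#' @param series list of `tr_series` (as from [generate_series()]).
#' @param waveforms list of extracted [breathing_waveform()]s (or bare
#'   numeric position vectors), one per series, supplying one diaphragm
#'   position per frame.
#' @param masks optional list (per series) of lists of 3D tumor masks to
#'   file in the library, e.g. from [segment_tumor()]; defaults to each
#'   frame's ground-truth `tumor_mask`.
#' @return object of class `motion_library`: `entries` (data frame with
#'   `series`, `frame_index`, `position`, `direction`, `entry_id`),
#'   `displacement_interval` (mm), and the stored masks.
#' @export
build_libraries <- function(series, waveforms, masks = NULL) {
  if (length(series) != length(waveforms)) {
    stop_invalid("need one waveform per series")
  }
  all_rows <- list()
  all_masks <- list()
  eid <- 0L
  for (s in seq_along(series)) {
    pos <- if (inherits(waveforms[[s]], "breathing_waveform")) {
      waveforms[[s]]$positions
    } else {
      as.numeric(waveforms[[s]])
    }
    nf <- length(series[[s]]$frames)
    if (length(pos) != nf) {
      stop_invalid("waveform length must equal the series frame count")
    }
    if (nf < 2) stop_invalid("series must have >= 2 frames")
    dir <- classify_direction(pos)
    msk <- if (is.null(masks)) {
      lapply(series[[s]]$frames, `[[`, "tumor_mask")
    } else {
      masks[[s]]
    }
    ids <- eid + seq_len(nf)
    eid <- eid + nf
    all_rows[[s]] <- data.frame(
      series = series[[s]]$series_id, frame_index = seq_len(nf),
      position = pos, direction = dir, entry_id = ids,
      stringsAsFactors = FALSE)
    all_masks[[s]] <- msk
  }
  entries <- do.call(rbind, all_rows)
  entries <- entries[order(entries$position), ]
  n_in <- sum(entries$direction == "inhale")
  n_ex <- sum(entries$direction == "exhale")
  interval <- (max(entries$position) - min(entries$position)) /
    mean(c(n_in, n_ex))
  structure(list(entries = entries,
                 displacement_interval = interval,
                 masks = unlist(all_masks, recursive = FALSE)),
            class = "motion_library")
}

#' Classify breathing direction from successive positions
#'
#' Brute direction labeling used by [build_libraries()]: decreasing SI
#' position is inhale, increasing is exhale, zero change inherits the
#' previous label, and the first sample inherits the second's label.
#'
#' @param pos numeric vector of diaphragm positions (length >= 2).
#' @return character vector of `"inhale"` / `"exhale"` labels.
#' @export
classify_direction <- function(pos) {
  n <- length(pos)
  if (n < 2) stop_invalid("need >= 2 positions to classify direction")
  d <- diff(pos)
  dir <- character(n)
  for (i in 2:n) {
    dir[i] <- if (d[i - 1] < 0) "inhale"
      else if (d[i - 1] > 0) "exhale"
      else if (nzchar(dir[i - 1])) dir[i - 1] else ""
  }
  # zero changes at the head inherit forward from the first signed move
  first_lab <- dir[which(nzchar(dir))[1]]
  if (is.na(first_lab)) stop_invalid("constant series has no direction")
  for (i in 2:n) if (!nzchar(dir[i])) dir[i] <- first_lab else break
  dir[1] <- dir[2]
  dir
}

#' @export
print.motion_library <- function(x, ...) {
  cat(sprintf("<motion_library> %d entries (inhale %d / exhale %d), interval %.3f mm, range %.1f mm\n",
              nrow(x$entries),
              sum(x$entries$direction == "inhale"),
              sum(x$entries$direction == "exhale"),
              x$displacement_interval,
              diff(range(x$entries$position))))
  invisible(x)
}

#' Identify the motion-matched, hysteresis-aware library entry
#'
#' The predicted moving direction first selects the inhalation or
#' exhalation library; the predicted diaphragm amplitude then selects
#' the entry with minimal absolute position difference (ties break
#' toward the smaller position). The matched-displacement decomposition
#' is populated as signed quantities: `dD_matching = predicted - entry`
#' and `dD_matched = dD_prediction + dD_matching`, so with
#' `dD_prediction = truth - predicted` the total is the net
#' truth-to-entry displacement error.
#'
#' @param pred_position predicted diaphragm position, mm.
#' @param pred_direction `"inhale"` or `"exhale"`.
#' @param lib a [build_libraries()] result.
#' @param dD_prediction signed prediction error (truth - predicted), mm.
#' @return object of class `match_result`: `entry` (1-row data frame),
#'   `predicted_position`, `dD_prediction`, `dD_matching`,
#'   `dD_matched`.
#' @export
match_library <- function(pred_position, pred_direction, lib,
                          dD_prediction = 0) {
  cand <- lib$entries[lib$entries$direction == pred_direction, ]
  if (nrow(cand) == 0) {
    stop("no-candidate: the ", pred_direction, " library is empty",
         call. = FALSE)
  }
  d <- abs(cand$position - pred_position)
  best <- which(d == min(d))
  if (length(best) > 1) {
    best <- best[which.min(cand$position[best])]  # tie toward smaller
  }
  entry <- cand[best, ]
  dD_matching <- pred_position - entry$position
  structure(list(entry = entry,
                 predicted_position = pred_position,
                 predicted_direction = pred_direction,
                 dD_prediction = dD_prediction,
                 dD_matching = dD_matching,
                 dD_matched = dD_prediction + dD_matching),
            class = "match_result")
}

#' Mask stored for a library entry
#'
#' @param lib a [build_libraries()] result.
#' @param entry a 1-row entry data frame (e.g. `match$entry`).
#' @return the 3D binary tumor mask of that entry.
#' @export
library_mask <- function(lib, entry) {
  lib$masks[[entry$entry_id]]
}

#' Inject a random prediction-library matching error
#'
#' Perturbs the matched diaphragm position with zero-mean uniform noise
#' of half-width `fraction * displacement_interval` and re-selects the
#' nearest entry in the same direction library, recomputing the
#' matched-displacement decomposition. Emulates the limited granularity
#' of a finite motion library.
#'
#' @param m a [match_library()] result.
#' @param fraction error fraction (e.g. 0.1 or 0.2); 0 returns `m`
#'   unchanged.
#' @param lib the [build_libraries()] result `m` came from.
#' @param seed integer seed (`NULL` draws from the current stream).
#' @return a new `match_result`.
#' @export
inject_matching_error <- function(m, fraction, lib, seed = 1L) {
  if (fraction < 0) stop_invalid("fraction must be >= 0")
  if (fraction == 0) return(m)
  hw <- fraction * lib$displacement_interval
  perturbed <- with_seed(seed, m$entry$position + runif(1, -hw, hw))
  m2 <- match_library(perturbed, m$predicted_direction, lib)
  structure(list(entry = m2$entry,
                 predicted_position = m$predicted_position,
                 predicted_direction = m$predicted_direction,
                 dD_prediction = m$dD_prediction,
                 dD_matching = m$predicted_position - m2$entry$position,
                 dD_matched = m$dD_prediction +
                   (m$predicted_position - m2$entry$position)),
            class = "match_result")
}
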