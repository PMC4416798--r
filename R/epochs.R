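# Batch and sliding-window epoch extraction with class and subclass
# labels. Windows are half-open [start, end) in samples; the onset
# sample belongs to the change-speed epoch.

.epoch_set <- function(data, label, subclass, session, trial, center,
                       window, fs, condition) {
  structure(list(data = data, label = label, subclass = subclass,
                 session = session, trial = trial, center = center,
                 window = window, fs = fs, condition = condition),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}

# slice one [start_s, end_s) window (relative to onset_s) out of a
# channels x samples matrix; NULL if out of range
.slice <- function(X, fs, onset_s, start_s, end_s) {
  len <- round((end_s - start_s) * fs)
  i0 <- round(onset_s * fs) + round(start_s * fs)   # 0-based first sample
  if (i0 < 0 || i0 + len > ncol(X)) return(NULL)
  X[, (i0 + 1):(i0 + len), drop = FALSE]
}

#' Batch epoch extraction
#'
#' Per speed-change onset, one change-speed epoch covering [-4, 4) s and
#' one constant-speed epoch covering [-12, -4) s relative to the onset.
#' The change epoch's subclass is the transition (e.g. "1->2"); the
#' constant epoch's subclass is the preceding plateau speed. Onsets
#' whose preceding constant period is shorter than 12 s (or that lie too
#' close to the recording edges) are skipped together with their
#' constant-speed partner, so classes stay balanced.
#'
#' @param rec An `eeg_recording` at the analysis rate.
#' @param events Event table (defaults to `rec$events`).
#' @param config Configuration list (epoch windows).
#' @return An `epoch_set` with balanced classes.
#' @export
extract_batch <- function(rec, events = NULL, config = default_config()) {
  if (is.null(events)) events <- rec$events
  ec <- config$epochs
  fs <- rec$fs
  chg <- ec$change_window
  cst <- ec$constant_window
  min_pre <- ec$min_preceding_s
  dat <- list(); lab <- c(); sub <- c(); cen <- c()
  dropped <- 0L
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]
    # time since the end of the previous transition's ramp
    if (i == 1) {
      pre <- on
    } else {
      prev_ramp <- if (events$to_kmh[i - 1] > events$from_kmh[i - 1])
        config$session$accel_s else config$session$decel_s
      pre <- on - (events$onset_s[i - 1] + prev_ramp)
    }
    e_chg <- .slice(rec$data, fs, on, chg[1], chg[2])
    e_cst <- .slice(rec$data, fs, on, cst[1], cst[2])
    if (pre < min_pre || is.null(e_chg) || is.null(e_cst)) {
      dropped <- dropped + 1L
      next
    }
    dat <- c(dat, list(e_chg, e_cst))
    lab <- c(lab, "change", "constant")
    sub <- c(sub, sprintf("%d->%d", events$from_kmh[i], events$to_kmh[i]),
             as.character(events$from_kmh[i]))
    cen <- c(cen, on, on)
  }
  if (length(dat) == 0) stop("no extractable trials in this recording")
  arr <- array(0, c(length(dat), nrow(rec$data), ncol(dat[[1]])))
  for (j in seq_along(dat)) arr[j, , ] <- dat[[j]]
  if (dropped > 0)
    message(sprintf("session %s: dropped %d trial pair(s) lacking %g s of preceding data",
                    rec$session_id, dropped, min_pre))
  .epoch_set(arr, lab, sub, rep(rec$session_id, length(lab)),
             trial = rep(seq_len(length(lab) / 2), each = 2),
             center = cen, window = list(change = chg, constant = cst),
             fs = fs, condition = rep(rec$condition, length(lab)))
}

#' Sliding-window epoch extraction for pseudo-online decoding
#'
#' Extracts 2 s epochs centred on a grid relative to each onset. In
#' train mode, 4 jittered windows per class per trial (change-speed
#' centres 0 to 1.5 s step 0.5 s; constant-speed centres -10 to -7 s
#' step 1 s). In test mode, 9 epochs per trial (change centres -1 to 3 s
#' step 0.5 s; constant centres -9 to -5 s step 0.5 s), grouped by
#' parent trial.
#'
#' @param rec An `eeg_recording` at the analysis rate.
#' @param events Event table (defaults to `rec$events`).
#' @param mode `"train"` or `"test"`.
#' @param config Configuration list (sliding grids).
#' @return An `epoch_set`; `trial` groups epochs by parent trial and
#'   `center` records each epoch's centre relative to its onset.
#' @export
extract_sliding <- function(rec, events = NULL, mode = c("train", "test"),
                            config = default_config()) {
  mode <- match.arg(mode)
  if (is.null(events)) events <- rec$events
  sl <- config$sliding
  ec <- config$epochs
  fs <- rec$fs
  half <- sl$window_s / 2
  centers <- if (mode == "train")
    list(change = sl$train_change_centers,
         constant = sl$train_constant_centers)
  else
    list(change = sl$test_change_centers,
         constant = sl$test_constant_centers)
  dat <- list(); lab <- c(); sub <- c(); trial <- c(); cen <- c()
  t_id <- 0L
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]
    if (i == 1) {
      pre <- on
    } else {
      prev_ramp <- if (events$to_kmh[i - 1] > events$from_kmh[i - 1])
        config$session$accel_s else config$session$decel_s
      pre <- on - (events$onset_s[i - 1] + prev_ramp)
    }
    if (pre < ec$min_preceding_s) next
    for (class in c("change", "constant")) {
      slices <- lapply(centers[[class]], function(c0)
        .slice(rec$data, fs, on, c0 - half, c0 + half))
      if (any(vapply(slices, is.null, TRUE))) next
      t_id <- t_id + 1L
      for (j in seq_along(slices)) {
        dat <- c(dat, slices[j])
        lab <- c(lab, class)
        sub <- c(sub, if (class == "change")
          sprintf("%d->%d", events$from_kmh[i], events$to_kmh[i])
          else as.character(events$from_kmh[i]))
        trial <- c(trial, t_id)
        cen <- c(cen, centers[[class]][j])
      }
    }
  }
  if (length(dat) == 0) stop("no extractable trials in this recording")
  arr <- array(0, c(length(dat), nrow(rec$data), ncol(dat[[1]])))
  for (j in seq_along(dat)) arr[j, , ] <- dat[[j]]
  .epoch_set(arr, lab, sub, rep(rec$session_id, length(lab)),
             trial = trial, center = cen,
             window = list(half = half, mode = mode), fs = fs,
             condition = rep(rec$condition, length(lab)))
}

#' Serialise an epoch set to a directory
#'
#' Writes one numeric matrix per epoch (plain TSV) and an index TSV.
#'
#' @param ep An `epoch_set`.
#' @param dir Output directory (created if needed).
#' @export
write_epoch_set <- function(ep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(ep$data)[1]
  idx <- data.frame(epoch = seq_len(n), label = ep$label,
                    subclass = ep$subclass, session = ep$session,
                    trial = ep$trial, center_s = ep$center,
                    condition = ep$condition)
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (j in seq_len(n)) {
    utils::write.table(ep$data[j, , ],
                       file.path(dir, sprintf("epoch_%04d.tsv", j)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
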