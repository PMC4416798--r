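# Cross-subject clustering of retained independent components and the
# two artifact quality-control analyses (channel r^2 matrices;
# retained-vs-rejected ERSP pairing).

#' Collect retained components of a batch run for clustering
#'
#' One member per (subject, fold, retained component): dipole location
#' and sign-aligned scalp map.
#'
#' @param batch A [run_batch()] result.
#' @return List with `subject`, `fold`, `component` vectors, `xyz`
#'   matrix and `maps` (members x channels).
#' @export
collect_cluster_members <- function(batch) {
  subject <- integer(0); fold <- integer(0); component <- integer(0)
  xyz <- NULL; maps <- NULL
  for (sub in batch$subjects) {
    s <- sub$cv$subject
    for (f in seq_along(sub$cv$folds)) {
      fb <- sub$cv$folds[[f]]
      for (k in fb$retained_ids) {
        fit <- fb$spatial$fits[[k]]
        m <- fb$spatial$model$scalp_maps[, k]
        # ICA sign is arbitrary: force the largest-|weight| channel positive
        m <- m * sign(m[which.max(abs(m))])
        subject <- c(subject, s); fold <- c(fold, f)
        component <- c(component, k)
        xyz <- rbind(xyz, fit$dipole$location)
        maps <- rbind(maps, m)
      }
    }
  }
  list(subject = subject, fold = fold, component = component,
       xyz = xyz, maps = maps)
}

#' Cluster independent components across subjects
#'
#' Each component is represented by its dipole coordinates plus the
#' principal components (90% variance) of its scalp map; both feature
#' blocks are z-scored. Robust k-means: members further than
#' `outlier_sd` SDs (of the within-cluster distance distribution) from
#' their centroid are removed and the centroids refit once. A subject
#' contributing fewer than `min_fold_frac` of their cross-validation
#' folds to a cluster is dropped from it, and clusters with fewer than
#' `min_subjects` subjects are dropped entirely.
#'
#' @param members A [collect_cluster_members()] result.
#' @param k Number of clusters requested (default 4).
#' @param outlier_sd Outlier threshold in SDs (default 5).
#' @param seed Integer seed for k-means initialisation.
#' @param n_folds Total folds per subject (default 10).
#' @param min_fold_frac Membership rule threshold (default 0.40).
#' @param min_subjects Minimum subjects per surviving cluster.
#' @param map_var Scalp-map PC variance fraction (default 0.90).
#' @return A `cluster_set`: `assignment` (0 = outlier or dropped),
#'   `centroids` (feature space), `centroid_xyz` (mm), `mean_maps`,
#'   `outlier` mask, `clusters` (surviving ids), `features`.
#' @export
cluster_components <- function(members, k = 4, outlier_sd = 5, seed = 1,
                               n_folds = 10, min_fold_frac = 0.40,
                               min_subjects = 2, map_var = 0.90) {
  n <- length(members$subject)
  if (n < k) stop("fewer members than requested clusters")
  pca <- fit_pca(members$maps, map_var)
  mp <- project_pca(members$maps, pca)
  zscore <- function(M) {
    s <- apply(M, 2, stats::sd)
    s[s == 0] <- 1
    sweep(sweep(M, 2, colMeans(M)), 2, s, "/")
  }
  feat <- cbind(zscore(members$xyz), zscore(mp))
  km <- .rng_local(seed, stats::kmeans(feat, centers = k, nstart = 10,
                                       iter.max = 50))
  assign <- km$cluster
  # robust step: drop members far from their centroid, refit once
  dist_to <- function(M, ctr, a) sqrt(rowSums((M - ctr[a, ])^2))
  d <- dist_to(feat, km$centers, assign)
  outlier <- rep(FALSE, n)
  for (cl in seq_len(k)) {
    sel <- assign == cl
    if (sum(sel) < 3) next
    # robust scale (median/MAD) so a single extreme member cannot mask
    # itself by inflating the spread estimate
    s_rob <- max(stats::mad(d[sel]), 1e-12)
    dz <- (d[sel] - stats::median(d[sel])) / s_rob
    outlier[sel][dz > outlier_sd] <- TRUE
  }
  centers <- km$centers
  for (cl in seq_len(k)) {
    sel <- assign == cl & !outlier
    if (any(sel)) centers[cl, ] <- colMeans(feat[sel, , drop = FALSE])
  }
  assign[outlier] <- 0L
  # membership rule: subjects must contribute >= 40% of their folds
  for (cl in seq_len(k)) {
    for (s in unique(members$subject)) {
      sel <- assign == cl & members$subject == s
      n_fold_s <- length(unique(members$fold[sel]))
      if (n_fold_s > 0 && n_fold_s < min_fold_frac * n_folds)
        assign[sel] <- 0L
    }
  }
  survivors <- integer(0)
  for (cl in seq_len(k)) {
    if (length(unique(members$subject[assign == cl])) >= min_subjects)
      survivors <- c(survivors, cl)
  }
  assign[!(assign %in% survivors)] <- 0L
  centroid_xyz <- NULL; mean_maps <- NULL
  for (cl in survivors) {
    sel <- assign == cl
    centroid_xyz <- rbind(centroid_xyz,
                          colMeans(members$xyz[sel, , drop = FALSE]))
    mean_maps <- rbind(mean_maps,
                       colMeans(members$maps[sel, , drop = FALSE]))
  }
  structure(list(assignment = assign, centroids = centers,
                 centroid_xyz = centroid_xyz, mean_maps = mean_maps,
                 outlier = outlier, clusters = survivors,
                 features = feat, members = members),
            class = "cluster_set")
}

#' Project a cluster centroid dorsally onto the cortex sphere
#'
#' For visualisation, a centroid inside the cortex sphere (58% of the
#' scalp sphere by default) is shifted straight upward until it
#' intercepts that sphere; a centroid on or outside it is returned
#' unchanged, as is (with a warning) one whose horizontal distance
#' already exceeds the cortex radius.
#'
#' @param xyz Centroid coordinates (mm).
#' @param cortex_fraction Cortex sphere radius as a fraction of the
#'   scalp radius (default 0.58).
#' @param scalp_radius Scalp sphere radius in mm (default 85).
#' @return Projected coordinates (mm).
#' @export
project_centroid_dorsal <- function(xyz, cortex_fraction = 0.58,
                                    scalp_radius = 85) {
  rc <- cortex_fraction * scalp_radius
  h2 <- xyz[1]^2 + xyz[2]^2
  if (h2 > rc^2) {
    warning("centroid lies outside the cortex cylinder; returned unchanged")
    return(xyz)
  }
  if (sum(xyz^2) >= rc^2) return(xyz)
  c(xyz[1], xyz[2], sqrt(rc^2 - h2))
}

#' Channel-correlation QC matrices by condition
#'
#' For every trial window the 64-channel Pearson correlation matrix of
#' the 1-45 Hz signal is squared; the r^2 matrices are averaged per
#' condition (standing-still = constant epochs at 0 km/h plateaus,
#' constant-speed = 1 and 2 km/h plateaus, change-speed = the batch
#' change windows), the three pairwise difference matrices are formed,
#' and each is summarised by the mean absolute difference over its
#' off-diagonal entries.
#'
#' @param recordings List of `eeg_recording`s (1-45 Hz, analysis rate).
#' @param config Configuration list.
#' @return A `qc_matrices`: `r2` (list of 3 matrices), `diff` (list of
#'   3), `mad` (named numeric).
#' @export
channel_correlation_qc <- function(recordings, config = default_config()) {
  sums <- list(standing = 0, constant = 0, change = 0)
  counts <- list(standing = 0, constant = 0, change = 0)
  for (rec in recordings) {
    ep <- extract_batch(rec, config = config)
    for (j in seq_len(dim(ep$data)[1])) {
      cond <- if (ep$label[j] == "change") "change"
              else if (ep$subclass[j] == "0") "standing"
              else "constant"
      r2 <- stats::cor(t(ep$data[j, , ]))^2
      sums[[cond]] <- sums[[cond]] + r2
      counts[[cond]] <- counts[[cond]] + 1
    }
  }
  if (any(unlist(counts) == 0))
    stop("every condition needs at least one trial window")
  r2 <- lapply(names(sums), function(nm) sums[[nm]] / counts[[nm]])
  names(r2) <- names(sums)
  pairs <- list(c("standing", "constant"), c("standing", "change"),
                c("constant", "change"))
  diffs <- list(); mads <- numeric(0)
  for (p in pairs) {
    dm <- r2[[p[1]]] - r2[[p[2]]]
    nm <- paste(p, collapse = "_vs_")
    diffs[[nm]] <- dm
    off <- dm[row(dm) != col(dm)]
    mads[nm] <- mean(abs(off))
  }
  structure(list(r2 = r2, diff = diffs, mad = mads,
                 n_trials = unlist(counts)),
            class = "qc_matrices")
}

#' Best retained-vs-rejected ERSP pair
#'
#' The rejected pool is restricted to well-localised far-field
#' components (radial fraction > 0.90, residual variance < 0.10,
#' posterior hemisphere x < 0). For every rejected x retained pair the
#' Pearson correlation of the flattened change-speed ERSPs is computed
#' and the highest-correlation pair returned.
#'
#' @param retained_ersps Named list of components x ERSP matrices
#'   (flattenable arrays) for retained components.
#' @param rejected_ersps Same for rejected components.
#' @param rejected_fits List of `dipole_fit`s matching
#'   `rejected_ersps`.
#' @param radial_min,rv_max,x_max Pool filters (defaults 0.90, 0.10, 0).
#' @return List with `pair` (names of the best rejected/retained pair),
#'   `correlation`, `n_eligible`; `pair = NULL` when no rejected
#'   component is eligible.
#' @export
retained_rejected_pairing <- function(retained_ersps, rejected_ersps,
                                      rejected_fits, radial_min = 0.90,
                                      rv_max = 0.10, x_max = 0) {
  eligible <- vapply(rejected_fits, function(f)
    f$radial_fraction > radial_min && f$residual_variance < rv_max &&
      f$dipole$location[1] < x_max, TRUE)
  if (!any(eligible))
    return(list(pair = NULL, correlation = NA_real_, n_eligible = 0L,
                message = "no eligible pair"))
  best <- NULL
  for (i in which(eligible)) {
    for (j in seq_along(retained_ersps)) {
      r <- stats::cor(as.numeric(rejected_ersps[[i]]),
                      as.numeric(retained_ersps[[j]]))
      if (is.null(best) || r > best$correlation)
        best <- list(pair = c(rejected = names(rejected_ersps)[i],
                              retained = names(retained_ersps)[j]),
                     correlation = r)
    }
  }
  best$n_eligible <- sum(eligible)
  best
}
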