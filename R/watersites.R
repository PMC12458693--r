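as_frame_matrix <- function(frames) {
  if (is.list(frames) && !is.data.frame(frames) && !is.matrix(frames)) {
    # list of per-frame (n_i x 3) matrices
    parts <- lapply(seq_along(frames), function(i) {
      m <- frames[[i]]
      if (is.null(m) || length(m) == 0) return(NULL)
      cbind(frame = i, matrix(as.numeric(m), ncol = 3))
    })
    out <- do.call(rbind, Filter(Negate(is.null), parts))
    if (is.null(out)) out <- matrix(numeric(0), ncol = 4)
    colnames(out) <- c("frame", "x", "y", "z")
    attr(out, "n_frames") <- length(frames)
    return(out)
  }
  m <- as.matrix(frames)
  stopifnot(ncol(m) == 4)
  colnames(m) <- c("frame", "x", "y", "z")
  m
}

#' Cluster sampled water positions into hydration sites
#'
#' Pools water oxygen positions over all frames and clusters them by
#' average-linkage hierarchical clustering cut at a fixed linkage distance
#' (default 2.4 Angstrom).  A site's occupancy is the fraction of frames
#' that contribute at least one member -- capped at 1 even if a cluster
#' transiently holds two waters.  Clusters are returned sorted by
#' occupancy, descending.
#'
#' @param frames a matrix with columns \code{frame, x, y, z} (as stored in
#'   a \code{gcmc_trajectory}), a \code{gcmc_trajectory}, or a list of
#'   per-frame coordinate matrices
#' @param cutoff linkage distance cutoff in Angstrom (default 2.4)
#' @param n_frames total number of frames (needed when trailing frames are
#'   empty; inferred otherwise)
#' @return a data frame of class \code{water_sites} with columns
#'   \code{x, y, z} (centroid), \code{occupancy}, \code{n_members};
#'   member frame indices in attribute \code{members}
#' @export
cluster_water_sites <- function(frames, cutoff = 2.4, n_frames = NULL) {
  if (inherits(frames, "gcmc_trajectory")) {
    n_frames <- n_frames %||% frames$n_frames
    frames <- frames$frames
  }
  m <- as_frame_matrix(frames)
  n_frames <- n_frames %||% attr(m, "n_frames") %||%
    (if (nrow(m)) max(m[, "frame"]) else 0)
  empty <- {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      occupancy = numeric(0), n_members = integer(0))
    attr(out, "members") <- list()
    attr(out, "n_frames") <- n_frames
    class(out) <- c("water_sites", "data.frame")
    out
  }
  if (nrow(m) == 0) return(empty)
  pts <- m[, c("x", "y", "z"), drop = FALSE]
  labels <- if (nrow(pts) == 1) {
    1L
  } else {
    cutree(hclust(dist(pts), method = "average"), h = cutoff)
  }
  ids <- sort(unique(labels))
  cent <- t(vapply(ids, function(k) colMeans(pts[labels == k, , drop = FALSE]),
                   numeric(3)))
  occ <- vapply(ids, function(k) {
    length(unique(m[labels == k, "frame"])) / n_frames
  }, numeric(1))
  nm <- vapply(ids, function(k) sum(labels == k), numeric(1))
  ord <- order(-occ, -nm)
  out <- data.frame(x = cent[ord, 1], y = cent[ord, 2], z = cent[ord, 3],
                    occupancy = occ[ord], n_members = as.integer(nm[ord]))
  attr(out, "members") <- lapply(ids[ord], function(k)
    unique(m[labels == k, "frame"]))
  attr(out, "n_frames") <- n_frames
  class(out) <- c("water_sites", "data.frame")
  out
}

#' Drop low-occupancy sites
#'
#' Keeps sites whose occupancy is at or above the threshold (inclusive:
#' "30\% or higher" keeps a site at exactly 0.30).
#'
#' @param clusters a \code{water_sites} table
#' @param threshold occupancy fraction in [0, 1] (default 0.30)
#' @return the filtered \code{water_sites} table
#' @export
filter_by_occupancy <- function(clusters, threshold = 0.30) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- clusters$occupancy >= threshold
  out <- clusters[keep, , drop = FALSE]
  attr(out, "members") <- attr(clusters, "members")[keep]
  attr(out, "n_frames") <- attr(clusters, "n_frames")
  class(out) <- class(clusters)
  out
}

#' True positive rate against crystallographic water sites
#'
#' Each crystallographic site is a true positive if at least one predicted
#' site lies within the distance threshold (inclusive), else a false
#' negative; TPR = TP / (TP + FN).  The match is per crystal site: one
#' predicted site may satisfy several crystal sites.
#'
#' @param predicted a \code{water_sites} table or a matrix of predicted
#'   centroids (n x 3)
#' @param crystal matrix (m x 3) of crystallographic water oxygens (m >= 1)
#' @param threshold match distance in Angstrom (default 1.5)
#' @return an object of class \code{site_comparison}: \code{tp}, \code{fn},
#'   \code{tpr}, \code{threshold} and a per-crystal-site match table
#' @export
true_positive_rate <- function(predicted, crystal, threshold = 1.5) {
  stopifnot(threshold > 0)
  crystal <- matrix(as.numeric(crystal), ncol = 3)
  if (nrow(crystal) == 0)
    stop("no crystallographic sites supplied; TPR is undefined")
  pred <- if (is.data.frame(predicted)) {
    as.matrix(predicted[, c("x", "y", "z"), drop = FALSE])
  } else {
    matrix(as.numeric(predicted), ncol = 3)
  }
  nearest <- vapply(seq_len(nrow(crystal)), function(i) {
    if (nrow(pred) == 0) return(Inf)
    min(sqrt(colSums((t(pred) - crystal[i, ])^2)))
  }, numeric(1))
  matched <- nearest <= threshold
  tab <- data.frame(crystal_site = seq_len(nrow(crystal)),
                    nearest_predicted = nearest, matched = matched)
  structure(list(tp = sum(matched), fn = sum(!matched),
                 tpr = mean(matched), threshold = threshold, matches = tab),
            class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("<site_comparison> TPR = %.3f (%d TP / %d crystal sites, threshold %.2f A)\n",
              x$tpr, x$tp, x$tp + x$fn, x$threshold))
  invisible(x)
}
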