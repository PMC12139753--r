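# Trajectory statistics: cluster identification, areas, the equilibration
# time t_c, the modal ("most possible") cluster-number pattern, dwelling
# times, neighbor counts and group comparisons.

#' Identify membrane clathrin clusters in a state
#'
#' Clusters are connected components of the clathrin-clathrin bond graph
#' restricted to membrane-associated clathrins; a component counts as a
#' cluster only if it has at least `min_cluster_size` members and is
#' anchored to the membrane through at least one AP-2.
#'
#' @param state An `fcl_state` frame.
#' @param min_cluster_size Minimum member count (default 5) below which a
#'   connected component is not reported as a cluster.
#' @param geom A [site_geometry()] used for the area computation.
#' @param pad_nm Hull dilation radius for [cluster_area()], nm.
#' @return A list of class `fcl_cluster_frame`: `frame_time_s`, `labels`
#'   (cluster id per clathrin, NA if not in a cluster), `cluster_sizes`,
#'   `cluster_areas_um2`, `n_membrane_clathrin`, `n_clusters`.
#' @export
identify_clusters <- function(state, min_cluster_size = 5,
                              geom = site_geometry(), pad_nm = 5) {
  n <- nrow(state$clat$pos)
  comp_id <- bond_components(state$clat$leg_bond)
  mem <- state$clat$comp == 1
  anchored <- tapply(state$clat$ap2_bond > 0, comp_id, any)
  labels <- rep(NA_integer_, n)
  sizes <- integer(0)
  areas <- numeric(0)
  next_id <- 0L
  for (cid in unique(comp_id[mem])) {
    members <- which(comp_id == cid & mem)
    if (length(members) < min_cluster_size) next
    if (!isTRUE(anchored[[as.character(cid)]])) next
    next_id <- next_id + 1L
    labels[members] <- next_id
    sizes[next_id] <- length(members)
    pts <- do.call(rbind, lapply(members, function(i) {
      s <- cpp_sites(state$clat$pos[i, ], state$clat$quat[i, ],
                     geom$leg_length_nm, geom$ap2_arm_length_nm)
      rbind(s[1:3, 1:2, drop = FALSE], state$clat$pos[i, 1:2])
    }))
    areas[next_id] <- cluster_area(pts, pad_nm) / 1e6   # nm^2 -> um^2
  }
  structure(list(frame_time_s = state$time,
                 labels = labels,
                 cluster_sizes = sizes,
                 cluster_areas_um2 = areas,
                 n_membrane_clathrin = sum(mem),
                 n_clusters = next_id),
            class = "fcl_cluster_frame")
}

# connected components over the leg-bond matrix (plain union-find)
bond_components <- function(leg_bond) {
  n <- nrow(leg_bond)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n))
    for (k in 1:3) {
      j <- leg_bond[i, k]
      if (j > i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  vapply(seq_len(n), find, integer(1))
}

#' Projected area of a cluster
#'
#' Area of the convex hull of the members' xy-projections (centers plus
#' leg sites), dilated by `pad`: hull area + perimeter * pad + pi * pad^2.
#' Degenerate point sets (single point, collinear) fall back to the
#' dilated segment/disc formula, which the general expression already
#' covers with zero hull area.
#'
#' @param xy k x 2 matrix of projected points (any length unit; the result
#'   is in that unit squared). The simulator works in nm.
#' @param pad Dilation radius in the same unit (default 5 nm, half the
#'   excluded-volume radius).
#' @return Scalar area.
#' @export
#' @examples
#' cluster_area(matrix(c(0, 0), 1), pad = 5)  # pi * 25 nm^2
cluster_area <- function(xy, pad = 5) {
  xy <- rbind(xy)
  if (nrow(xy) == 0) stop("cluster must have at least one member point")
  xy <- unique(xy)
  if (nrow(xy) == 1) return(pi * pad^2)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[h, 1]; hy <- xy[h, 2]
  k <- length(h)
  if (k < 3) {
    len <- max(stats::dist(xy))
    return(2 * len * pad + pi * pad^2)
  }
  j <- c(2:k, 1)
  area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  if (area < .Machine$double.eps * max(abs(c(hx, hy)))^2) {
    len <- max(stats::dist(xy))
    return(2 * len * pad + pi * pad^2)
  }
  perim <- sum(sqrt((hx[j] - hx)^2 + (hy[j] - hy)^2))
  area + perim * pad + pi * pad^2
}

#' Per-frame cluster summary table of a trajectory
#'
#' @param traj An `fcl_trajectory`.
#' @param min_cluster_size,pad_nm Passed to [identify_clusters()].
#' @param geom A [site_geometry()].
#' @return A data frame with one row per frame: `time_s`,
#'   `n_membrane_clathrin`, `n_clusters`, `total_area_um2`, `max_area_um2`.
#' @export
cluster_frames <- function(traj, min_cluster_size = traj$config$analysis$min_cluster_size,
                           pad_nm = traj$config$analysis$hull_pad_nm,
                           geom = do.call(site_geometry, traj$config$site_geometry)) {
  if (is.null(min_cluster_size)) min_cluster_size <- 5
  if (is.null(pad_nm)) pad_nm <- 5
  rows <- lapply(traj$frames, function(f) {
    cf <- identify_clusters(f, min_cluster_size, geom, pad_nm)
    data.frame(time_s = cf$frame_time_s,
               n_membrane_clathrin = cf$n_membrane_clathrin,
               n_clusters = cf$n_clusters,
               total_area_um2 = sum(cf$cluster_areas_um2),
               max_area_um2 = if (cf$n_clusters > 0) max(cf$cluster_areas_um2) else 0)
  })
  do.call(rbind, rows)
}

#' Equilibration time t_c
#'
#' The first time at which the membrane-bound clathrin count reaches 90%
#' of its value at `t_end`. If the final count is zero, `t_c = 0` by
#' convention.
#'
#' @param times Frame times, s.
#' @param counts Membrane-bound clathrin count per frame.
#' @param t_end End of the analysis window (default: last frame time).
#' @return `t_c` in seconds.
#' @export
compute_tc <- function(times, counts, t_end = max(times)) {
  if (!length(times)) stop("empty trace")
  stopifnot(length(times) == length(counts))
  end_count <- counts[which.min(abs(times - t_end))]
  if (end_count == 0) return(0)
  idx <- which(counts >= 0.9 * end_count & times <= t_end)
  if (!length(idx)) return(as.numeric(t_end))
  as.numeric(times[idx[1]])
}

#' Most possible pattern (modal cluster number)
#'
#' The cluster-number value with the highest frame frequency; ties go to
#' the smaller cluster number.
#'
#' @param series Integer vector of per-frame cluster numbers (post-t_c).
#' @return A list: `mode` (integer) and `frequency` (named numeric table
#'   of relative frequencies).
#' @export
most_possible_pattern <- function(series) {
  if (!length(series)) stop("need at least one frame")
  tab <- table(series) / length(series)
  vals <- as.integer(names(tab))
  best <- vals[tab == max(tab)]
  list(mode = min(best), frequency = tab)
}

#' Dwelling-time segments of a cluster-number series
#'
#' Run-length encodes the series; each run's duration is its length times
#' the frame interval. The first and last segments touch the trace
#' boundary and are flagged censored (their true duration is unknown);
#' mean dwelling times exclude censored segments by default.
#'
#' @param series Integer vector of per-frame cluster numbers, uniformly
#'   sampled.
#' @param frame_interval Frame spacing, s.
#' @return A data frame: `value`, `duration_s`, `censored`.
#' @export
dwell_segments <- function(series, frame_interval) {
  if (!length(series)) return(data.frame(value = integer(0),
                                         duration_s = numeric(0),
                                         censored = logical(0)))
  r <- rle(as.integer(series))
  k <- length(r$values)
  data.frame(value = r$values,
             duration_s = r$lengths * frame_interval,
             censored = seq_len(k) %in% c(1L, k))
}

#' Summary metrics of a trajectory
#'
#' Computes `t_c` from the membrane-bound clathrin trace, restricts to
#' post-`t_c` frames, and reports the modal cluster number, the mean over
#' modal-pattern frames of the mean cluster size (total area / cluster
#' count), the mean dwelling time of the modal pattern (censored boundary
#' segments excluded), and the three frequency histograms.
#'
#' @param x An `fcl_trajectory`, or a per-frame data frame with columns
#'   `time_s`, `n_membrane_clathrin`, `n_clusters`, `total_area_um2`
#'   (as produced by [cluster_frames()] or [make_cluster_trace()]).
#' @param ... Passed to [cluster_frames()] for trajectory input.
#' @param t_end End of the analysis window, s (default: last frame).
#' @return A list of class `fcl_metrics`: `t_c_s`, `modal_cluster_number`,
#'   `mean_mean_cluster_size_um2`, `mean_dwelling_time_s`, `histograms`
#'   (`cluster_number`, `mean_size_um2`, `dwelling_time_s`), and
#'   `n_frames_post_tc`.
#' @export
summarize_trajectory <- function(x, ..., t_end = NULL) {
  frames <- if (inherits(x, "fcl_trajectory")) cluster_frames(x, ...) else as.data.frame(x)
  need <- c("time_s", "n_membrane_clathrin", "n_clusters", "total_area_um2")
  missing_cols <- setdiff(need, names(frames))
  if (length(missing_cols))
    stop("missing frame columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(t_end)) t_end <- max(frames$time_s)
  tc <- compute_tc(frames$time_s, frames$n_membrane_clathrin, t_end)
  post <- frames[frames$time_s >= tc & frames$time_s <= t_end, , drop = FALSE]
  if (!nrow(post)) stop("no frames after t_c")
  mpp <- most_possible_pattern(post$n_clusters)
  modal <- post[post$n_clusters == mpp$mode, , drop = FALSE]
  mean_sizes <- if (mpp$mode > 0) modal$total_area_um2 / modal$n_clusters else numeric(0)
  if (length(unique(diff(post$time_s))) > 1 &&
      diff(range(diff(post$time_s))) > 1e-9 * max(diff(post$time_s)))
    warning("post-t_c frames are not uniformly sampled; dwell times use the median interval")
  fi <- stats::median(diff(post$time_s))
  segs <- dwell_segments(post$n_clusters, fi)
  modal_segs <- segs[segs$value == mpp$mode, , drop = FALSE]
  open_segs <- modal_segs[!modal_segs$censored, , drop = FALSE]
  structure(list(
    t_c_s = tc,
    modal_cluster_number = mpp$mode,
    mean_mean_cluster_size_um2 = if (length(mean_sizes)) mean(mean_sizes) else NA_real_,
    mean_dwelling_time_s = if (nrow(open_segs)) mean(open_segs$duration_s) else NA_real_,
    histograms = list(cluster_number = mpp$frequency,
                      mean_size_um2 = mean_sizes,
                      dwelling_time_s = modal_segs),
    n_frames_post_tc = nrow(post)
  ), class = "fcl_metrics")
}

#' @export
print.fcl_metrics <- function(x, ...) {
  cat(sprintf(paste0("<fcl_metrics> t_c = %.3g s | modal cluster number = %d | ",
                     "mean cluster size = %.4g um^2 | mean dwell = %.3g s\n"),
              x$t_c_s, x$modal_cluster_number,
              x$mean_mean_cluster_size_um2, x$mean_dwelling_time_s))
  invisible(x)
}

#' Neighbor counts in a square window
#'
#' For every point, the number of *other* points inside the axis-aligned
#' `window` x `window` square centered on it.
#'
#' @param xy n x 2 matrix of centroids, um.
#' @param window Window side length, um (default 1).
#' @return Integer vector of per-point counts.
#' @export
neighbor_counts <- function(xy, window = 1) {
  xy <- rbind(xy)
  if (!nrow(xy)) stop("need at least one point")
  half <- window / 2
  vapply(seq_len(nrow(xy)), function(i) {
    inside <- abs(xy[, 1] - xy[i, 1]) <= half & abs(xy[, 2] - xy[i, 2]) <= half
    sum(inside) - 1L
  }, integer(1))
}

#' Box-plot summary of cluster areas
#'
#' Median and quartiles use linear interpolation (quantile type 7).
#' Whiskers extend to the most extreme data inside the Tukey 1.5 IQR
#' fences; anything beyond is listed as an outlier.
#'
#' @param areas Numeric vector of areas (um^2), length >= 1.
#' @return A list: `median`, `q25`, `q75`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
area_stats <- function(areas) {
  if (!length(areas)) stop("need at least one area")
  q <- stats::quantile(areas, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- areas >= lo & areas <= hi
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(areas[inside]), whisker_high = max(areas[inside]),
       outliers = sort(areas[!inside]), n = length(areas))
}

#' Unpaired two-sample comparison of replicate metrics
#'
#' Welch's unpaired t-test by default; set `var_equal = TRUE` for the
#' classical Student's test.
#'
#' @param a,b Numeric vectors of per-replicate metric values (length >= 2).
#' @param var_equal Assume equal variances (Student) instead of Welch.
#' @return A list with `statistic` (t), `p_value` and `df`.
#' @export
compare_groups <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both groups have zero variance; t-test undefined")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}
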