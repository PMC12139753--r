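# Persistence: tabular trajectory round-trip (CSV dialect: UTF-8, '.'
# decimal, header row) and run manifests for provenance.

#' Write a trajectory to a directory
#'
#' Writes `frames.csv` (one row per molecule per frame), `bonds.csv`
#' (one row per bond per frame; site ids encode `(molecule - 1) * 4 +
#' site`, AP-2 partners as negative AP-2 indices), `events.csv`,
#' `config.json` and `manifest.json`.
#'
#' @param traj An `fcl_trajectory`.
#' @param dir Output directory (created if absent).
#' @param seed Seed recorded in the manifest (provenance only).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- do.call(rbind, lapply(traj$frames, frame_to_table))
  bonds <- do.call(rbind, lapply(traj$frames, frame_bonds_table))
  utils::write.csv(frames, file.path(dir, "frames.csv"), row.names = FALSE)
  utils::write.csv(bonds, file.path(dir, "bonds.csv"), row.names = FALSE)
  utils::write.csv(traj$events, file.path(dir, "events.csv"), row.names = FALSE)
  save_config(traj$config, file.path(dir, "config.json"))
  manifest <- list(
    config_hash = unname(tools::md5sum(file.path(dir, "config.json"))),
    seed = seed,
    code_version = as.character(utils::packageVersion("fclsim")),
    written_utc = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_frames = length(traj$frames),
    skipped_moves = traj$skipped_moves,
    files = c("frames.csv", "bonds.csv", "events.csv", "config.json"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

frame_to_table <- function(f) {
  n <- nrow(f$clat$pos)
  m <- nrow(f$ap2$pos)
  rbind(
    data.frame(frame_time_s = f$time, molecule_id = seq_len(n),
               type = "clathrin",
               x_nm = f$clat$pos[, 1], y_nm = f$clat$pos[, 2],
               z_nm = f$clat$pos[, 3],
               qw = f$clat$quat[, 1], qx = f$clat$quat[, 2],
               qy = f$clat$quat[, 3], qz = f$clat$quat[, 4],
               compartment = ifelse(f$clat$comp == 1, "membrane", "cytosol")),
    data.frame(frame_time_s = f$time, molecule_id = seq_len(m),
               type = "ap2",
               x_nm = f$ap2$pos[, 1], y_nm = f$ap2$pos[, 2], z_nm = 0,
               qw = 1, qx = 0, qy = 0, qz = 0,
               compartment = "membrane"))
}

frame_bonds_table <- function(f) {
  n <- nrow(f$clat$pos)
  rows <- list()
  for (i in seq_len(n)) {
    for (k in 1:3) {
      j <- f$clat$leg_bond[i, k]
      if (j > i) {
        ks <- f$clat$leg_bond_site[i, k]
        rows[[length(rows) + 1]] <- data.frame(
          frame_time_s = f$time,
          site_a = (i - 1L) * 4L + k, site_b = (j - 1L) * 4L + ks)
      }
    }
    a <- f$clat$ap2_bond[i]
    if (a > 0)
      rows[[length(rows) + 1]] <- data.frame(
        frame_time_s = f$time, site_a = (i - 1L) * 4L + 4L, site_b = -a)
  }
  if (!length(rows))
    return(data.frame(frame_time_s = numeric(0), site_a = integer(0),
                      site_b = integer(0)))
  do.call(rbind, rows)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param dir Directory containing the trajectory tables.
#' @return An `fcl_trajectory` equal, field for field, to the one
#'   written.
#' @export
read_trajectory <- function(dir) {
  for (fn in c("frames.csv", "bonds.csv", "events.csv", "config.json"))
    if (!file.exists(file.path(dir, fn)))
      stop("missing trajectory file: ", fn)
  frames_tab <- utils::read.csv(file.path(dir, "frames.csv"))
  bonds_tab <- utils::read.csv(file.path(dir, "bonds.csv"))
  events <- utils::read.csv(file.path(dir, "events.csv"))
  config <- load_config(file.path(dir, "config.json"))
  num_cols <- c("frame_time_s", "x_nm", "y_nm", "z_nm", "qw", "qx", "qy", "qz")
  if (anyNA(frames_tab[num_cols]))
    stop("malformed frames.csv at frame index ",
         findInterval(min(which(rowSums(is.na(frames_tab[num_cols])) > 0)),
                      cumsum(table(frames_tab$frame_time_s))) + 1)
  times <- unique(frames_tab$frame_time_s)
  counts <- table(frames_tab$frame_time_s)
  if (length(unique(counts)) > 1)
    stop("truncated frames.csv: last good frame index ",
         sum(counts == counts[1]))
  frames <- lapply(seq_along(times), function(fi) {
    tt <- times[fi]
    sub <- frames_tab[frames_tab$frame_time_s == tt, , drop = FALSE]
    cl <- sub[sub$type == "clathrin", , drop = FALSE]
    ap <- sub[sub$type == "ap2", , drop = FALSE]
    cl <- cl[order(cl$molecule_id), , drop = FALSE]
    ap <- ap[order(ap$molecule_id), , drop = FALSE]
    n <- nrow(cl)
    leg_bond <- matrix(0L, n, 3)
    leg_bond_site <- matrix(0L, n, 3)
    ap2_bond <- integer(n)
    ap2_partner <- integer(nrow(ap))
    bsub <- bonds_tab[bonds_tab$frame_time_s == tt, , drop = FALSE]
    for (r in seq_len(nrow(bsub))) {
      sa <- bsub$site_a[r]; sb <- bsub$site_b[r]
      i <- (sa - 1L) %/% 4L + 1L
      ki <- (sa - 1L) %% 4L + 1L
      if (sb < 0) {                      # clathrin arm -- AP-2
        ap2_bond[i] <- -sb
        ap2_partner[-sb] <- i
      } else {
        j <- (sb - 1L) %/% 4L + 1L
        kj <- (sb - 1L) %% 4L + 1L
        leg_bond[i, ki] <- j; leg_bond_site[i, ki] <- kj
        leg_bond[j, kj] <- i; leg_bond_site[j, kj] <- ki
      }
    }
    sim_state(as.matrix(cl[, c("x_nm", "y_nm", "z_nm")]),
              as.matrix(cl[, c("qw", "qx", "qy", "qz")]),
              as.integer(cl$compartment == "membrane"),
              as.matrix(ap[, c("x_nm", "y_nm")]),
              leg_bond, leg_bond_site, ap2_bond, ap2_partner,
              time = tt)
  })
  structure(list(frames = frames, events = events, config = config,
                 skipped_moves = NA, placement_rejects = NA),
            class = "fcl_trajectory")
}

#' Read a standalone centroid/area table
#'
#' CSV with columns `x_um`, `y_um`, `area_um2`, as produced by external
#' segmentations, for use with [neighbor_counts()] and [area_stats()].
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_centroid_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("x_um", "y_um", "area_um2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Write a metrics report as JSON plus tidy CSV histograms
#'
#' @param metrics An `fcl_metrics` object.
#' @param dir Output directory.
#' @param min_cluster_size Reported in the JSON header for provenance.
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(metrics, dir, min_cluster_size = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    min_cluster_size = min_cluster_size,
    t_c_s = metrics$t_c_s,
    modal_cluster_number = metrics$modal_cluster_number,
    mean_mean_cluster_size_um2 = metrics$mean_mean_cluster_size_um2,
    mean_dwelling_time_s = metrics$mean_dwelling_time_s,
    n_frames_post_tc = metrics$n_frames_post_tc
  ), file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  freq <- metrics$histograms$cluster_number
  utils::write.csv(data.frame(cluster_number = as.integer(names(freq)),
                              frequency = as.numeric(freq)),
                   file.path(dir, "hist_cluster_number.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mean_size_um2 = metrics$histograms$mean_size_um2),
                   file.path(dir, "hist_mean_size.csv"), row.names = FALSE)
  utils::write.csv(metrics$histograms$dwelling_time_s,
                   file.path(dir, "hist_dwelling_time.csv"), row.names = FALSE)
  invisible(dir)
}
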