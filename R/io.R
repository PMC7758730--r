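# Persistence: HDF5 for movies/stores/spikes (mirroring the deposited
# "SVD-compressed format"), CSV for trial tables and pupil traces, YAML for
# configurations and ROI sets.

#' @noRd
h5_fresh <- function(path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
}

#' Write / read an SVD store to HDF5
#'
#' Layout: /U (pixels x k), /V (k x time), /sv, /timestamps, and a /meta
#' group with pixel_shape, k and channel_tag. This is the package's
#' interchange format for compressed movies.
#'
#' @param store an \code{svd_store}.
#' @param path HDF5 file path.
#' @return \code{write_svd_store_h5}: the path, invisibly;
#'   \code{read_svd_store_h5}: an \code{svd_store}.
#' @export
write_svd_store_h5 <- function(store, path) {
  h5_fresh(path)
  rhdf5::h5write(store$U, path, "U")
  rhdf5::h5write(store$V, path, "V")
  rhdf5::h5write(store$sv, path, "sv")
  rhdf5::h5write(store$timestamps, path, "timestamps")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(store$pixel_shape, path, "meta/pixel_shape")
  rhdf5::h5write(store$k, path, "meta/k")
  rhdf5::h5write(store$channel, path, "meta/channel_tag")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_svd_store_h5
#' @export
read_svd_store_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  svd_store(rhdf5::h5read(path, "U"), rhdf5::h5read(path, "V"),
            as.numeric(rhdf5::h5read(path, "sv")),
            as.numeric(rhdf5::h5read(path, "timestamps")),
            as.integer(rhdf5::h5read(path, "meta/pixel_shape")),
            channel = as.character(rhdf5::h5read(path, "meta/channel_tag")))
}

#' Write / read a raw dual-channel movie to HDF5
#'
#' Layout: /calcium and /hemo (pixels x time, row-major pixel order),
#' /timestamps_cal, /timestamps_hemo, /meta (fs, pixel_shape).
#'
#' @param movie a \code{widefield_movie}.
#' @param path HDF5 file path.
#' @export
write_movie_h5 <- function(movie, path) {
  h5_fresh(path)
  rhdf5::h5write(movie$calcium_frames, path, "calcium")
  rhdf5::h5write(movie$hemo_frames, path, "hemo")
  rhdf5::h5write(movie$timestamps_cal, path, "timestamps_cal")
  rhdf5::h5write(movie$timestamps_hemo, path, "timestamps_hemo")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(movie$fs, path, "meta/fs")
  rhdf5::h5write(movie$pixel_shape, path, "meta/pixel_shape")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_movie_h5
#' @export
read_movie_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  structure(list(calcium_frames = rhdf5::h5read(path, "calcium"),
                 hemo_frames = rhdf5::h5read(path, "hemo"),
                 timestamps_cal = as.numeric(rhdf5::h5read(path, "timestamps_cal")),
                 timestamps_hemo = as.numeric(rhdf5::h5read(path, "timestamps_hemo")),
                 fs = as.numeric(rhdf5::h5read(path, "meta/fs")),
                 pixel_shape = as.integer(rhdf5::h5read(path, "meta/pixel_shape"))),
            class = "widefield_movie")
}

#' Write / read spike and LFP data to HDF5
#'
#' Layout: /spikes/times, /spikes/clusters, /spikes/depths, /lfp (channels x
#' time), /lfp_fs, /light_onsets.
#'
#' @param spikes a \code{spike_data}.
#' @param path HDF5 file path.
#' @export
write_spikes_h5 <- function(spikes, path) {
  h5_fresh(path)
  rhdf5::h5createGroup(path, "spikes")
  rhdf5::h5write(spikes$spike_times_s, path, "spikes/times")
  rhdf5::h5write(spikes$cluster_ids, path, "spikes/clusters")
  rhdf5::h5write(spikes$cluster_depths, path, "spikes/depths")
  rhdf5::h5write(spikes$lfp, path, "lfp")
  rhdf5::h5write(spikes$lfp_fs, path, "lfp_fs")
  rhdf5::h5write(spikes$light_onsets_s, path, "light_onsets")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_spikes_h5
#' @export
read_spikes_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  structure(list(spike_times_s = as.numeric(rhdf5::h5read(path, "spikes/times")),
                 cluster_ids = as.integer(rhdf5::h5read(path, "spikes/clusters")),
                 cluster_depths = as.numeric(rhdf5::h5read(path, "spikes/depths")),
                 lfp = rhdf5::h5read(path, "lfp"),
                 lfp_fs = as.numeric(rhdf5::h5read(path, "lfp_fs")),
                 light_onsets_s = as.numeric(rhdf5::h5read(path, "light_onsets"))),
            class = "spike_data")
}

#' Write / read a trial table as CSV
#'
#' Columns are the trial-event schema used throughout the package:
#' iti_start_s, quiescent_start_s, quiescent_end_s, stim_onset_s, gocue_s,
#' response_window_end_s, response_s, response_direction, outcome,
#' contrast_left, contrast_right, rewarded, session_id, subject_id,
#' genotype_id.
#'
#' @param trials trial table data.frame.
#' @param path CSV file path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a pupil trace as CSV (timestamps_s, diameter, derivative)
#' @param pupil a \code{pupil_trace}.
#' @param path CSV file path.
#' @export
write_pupil_csv <- function(pupil, path) {
  utils::write.csv(data.frame(timestamps_s = pupil$timestamps_s,
                              diameter = pupil$diameter,
                              derivative = pupil$derivative),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pupil_csv
#' @export
read_pupil_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(as.list(df), class = "pupil_trace")
}

#' Round-trip a simulation configuration through YAML
#' @param config a \code{sim_config}.
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Round-trip an ROI set through YAML (name: [row, col], 0-based)
#' @param rois a \code{roi_set} or named list of (row, col) pairs.
#' @param path YAML file path.
#' @export
write_roi_set <- function(rois, path) {
  yaml::write_yaml(lapply(unclass(rois), as.integer), path)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  structure(lapply(yaml::read_yaml(path), as.integer), class = "roi_set")
}
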