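#' Write a recording to flat binary with a JSON sidecar
#'
#' The on-disk container is a raw little-endian binary file of
#' channel-interleaved frames (all channels at sample 1, then sample 2,
#' ...) plus a `<path>.json` sidecar holding the sampling rate, shape,
#' dtype, units and provenance — the sidecar is authoritative and a
#' recording can never be read without one (the sampling rate is never
#' guessed). `float32` stores microvolts directly; `int16` stores
#' `round(uV / scale_uV_per_lsb)` counts.
#'
#' @param rec A `"recording"`.
#' @param path Output file path (sidecar written at `<path>.json`).
#' @param dtype `"float32"` or `"int16"`.
#' @param scale_uV_per_lsb Microvolts per count for `int16` (default
#'   0.195, a common acquisition LSB).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dtype = c("float32", "int16"),
                            scale_uV_per_lsb = 0.195) {
  stopifnot(inherits(rec, "recording"))
  dtype <- match.arg(dtype)
  con <- file(path, "wb")
  on.exit(close(con))
  if (dtype == "float32") {
    writeBin(as.numeric(rec$signal), con, size = 4L, endian = "little")
  } else {
    counts <- as.integer(round(rec$signal / scale_uV_per_lsb))
    if (any(abs(counts) > 32767L)) stop("signal exceeds int16 range at this LSB")
    writeBin(counts, con, size = 2L, endian = "little")
  }
  meta <- list(
    fs_hz = rec$fs,
    n_channels = nrow(rec$signal),
    n_samples = ncol(rec$signal),
    dtype = dtype,
    units = rec$units %||% "uV",
    order = "interleaved",
    channel_ids = rec$channel_ids,
    provenance = rec$meta %||% list()
  )
  if (dtype == "int16") meta$scale_uV_per_lsb <- scale_uV_per_lsb
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Binary file path; `<path>.json` must exist.
#' @return A `"recording"` in microvolts.
#' @export
read_recording <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("sidecar lacks fs_hz; refusing to guess")
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- if (meta$dtype == "float32") {
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  } else if (meta$dtype == "int16") {
    if (is.null(meta$scale_uV_per_lsb)) stop("int16 sidecar lacks scale_uV_per_lsb")
    readBin(con, "integer", n = n, size = 2L, signed = TRUE,
            endian = "little") * meta$scale_uV_per_lsb
  } else {
    stop("unknown dtype: ", meta$dtype)
  }
  structure(
    list(signal = matrix(sig, nrow = meta$n_channels),
         fs = meta$fs_hz,
         channel_ids = meta$channel_ids %||% seq_len(meta$n_channels),
         units = meta$units %||% "uV",
         meta = meta$provenance),
    class = "recording"
  )
}

#' Write spike trains to CSV
#'
#' Columns: `channel`, `unit`, `sample_index` (0-based, per the file
#' convention; the in-memory API is 1-based), `time_s`
#' (`sample_index / fs`, 9 decimals). Rows are ordered by channel,
#' unit, then time.
#'
#' @param trains Data frame with `channel`, `sample` (1-based) and
#'   optionally `unit` — e.g. the `spikes` element of a ground truth.
#' @param path Output CSV path.
#' @param fs Sampling rate, Hz.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path, fs) {
  trains <- as.data.frame(trains)
  if (is.null(trains$unit)) trains$unit <- 1L
  req <- c("channel", "unit", "sample")
  if (!all(req %in% names(trains))) stop("trains needs channel, unit, sample")
  for (g in split(trains$sample,
                  interaction(trains$channel, trains$unit, drop = TRUE))) {
    if (is.unsorted(g, strictly = TRUE)) {
      stop("spike times must be strictly increasing per unit")
    }
  }
  trains <- trains[order(trains$channel, trains$unit, trains$sample), ,
                   drop = FALSE]
  out <- data.frame(
    channel = trains$channel,
    unit = trains$unit,
    sample_index = trains$sample - 1L,
    time_s = sprintf("%.9f", (trains$sample - 1L) / fs)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#'
#' @param path CSV path.
#' @return Data frame with `channel`, `unit`, `sample` (1-based),
#'   `time_s`.
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.csv(path)
  data.frame(channel = df$channel, unit = df$unit,
             sample = df$sample_index + 1L, time_s = df$time_s)
}

#' Save / load a network checkpoint
#'
#' Parameters are written as little-endian float64 in declaration
#' order, with a JSON sidecar carrying the model configuration and
#' every parameter's name and dimensions, so a checkpoint fully
#' round-trips.
#'
#' @param net A `"swin1d_net"`.
#' @param path Binary checkpoint path (sidecar at `<path>.json`).
#' @return `path` (`save_model`) or the rebuilt network (`load_model`).
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "swin1d_net"))
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in net$params) writeBin(as.numeric(p), con, size = 8L, endian = "little")
  meta <- list(
    class = "swin1d_net",
    config = unclass(net$config),
    params = lapply(net$params, function(p) as.integer(dim(p) %||% length(p)))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(swin1d_config, meta$config[c("T", "C", "n_rstb", "n_stl",
                                              "kernel", "heads",
                                              "attn_window", "mlp_ratio")])
  con <- file(path, "rb")
  on.exit(close(con))
  params <- list()
  for (nm in names(meta$params)) {
    dims <- meta$params[[nm]]
    vals <- readBin(con, "numeric", n = prod(dims), size = 8L,
                    endian = "little")
    params[[nm]] <- if (length(dims) > 1L) array(vals, dims) else vals
  }
  structure(list(config = cfg, params = params), class = "swin1d_net")
}

# Persist a list of normalized pairs: per channel, lpf then hpf blocks
# of float64, with one JSON sidecar for scales and preprocessing
# provenance.
#' Write / read preprocessed pairs
#'
#' Stores a list of `"normalized_pair"` objects (all the same length)
#' as consecutive float64 blocks — per electrode, the normalised
#' interpolated low-pass input then the normalised high-pass ground
#' truth — with a JSON sidecar recording `fs`, per-electrode `scale`
#' and `sigma`, and the preprocessing settings (`M`, `L`, `cutoff`,
#' `mode`).
#'
#' @param pairs List of `"normalized_pair"` objects.
#' @param path Binary path (sidecar at `<path>.json`).
#' @return `path` / the list of pairs.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(length(pairs) > 0L)
  ns <- vapply(pairs, function(p) length(p$hpf_gt), integer(1))
  if (length(unique(ns)) != 1L) stop("pairs must share one length")
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in pairs) {
    writeBin(as.numeric(p$lpf_input), con, size = 8L, endian = "little")
    writeBin(as.numeric(p$hpf_gt), con, size = 8L, endian = "little")
  }
  meta <- list(
    n_channels = length(pairs),
    n_samples = ns[1],
    fs = pairs[[1]]$fs,
    scale = vapply(pairs, function(p) p$scale, numeric(1)),
    sigma = vapply(pairs, function(p) p$sigma, numeric(1)),
    electrode_id = lapply(pairs, function(p) p$electrode_id),
    M = attr(pairs[[1]], "M"), L = attr(pairs[[1]], "L"),
    cutoff = attr(pairs[[1]], "cutoff"), mode = attr(pairs[[1]], "mode")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  n <- meta$n_samples
  pairs <- vector("list", meta$n_channels)
  for (k in seq_len(meta$n_channels)) {
    lpf <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
    hpf <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
    pr <- structure(
      list(lpf_input = lpf, hpf_gt = hpf, scale = meta$scale[k],
           sigma = meta$sigma[k], fs = meta$fs,
           electrode_id = meta$electrode_id[[k]]),
      class = "normalized_pair"
    )
    attr(pr, "M") <- meta$M; attr(pr, "L") <- meta$L
    attr(pr, "cutoff") <- meta$cutoff; attr(pr, "mode") <- meta$mode
    pairs[[k]] <- pr
  }
  pairs
}
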