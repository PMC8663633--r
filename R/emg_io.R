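#' Construct a channel label
#'
#' Channels are identified by body side and muscle. Four lower-limb muscles
#' are supported: tibialis anterior (TA), soleus (SOL), rectus femoris (RF)
#' and semitendinosus (ST). For stroke patients a channel additionally
#' carries its clinical role (paretic or non-paretic side); healthy subjects
#' have no paretic side and use role \code{"NA"}.
#'
#' @param side "L" or "R".
#' @param muscle one of "TA", "SOL", "RF", "ST".
#' @param role "PARETIC", "NON_PARETIC" or "NA".
#' @return a \code{channel_label} object; its character form is
#'   \code{"SIDE_MUSCLE"}, e.g. \code{"L_SOL"}.
#' @export
channel_label <- function(side, muscle, role = "NA") {
  side <- toupper(side)
  if (side %in% c("LEFT", "RIGHT")) side <- substr(side, 1, 1)
  assert_that(side %in% SIDES, "unknown_side", "unknown side '%s'", side)
  assert_that(muscle %in% MUSCLES, "unknown_muscle",
              "unknown muscle '%s' (expected TA, SOL, RF or ST)", muscle)
  assert_that(role %in% c("PARETIC", "NON_PARETIC", "NA"), "bad_role",
              "unknown role '%s'", role)
  structure(list(side = side, muscle = muscle, role = role),
            class = "channel_label")
}

#' @export
format.channel_label <- function(x, ...) paste(x$side, x$muscle, sep = "_")

#' @export
print.channel_label <- function(x, ...) {
  cat("<channel ", format(x), if (x$role != "NA") paste0(" (", x$role, ")"),
      ">\n", sep = "")
  invisible(x)
}

#' Parse a "SIDE_MUSCLE" channel name
#' @param name e.g. "R_SOL".
#' @param role optional clinical role.
#' @return a \code{channel_label}.
#' @export
parse_channel <- function(name, role = "NA") {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  assert_that(length(parts) == 2L, "malformed_channel",
              "channel name '%s' is not SIDE_MUSCLE", name)
  channel_label(parts[1], parts[2], role)
}

#' Construct an EMG recording
#'
#' The core data container: a multi-channel surface-EMG walk, sampled at a
#' common rate (1 kHz in the acquisitions this pipeline targets), with an
#' optional binary footswitch channel marking stance.
#'
#' @param samples numeric matrix, one column per channel, or a named list of
#'   equal-length numeric vectors.
#' @param channels list of \code{channel_label}s, one per column.
#' @param sampling_rate samples per second.
#' @param footswitch optional 0/1 vector, same length as the channels.
#' @param subject_id subject identifier.
#' @param timepoint "T0" or "T1".
#' @param group "CG", "EG" or "HEALTHY".
#' @return an \code{emg_recording} object.
#' @export
emg_recording <- function(samples, channels, sampling_rate = 1000,
                          footswitch = NULL, subject_id = "S0",
                          timepoint = "T0", group = "HEALTHY") {
  if (is.list(samples) && !is.data.frame(samples)) {
    lens <- lengths(samples)
    assert_that(length(unique(lens)) <= 1L, "ragged_channels",
                "channels have unequal lengths")
    samples <- do.call(cbind, lapply(samples, as.numeric))
  }
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (inherits(channels, "channel_label")) channels <- list(channels)
  assert_that(length(channels) == ncol(samples), "channel_mismatch",
              "%d labels for %d channels", length(channels), ncol(samples))
  for (ch in channels)
    assert_that(inherits(ch, "channel_label"), "bad_channel",
                "channels must be channel_label objects")
  keys <- unname(vapply(channels, format, ""))
  assert_that(!anyDuplicated(keys), "duplicate_channel",
              "duplicate channel labels")
  assert_that(is.numeric(sampling_rate) && sampling_rate > 0, "bad_rate",
              "sampling_rate must be > 0")
  if (!is.null(footswitch)) {
    assert_that(length(footswitch) == nrow(samples), "ragged_channels",
                "footswitch length differs from channels")
    assert_that(all(footswitch %in% c(0, 1)), "bad_footswitch",
                "footswitch values must be 0 or 1")
    footswitch <- as.integer(footswitch)
  }
  assert_that(timepoint %in% TIMEPOINTS, "bad_timepoint",
              "timepoint must be T0 or T1")
  assert_that(group %in% GROUPS, "bad_group", "group must be CG, EG or HEALTHY")
  if (group == "HEALTHY")
    for (ch in channels)
      assert_that(ch$role == "NA", "bad_role",
                  "healthy recordings cannot carry a paretic role")
  colnames(samples) <- keys
  structure(list(samples = samples, channels = channels,
                 sampling_rate = sampling_rate, footswitch = footswitch,
                 subject_id = subject_id, timepoint = timepoint,
                 group = group),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording %s/%s %s: %d channels x %d samples @ %g Hz%s>\n",
              x$subject_id, x$timepoint, x$group, ncol(x$samples),
              nrow(x$samples), x$sampling_rate,
              if (!is.null(x$footswitch)) " +footswitch" else ""))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an \code{emg_recording}.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Recording duration in seconds
#' @param rec an \code{emg_recording}.
#' @export
duration <- function(rec) nrow(rec$samples) / rec$sampling_rate

#' Extract one channel's signal
#' @param rec an \code{emg_recording}.
#' @param channel a \code{channel_label} or "SIDE_MUSCLE" string.
#' @export
channel_signal <- function(rec, channel) {
  key <- if (inherits(channel, "channel_label")) format(channel) else channel
  assert_that(key %in% colnames(rec$samples), "missing_channel",
              "no channel '%s' in recording", key)
  rec$samples[, key]
}

#' Write a recording to a tab-separated file
#'
#' The on-disk dialect is a plain TSV with a '#'-prefixed header block
#' (rate_hz, channels, roles, group, timepoint, subject) followed by one row
#' per sample; the footswitch, if present, is the last column. The format is
#' human-inspectable and diff-friendly.
#'
#' @param rec an \code{emg_recording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  keys <- colnames(rec$samples)
  roles <- vapply(rec$channels, function(ch) ch$role, "")
  hdr <- c(sprintf("# rate_hz: %.10g", rec$sampling_rate),
           sprintf("# channels: %s", paste(keys, collapse = ",")),
           sprintf("# roles: %s", paste(roles, collapse = ",")),
           sprintf("# group: %s", rec$group),
           sprintf("# timepoint: %s", rec$timepoint),
           sprintf("# subject: %s", rec$subject_id))
  con <- tryCatch(file(path, "w"), error = function(e)
    emgait_error("io_failure", "cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(hdr, con)
  cols <- keys
  if (!is.null(rec$footswitch)) cols <- c(cols, "footswitch")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(rec$samples) > 0) {
    tab <- as.data.frame(rec$samples)
    if (!is.null(rec$footswitch)) tab$footswitch <- rec$footswitch
    utils::write.table(format(tab, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a recording written by \code{write_recording}
#'
#' The reader validates every declared invariant (known muscles, equal
#' channel lengths, binary footswitch) and refuses malformed files rather
#' than coercing them.
#'
#' @param path file path.
#' @return an \code{emg_recording}.
#' @export
read_recording <- function(path) {
  assert_that(file.exists(path), "io_failure", "file '%s' not found", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[seq_len(match(FALSE, is_hdr, nomatch = length(lines) + 1L) - 1L)]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("rate_hz", "channels", "group", "timepoint", "subject"))
    assert_that(!is.null(meta[[key]]), "malformed_header",
                "header is missing '%s'", key)
  rate <- suppressWarnings(as.numeric(meta$rate_hz))
  assert_that(is.finite(rate) && rate > 0, "malformed_header",
              "invalid rate_hz '%s'", meta$rate_hz)
  keys <- strsplit(meta$channels, ",", fixed = TRUE)[[1]]
  roles <- if (!is.null(meta$roles))
    strsplit(meta$roles, ",", fixed = TRUE)[[1]] else rep("NA", length(keys))
  assert_that(length(roles) == length(keys), "malformed_header",
              "roles/channels count mismatch")
  channels <- mapply(parse_channel, keys, roles, SIMPLIFY = FALSE,
                     USE.NAMES = FALSE)
  body <- lines[(length(hdr) + 1L):length(lines)]
  body <- body[nzchar(body)]
  assert_that(length(body) >= 1L, "malformed_header", "missing column row")
  cols <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  has_fs <- identical(cols[length(cols)], "footswitch")
  expected <- c(keys, if (has_fs) "footswitch")
  assert_that(identical(cols, expected), "malformed_header",
              "column row does not match declared channels")
  if (length(body) > 1L) {
    tab <- tryCatch(
      utils::read.table(text = body[-1L], sep = "\t",
                        colClasses = "numeric"),
      error = function(e)
        emgait_error("ragged_channels", "malformed data rows: %s",
                     conditionMessage(e)))
    assert_that(ncol(tab) == length(expected), "ragged_channels",
                "data rows have %d columns, expected %d", ncol(tab),
                length(expected))
    samples <- as.matrix(tab[, seq_along(keys), drop = FALSE])
    fs <- if (has_fs) tab[[length(expected)]] else NULL
  } else {
    samples <- matrix(0, nrow = 0, ncol = length(keys))
    fs <- if (has_fs) integer(0) else NULL
  }
  emg_recording(samples, channels, sampling_rate = rate, footswitch = fs,
                subject_id = meta$subject, timepoint = meta$timepoint,
                group = meta$group)
}
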