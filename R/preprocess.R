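# Sensor preprocessing chain: channel-role filtering, linear interpolation
# of missing runs, zero-fill of boundary gaps, per-channel min-max
# normalization, and overlapping sliding-window extraction.
#
# The pipeline order is fixed: filter -> interpolate (-> zero-fill) ->
# normalize -> window. Missing values are represented as NA inside a
# sensor_frame; the file dialect encodes them with a sentinel (literal NaN
# by default, matching body-sensor recordings where Bluetooth dropouts
# leave gaps).

GN_ROLES <- c("body", "quaternion", "object_env", "label", "ignore")

#' Channel schema: per-column roles
#'
#' @param name character vector of column names.
#' @param role per-column role: `"body"`, `"quaternion"`, `"object_env"`,
#'   `"label"` or `"ignore"`. Exactly one column must be the label.
#' @return a data frame of class `channel_schema` with columns
#'   `index`, `name`, `role`.
#' @export
channel_schema <- function(name, role) {
  gn_assert(length(name) == length(role), "name/role length mismatch")
  gn_assert(all(role %in% GN_ROLES),
            sprintf("roles must be in {%s}", paste(GN_ROLES, collapse = ", ")))
  gn_assert(sum(role == "label") == 1, "schema needs exactly one label column",
            "gennas_schema_error")
  gn_assert(!anyDuplicated(name), "duplicate column names")
  structure(data.frame(index = seq_along(name), name = name, role = role,
                       stringsAsFactors = FALSE),
            class = c("channel_schema", "data.frame"))
}

#' Read / write a channel schema file
#'
#' Tab-separated text with columns `index`, `name`, `role`.
#'
#' @param path file path.
#' @return `read_channel_schema`: a [channel_schema()].
#' @export
read_channel_schema <- function(path) {
  gn_assert(file.exists(path), sprintf("schema file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gn_assert(all(c("name", "role") %in% names(df)),
            "schema file needs 'name' and 'role' columns",
            "gennas_schema_error")
  channel_schema(df$name, df$role)
}

#' @rdname read_channel_schema
#' @param schema a [channel_schema()].
#' @export
write_channel_schema <- function(schema, path) {
  utils::write.table(as.data.frame(schema), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sensor frame
#'
#' A timestep-by-channel table of sensor readings with per-timestep class
#' labels. Missing readings are `NA` (the missing mask is `is.na(values)`).
#'
#' @param values numeric matrix, timesteps x data channels; `NA` = missing.
#' @param labels integer class id per timestep (null class included).
#' @param schema a [channel_schema()] covering the data channels plus the
#'   label column, in file order; or `NULL` for an all-body default.
#' @param stats optional per-channel normalization stats (see
#'   [compute_norm_stats()]).
#' @return an object of class `sensor_frame`.
#' @export
sensor_frame <- function(values, labels, schema = NULL, stats = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gn_assert(nrow(values) == length(labels),
            "labels length must equal timestep count")
  if (is.null(schema)) {
    nm <- colnames(values)
    if (is.null(nm)) nm <- sprintf("ch%03d", seq_len(ncol(values)))
    schema <- channel_schema(c(nm, "label"),
                             c(rep("body", ncol(values)), "label"))
  }
  data_cols <- schema[schema$role != "label", , drop = FALSE]
  gn_assert(nrow(data_cols) == ncol(values),
            sprintf("schema has %d data columns but values has %d",
                    nrow(data_cols), ncol(values)), "gennas_schema_error")
  colnames(values) <- data_cols$name
  structure(list(values = values, labels = as.integer(labels),
                 schema = schema, stats = stats),
            class = "sensor_frame")
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat("<sensor_frame> ", nrow(x$values), " timesteps x ", ncol(x$values),
      " channels (", sum(is.na(x$values)), " missing values, ",
      length(unique(x$labels)), " label values)\n", sep = "")
  invisible(x)
}

#' Read a whitespace-separated sensor table
#'
#' One row per timestep, columns in schema order (data channels and one
#' label column). Missing values are encoded by `sentinel`: either the
#' literal string `"NaN"` (default) / `"NA"`, or a numeric value.
#'
#' @param path file path.
#' @param schema a [channel_schema()] describing the columns.
#' @param sentinel missing-value sentinel (string or number).
#' @return a [sensor_frame()] (columns with role `ignore` are dropped from
#'   values but kept in the schema until [filter_channels()]).
#' @export
read_sensor_table <- function(path, schema, sentinel = "NaN") {
  gn_assert(file.exists(path), sprintf("file not found: %s", path))
  stopifnot(inherits(schema, "channel_schema"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ncols <- nrow(schema)
  if (length(lines) == 0) {
    return(sensor_frame(matrix(numeric(0), 0, ncols - 1L), integer(0), schema))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  if (any(nt != ncols))
    gn_stop(sprintf("row %d has %d columns, schema expects %d",
                    which(nt != ncols)[[1]], nt[nt != ncols][[1]], ncols),
            "gennas_schema_error")
  flat <- unlist(toks, use.names = FALSE)
  num <- suppressWarnings(as.numeric(flat))
  bad <- is.na(num) & !(flat %in% c("NA", "NaN", "nan"))
  if (any(bad)) {
    row <- ceiling(which(bad)[[1]] / ncols)
    gn_stop(sprintf("non-numeric cell '%s' at row %d", flat[bad][[1]], row),
            "gennas_parse_error")
  }
  mat <- matrix(num, nrow = length(lines), ncol = ncols, byrow = TRUE)
  if (is.numeric(sentinel)) mat[mat == sentinel] <- NA
  mat[is.nan(mat)] <- NA
  lab_col <- which(schema$role == "label")
  labels <- as.integer(mat[, lab_col])
  values <- mat[, -lab_col, drop = FALSE]
  sensor_frame(values, labels, schema)
}

#' Write a sensor frame in the whitespace-separated dialect
#'
#' @param frame a [sensor_frame()].
#' @param path output path.
#' @param sentinel string written for missing values.
#' @return the path, invisibly.
#' @export
write_sensor_table <- function(frame, path, sentinel = "NaN") {
  stopifnot(inherits(frame, "sensor_frame"))
  lab_col <- which(frame$schema$role == "label")
  full <- matrix(NA_real_, nrow(frame$values), nrow(frame$schema))
  full[, -lab_col] <- frame$values
  full[, lab_col] <- frame$labels
  txt <- apply(full, 1, function(r) {
    s <- fmt_num(r)
    s[is.na(r)] <- sentinel
    paste(s, collapse = " ")
  })
  writeLines(txt, path)
  invisible(path)
}

#' Keep only body-worn sensor channels
#'
#' Drops channels whose role is `quaternion`, `object_env` or `ignore`,
#' keeping body channels and the label.
#'
#' @param frame a [sensor_frame()].
#' @return a [sensor_frame()] with only body channels.
#' @export
filter_channels <- function(frame) {
  stopifnot(inherits(frame, "sensor_frame"))
  data_schema <- frame$schema[frame$schema$role != "label", , drop = FALSE]
  keep <- data_schema$role == "body"
  if (!any(keep))
    gn_stop("no body channels remain after filtering",
            "gennas_validation_error")
  new_schema <- channel_schema(
    c(data_schema$name[keep], frame$schema$name[frame$schema$role == "label"]),
    c(rep("body", sum(keep)), "label"))
  sensor_frame(frame$values[, keep, drop = FALSE], frame$labels, new_schema)
}

#' Linearly interpolate missing values, zero-filling the boundaries
#'
#' Interior runs of missing values in each channel are replaced by linear
#' interpolation between the nearest defined neighbours; leading/trailing
#' runs (which have no neighbour on one side) are then set to zero. The
#' result has no missing values.
#'
#' @param frame a [sensor_frame()].
#' @return a [sensor_frame()] with a clear missing mask.
#' @export
interpolate_missing <- function(frame) {
  stopifnot(inherits(frame, "sensor_frame"))
  v <- frame$values
  T <- nrow(v)
  if (T > 0) {
    for (c in seq_len(ncol(v))) {
      col <- v[, c]
      na <- is.na(col)
      if (!any(na)) next
      if (all(na)) { v[, c] <- 0; next }
      ok <- which(!na)
      if (length(ok) >= 2) {
        col[na] <- stats::approx(ok, col[ok], xout = which(na),
                                 method = "linear", rule = 1)$y
      }
      col[is.na(col)] <- 0   # boundary runs: no neighbour on one side
      v[, c] <- col
    }
  }
  sensor_frame(v, frame$labels, frame$schema, frame$stats)
}

#' Per-channel minimum and maximum
#'
#' @param frame a [sensor_frame()] without missing values.
#' @return a data frame with columns `channel`, `min`, `max`.
#' @export
compute_norm_stats <- function(frame) {
  stopifnot(inherits(frame, "sensor_frame"))
  gn_assert(!anyNA(frame$values),
            "interpolate_missing() must run before computing stats")
  gn_assert(nrow(frame$values) > 0, "cannot compute stats on 0 timesteps")
  data.frame(channel = colnames(frame$values),
             min = apply(frame$values, 2, min),
             max = apply(frame$values, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Min-max normalize each channel into [0, 1]
#'
#' Applies `(x - min(c)) / (max(c) - min(c))` per channel. Channels with
#' `max == min` map to 0. When `stats` come from a different split (e.g.
#' training stats applied to validation data), out-of-range values are
#' clipped to `[0, 1]`.
#'
#' @param frame a [sensor_frame()] without missing values.
#' @param stats per-channel stats from [compute_norm_stats()]; default:
#'   computed from `frame` itself (in which case no clipping is needed).
#' @param clip clip to `[0, 1]`; defaults to `TRUE` when foreign stats are
#'   supplied.
#' @return a normalized [sensor_frame()] carrying the stats used.
#' @export
normalize_frame <- function(frame, stats = NULL, clip = !is.null(stats)) {
  stopifnot(inherits(frame, "sensor_frame"))
  gn_assert(!anyNA(frame$values),
            "interpolate_missing() must run before normalize")
  own <- is.null(stats)
  if (own) stats <- compute_norm_stats(frame)
  gn_assert(setequal(stats$channel, colnames(frame$values)),
            "stats do not cover the frame's channels")
  stats <- stats[match(colnames(frame$values), stats$channel), ]
  rng <- stats$max - stats$min
  rng[rng == 0] <- 1          # constant channels map to 0
  v <- sweep(frame$values, 2, stats$min, "-")
  v <- sweep(v, 2, rng, "/")
  v[, stats$max == stats$min] <- 0
  if (clip) v <- pmin(pmax(v, 0), 1)
  sensor_frame(v, frame$labels, frame$schema, stats)
}

#' Extract overlapping sliding windows as a 4-D tensor
#'
#' Windows of `w` timesteps start at 0, `wstep`, `2*wstep`, ...; with `T`
#' timesteps there are `floor((T - w)/wstep) + 1` windows (0 when `T < w`,
#' with a warning). The tensor axis order is (window, 1, time, channel),
#' i.e. shape `N x 1 x w x C`.
#'
#' @param frame a normalized [sensor_frame()].
#' @param w window size in timesteps (>= 1).
#' @param wstep window step in timesteps (>= 1).
#' @param label_rule how a window inherits a label: `"last"` (label of the
#'   window's final timestep; default) or `"majority"` (modal label, ties
#'   to the later class seen).
#' @return an object of class `windowed_dataset`: list with `tensor`
#'   (`N x 1 x w x C` array), `labels` (length `N`), `starts` (0-based
#'   window origins), `w`, `wstep`, `channels`.
#' @export
slide_windows <- function(frame, w, wstep,
                          label_rule = c("last", "majority")) {
  stopifnot(inherits(frame, "sensor_frame"))
  label_rule <- match.arg(label_rule)
  gn_assert(w >= 1 && wstep >= 1, "w and wstep must be >= 1")
  T <- nrow(frame$values); C <- ncol(frame$values)
  if (T < w) {
    warning(sprintf("frame has %d timesteps < window size %d: 0 windows", T, w))
    return(structure(list(tensor = array(0, c(0, 1, w, C)),
                          labels = integer(0), starts = integer(0),
                          w = as.integer(w), wstep = as.integer(wstep),
                          channels = colnames(frame$values)),
                     class = "windowed_dataset"))
  }
  N <- (T - w) %/% wstep + 1L
  starts <- (seq_len(N) - 1L) * wstep          # 0-based origins
  idx <- outer(starts + 1L, 0:(w - 1L), "+")   # N x w timestep indices
  tensor <- array(0, c(N, 1, w, C))
  for (c in seq_len(C))
    tensor[, 1, , c] <- matrix(frame$values[idx, c], N, w)
  labels <- if (label_rule == "last") {
    frame$labels[starts + w]
  } else {
    apply(matrix(frame$labels[idx], N, w), 1, function(r) {
      tb <- table(r)
      as.integer(names(tb)[which.max(tb)])
    })
  }
  structure(list(tensor = tensor, labels = as.integer(labels),
                 starts = as.integer(starts), w = as.integer(w),
                 wstep = as.integer(wstep), channels = colnames(frame$values)),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<windowed_dataset> ", d[[1]], " windows of shape 1 x ", d[[3]], " x ",
      d[[4]], " (w=", x$w, ", wstep=", x$wstep, ")\n", sep = "")
  invisible(x)
}

#' Run the full preprocessing pipeline
#'
#' filter -> interpolate -> normalize -> window, in that fixed order.
#'
#' @inheritParams slide_windows
#' @param stats optional training-split stats for normalization (clipped).
#' @return a `windowed_dataset`.
#' @export
preprocess_pipeline <- function(frame, w, wstep, label_rule = "last",
                                stats = NULL) {
  frame <- filter_channels(frame)
  frame <- interpolate_missing(frame)
  frame <- normalize_frame(frame, stats = stats)
  slide_windows(frame, w, wstep, label_rule = label_rule)
}

# subset a windowed dataset by window index (used for splits / sampling)
subset_windows <- function(wd, i) {
  structure(list(tensor = wd$tensor[i, , , , drop = FALSE],
                 labels = wd$labels[i], starts = wd$starts[i],
                 w = wd$w, wstep = wd$wstep, channels = wd$channels),
            class = "windowed_dataset")
}
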