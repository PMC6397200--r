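# CSV interchange: strict schema readers, deterministic writers, and the
# seeded-run manifest. All files are UTF-8 CSV with "\n" newlines; frame
# indices are 0-based on disk; seconds and micrometers are the only time
# and length units.

read_csv_schema <- function(path, col_types, required, what) {
  if (!file.exists(path)) {
    stop_data(sprintf("%s file '%s' does not exist", what, path))
  }
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  show_col_types = FALSE))
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    stop_schema(sprintf("%s file '%s' is missing column(s): %s",
                        what, path, paste(missing, collapse = ", ")))
  }
  readr::read_csv(path, col_types = col_types, show_col_types = FALSE)
}

#' Read a track CSV
#'
#' Expected columns: `track_id,frame,t_s,x_um[,y_um],channel,condition`
#' with 0-based frames. Rows are grouped by track and sorted by frame;
#' duplicate `(track_id, frame)` pairs are rejected, and each track is
#' validated (monotone time, uniform frame interval — gappy tracks are
#' rejected with the offending track named). A `y_um` column is accepted
#' and carried through but ignored by the 1-D kinematics.
#'
#' @param path Path to the CSV file.
#' @return A track tibble.
#' @export
read_tracks <- function(path) {
  df <- read_csv_schema(
    path,
    col_types = readr::cols(
      track_id = readr::col_character(),
      frame = readr::col_integer(),
      t_s = readr::col_double(),
      x_um = readr::col_double(),
      .default = readr::col_guess()
    ),
    required = c("track_id", "frame", "t_s", "x_um"),
    what = "track"
  )
  if (nrow(df) == 0L) {
    return(df)
  }
  dup <- duplicated(df[c("track_id", "frame")])
  if (any(dup)) {
    stop_data(sprintf(
      "duplicate (track_id, frame) pairs in '%s' (first: track '%s', frame %d)",
      path, df$track_id[dup][1], df$frame[dup][1]
    ))
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  # validates monotone time and uniform frame interval per track
  invisible(split_tracks(df))
  df
}

#' Read an intensity-trace CSV
#'
#' Expected columns: `fiber_id,chamber_id,condition,frame,intensity`.
#'
#' @param path Path to the CSV file.
#' @return A trace tibble sorted by fiber and frame.
#' @export
read_traces <- function(path) {
  df <- read_csv_schema(
    path,
    col_types = readr::cols(
      fiber_id = readr::col_character(),
      chamber_id = readr::col_character(),
      condition = readr::col_character(),
      frame = readr::col_integer(),
      intensity = readr::col_double()
    ),
    required = c("fiber_id", "chamber_id", "condition", "frame", "intensity"),
    what = "trace"
  )
  df[order(df$fiber_id, df$frame), , drop = FALSE]
}

#' Read an NMJ event CSV
#'
#' Expected columns:
#' `event_id,unit_id,condition,pre_present,post_present,axon_intact`;
#' flags may be written as TRUE/FALSE or 0/1.
#'
#' @param path Path to the CSV file.
#' @return An event tibble with logical flag columns.
#' @export
read_nmj_events <- function(path) {
  df <- read_csv_schema(
    path,
    col_types = readr::cols(
      event_id = readr::col_character(),
      unit_id = readr::col_character(),
      condition = readr::col_character(),
      .default = readr::col_guess()
    ),
    required = c("event_id", "unit_id", "condition", "pre_present",
                 "post_present", "axon_intact"),
    what = "NMJ event"
  )
  for (col in c("pre_present", "post_present", "axon_intact")) {
    df[[col]] <- as.logical(df[[col]])
    if (any(is.na(df[[col]]))) {
      stop_data(sprintf("column '%s' in '%s' has values that are not 0/1 or TRUE/FALSE",
                        col, path))
    }
  }
  df
}

#' Read a section-count CSV
#'
#' Expected columns: `section_id,group,compartment,area_mm2,n_aggregates`.
#'
#' @param path Path to the CSV file.
#' @return A section tibble.
#' @export
read_section_counts <- function(path) {
  read_csv_schema(
    path,
    col_types = readr::cols(
      section_id = readr::col_character(),
      group = readr::col_character(),
      compartment = readr::col_character(),
      area_mm2 = readr::col_double(),
      n_aggregates = readr::col_integer()
    ),
    required = c("section_id", "group", "compartment", "area_mm2",
                 "n_aggregates"),
    what = "section count"
  )
}

#' Read a fiber-diameter CSV
#'
#' Expected columns: `group,diameter_um`.
#'
#' @param path Path to the CSV file.
#' @return A diameter tibble.
#' @export
read_fiber_diameters <- function(path) {
  read_csv_schema(
    path,
    col_types = readr::cols(
      group = readr::col_character(),
      diameter_um = readr::col_double()
    ),
    required = c("group", "diameter_um"),
    what = "fiber diameter"
  )
}

#' Read an explant-count CSV
#'
#' Expected columns: `explant_id,condition,day,count`.
#'
#' @param path Path to the CSV file.
#' @return A count tibble sorted by explant and day.
#' @export
read_explant_counts <- function(path) {
  df <- read_csv_schema(
    path,
    col_types = readr::cols(
      explant_id = readr::col_character(),
      condition = readr::col_character(),
      day = readr::col_double(),
      count = readr::col_integer()
    ),
    required = c("explant_id", "condition", "day", "count"),
    what = "explant count"
  )
  df[order(df$explant_id, df$day), , drop = FALSE]
}

#' Write result tables deterministically
#'
#' Each named table is written to `<out_dir>/<name>.csv` with a fixed
#' column order (as given), floating-point values at 6 significant
#' digits, UTF-8 encoding and `"\n"` newlines, so identical tables always
#' produce byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop_parameter("`tables` must be a fully named list")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(sprintf("cannot create output directory '%s'", out_dir),
                 class = "motorunit_io_error")
  }
  paths <- vapply(names(tables), function(nm) {
    df <- tables[[nm]]
    is_dbl <- vapply(df, is.double, logical(1))
    df[is_dbl] <- lapply(df[is_dbl], signif, digits = 6)
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(df, path, eol = "\n")
    path
  }, character(1))
  invisible(unname(paths))
}

#' Build a reproducibility manifest for a run
#'
#' Captures the command, a configuration snapshot, the seed, MD5 hashes of
#' every input file, the output file list, a timestamp and the package
#' version. Re-running the command with the same configuration and seed
#' reproduces the result tables.
#'
#' @param command Subcommand name.
#' @param config Named list of configuration values for the run.
#' @param seed Integer seed (or `NULL` for deterministic stages).
#' @param inputs Character vector of input file paths.
#' @param outputs Character vector of output file paths.
#' @return A named list (the manifest).
#' @export
run_manifest <- function(command, config = list(), seed = NULL,
                         inputs = character(), outputs = character()) {
  hashes <- if (length(inputs) > 0L) {
    h <- tools::md5sum(inputs)
    stats::setNames(as.character(h), inputs)
  } else {
    stats::setNames(character(), character())
  }
  list(
    command = command,
    config = config,
    seed = seed,
    input_hashes = as.list(hashes),
    outputs = as.list(unname(outputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tool_version = as.character(utils::packageVersion("motorunit"))
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A manifest from [run_manifest()].
#' @param path Output path (conventionally `manifest.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
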