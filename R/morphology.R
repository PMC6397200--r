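# Morphology scoring: in vitro NMJ health, in vivo innervation, mutant
# SOD1 aggregate density, and muscle-fiber diameter summaries.

check_event_cols <- function(events) {
  required <- c("event_id", "unit_id", "pre_present", "post_present",
                "axon_intact")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0L) {
    stop_schema(sprintf("event table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  invisible(events)
}

#' Percentage of healthy NMJs per unit (in vitro)
#'
#' Intact colocalization events (pre- and postsynaptic marker present,
#' axon non-degenerated) divided by all colocalization events in the same
#' unit, times 100. Non-colocalized events are ignored entirely; units
#' with no colocalized events are dropped with a warning.
#'
#' @param events Event table with columns `event_id`, `unit_id`,
#'   `pre_present`, `post_present`, `axon_intact` (plus optional
#'   `condition`).
#' @return A tibble with columns `unit_id` (plus `condition`),
#'   `n_colocalized`, `n_intact`, `percent_healthy`.
#' @export
healthy_nmj_fraction <- function(events) {
  check_event_cols(events)
  group_cols <- intersect(c("unit_id", "condition"), names(events))
  out <- events |>
    dplyr::mutate(colocalized = .data$pre_present & .data$post_present) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_colocalized = sum(.data$colocalized),
      n_intact = sum(.data$colocalized & .data$axon_intact),
      .groups = "drop"
    )
  empty <- out$n_colocalized == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d unit(s) with no colocalized events: %s",
                    sum(empty), paste(out$unit_id[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  out |>
    dplyr::mutate(percent_healthy = 100 * .data$n_intact / .data$n_colocalized)
}

#' Percentage of innervated NMJs per unit (in vivo)
#'
#' Postsynaptic (AChR) sites with the presynaptic marker present divided
#' by all postsynaptic sites in the unit, times 100. Units with no
#' postsynaptic sites are dropped with a warning.
#'
#' @inheritParams healthy_nmj_fraction
#' @return A tibble with columns `unit_id` (plus `condition`), `n_post`,
#'   `n_innervated`, `percent_innervated`.
#' @export
innervation_percent <- function(events) {
  check_event_cols(events)
  group_cols <- intersect(c("unit_id", "condition"), names(events))
  out <- events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_post = sum(.data$post_present),
      n_innervated = sum(.data$post_present & .data$pre_present),
      .groups = "drop"
    )
  empty <- out$n_post == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d unit(s) with no postsynaptic sites: %s",
                    sum(empty), paste(out$unit_id[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  out |>
    dplyr::mutate(percent_innervated = 100 * .data$n_innervated / .data$n_post)
}

#' Aggregate density per group and compartment, with percent change
#'
#' Per-section density is `n_aggregates / area_mm2`; the group statistic
#' is the mean over sections (or over animal means when `animal_col` is
#' given), with SEM. Percent change of each group against the reference
#' group is `100 * (1 - group / reference)` within each compartment.
#'
#' @param sections Section table with columns `section_id`, `group`,
#'   `compartment`, `area_mm2`, `n_aggregates` (plus the optional animal
#'   column).
#' @param reference_group Group label percent change is computed against.
#' @param animal_col Optional name of an animal-identifier column; when
#'   given, sections are first averaged within animal.
#' @return A tibble with columns `group`, `compartment`, `n`,
#'   `density_mean`, `density_sem`, `percent_change`.
#' @export
aggregate_density <- function(sections, reference_group, animal_col = NULL) {
  required <- c("section_id", "group", "compartment", "area_mm2",
                "n_aggregates")
  missing <- setdiff(required, names(sections))
  if (length(missing) > 0L) {
    stop_schema(sprintf("section table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (any(sections$area_mm2 <= 0)) {
    stop_data("section areas must be positive")
  }
  if (any(sections$n_aggregates < 0)) {
    stop_data("aggregate counts must be non-negative")
  }
  if (!reference_group %in% sections$group) {
    stop_parameter(sprintf("reference group '%s' not present in the data",
                           reference_group))
  }
  dens <- sections |>
    dplyr::mutate(density = .data$n_aggregates / .data$area_mm2)
  if (!is.null(animal_col)) {
    if (!animal_col %in% names(sections)) {
      stop_parameter(sprintf("animal column '%s' not present", animal_col))
    }
    dens <- dens |>
      dplyr::group_by(.data$group, .data$compartment,
                      dplyr::across(dplyr::all_of(animal_col))) |>
      dplyr::summarise(density = mean(.data$density), .groups = "drop")
  }
  out <- dens |>
    dplyr::group_by(.data$group, .data$compartment) |>
    dplyr::summarise(
      n = dplyr::n(),
      density_mean = mean(.data$density),
      density_sem = sem0(.data$density),
      .groups = "drop"
    )
  ref <- out |>
    dplyr::filter(.data$group == reference_group) |>
    dplyr::select("compartment", ref_density = "density_mean")
  out |>
    dplyr::left_join(ref, by = "compartment") |>
    dplyr::mutate(
      percent_change = 100 * (1 - .data$density_mean / .data$ref_density)
    ) |>
    dplyr::select(-"ref_density")
}

#' Summaries and pairwise differences of fiber diameters
#'
#' @param diameters Table with columns `group`, `diameter_um`.
#' @return A list with `summary` (tibble: `group`, `n`, `mean_um`,
#'   `sd_um`, `sem_um`) and `differences` (tibble of all group pairs:
#'   `group_a`, `group_b`, `mean_diff_um` = mean(a) - mean(b),
#'   `se_diff_um`).
#' @export
fiber_diameter_summary <- function(diameters) {
  required <- c("group", "diameter_um")
  missing <- setdiff(required, names(diameters))
  if (length(missing) > 0L) {
    stop_schema(sprintf("diameter table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(diameters$diameter_um)) || any(diameters$diameter_um <= 0)) {
    stop_data("fiber diameters must be positive finite values")
  }
  summary <- diameters |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_um = mean(.data$diameter_um),
      sd_um = if (dplyr::n() > 1L) stats::sd(.data$diameter_um) else 0,
      sem_um = sem0(.data$diameter_um),
      .groups = "drop"
    )
  groups <- summary$group
  differences <- if (length(groups) < 2L) {
    tibble::tibble(group_a = character(), group_b = character(),
                   mean_diff_um = numeric(), se_diff_um = numeric())
  } else {
    pairs <- utils::combn(seq_along(groups), 2L)
    tibble::tibble(
      group_a = groups[pairs[1, ]],
      group_b = groups[pairs[2, ]],
      mean_diff_um = summary$mean_um[pairs[1, ]] - summary$mean_um[pairs[2, ]],
      se_diff_um = sqrt(summary$sem_um[pairs[1, ]]^2 +
                          summary$sem_um[pairs[2, ]]^2)
    )
  }
  list(summary = summary, differences = differences)
}

#' Blind group labels with opaque codes
#'
#' Replaces the values of a grouping column with opaque codes (in a
#' seeded random order) so downstream scoring can run blinded; the
#' returned key maps codes back to labels via [unblind_groups()].
#'
#' @param data A data frame.
#' @param group_col Name of the grouping column.
#' @param seed Integer seed for the code assignment.
#' @return A list with `data` (labels replaced by codes) and `key`
#'   (tibble: `code`, original label).
#' @export
blind_groups <- function(data, group_col, seed = 1) {
  if (!group_col %in% names(data)) {
    stop_parameter(sprintf("column '%s' not present", group_col))
  }
  labels <- unique(data[[group_col]])
  codes <- withr::with_seed(seed, sample(sprintf("code_%02d",
                                                 seq_along(labels))))
  key <- tibble::tibble(code = codes, label = labels)
  data[[group_col]] <- key$code[match(data[[group_col]], key$label)]
  list(data = data, key = key)
}

#' Map blinded group codes back to their labels
#'
#' @param data A data frame whose `group_col` holds codes from
#'   [blind_groups()].
#' @param key The key returned by [blind_groups()].
#' @param group_col Name of the grouping column.
#' @return `data` with original labels restored.
#' @export
unblind_groups <- function(data, key, group_col) {
  if (!group_col %in% names(data)) {
    stop_parameter(sprintf("column '%s' not present", group_col))
  }
  data[[group_col]] <- key$label[match(data[[group_col]], key$code)]
  data
}
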