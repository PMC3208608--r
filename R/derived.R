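#' Derive secondary morphology statistics from per-field measurements
#'
#' Appends derived columns to a tibble of primary per-field measurements
#' (as produced by [measure_field()] or [run_plate()]):
#'
#' * `branch_count`: `max(endpoint_count - attachment_count, 0)`. On a clean
#'   acyclic arbor with A attachment points and E tips there are E - A
#'   junctions (tree Euler relation); disconnected fragments inflate this
#'   count, which is the documented failure direction.
#' * `branch_density`: branches per skeleton pixel,
#'   `branch_count / total_neurite_length` (`NA` when length is 0).
#' * `estimated_neuron_count`: `total_soma_area / reference_soma_area`.
#' * `clustering_index`: `avg_soma_cluster_area / reference_soma_area`; an
#'   approximate measure of cell-body clustering (1 = mostly single cells).
#' * `avg_neurite_length_per_neuron`:
#'   `total_neurite_length / estimated_neuron_count` (`NA` if no soma area).
#' * `avg_individual_neurite_length`: total length divided by
#'   `attachment_count` (neurite roots) by default, or by `endpoint_count`
#'   under `cfg$individual_length_denominator = "endpoints"`; `NA` when the
#'   denominator is 0.
#' * `normalized_neurite_length`: total neurite length per unit soma area
#'   (`NA` when soma area is 0).
#' * `low_content`: flag set when skeleton length or soma area falls below
#'   the configured floors; ratio measurements of such fields are unreliable
#'   and are excluded from condition summaries.
#'
#' Undefined values are `NA` sentinels, never errors, so one degenerate field
#' cannot abort a plate run.
#'
#' @param fm Tibble/data frame with the primary measurement columns.
#' @param cfg A [pipeline_config()] (supplies `reference_soma_area`, the
#'   denominator switch and low-content floors).
#' @return The input tibble with derived columns appended.
#' @examples
#' fm <- tibble::tibble(total_neurite_length = 200, total_soma_area = 5000,
#'                      soma_count = 9L, avg_soma_cluster_area = 5000 / 9,
#'                      endpoint_count = 3L, attachment_count = 1L,
#'                      mean_intensity = 30)
#' derive_measurements(fm, pipeline_config(reference_soma_area = 500))
#' @export
derive_measurements <- function(fm, cfg = pipeline_config()) {
  check_config(cfg)
  need <- c("total_neurite_length", "total_soma_area", "avg_soma_cluster_area",
            "endpoint_count", "attachment_count")
  missing_cols <- setdiff(need, names(fm))
  if (length(missing_cols)) {
    stop("missing measurement columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ind_den <- if (cfg$individual_length_denominator == "attachments") {
    fm$attachment_count
  } else {
    fm$endpoint_count
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(
    tibble::as_tibble(fm),
    branch_count = pmax(.data$endpoint_count - .data$attachment_count, 0L),
    branch_density = safe_div(.data$branch_count, .data$total_neurite_length),
    estimated_neuron_count = .data$total_soma_area / cfg$reference_soma_area,
    clustering_index = safe_div(.data$avg_soma_cluster_area,
                                cfg$reference_soma_area),
    avg_neurite_length_per_neuron = safe_div(.data$total_neurite_length,
                                             .data$estimated_neuron_count),
    avg_individual_neurite_length = safe_div(.data$total_neurite_length,
                                             ind_den),
    normalized_neurite_length = safe_div(.data$total_neurite_length,
                                         .data$total_soma_area),
    low_content = .data$total_neurite_length < cfg$low_content_min_length |
      .data$total_soma_area < cfg$low_content_min_soma_area
  )
}

#' Summarize measurements per experimental condition
#'
#' Long-format per-condition summary: for every measurement column, the mean,
#' standard deviation and standard error over fields, with `NA` (flagged
#' undefined) values excluded and counted. Ratio measurements of fields
#' flagged `low_content` are excluded as well.
#'
#' @param fields Tibble of per-field measurements (primary and/or derived).
#'   If a `condition` column is absent all fields form one condition.
#' @param measurements Character vector of measurement columns to summarize;
#'   defaults to every numeric measurement column present.
#' @param condition Name of the grouping column (default `"condition"`).
#' @return Tibble with columns `condition`, `measurement`, `n_fields`,
#'   `n_used`, `n_excluded`, `mean`, `sd`, `sem`. `sd` and `sem` are 0 when a
#'   single field is available.
#' @export
summarize_condition <- function(fields,
                                measurements = NULL,
                                condition = "condition") {
  fields <- tibble::as_tibble(fields)
  if (nrow(fields) == 0) stop("no fields to summarize", call. = FALSE)
  if (!condition %in% names(fields)) fields[[condition]] <- "all"
  ratio_cols <- c("branch_density", "avg_neurite_length_per_neuron",
                  "avg_individual_neurite_length", "normalized_neurite_length",
                  "clustering_index")
  if (is.null(measurements)) {
    skip <- c(condition, "field_id", "plate", "well", "field", "channel",
              "dose", "low_content", "path")
    measurements <- names(fields)[vapply(fields, is.numeric, logical(1))]
    measurements <- setdiff(measurements, skip)
  }
  absent <- setdiff(measurements, names(fields))
  if (length(absent)) {
    stop("unknown measurement columns: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  low <- if ("low_content" %in% names(fields)) {
    fields$low_content %in% TRUE
  } else {
    rep(FALSE, nrow(fields))
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(fields[, c(condition, measurements)],
                  .low = low),
    cols = dplyr::all_of(measurements),
    names_to = "measurement", values_to = "value"
  )
  long$value[long$.low & long$measurement %in% ratio_cols] <- NA_real_
  out <- dplyr::summarize(
    dplyr::group_by(long, .data[[condition]], .data$measurement),
    n_fields = dplyr::n(),
    n_used = sum(!is.na(.data$value)),
    n_excluded = sum(is.na(.data$value)),
    mean = if (sum(!is.na(.data$value)) > 0) {
      mean(.data$value, na.rm = TRUE)
    } else {
      NA_real_
    },
    sd = if (sum(!is.na(.data$value)) > 1) {
      stats::sd(.data$value, na.rm = TRUE)
    } else {
      0
    },
    .groups = "drop"
  )
  out$sem <- ifelse(out$n_used > 0, out$sd / sqrt(pmax(out$n_used, 1)), NA_real_)
  names(out)[1] <- "condition"
  dplyr::arrange(out, .data$condition, .data$measurement)
}

# closed-form Z-factor from condition moments
z_from_moments <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  denom <- abs(mean_pos - mean_neg)
  if (!is.finite(denom) || denom == 0) return(-Inf)
  1 - 3 * (sd_pos + sd_neg) / denom
}

#' Z-factor assay-quality statistic
#'
#' `Z = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|` (Zhang, Chung &
#' Oldenburg 1999). Z > 0.5 characterizes a robust screening assay; Z < 0 a
#' poor one. Symmetric in which condition is called positive. When the
#' condition means coincide the statistic is `-Inf`, returned as a flagged
#' sentinel with a warning rather than an error.
#'
#' @param summary A condition summary from [summarize_condition()], or `NULL`
#'   when `positive`/`negative` are numeric vectors of per-field values.
#' @param positive,negative Condition labels present in `summary`, or (when
#'   `summary` is `NULL`) numeric vectors of raw per-field values.
#' @param measurement Measurement name to compare (required with a summary).
#' @return Single numeric Z-factor (possibly `-Inf`).
#' @examples
#' z_factor(positive = c(10, 10, 10), negative = c(0, 0, 0))  # noiseless: 1
#' @export
z_factor <- function(summary = NULL, positive, negative, measurement = NULL) {
  if (is.null(summary)) {
    stopifnot(is.numeric(positive), is.numeric(negative))
    sp <- if (length(positive) > 1) stats::sd(positive) else 0
    sn <- if (length(negative) > 1) stats::sd(negative) else 0
    z <- z_from_moments(mean(positive), sp, mean(negative), sn)
  } else {
    if (is.null(measurement)) {
      stop("`measurement` is required with a condition summary", call. = FALSE)
    }
    pick <- function(cond) {
      row <- summary[summary$condition == cond &
                       summary$measurement == measurement, ]
      if (nrow(row) != 1) {
        stop(sprintf("condition '%s' / measurement '%s' not found in summary",
                     cond, measurement), call. = FALSE)
      }
      row
    }
    p <- pick(positive); n <- pick(negative)
    z <- z_from_moments(p$mean, p$sd, n$mean, n$sd)
  }
  if (identical(z, -Inf)) {
    warning("condition means are equal; Z-factor is -Inf", call. = FALSE)
  }
  z
}
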