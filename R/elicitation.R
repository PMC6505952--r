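#' @title Trial-roulette elicitation records
#' @description
#' In a trial-roulette (histogram) elicitation an expert states a plausible
#' interval \[theta_min, theta_max\] for a quantity; the interval is divided
#' into 10 equal bins and the expert distributes 100 "chips" among the bins,
#' the share of chips in a bin representing the probability of that outcome.
#' This file holds the data model: bin construction, chip-to-probability
#' conversion, record construction and validation, and the CSV readers and
#' writers for elicitation, point-score and site tables.
#' @name elicitation
NULL

.states <- c("reference", "future_bau", "future_offset")

.validation_error <- function(msg, violations) {
  stop(errorCondition(
    paste0(msg, " [", paste(violations, collapse = ", "), "]"),
    violations = violations,
    class = c("offsetElicit_validation_error", "error", "condition")
  ))
}

#' Divide an elicitation interval into 10 equal bins
#'
#' Bins are half-open `[lo, hi)` except the last, which is closed, so the
#' ten bins partition `[theta_min, theta_max]` with no gaps or overlaps.
#'
#' @param theta_min,theta_max Finite interval bounds, `theta_min < theta_max`.
#' @return data.frame with columns `bin` (1..10), `lower`, `upper`.
#' @examples
#' make_bins(0, 100)$lower  # 0, 10, ..., 90
#' @export
make_bins <- function(theta_min, theta_max) {
  if (!is.finite(theta_min) || !is.finite(theta_max)) {
    .validation_error("non-finite interval bound", "interval_finite")
  }
  if (theta_min >= theta_max) {
    .validation_error(
      sprintf("degenerate interval [%s, %s]", theta_min, theta_max),
      "degenerate_interval"
    )
  }
  edges <- seq(theta_min, theta_max, length.out = 11L)
  data.frame(bin = 1:10, lower = edges[1:10], upper = edges[2:11])
}

#' Convert chip counts to bin probabilities
#'
#' @param chips Vector of 10 non-negative integer chip counts summing to 100.
#' @return Numeric vector of 10 probabilities summing to 1.
#' @examples
#' chips_to_probabilities(rep(10, 10))
#' @export
chips_to_probabilities <- function(chips) {
  v <- character(0)
  if (length(chips) != 10L) v <- c(v, "chip_count")
  if (any(chips < 0) || any(chips != round(chips))) v <- c(v, "chip_integer")
  if (length(chips) == 10L && sum(chips) != 100) v <- c(v, "chip_sum")
  if (length(v)) .validation_error("invalid chip vector", v)
  as.numeric(chips) / 100
}

#' Construct a roulette elicitation record
#'
#' @param expert_id,scenario_id,attribute Labels.
#' @param state One of `"reference"`, `"future_bau"`, `"future_offset"`.
#' @param theta_min,theta_max Elicited interval bounds (attribute units).
#' @param chips 10 chip counts summing to 100.
#' @return A list of class `roulette_elicitation`.
#' @export
roulette_elicitation <- function(expert_id, scenario_id, attribute, state,
                                 theta_min, theta_max, chips) {
  rec <- list(expert_id = as.character(expert_id),
              scenario_id = as.character(scenario_id),
              attribute = as.character(attribute),
              state = as.character(state),
              theta_min = as.numeric(theta_min),
              theta_max = as.numeric(theta_max),
              chips = as.integer(chips))
  class(rec) <- "roulette_elicitation"
  rec
}

#' Validate a roulette elicitation against its attribute definition
#'
#' Checks the chip budget (exactly 100 over 10 bins), the interval
#' (`theta_min < theta_max`, both finite) and that the interval lies inside
#' the attribute's support. Unknown attributes or states are a hard error:
#' silently dropping records would bias the pooled benefit distributions.
#'
#' @param record A [roulette_elicitation()] record.
#' @param attributes Attribute table, see [wsgw_attributes()].
#' @return The record, invisibly unchanged, if valid. Otherwise an error of
#'   class `offsetElicit_validation_error` whose `violations` field lists the
#'   failed checks (e.g. `"chip_sum"`, `"support"`).
#' @export
validate_elicitation <- function(record, attributes = wsgw_attributes()) {
  v <- character(0)
  i <- match(record$attribute, attributes$name)
  if (is.na(i)) v <- c(v, "unknown_attribute")
  if (!record$state %in% .states) v <- c(v, "unknown_state")
  if (length(record$chips) != 10L) v <- c(v, "chip_count")
  else {
    if (any(record$chips < 0)) v <- c(v, "chip_negative")
    if (sum(record$chips) != 100L) v <- c(v, "chip_sum")
  }
  if (!is.finite(record$theta_min) || !is.finite(record$theta_max) ||
      record$theta_min >= record$theta_max) {
    v <- c(v, "degenerate_interval")
  } else if (!is.na(i)) {
    if (record$theta_min < attributes$support_min[i] ||
        record$theta_max > attributes$support_max[i]) {
      v <- c(v, "support")
    }
  }
  if (length(v)) {
    .validation_error(
      sprintf("invalid elicitation (expert %s, %s, %s, %s)",
              record$expert_id, record$scenario_id, record$attribute,
              record$state),
      v
    )
  }
  invisible(record)
}

#' Construct and validate a point-score record
#'
#' One expert's aggregate vegetation-condition scores for one site: current
#' score, the score expected in 20 years under offset management, and
#' (optionally) under business as usual. All scores are on 0-100.
#'
#' @param expert_id,site_id Labels.
#' @param current_score,future_offset_score Scores in \[0, 100\].
#' @param future_bau_score Optional score in \[0, 100\] (`NA` if not elicited).
#' @return A list of class `point_score_record`.
#' @export
point_score_record <- function(expert_id, site_id, current_score,
                               future_offset_score, future_bau_score = NA_real_) {
  sc <- c(current_score, future_offset_score,
          if (!is.na(future_bau_score)) future_bau_score)
  if (any(!is.finite(sc)) || any(sc < 0) || any(sc > 100)) {
    .validation_error(
      sprintf("point score out of [0,100] (expert %s, site %s)",
              expert_id, site_id),
      "score_range"
    )
  }
  rec <- list(expert_id = as.character(expert_id),
              site_id = as.character(site_id),
              current_score = as.numeric(current_score),
              future_offset_score = as.numeric(future_offset_score),
              future_bau_score = as.numeric(future_bau_score))
  class(rec) <- "point_score_record"
  rec
}

# ---- CSV schemas -----------------------------------------------------------

.chip_cols <- sprintf("chip_%02d", 1:10)

#' Write and read elicitation tables
#'
#' The on-disk schema is one row per record:
#' `expert_id, scenario_id, attribute, state, theta_min, theta_max,
#' chip_01..chip_10`. Reading validates every row against the attribute
#' table; a schema or validation failure reports the offending row.
#'
#' @param records data.frame in the schema above (as produced by
#'   [simulate_roulette_elicitations()]).
#' @param path File path.
#' @param attributes Attribute table used for validation.
#' @return `read_elicitations()` returns the validated data.frame.
#' @export
write_elicitations <- function(records, path) {
  cols <- c("expert_id", "scenario_id", "attribute", "state",
            "theta_min", "theta_max", .chip_cols)
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    .validation_error(paste("missing columns:", paste(missing, collapse = ", ")),
                      "schema")
  }
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_elicitations
#' @export
read_elicitations <- function(path, attributes = wsgw_attributes()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("expert_id", "scenario_id", "attribute", "state",
            "theta_min", "theta_max", .chip_cols)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    .validation_error(paste("missing columns:", paste(missing, collapse = ", ")),
                      "schema")
  }
  for (r in seq_len(nrow(df))) {
    rec <- df_row_to_record(df[r, ])
    tryCatch(validate_elicitation(rec, attributes), error = function(e) {
      stop(sprintf("row %d of %s: %s", r, path, conditionMessage(e)),
           call. = FALSE)
    })
  }
  df
}

# one data.frame row (schema above) -> roulette_elicitation
df_row_to_record <- function(row) {
  roulette_elicitation(row$expert_id, row$scenario_id, row$attribute,
                       row$state, row$theta_min, row$theta_max,
                       as.integer(row[.chip_cols]))
}

#' Write and read point-score tables
#'
#' Schema: `expert_id, site_id, current, future_offset, future_bau`
#' (`future_bau` may be blank where that future was not elicited).
#'
#' @param scores data.frame in the schema above.
#' @param path File path.
#' @return `read_point_scores()` returns the validated data.frame.
#' @export
write_point_scores <- function(scores, path) {
  cols <- c("expert_id", "site_id", "current", "future_offset", "future_bau")
  missing <- setdiff(cols, names(scores))
  if (length(missing)) {
    .validation_error(paste("missing columns:", paste(missing, collapse = ", ")),
                      "schema")
  }
  utils::write.csv(scores[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_scores
#' @export
read_point_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("expert_id", "site_id", "current", "future_offset", "future_bau")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    .validation_error(paste("missing columns:", paste(missing, collapse = ", ")),
                      "schema")
  }
  for (r in seq_len(nrow(df))) {
    tryCatch(
      point_score_record(df$expert_id[r], df$site_id[r], df$current[r],
                         df$future_offset[r], df$future_bau[r]),
      error = function(e) {
        stop(sprintf("row %d of %s: %s", r, path, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  df
}

#' Write and read site-description tables
#'
#' Schema: `site_id`, one column per condition attribute (named as in
#' [wsgw_attributes()]), `landscape_cover`, `invasive_alien_cover`,
#' `total_alien_cover`.
#'
#' @param sites data.frame in the schema above.
#' @param path File path.
#' @param attributes Attribute table used for validation.
#' @return `read_sites()` returns the validated data.frame.
#' @export
write_sites <- function(sites, path, attributes = wsgw_attributes()) {
  cols <- c("site_id", attributes$name,
            "landscape_cover", "invasive_alien_cover", "total_alien_cover")
  missing <- setdiff(cols, names(sites))
  if (length(missing)) {
    .validation_error(paste("missing columns:", paste(missing, collapse = ", ")),
                      "schema")
  }
  utils::write.csv(sites[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path, attributes = wsgw_attributes()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("site_id", attributes$name,
            "landscape_cover", "invasive_alien_cover", "total_alien_cover")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    .validation_error(paste("missing columns:", paste(missing, collapse = ", ")),
                      "schema")
  }
  for (a in seq_len(nrow(attributes))) {
    x <- df[[attributes$name[a]]]
    if (any(x < attributes$support_min[a] | x > attributes$support_max[a])) {
      .validation_error(
        sprintf("attribute %s outside support in %s", attributes$name[a], path),
        "support"
      )
    }
  }
  covers <- c("landscape_cover", "invasive_alien_cover", "total_alien_cover")
  for (cc in covers) {
    if (any(df[[cc]] < 0 | df[[cc]] > 100)) {
      .validation_error(sprintf("%s outside [0,100] in %s", cc, path), "support")
    }
  }
  df
}
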