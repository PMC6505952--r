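#' @title Averted loss, management gain and total benefit
#' @description
#' The benefit of managing a site as a biodiversity offset is decomposed
#' relative to a business-as-usual (BAU) counterfactual:
#' management gain MG = future value with offset - current value,
#' averted loss AL = current value - future value without offset, and
#' total benefit TB = AL + MG. For individual attributes, values are first
#' standardised against a reference benchmark: BC = V / R capped at 1, so
#' benefits are expressed on a 0-1 condition scale. Expert-specific fitted
#' distributions are sampled and pooled across the panel, so the resulting
#' benefit distributions reflect variation both within and among experts.
#' @name benefit_engine
NULL

#' Reference-standardised condition score
#'
#' `condition_score(value, reference)` returns `min(value / reference, 1)`:
#' an attribute at or above its reference benchmark scores 1; below it, the
#' proportion of the benchmark attained. Capping at 1 reflects the common
#' assessment assumption that accrual beyond the reference does not
#' represent additional biodiversity value.
#'
#' @param value Current or future attribute value (>= 0). Vectorised.
#' @param reference Reference benchmark value (> 0). Vectorised.
#' @return Condition score(s) in \[0, 1\].
#' @examples
#' condition_score(30, 60)  # 0.5
#' condition_score(75, 60)  # capped at 1
#' @export
condition_score <- function(value, reference) {
  if (any(!is.finite(value)) || any(!is.finite(reference))) {
    stop("condition_score: non-finite input")
  }
  if (any(value < 0) || any(reference <= 0)) {
    stop("condition_score: value must be >= 0 and reference > 0")
  }
  pmin(value / reference, 1)
}

#' Benefit arithmetic for aggregate point scores
#'
#' On the aggregate 0-100 condition scale no reference standardisation is
#' applied: MG = future-with-offset - current; where a BAU future was
#' elicited, AL = current - future-BAU and TB = AL + MG. Negative values are
#' meaningful (an expected decline despite, or relative to, management).
#'
#' @param record A [point_score_record()] (or any list with `current_score`,
#'   `future_offset_score`, `future_bau_score`).
#' @return list with `MG`, and `AL`, `TB` (both `NA` when no BAU score).
#' @examples
#' aggregate_point_benefit(point_score_record("e", "s", 60, 70, 50))
#' @export
aggregate_point_benefit <- function(record) {
  MG <- record$future_offset_score - record$current_score
  if (is.null(record$future_bau_score) || is.na(record$future_bau_score)) {
    list(MG = MG, AL = NA_real_, TB = NA_real_)
  } else {
    AL <- record$current_score - record$future_bau_score
    list(MG = MG, AL = AL, TB = AL + MG)
  }
}

# fits table -> named list of per-expert fitted params for one attr/state
.fits_lookup <- function(fits, attribute, state) {
  f <- fits[fits$attribute == attribute & fits$state == state, , drop = FALSE]
  stats::setNames(
    lapply(seq_len(nrow(f)), function(i) {
      list(family = f$family[i], params = c(f$param1[i], f$param2[i]))
    }),
    f$expert_id
  )
}

#' Monte-Carlo pooled benefit distributions for one scenario
#'
#' For every expert contributing a fitted future-with-offset distribution,
#' draws `draws_per_expert` triples: one reference value R, one offset
#' future V_off and (where a BAU distribution exists) one BAU future V_bau.
#' Within a draw the same reference sample standardises the start value and
#' both futures, keeping AL, MG and TB internally coherent. Per draw:
#' `BC_start = condition_score(start, R)`, `BC_offset =
#' condition_score(V_off, R)`, `MG = BC_offset - BC_start`, and with BAU
#' `AL = BC_start - BC_bau`, `TB = AL + MG`. Draws pool across experts, so
#' the per-attribute sample count is exactly
#' `n_experts x draws_per_expert` (25 experts at the default of 84 draws
#' give 2100 pooled samples).
#'
#' Reference draws below `ref_floor_frac` of the reference distribution's
#' mean are floored there to prevent ratio blow-ups; the number of floor
#' events is attached as attribute `floor_events`.
#'
#' @param fits Fits table from [fit_elicitations()] for one scenario (must
#'   contain `reference` and `future_offset` states; `future_bau` optional).
#' @param start_values Named numeric vector of the scenario's starting
#'   attribute values.
#' @param draws_per_expert Draws per expert per attribute (default 84).
#' @param exclude Attributes to drop from pooling (e.g. fern attributes,
#'   which are typically absent or near-zero in reference distributions and
#'   make the standardised ratio unstable).
#' @param ref_floor_frac Floor for reference draws, as a fraction of the
#'   reference distribution mean.
#' @param seed Optional seed; draws are reproducible given it (experts and
#'   attributes are visited in sorted order, so the draw stream is
#'   well-defined).
#' @param attributes Attribute table.
#' @return data.frame of benefit samples: `expert_id`, `attribute`, `draw`,
#'   `BC_start`, `BC_bau`, `BC_offset`, `AL`, `MG`, `TB` (AL/TB `NA` without
#'   BAU). Attribute `floor_events` counts floored reference draws.
#' @export
pooled_benefit <- function(fits, start_values, draws_per_expert = 84,
                           exclude = character(0), ref_floor_frac = 0.01,
                           seed = NULL, attributes = wsgw_attributes()) {
  if (!is.null(seed)) set.seed(seed)
  attrs <- intersect(unique(fits$attribute), names(start_values))
  attrs <- sort(setdiff(attrs, exclude))
  if (!length(attrs)) stop("pooled_benefit: no attributes to pool")
  floor_events <- 0L
  out <- list()
  for (a in attrs) {
    ref <- .fits_lookup(fits, a, "reference")
    off <- .fits_lookup(fits, a, "future_offset")
    bau <- .fits_lookup(fits, a, "future_bau")
    experts <- sort(names(off))
    missing_ref <- setdiff(experts, names(ref))
    if (length(missing_ref)) {
      stop(sprintf(
        "pooled_benefit: expert(s) %s have a future_offset fit but no reference fit for %s",
        paste(missing_ref, collapse = ", "), a))
    }
    start <- start_values[[a]]
    def <- attribute_definition(a, attributes)
    if (start < def$support_min || start > def$support_max) {
      stop(sprintf("pooled_benefit: start value for %s outside support", a))
    }
    for (e in experts) {
      R <- sample_fitted(ref[[e]], draws_per_expert, a, attributes)
      ref_mean <- if (ref[[e]]$family == "normal") ref[[e]]$params[1]
                  else 100 * ref[[e]]$params[1] / sum(ref[[e]]$params)
      floor_val <- max(ref_floor_frac * ref_mean, 1e-6)
      floor_events <- floor_events + sum(R < floor_val)
      R <- pmax(R, floor_val)
      V_off <- sample_fitted(off[[e]], draws_per_expert, a, attributes)
      BC_start <- condition_score(rep(start, draws_per_expert), R)
      BC_offset <- condition_score(V_off, R)
      MG <- BC_offset - BC_start
      if (e %in% names(bau)) {
        V_bau <- sample_fitted(bau[[e]], draws_per_expert, a, attributes)
        BC_bau <- condition_score(V_bau, R)
        AL <- BC_start - BC_bau
        TB <- AL + MG
      } else {
        BC_bau <- AL <- TB <- rep(NA_real_, draws_per_expert)
      }
      out[[length(out) + 1L]] <- data.frame(
        expert_id = e, attribute = a, draw = seq_len(draws_per_expert),
        BC_start = BC_start, BC_bau = BC_bau, BC_offset = BC_offset,
        AL = AL, MG = MG, TB = TB, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "floor_events") <- floor_events
  res
}

#' Summarise pooled benefit samples per attribute
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) so results are bit-reproducible. The negative
#' and zero fractions of total benefit are reported with an explicit
#' tolerance: `fraction_negative_TB` is the share with `TB < -zero_tolerance`
#' and `fraction_zero_TB` the share with `|TB| <= zero_tolerance` (exact
#' zeros arise from the condition-score cap when both futures and the start
#' sit at or above the reference).
#'
#' @param samples Benefit samples from [pooled_benefit()].
#' @param zero_tolerance Half-width of the "zero" band for TB.
#' @return data.frame, one row per attribute: `n_samples`, `q25/median/q75`
#'   for each of AL, MG, TB (NA where no BAU), `fraction_negative_TB`,
#'   `fraction_zero_TB`.
#' @export
summarize_benefit <- function(samples, zero_tolerance = 1e-9) {
  if (is.null(samples) || !nrow(samples)) stop("summarize_benefit: empty sample set")
  q <- function(x, p) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    unname(stats::quantile(x, p, type = 7))
  }
  do.call(rbind, lapply(split(samples, samples$attribute), function(s) {
    tb <- s$TB[!is.na(s$TB)]
    data.frame(
      attribute = s$attribute[1], n_samples = nrow(s),
      AL_q25 = q(s$AL, .25), AL_median = q(s$AL, .5), AL_q75 = q(s$AL, .75),
      MG_q25 = q(s$MG, .25), MG_median = q(s$MG, .5), MG_q75 = q(s$MG, .75),
      TB_q25 = q(s$TB, .25), TB_median = q(s$TB, .5), TB_q75 = q(s$TB, .75),
      fraction_negative_TB = if (length(tb)) mean(tb < -zero_tolerance) else NA_real_,
      fraction_zero_TB = if (length(tb)) mean(abs(tb) <= zero_tolerance) else NA_real_,
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Management gain against starting condition, per attribute
#'
#' Pairs each attribute's starting-condition summary (median and quartiles
#' of BC_start over the pooled draws) with its management-gain summary, the
#' table behind the "does gain depend on starting condition" scatter.
#'
#' @param samples Benefit samples from [pooled_benefit()] (one scenario), or
#'   several scenarios' samples rbind-ed with a `scenario_id` column.
#' @return data.frame, one row per (scenario x) attribute with BC_start and
#'   MG medians and quartiles.
#' @export
mg_vs_start <- function(samples) {
  if (is.null(samples) || !nrow(samples)) stop("mg_vs_start: empty sample set")
  key <- if ("scenario_id" %in% names(samples)) {
    interaction(samples$scenario_id, samples$attribute, drop = TRUE)
  } else samples$attribute
  do.call(rbind, lapply(split(samples, key), function(s) {
    qq <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))
    data.frame(
      scenario_id = if ("scenario_id" %in% names(s)) s$scenario_id[1] else NA_character_,
      attribute = s$attribute[1],
      BC_start_q25 = qq(s$BC_start, .25), BC_start_median = qq(s$BC_start, .5),
      BC_start_q75 = qq(s$BC_start, .75),
      MG_q25 = qq(s$MG, .25), MG_median = qq(s$MG, .5), MG_q75 = qq(s$MG, .75),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}
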