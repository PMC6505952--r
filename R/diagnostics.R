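#' @title Per-expert optimism and pessimism diagnostics
#' @description
#' Averaging each expert's benefit draws per attribute gives a point in the
#' (mean AL, mean MG) plane. Quadrants of that plane read as opinions about
#' future trends: low AL with high MG is optimism under both BAU and offset
#' management; high AL with low MG is pessimism regardless of management;
#' high AL with high MG is pessimism about BAU but belief in the offset.
#' A negative AL-MG association across experts indicates a shared
#' "temporal" disposition: experts pessimistic about the counterfactual also
#' tend not to believe values will improve with an offset.
#' @name expert_diagnostics
NULL

#' Per-expert mean averted loss and management gain
#'
#' @param samples Benefit samples from [pooled_benefit()]. Attributes with
#'   no BAU draws at all (AL entirely missing) are excluded with a warning.
#' @return data.frame: `expert_id`, `attribute`, `mean_AL`, `mean_MG`,
#'   `n_draws`.
#' @export
expert_means <- function(samples) {
  has_al <- tapply(!is.na(samples$AL), samples$attribute, any)
  dropped <- names(has_al)[!has_al]
  if (length(dropped)) {
    warning(sprintf("no BAU draws for attribute(s) %s; excluded from expert means",
                    paste(dropped, collapse = ", ")))
    samples <- samples[samples$attribute %in% names(has_al)[has_al], , drop = FALSE]
  }
  if (!nrow(samples)) stop("expert_means: no attributes with averted-loss draws")
  samples <- samples[!is.na(samples$AL), , drop = FALSE]
  agg <- stats::aggregate(cbind(AL, MG) ~ expert_id + attribute, data = samples,
                          FUN = mean)
  n <- stats::aggregate(draw ~ expert_id + attribute, data = samples,
                        FUN = length)
  out <- merge(agg, n, by = c("expert_id", "attribute"))
  names(out) <- c("expert_id", "attribute", "mean_AL", "mean_MG", "n_draws")
  out[order(out$attribute, out$expert_id), , drop = FALSE]
}

#' Classify an expert-attribute mean into an opinion quadrant
#'
#' A tolerance band around both axes gives a tie rule for points near the
#' origin. The classification is exhaustive and mutually exclusive:
#' `neutral` (both means within tolerance), `optimistic_both` (MG above
#' tolerance, AL not above it), `offset_believer` (both above),
#' `pessimistic_both` (AL above, MG not above), `offset_sceptic` (the rest:
#' neither gain believed, no loss averted).
#'
#' @param mean_AL,mean_MG Per-expert per-attribute means (vectorised).
#' @param tolerance Half-width of the neutral band on the condition scale.
#' @return Character vector of quadrant labels.
#' @examples
#' classify_quadrant(-0.05, 0.10)  # optimistic_both
#' classify_quadrant(0.10, 0.10)   # offset_believer
#' @export
classify_quadrant <- function(mean_AL, mean_MG, tolerance = 0.01) {
  stopifnot(length(mean_AL) == length(mean_MG), tolerance >= 0)
  s_al <- ifelse(mean_AL > tolerance, 1L, ifelse(mean_AL < -tolerance, -1L, 0L))
  s_mg <- ifelse(mean_MG > tolerance, 1L, ifelse(mean_MG < -tolerance, -1L, 0L))
  ifelse(s_al == 0L & s_mg == 0L, "neutral",
  ifelse(s_mg > 0L & s_al <= 0L, "optimistic_both",
  ifelse(s_mg > 0L & s_al > 0L, "offset_believer",
  ifelse(s_al > 0L, "pessimistic_both", "offset_sceptic"))))
}

#' Linear AL-MG relationship across experts for one attribute
#'
#' Ordinary least squares of mean MG on mean AL over experts, plus the
#' Pearson correlation. A negative slope indicates that experts expecting
#' larger counterfactual losses also expect smaller offset gains.
#'
#' @param means Output of [expert_means()].
#' @param attribute Attribute to fit.
#' @return list with `slope`, `intercept`, `correlation`, `n`.
#' @export
al_mg_fit <- function(means, attribute) {
  m <- means[means$attribute == attribute, , drop = FALSE]
  if (nrow(m) < 3) {
    stop(sprintf("al_mg_fit: need >= 3 experts for %s, have %d",
                 attribute, nrow(m)))
  }
  fit <- stats::lm(mean_MG ~ mean_AL, data = m)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = stats::cor(m$mean_AL, m$mean_MG),
       n = nrow(m))
}

#' Flag experts with a systematic optimistic or pessimistic bias
#'
#' An expert is flagged optimistic (pessimistic) when their mean management
#' gain is positive (negative) for at least `threshold` of the attributes
#' they assessed; anything less consistent is `unbiased`. Experts assessed
#' on fewer than `min_attributes` attributes are not classified (`NA`).
#'
#' @param means Output of [expert_means()].
#' @param threshold Fraction of attributes with a consistent sign (default
#'   0.8, flagging only strong consistency).
#' @param min_attributes Minimum attributes per expert for a classification.
#' @return data.frame: `expert_id`, `n_attributes`, `n_positive`,
#'   `n_negative`, `bias` in `{optimist, pessimist, unbiased, NA}`.
#' @export
systematic_bias <- function(means, threshold = 0.8, min_attributes = 5) {
  do.call(rbind, lapply(split(means, means$expert_id), function(m) {
    n <- nrow(m)
    npos <- sum(m$mean_MG > 0)
    nneg <- sum(m$mean_MG < 0)
    bias <- if (n < min_attributes) NA_character_
            else if (npos / n >= threshold) "optimist"
            else if (nneg / n >= threshold) "pessimist"
            else "unbiased"
    data.frame(expert_id = m$expert_id[1], n_attributes = n,
               n_positive = npos, n_negative = nneg, bias = bias,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
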