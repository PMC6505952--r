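#' Elicitation scenarios for future attribute values
#'
#' A scenario is a hypothetical 2 ha vegetation patch, described by starting
#' values of the 13 condition attributes plus landscape and alien-plant
#' covers, for which experts predict attribute values 20 years ahead. Three
#' grassy-woodland scenarios are built in, spanning good (aggregate condition
#' 84/100), moderate (60/100) and poor (39/100) starting quality. Only the
#' moderate scenario elicits a business-as-usual future in addition to the
#' future with offset, so averted loss and total benefit are computable for
#' it alone; the good and poor scenarios elicit management gain only.
#'
#' Starting attribute values are placed on the same latent condition gradient
#' the synthetic site generator uses, with a fixed per-attribute spread so
#' that starting condition (relative to reference) varies across attributes
#' within a scenario.
#'
#' @param attributes Attribute table, see [wsgw_attributes()].
#' @param reference Reference-benchmark table, see
#'   [wsgw_reference_distributions()].
#' @return A list of three scenario objects (class `offset_scenario`), each a
#'   list with `id`, `vegetation_class`, `condition_score`, `u` (latent
#'   gradient position), `start_values` (named numeric, one per attribute),
#'   `landscape_cover_pct`, `invasive_alien_cover_pct`,
#'   `total_alien_cover_pct`, `states_elicited`, `horizon_years`.
#' @export
wsgw_scenarios <- function(attributes = wsgw_attributes(),
                           reference = wsgw_reference_distributions()) {
  specs <- list(
    list(id = "wsgw_moderate", condition_score = 60, u = 0.60,
         states = c("reference", "future_bau", "future_offset")),
    list(id = "wsgw_good", condition_score = 84, u = 0.84,
         states = c("reference", "future_offset")),
    list(id = "wsgw_poor", condition_score = 39, u = 0.39,
         states = c("reference", "future_offset"))
  )
  lapply(specs, function(s) {
    sc <- list(
      id = s$id,
      vegetation_class = "Western Slopes Grassy Woodland",
      condition_score = s$condition_score,
      u = s$u,
      start_values = scenario_start_values(s$u, attributes, reference),
      landscape_cover_pct = min(100, 20 + 60 * s$u),
      invasive_alien_cover_pct = max(0, 55 * (1 - s$u) - 5),
      total_alien_cover_pct = max(0, 70 * (1 - s$u)),
      states_elicited = s$states,
      horizon_years = 20
    )
    class(sc) <- "offset_scenario"
    sc
  })
}

# Deterministic per-attribute spread around the scenario's gradient position,
# so starting condition varies across attributes within one scenario.
.attribute_u_offsets <- function(attributes) {
  k <- nrow(attributes)
  delta <- seq(-0.15, 0.15, length.out = k)
  # fixed interleave so neighbouring table rows do not get neighbouring offsets
  ord <- as.vector(rbind(seq_len(ceiling(k / 2)), k + 1 - seq_len(ceiling(k / 2))))
  delta[ord[seq_len(k)]]
}

#' Starting attribute values at a latent condition position
#'
#' Maps a position `u` in \[0, 1\] on the condition gradient to starting
#' values for every attribute: a monotone fraction of the reference mean,
#' clipped to the attribute support. Used both by [wsgw_scenarios()] and by
#' the synthetic site generator.
#'
#' @param u Latent condition in \[0, 1\] (1 = near reference).
#' @inheritParams wsgw_scenarios
#' @return Named numeric vector of starting values.
#' @export
scenario_start_values <- function(u, attributes = wsgw_attributes(),
                                  reference = wsgw_reference_distributions()) {
  du <- .attribute_u_offsets(attributes)
  ua <- pmin(1, pmax(0.02, u + du))
  v <- reference$ref_mean[match(attributes$name, reference$name)] *
    (0.05 + 0.95 * ua)
  v <- pmin(pmax(v, attributes$support_min), attributes$support_max)
  # counts are whole numbers in a site description
  counts <- attributes$category %in% c("richness_count", "large_tree_count")
  v[counts] <- round(v[counts])
  stats::setNames(v, attributes$name)
}
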