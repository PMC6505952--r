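#' Vegetation condition attributes for a grassy-woodland assessment
#'
#' The 13 site-scale attributes used throughout the package: native foliage
#' cover and native species richness for five growth forms (tree, shrub,
#' grass and grass-like, forb, fern), plus three habitat-structure attributes
#' (number of large trees, litter cover, lineal length of fallen logs).
#' Cover and richness are assessed in a 400 m^2 (20 m x 20 m) plot and
#' habitat structure in a 1000 m^2 (20 m x 50 m) plot.
#'
#' Supports are fixed per category: percentage covers live on \[0, 100\];
#' counts and lengths are non-negative and unbounded above.
#'
#' @return A data.frame with one row per attribute and columns `name`,
#'   `category`, `plot_area_m2`, `support_min`, `support_max`.
#' @examples
#' wsgw_attributes()
#' @export
wsgw_attributes <- function() {
  data.frame(
    name = c("tree_cover", "shrub_cover", "grass_cover", "forb_cover",
             "fern_cover",
             "tree_richness", "shrub_richness", "grass_richness",
             "forb_richness", "fern_richness",
             "large_trees", "litter_cover", "log_length"),
    category = c(rep("foliage_cover_pct", 5),
                 rep("richness_count", 5),
                 "large_tree_count", "litter_cover_pct", "log_length_m"),
    plot_area_m2 = c(rep(400, 10), 1000, 1000, 1000),
    support_min = 0,
    support_max = c(rep(100, 5), rep(Inf, 5), Inf, 100, Inf),
    stringsAsFactors = FALSE
  )
}

# categories measured as a percentage (rescalable to (0,1) for beta fitting)
.percent_categories <- c("foliage_cover_pct", "litter_cover_pct")

#' Look up one attribute definition
#'
#' @param name Attribute name as in [wsgw_attributes()].
#' @param attributes Attribute table; defaults to [wsgw_attributes()].
#' @return A one-row data.frame (the attribute definition).
#' @export
attribute_definition <- function(name, attributes = wsgw_attributes()) {
  i <- match(name, attributes$name)
  if (is.na(i)) {
    stop(errorCondition(
      sprintf("unknown attribute '%s'", name),
      violations = "unknown_attribute",
      class = c("offsetElicit_validation_error", "error", "condition")
    ))
  }
  attributes[i, , drop = FALSE]
}

#' Parametric family used for an attribute's subjective distribution
#'
#' Attributes estimated as a percentage (foliage and litter covers) are fitted
#' with a beta distribution after rescaling to (0, 1); all remaining
#' attributes (richness counts, large-tree counts, log length) use a normal
#' distribution.
#'
#' @inheritParams attribute_definition
#' @return `"beta_rescaled"` or `"normal"`.
#' @examples
#' choose_family("grass_cover")   # beta_rescaled
#' choose_family("forb_richness") # normal
#' @export
choose_family <- function(name, attributes = wsgw_attributes()) {
  def <- attribute_definition(name, attributes)
  if (def$category %in% .percent_categories) "beta_rescaled" else "normal"
}

#' Synthetic reference-benchmark distributions for the 13 attributes
#'
#' A reference (benchmark) condition is the best-attainable state of an
#' attribute in the contemporary landscape. The study's elicited reference
#' distributions are not deposited, so the generator uses this synthetic
#' benchmark table: a plausible mean and spread per attribute for a grassy
#' woodland in reference condition. These values parameterise the synthetic
#' expert panel; they are stand-ins, not field estimates.
#'
#' @return data.frame with columns `name`, `ref_mean`, `ref_sd`.
#' @export
wsgw_reference_distributions <- function() {
  data.frame(
    name = wsgw_attributes()$name,
    ref_mean = c(30, 15, 60, 20, 5,     # % foliage covers
                 4, 8, 18, 25, 2,       # richness / 400 m^2
                 10, 70, 60),           # large trees, litter %, logs m
    ref_sd = c(7.5, 4, 12, 5, 2,
               1.2, 2, 4, 6, 1,
               3, 15, 18),
    stringsAsFactors = FALSE
  )
}
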