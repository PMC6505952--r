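#' @title Fitting subjective probability distributions to roulette histograms
#' @description
#' An elicited histogram (10 bins, 100 chips) is summarised by a parametric
#' subjective distribution: a beta distribution rescaled from (0,1) to
#' (0,100) for percentage attributes, or a normal distribution otherwise.
#' Parameters minimise the sum of squared differences between the parametric
#' CDF and the elicited cumulative probabilities at the nine interior bin
#' edges (the convention of standard elicitation-fitting toolkits). Fitting
#' parametric forms lets distributions elicited on different intervals (and
#' hence non-matching bins) be pooled.
#' @name distribution_fit
NULL

# interior-edge cumulative probabilities of a fitted family
.family_cdf <- function(family, params, edges) {
  if (family == "normal") {
    stats::pnorm(edges, mean = params[1], sd = params[2])
  } else {
    x <- pmin(pmax(edges / 100, 1e-9), 1 - 1e-9) # rescale + boundary nudge
    stats::pbeta(x, shape1 = params[1], shape2 = params[2])
  }
}

.cdf_sse <- function(family, params, edges, cum_probs) {
  sum((.family_cdf(family, params, edges) - cum_probs)^2)
}

# moment-matched starting values from the histogram (midpoint approximation)
.moment_start <- function(bins, probs, family, min_sd) {
  mid <- (bins$lower + bins$upper) / 2
  m <- sum(probs * mid)
  s <- sqrt(max(sum(probs * (mid - m)^2), min_sd^2))
  if (family == "normal") return(c(m, s))
  mm <- min(max(m / 100, 1e-3), 1 - 1e-3)
  ss <- min(s / 100, 0.95 * sqrt(mm * (1 - mm)))
  nu <- mm * (1 - mm) / ss^2 - 1
  nu <- max(nu, 1e-2)
  c(mm * nu, (1 - mm) * nu)
}

# coarse grid fallback when the local search fails to converge
.grid_fallback <- function(family, edges, cum_probs, bins) {
  if (family == "normal") {
    width <- bins$upper[1] - bins$lower[1]
    mus <- seq(bins$lower[1], bins$upper[10], length.out = 41)
    sds <- seq(width / 4, (bins$upper[10] - bins$lower[1]), length.out = 40)
    grid <- expand.grid(mu = mus, sd = sds)
    sse <- mapply(function(a, b) .cdf_sse("normal", c(a, b), edges, cum_probs),
                  grid$mu, grid$sd)
  } else {
    ab <- exp(seq(log(0.05), log(200), length.out = 40))
    grid <- expand.grid(mu = ab, sd = ab) # mu, sd reused as alpha, beta
    sse <- mapply(function(a, b) .cdf_sse("beta_rescaled", c(a, b), edges, cum_probs),
                  grid$mu, grid$sd)
  }
  as.numeric(grid[which.min(sse), ])
}

#' Fit a parametric subjective distribution to a roulette histogram
#'
#' Minimises the squared distance between the family's CDF and the elicited
#' cumulative probabilities at the nine interior bin edges. For the
#' `beta_rescaled` family edges are first divided by 100; interior edges that
#' land exactly on 0 or 1 are nudged inward by 1e-9 before CDF evaluation.
#' Optimisation is a derivative-free Nelder-Mead search on (location,
#' log-scale) (normal) or (log alpha, log beta) (beta), started from
#' moment-matched values, with a coarse grid fallback.
#'
#' Histograms with all chips in a single bin would imply a degenerate
#' zero-variance distribution, which would collapse Monte-Carlo pooling;
#' instead the location is fixed at the bin midpoint and the spread floored
#' at a quarter of the bin width.
#'
#' @param record A validated [roulette_elicitation()] record.
#' @param attributes Attribute table, see [wsgw_attributes()].
#' @return A list of class `fitted_distribution`: `family`, `params` (named
#'   `mu`,`sigma` or `alpha`,`beta`), `fit_sse`, `single_bin` flag,
#'   `multimodal` flag plus the record's identifying labels.
#' @examples
#' rec <- roulette_elicitation("e1", "s1", "forb_richness", "reference",
#'                             8, 32, c(0, 2, 10, 24, 30, 22, 9, 3, 0, 0))
#' fit_distribution(rec)$params
#' @export
fit_distribution <- function(record, attributes = wsgw_attributes()) {
  validate_elicitation(record, attributes)
  family <- choose_family(record$attribute, attributes)
  bins <- make_bins(record$theta_min, record$theta_max)
  width <- bins$upper[1] - bins$lower[1]
  probs <- chips_to_probabilities(record$chips)
  edges <- bins$upper[1:9]
  cum_probs <- cumsum(probs)[1:9]
  mm <- detect_multimodality(record)

  nonzero <- which(record$chips > 0)
  if (length(nonzero) == 1L) {
    # single-bin fallback: midpoint location, minimum spread of width/4
    mid <- (bins$lower[nonzero] + bins$upper[nonzero]) / 2
    if (family == "normal") {
      params <- c(mu = mid, sigma = width / 4)
    } else {
      m <- min(max(mid / 100, 1e-3), 1 - 1e-3)
      s <- min((width / 4) / 100, 0.95 * sqrt(m * (1 - m)))
      nu <- m * (1 - m) / s^2 - 1
      params <- c(alpha = m * nu, beta = (1 - m) * nu)
    }
    sse <- .cdf_sse(family, params, edges, cum_probs)
    fit <- list(params = params, fit_sse = sse, single_bin = TRUE)
  } else {
    start <- .moment_start(bins, probs, family, min_sd = width / 4)
    if (family == "normal") {
      par0 <- c(start[1], log(start[2]))
      obj <- function(p) .cdf_sse("normal", c(p[1], exp(p[2])), edges, cum_probs)
      unpack <- function(p) c(mu = p[1], sigma = exp(p[2]))
    } else {
      par0 <- log(start)
      obj <- function(p) .cdf_sse("beta_rescaled", exp(p), edges, cum_probs)
      unpack <- function(p) c(alpha = exp(p[1]), beta = exp(p[2]))
    }
    opt <- tryCatch(
      stats::optim(par0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) {
      g <- .grid_fallback(family, edges, cum_probs, bins)
      params <- if (family == "normal") c(mu = g[1], sigma = g[2])
                else c(alpha = g[1], beta = g[2])
      sse <- .cdf_sse(family, params, edges, cum_probs)
      if (!is.finite(sse)) {
        stop(sprintf("distribution fit failed (expert %s, %s, %s, %s)",
                     record$expert_id, record$scenario_id, record$attribute,
                     record$state))
      }
      fit <- list(params = params, fit_sse = sse, single_bin = FALSE)
    } else {
      fit <- list(params = unpack(opt$par), fit_sse = opt$value,
                  single_bin = FALSE)
    }
  }

  out <- c(list(expert_id = record$expert_id,
                scenario_id = record$scenario_id,
                attribute = record$attribute,
                state = record$state,
                family = family),
           fit,
           list(multimodal = mm$multimodal))
  class(out) <- "fitted_distribution"
  out
}

#' Fit every record in an elicitation table
#'
#' @param records data.frame in the `elicitations.csv` schema (see
#'   [write_elicitations()]).
#' @param attributes Attribute table.
#' @return data.frame with one row per record: identifying labels, `family`,
#'   `param1`, `param2`, `fit_sse`, `single_bin`, `multimodal`. `param1`,
#'   `param2` are (mu, sigma) for normal fits and (alpha, beta) for
#'   rescaled-beta fits.
#' @export
fit_elicitations <- function(records, attributes = wsgw_attributes()) {
  fits <- lapply(seq_len(nrow(records)), function(r) {
    f <- fit_distribution(df_row_to_record(records[r, ]), attributes)
    data.frame(expert_id = f$expert_id, scenario_id = f$scenario_id,
               attribute = f$attribute, state = f$state, family = f$family,
               param1 = unname(f$params[1]), param2 = unname(f$params[2]),
               fit_sse = f$fit_sse, single_bin = f$single_bin,
               multimodal = f$multimodal, stringsAsFactors = FALSE)
  })
  do.call(rbind, fits)
}

#' Draw samples from a fitted subjective distribution
#'
#' Draws are clipped to the attribute's support (counts and lengths floored
#' at zero; covers clipped to \[0, 100\]). The fraction of draws clipped is
#' attached as attribute `clipped_fraction` so truncation is never silent.
#'
#' @param fit A `fitted_distribution` (or a list with `family` and `params`).
#' @param n Number of draws.
#' @param attribute Attribute name (determines the support).
#' @param attributes Attribute table.
#' @return Numeric vector of `n` draws.
#' @export
sample_fitted <- function(fit, n, attribute = fit$attribute,
                          attributes = wsgw_attributes()) {
  def <- attribute_definition(attribute, attributes)
  x <- if (fit$family == "normal") {
    stats::rnorm(n, mean = fit$params[1], sd = fit$params[2])
  } else {
    100 * stats::rbeta(n, shape1 = fit$params[1], shape2 = fit$params[2])
  }
  clipped <- mean(x < def$support_min | x > def$support_max)
  x <- pmin(pmax(x, def$support_min), def$support_max)
  attr(x, "clipped_fraction") <- clipped
  x
}

#' Flag multimodal roulette histograms
#'
#' A histogram is flagged when its chip vector has two or more strict local
#' maxima separated by at least one bin with strictly fewer chips. Flagged
#' records are still fitted (with a unimodal family); the flag is carried
#' through so such fits can be reviewed.
#'
#' @param record A [roulette_elicitation()] record (or any 10-chip vector via
#'   `record$chips`).
#' @return list with `multimodal` (logical) and `modes` (bin indices of
#'   strict local maxima).
#' @examples
#' r <- roulette_elicitation("e", "s", "grass_cover", "reference", 0, 100,
#'                           c(0, 30, 0, 0, 0, 0, 0, 30, 0, 40))
#' detect_multimodality(r)
#' @export
detect_multimodality <- function(record) {
  chips <- record$chips
  k <- length(chips)
  peaks <- integer(0)
  for (i in seq_len(k)) {
    left <- if (i > 1) chips[i - 1] else -Inf
    right <- if (i < k) chips[i + 1] else -Inf
    if (chips[i] > left && chips[i] > right) peaks <- c(peaks, i)
  }
  flagged <- FALSE
  if (length(peaks) >= 2) {
    for (j in seq_len(length(peaks) - 1)) {
      p <- peaks[j]; q <- peaks[j + 1]
      valley <- chips[(p + 1):(q - 1)]
      if (any(valley < min(chips[p], chips[q]))) flagged <- TRUE
    }
  }
  list(multimodal = flagged, modes = peaks)
}
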