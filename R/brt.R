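#' @title Boosted regression trees for aggregate condition scores
#' @description
#' Exploratory analysis of the point-score elicitation: stagewise
#' squared-error gradient boosting of current condition, management gain,
#' averted loss or total benefit on the 13 vegetation attributes, landscape
#' vegetation cover, invasive and total alien plant cover, and expert
#' identity (plus the expert's current score for the change responses).
#' Covariate importance is summarised as normalised relative influence
#' (NRI): the squared-error improvement credited to each covariate's splits,
#' accumulated over all trees and normalised to sum to 100. Boosting is
#' performed by \pkg{xgboost}; the tree count is chosen by k-fold
#' cross-validation grown in steps, stopping when the cross-validated
#' deviance stops improving.
#' @name relative_influence_module
NULL

#' Boosting configuration
#'
#' Defaults follow common practice for expert-score analyses of this size:
#' small learning rate (0.005) so many trees contribute, interaction depth
#' (tree complexity) 5, and per-tree row subsampling at a bag fraction of
#' 0.75. `tree_step` is both the granularity of the tree-count search and
#' the early-stopping patience of the cross-validated deviance.
#'
#' @param tree_complexity Maximum splits per tree (interaction depth).
#' @param learning_rate Shrinkage weight of each tree.
#' @param bag_fraction Per-tree row-subsampling fraction in (0, 1\].
#' @param cv_folds Folds for the tree-count cross-validation.
#' @param tree_step Step size / patience (trees) of the tree-count search.
#' @param max_trees Upper bound on the ensemble size.
#' @param seed Seed controlling subsampling and fold assignment.
#' @return list of class `brt_config`.
#' @export
brt_config <- function(tree_complexity = 5, learning_rate = 0.005,
                       bag_fraction = 0.75, cv_folds = 10, tree_step = 50,
                       max_trees = 10000, seed = 1) {
  stopifnot(tree_complexity >= 1, learning_rate > 0,
            bag_fraction > 0, bag_fraction <= 1,
            cv_folds >= 2, tree_step >= 1, max_trees >= 1)
  structure(list(tree_complexity = tree_complexity,
                 learning_rate = learning_rate,
                 bag_fraction = bag_fraction,
                 cv_folds = cv_folds, tree_step = tree_step,
                 max_trees = max_trees, seed = seed),
            class = "brt_config")
}

#' Build a model table from point scores and site descriptions
#'
#' Joins each score record to its site description, computes the response,
#' and assembles the covariates: the 13 condition attributes, landscape
#' cover, invasive and total alien cover, and expert identity (a
#' categorical covariate — some experts score everything higher or lower
#' than the average expert). For the change responses (`MG`, `AL`, `TB`)
#' the expert's own current score is appended as an additional covariate,
#' and rows from experts who did not score a BAU future are dropped for
#' `AL`/`TB`. Rows are sorted by (expert, site), so downstream fits are
#' invariant to the input row order.
#'
#' @param scores Point-score table (schema of [read_point_scores()]).
#' @param sites Site table (schema of [read_sites()]).
#' @param response One of `"current"`, `"MG"`, `"AL"`, `"TB"`.
#' @param attributes Attribute table.
#' @return list of class `brt_design`: `x` (covariate data.frame with
#'   `expert_id` as factor), `y` (response vector), `response`,
#'   `covariates` (names).
#' @export
build_design <- function(scores, sites, response = c("current", "MG", "AL", "TB"),
                         attributes = wsgw_attributes()) {
  response <- match.arg(response)
  missing_sites <- setdiff(unique(scores$site_id), sites$site_id)
  if (length(missing_sites)) {
    stop(sprintf("build_design: no site description for %s",
                 paste(missing_sites, collapse = ", ")))
  }
  site_cols <- c(attributes$name, "landscape_cover", "invasive_alien_cover",
                 "total_alien_cover")
  d <- merge(scores, sites[, c("site_id", site_cols)], by = "site_id")
  d <- d[order(d$expert_id, d$site_id), , drop = FALSE]
  y <- switch(response,
    current = d$current,
    MG = d$future_offset - d$current,
    AL = d$current - d$future_bau,
    TB = (d$current - d$future_bau) + (d$future_offset - d$current))
  if (response %in% c("AL", "TB")) {
    keep <- !is.na(d$future_bau)
    d <- d[keep, , drop = FALSE]
    y <- y[keep]
  }
  covs <- site_cols
  x <- d[, covs, drop = FALSE]
  if (response != "current") {
    x$current_score <- d$current
    covs <- c(covs, "current_score")
  }
  x$expert_id <- factor(d$expert_id)
  covs <- c(covs, "expert_id")
  rownames(x) <- NULL
  structure(list(x = x, y = y, response = response, covariates = covs,
                 site_id = d$site_id),
            class = "brt_design")
}

# covariate data.frame -> numeric matrix with one-hot expert identity
.design_matrix <- function(x, expert_levels) {
  num <- x[, setdiff(names(x), "expert_id"), drop = FALSE]
  m <- as.matrix(num)
  if (!is.null(expert_levels)) {
    oh <- outer(as.character(x$expert_id), expert_levels, `==`) * 1
    colnames(oh) <- paste0("expert_id__", expert_levels)
    m <- cbind(m, oh)
  }
  m
}

#' Fit a boosted regression tree ensemble
#'
#' Stagewise squared-error gradient boosting with per-tree row subsampling
#' at the bag fraction and trees of the configured interaction depth.
#' The number of trees is selected by `cv_folds`-fold cross-validation:
#' trees are added until the cross-validated deviance has not improved for
#' `tree_step` rounds (or `max_trees` is reached), and the final ensemble is
#' refitted on all rows at the selected size, rounded up to a multiple of
#' `tree_step`. Expert identity is one-hot encoded for the tree builder;
#' [relative_influence()] sums the encoded columns back to a single
#' expert-identity influence. Deterministic given `config$seed`.
#'
#' @param design A [build_design()] result.
#' @param config A [brt_config()].
#' @return list of class `brt_fit`: the booster, selected tree count,
#'   cross-validated deviance profile, feature names, expert levels, the
#'   training table and the configuration.
#' @export
fit_brt <- function(design, config = brt_config()) {
  if (length(design$covariates) < 2) stop("fit_brt: need >= 2 covariates")
  if (length(design$y) < 50) stop("fit_brt: need >= 50 rows")
  expert_levels <- levels(design$x$expert_id)
  X <- .design_matrix(design$x, expert_levels)
  y <- design$y
  params <- list(objective = "reg:squarederror",
                 eta = config$learning_rate,
                 max_depth = config$tree_complexity,
                 subsample = config$bag_fraction,
                 nthread = 1,
                 base_score = mean(y))
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  if (stats::var(y) < 1e-12) {
    # constant response: the ensemble is its base score, no splits needed
    set.seed(config$seed)
    booster <- xgboost::xgb.train(params, dtrain, nrounds = 1, verbose = 0)
    n_trees <- 0L
    cv_profile <- numeric(0)
  } else {
    set.seed(config$seed)
    cv <- xgboost::xgb.cv(params = params, data = dtrain,
                          nrounds = config$max_trees,
                          nfold = config$cv_folds,
                          early_stopping_rounds = config$tree_step,
                          verbose = 0)
    best <- cv$early_stop$best_iteration
    if (is.null(best)) best <- which.min(cv$evaluation_log$test_rmse_mean)
    n_trees <- min(config$max_trees,
                   as.integer(ceiling(best / config$tree_step) * config$tree_step))
    cv_profile <- cv$evaluation_log$test_rmse_mean
    if (best >= config$max_trees - config$tree_step) {
      warning("fit_brt: cross-validated deviance still improving at max_trees; ",
              "returning the ensemble at max_trees")
    }
    set.seed(config$seed)
    booster <- xgboost::xgb.train(params, dtrain, nrounds = n_trees, verbose = 0)
  }
  structure(list(booster = booster, n_trees = n_trees,
                 cv_deviance_profile = cv_profile,
                 feature_names = colnames(X),
                 expert_levels = expert_levels,
                 x = design$x, y = y,
                 response = design$response,
                 covariates = design$covariates,
                 config = config),
            class = "brt_fit")
}

#' @export
print.brt_fit <- function(x, ...) {
  cat(sprintf("Boosted regression tree fit: response '%s', %d trees, %d covariates, %d rows\n",
              x$response, x$n_trees, length(x$covariates), length(x$y)))
  invisible(x)
}

#' Normalised relative influence of covariates
#'
#' Each covariate's influence is the squared-error improvement credited to
#' its splits, accumulated over all trees, normalised so the influences sum
#' to 100. One-hot expert-identity columns are summed back into a single
#' `expert_id` entry so the categorical covariate is reported on the same
#' footing as the numeric ones; covariates never selected for splitting
#' report 0.
#'
#' @param fit A [fit_brt()] result.
#' @return data.frame of class `influence_report`: `covariate`, `NRI`,
#'   sorted by decreasing influence; attributes `n_trees_selected` and
#'   `cv_deviance_profile`.
#' @export
relative_influence <- function(fit) {
  stopifnot(inherits(fit, "brt_fit"))
  imp <- xgboost::xgb.importance(model = fit$booster)
  if (is.null(imp) || nrow(imp) == 0) {
    stop("relative_influence: ensemble contains no splits")
  }
  gain <- stats::setNames(imp$Gain, imp$Feature)
  covariate <- ifelse(startsWith(names(gain), "expert_id__"),
                      "expert_id", names(gain))
  agg <- tapply(gain, covariate, sum)
  nri <- stats::setNames(rep(0, length(fit$covariates)), fit$covariates)
  nri[names(agg)] <- agg
  nri <- 100 * nri / sum(nri)
  out <- data.frame(covariate = names(nri), NRI = unname(nri),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$NRI), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trees_selected") <- fit$n_trees
  attr(out, "cv_deviance_profile") <- fit$cv_deviance_profile
  class(out) <- c("influence_report", "data.frame")
  out
}

#' Partial-dependence function of one covariate
#'
#' The fitted function of a covariate: the mean model prediction over the
#' training rows with that covariate fixed at each grid value.
#'
#' @param fit A [fit_brt()] result.
#' @param covariate Covariate name (numeric covariates take a numeric grid;
#'   `expert_id` takes a character grid of levels, defaulting to all).
#' @param grid Values at which to evaluate (default: 25 points over the
#'   covariate's training range).
#' @return data.frame `value`, `partial_dependence`.
#' @export
fitted_function <- function(fit, covariate, grid = NULL) {
  stopifnot(inherits(fit, "brt_fit"))
  if (!covariate %in% fit$covariates) {
    stop(sprintf("fitted_function: unknown covariate '%s'", covariate))
  }
  if (covariate == "expert_id") {
    if (is.null(grid)) grid <- fit$expert_levels
  } else if (is.null(grid)) {
    r <- range(fit$x[[covariate]])
    grid <- seq(r[1], r[2], length.out = 25)
  }
  pd <- vapply(grid, function(g) {
    x <- fit$x
    x[[covariate]] <- if (covariate == "expert_id") {
      factor(rep(g, nrow(x)), levels = fit$expert_levels)
    } else rep(as.numeric(g), nrow(x))
    X <- .design_matrix(x, fit$expert_levels)
    mean(stats::predict(fit$booster, xgboost::xgb.DMatrix(X)))
  }, numeric(1))
  data.frame(value = grid, partial_dependence = pd)
}

#' Ensemble prediction of aggregate condition for new sites
#'
#' Predicts the 0-100 condition score of new site descriptions from one or
#' more fitted current-condition models (e.g. fits at different seeds).
#' Expert identity is marginalised: each member predicts the site for every
#' expert level and averages, so the prediction is for the average expert.
#' The reported value is the mean of member predictions clipped to
#' \[0, 100\]; the spread is the between-member standard deviation (0 for a
#' single member).
#'
#' @param fits A `brt_fit` or list of `brt_fit`s (response `"current"`).
#' @param sites Site table rows (schema of [read_sites()]).
#' @return data.frame: `site_id`, `predicted`, `spread`.
#' @export
predict_condition <- function(fits, sites) {
  if (inherits(fits, "brt_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "brt_fit")))
  need <- setdiff(fits[[1]]$covariates, "expert_id")
  missing <- setdiff(need, names(sites))
  if (length(missing)) {
    stop(sprintf("predict_condition: site table missing covariate(s) %s",
                 paste(missing, collapse = ", ")))
  }
  member <- vapply(fits, function(f) {
    vapply(seq_len(nrow(sites)), function(i) {
      x <- sites[rep(i, length(f$expert_levels)), need, drop = FALSE]
      x$expert_id <- factor(f$expert_levels, levels = f$expert_levels)
      X <- .design_matrix(x[, c(need, "expert_id")], f$expert_levels)
      mean(stats::predict(f$booster, xgboost::xgb.DMatrix(X)))
    }, numeric(1))
  }, numeric(nrow(sites)))
  member <- matrix(member, nrow = nrow(sites))
  pred <- pmin(pmax(rowMeans(member), 0), 100)
  spread <- apply(member, 1, function(z) if (length(z) > 1) stats::sd(z) else 0)
  data.frame(site_id = if ("site_id" %in% names(sites)) sites$site_id
                       else seq_len(nrow(sites)),
             predicted = pred, spread = spread,
             stringsAsFactors = FALSE)
}
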