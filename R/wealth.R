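#' Wealth-index construction (Filmer-Pritchett asset index)
#'
#' DHS-style socioeconomic position is measured by an asset index: the
#' first principal component of standardized household asset-ownership
#' indicators. Households are then ranked into weighted population
#' quintiles labelled poorest to wealthiest.
#'
#' @name wealth
NULL

#' Quintile labels, poorest to wealthiest
#' @export
wealth_quintile_levels <- function() {
  c("poorest", "poorer", "middle", "wealthier", "wealthiest")
}

#' Compute the household asset index
#'
#' Projects each household's asset vector onto the first principal
#' component of the standardized (correlation-matrix) asset data.
#' Zero-variance asset columns carry no information and are dropped;
#' the component sign is oriented so that a higher score means higher
#' mean asset ownership, and scores are standardized to mean 0,
#' variance 1.
#'
#' @param assets numeric matrix or data.frame, one row per household,
#'   one column per binary/ordinal asset indicator.
#' @return numeric vector of standardized first-component scores, one
#'   per household.
#' @examples
#' a <- matrix(c(0, 0, 1, 0, 1, 1), nrow = 3, byrow = TRUE)
#' compute_asset_index(a)
#' @export
compute_asset_index <- function(assets) {
  x <- as.matrix(assets)
  storage.mode(x) <- "double"
  check_that(nrow(x) >= 2, "need at least 2 households to build an asset index")
  check_that(!anyNA(x), "asset matrix must not contain missing values")
  v <- apply(x, 2, stats::var)
  keep <- v > 0
  check_that(any(keep),
             "all asset columns are constant: asset index is degenerate")
  x <- x[, keep, drop = FALSE]
  z <- scale(x)               # standardize each indicator
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  # orient: richer households (more assets overall) score higher
  tot <- rowSums(x)
  ori <- sum(score * (tot - mean(tot)))
  if (ori < 0) score <- -score
  as.numeric(scale(score))
}

#' Assign weighted wealth quintiles
#'
#' Cuts asset-index scores at the weighted 20/40/60/80th percentiles so
#' that each quintile holds (to within one household weight) 20% of the
#' weighted household population. Ties in score are broken by the stable
#' input order of the households.
#'
#' @param scores numeric asset-index scores.
#' @param weights positive sampling weights, same length as `scores`
#'   (default: equal weights).
#' @return a `data.frame` with columns `score`, `weight` and `quintile`
#'   (factor with levels [wealth_quintile_levels()]), rows in input order.
#' @export
assign_wealth_quintiles <- function(scores, weights = rep(1, length(scores))) {
  check_that(is.numeric(scores) && !anyNA(scores), "scores must be numeric")
  check_that(length(weights) == length(scores),
             "weights must align with scores")
  check_that(is.numeric(weights) && all(is.finite(weights)) && all(weights > 0),
             "weights must be strictly positive")
  n <- length(scores)
  ord <- order(scores)                      # stable: ties keep input order
  w <- weights[ord]
  # cumulative weight share at the midpoint of each household's mass
  cmid <- (cumsum(w) - w / 2) / sum(w)
  q <- findInterval(cmid, c(0.2, 0.4, 0.6, 0.8)) + 1L
  quintile <- integer(n)
  quintile[ord] <- q
  data.frame(
    score = scores,
    weight = weights,
    quintile = factor(wealth_quintile_levels()[quintile],
                      levels = wealth_quintile_levels())
  )
}
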