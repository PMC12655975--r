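#' Per-element descriptive statistics of a concentration table
#'
#' Arithmetic mean, maximum, minimum, sample standard deviation (n-1
#' denominator), adjusted Fisher-Pearson skewness and the coefficient of
#' variation (CV, percent) for every element column.
#'
#' @param samples a [sample_table()] with at least two sites.
#' @return data.frame with columns `element`, `mean`, `max`, `min`, `sd`,
#'   `skewness`, `cv_percent` (full precision) and `cv_display` (rounded to
#'   the nearest integer percent, half away from zero).
#' @export
descriptive_stats <- function(samples) {
  stopifnot(inherits(samples, "sample_table"))
  if (length(samples$sites) < 2)
    stop("descriptive statistics need at least two sites (SD undefined)")
  rows <- lapply(samples$elements, function(el) {
    x <- samples$values[, el]
    s <- stats::sd(x)
    # constant column: skewness undefined, reported as 0 by convention
    skew <- if (s == 0) 0 else e1071::skewness(x, type = 2)
    m <- mean(x)
    cv <- if (m > 0) 100 * s / m else NA_real_
    data.frame(element = el, mean = m, max = max(x), min = min(x), sd = s,
               skewness = skew, cv_percent = cv,
               cv_display = round_half_away(cv))
  })
  do.call(rbind, rows)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Coefficient of variation in percent
#'
#' CV = 100 * sd / mean. With `display = TRUE` the result is rounded to the
#' nearest integer percent (half away from zero), the convention used in
#' reported concentration summaries.
#'
#' @param mean arithmetic mean (> 0).
#' @param sd standard deviation (>= 0).
#' @param display round to integer percent?
#' @return CV in percent; vectorised.
#' @export
cv_percent <- function(mean, sd, display = FALSE) {
  if (any(mean <= 0)) stop("CV needs a positive mean")
  if (any(sd < 0)) stop("SD must be non-negative")
  cv <- 100 * sd / mean
  if (display) round_half_away(cv) else cv
}

#' Single pollution index
#'
#' Ratio of the measured concentration to the screening / background value:
#' PI = C / S.
#'
#' @param c measured concentration (same units as `s`), non-negative.
#' @param s screening or background value, strictly positive.
#' @return PI (dimensionless); vectorised over `c` and `s`.
#' @export
single_pollution_index <- function(c, s) {
  if (any(s <= 0)) stop("screening value must be positive")
  if (any(c < 0)) stop("concentration must be non-negative")
  c / s
}

#' Nemerow comprehensive pollution index
#'
#' Combines the worst and the average single pollution index of a sample:
#' NI = sqrt((max(PI)^2 + mean(PI)^2) / 2). Always lies between the mean and
#' the maximum of the inputs.
#'
#' @param pis non-empty numeric vector of single pollution indices (>= 0).
#' @return NI (dimensionless).
#' @export
nemerow_index <- function(pis) {
  if (length(pis) == 0) stop("nemerow_index needs at least one PI")
  if (any(pis < 0)) stop("PI values must be non-negative")
  sqrt((max(pis)^2 + mean(pis)^2) / 2)
}

#' Hakanson single ecological risk index
#'
#' Toxicity-weighted pollution index: EI = PI * T_r. The comprehensive index
#' PERI for a sample is the sum of the EIs of its configured elements.
#'
#' @param pi single pollution index (>= 0).
#' @param tr toxicity response coefficient (> 0).
#' @return EI (dimensionless); vectorised.
#' @export
ecological_index <- function(pi, tr) {
  if (any(is.na(tr))) stop("missing toxicity coefficient")
  if (any(tr <= 0)) stop("toxicity coefficient must be positive")
  pi * tr
}

# category schemes: upper bounds and labels. PI/NI intervals are read
# left-open/right-closed (a boundary belongs to the lower class); EI/PERI are
# left-closed/right-open (a boundary belongs to the upper class).
index_schemes <- list(
  PI   = list(breaks = c(1, 2, 3, 5), right = TRUE,
              labels = c("safe", "alert", "slight", "moderate", "severe")),
  NI   = list(breaks = c(0.7, 1, 2, 3), right = TRUE,
              labels = c("safe", "alert", "slight", "moderate", "severe")),
  EI   = list(breaks = c(40, 80, 160, 320), right = FALSE,
              labels = c("low", "moderate", "considerable", "high",
                         "extremely high")),
  PERI = list(breaks = c(150, 300, 600, 1200), right = FALSE,
              labels = c("low", "moderate", "considerable", "high",
                         "extremely high"))
)

#' Categorise a pollution or ecological index value
#'
#' Maps an index value to its standard category. PI: safe (<=1), alert (1-2],
#' slight (2-3], moderate (3-5], severe (>5). NI: safe (<=0.7), alert
#' (0.7-1], slight (1-2], moderate (2-3], severe (>3). EI: low (<40),
#' moderate [40-80), considerable [80-160), high [160-320), extremely high
#' (>=320). PERI: low (<150), moderate [150-300), considerable [300-600),
#' high [600-1200), extremely high (>=1200).
#'
#' @param value index value(s), non-negative.
#' @param scheme one of `"PI"`, `"NI"`, `"EI"`, `"PERI"`.
#' @return character vector of category labels.
#' @export
classify_index <- function(value, scheme = c("PI", "NI", "EI", "PERI")) {
  scheme <- match.arg(scheme)
  if (any(value < 0)) stop("index values must be non-negative")
  sc <- index_schemes[[scheme]]
  idx <- if (sc$right) {
    findInterval(value, sc$breaks, left.open = TRUE) + 1
  } else {
    findInterval(value, sc$breaks) + 1
  }
  sc$labels[idx]
}

#' Per-site pollution and ecological indices for a medium
#'
#' Computes, for every site, the single pollution index of each element with
#' a screening value, the Nemerow index over those elements, and (where
#' toxicity coefficients exist) the ecological indices and their sum PERI.
#' Elements without a screening value for the medium (e.g. Mo and V in crops
#' under the default configuration) are excluded from all indices.
#'
#' @param samples a [sample_table()].
#' @param refs a [reference_bundle()].
#' @param elements optional subset of elements to assess.
#' @return list with `pi` (site x element matrix), `ni` (named vector),
#'   `ei` (site x element matrix), `peri` (named vector), `ni_category`,
#'   `peri_category`, and `elements` (those actually assessed).
#' @export
pollution_indices <- function(samples, refs, elements = NULL) {
  stopifnot(inherits(samples, "sample_table"),
            inherits(refs, "reference_bundle"))
  scr <- refs$screening[[samples$medium]]
  if (is.null(scr)) stop("no screening values for medium ", samples$medium)
  use <- intersect(elements %||% samples$elements, samples$elements)
  use <- use[use %in% names(scr) & !is.na(scr[use])]
  if (length(use) == 0) stop("no assessable elements (no screening values)")
  pim <- sweep(samples$values[, use, drop = FALSE], 2, scr[use], "/")
  ni <- apply(pim, 1, nemerow_index)
  tr_use <- use[use %in% names(refs$toxicity)]
  eim <- sweep(pim[, tr_use, drop = FALSE], 2, refs$toxicity[tr_use], "*")
  peri <- rowSums(eim)
  list(pi = pim, ni = ni, ei = eim, peri = peri,
       ni_category = classify_index(ni, "NI"),
       peri_category = classify_index(peri, "PERI"),
       elements = use)
}

#' Share of sites per index category
#'
#' @param categories character vector of category labels for one scheme.
#' @param scheme the scheme the labels come from.
#' @return data.frame of category, count and percent (sums to 100).
#' @export
category_shares <- function(categories, scheme = c("PI", "NI", "EI", "PERI")) {
  scheme <- match.arg(scheme)
  labels <- index_schemes[[scheme]]$labels
  counts <- table(factor(categories, levels = labels))
  data.frame(category = labels, count = as.integer(counts),
             percent = 100 * as.integer(counts) / length(categories))
}
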