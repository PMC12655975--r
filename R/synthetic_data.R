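# Synthetic concentration tables with known structure: a source-mixing model
# (site loadings x source signatures x multiplicative lognormal noise) for
# parameter-recovery testing, and a marginal moment-matching generator that
# emulates published per-element mean/SD targets.

#' Define a pollution source profile
#'
#' @param label source name (e.g. `"geogenic"`, `"mining"`).
#' @param signature named non-negative vector: emission strength per element
#'   in medium concentration units; at least one positive entry.
#' @param mix_shape shape of the gamma distribution of per-site mixing
#'   coefficients (mean fixed at 1; CV = 1/sqrt(shape)).
#' @return An object of class `source_profile`.
#' @export
source_profile <- function(label, signature, mix_shape = 4) {
  signature <- unlist(signature)
  if (all(signature <= 0)) stop("signature needs at least one positive entry")
  if (any(signature < 0)) stop("signature entries must be non-negative")
  if (mix_shape <= 0) stop("mix_shape must be positive")
  structure(list(label = label, signature = signature, mix_shape = mix_shape),
            class = "source_profile")
}

#' Built-in source profile presets
#'
#' Fixed sets of source profiles whose dominant elements mirror the source
#' structure typical of a mining-impacted agricultural basin:
#' `soil_3source` — geogenic (Cr, Ni, V), mining (Pb, Zn, Mo, Cd, Sb) and
#' agricultural inputs (Cu, As); `water_4source` — an upstream-mining
#' component (Cr, Ni, Cu), an antimony-mining component (As, Sb), a
#' lead-zinc-mining component (Pb, Zn, Cd) and a geogenic component (Mo, V);
#' `crop_2source` — agrochemical inputs (Pb, Cr, Ni, Cu, Zn, As, Cd, V) and
#' mining deposition (Mo, Sb). Signature magnitudes are on the scale of the
#' shipped summary-statistic targets ([concentration_targets()]).
#'
#' @param name preset name.
#' @return list of [source_profile()]s.
#' @export
preset_profiles <- function(name = c("soil_3source", "water_4source",
                                     "crop_2source")) {
  name <- match.arg(name)
  sig <- function(...) {
    s <- stats::setNames(rep(0, length(pte_elements)), pte_elements)
    v <- c(...)
    s[names(v)] <- v
    s
  }
  switch(name,
    soil_3source = list(
      source_profile("geogenic",
                     sig(Cr = 15, Ni = 8, V = 23, Pb = 2, Cu = 1, Zn = 3,
                         As = 0.5, Mo = 0.05, Cd = 0.02, Sb = 0.3)),
      source_profile("mining",
                     sig(Pb = 18, Zn = 13, Mo = 0.7, Cd = 0.25, Sb = 9)),
      source_profile("agriculture", sig(Cu = 5.5, As = 3.2))),
    water_4source = list(
      source_profile("mining_upstream", sig(Cr = 1.2, Ni = 50, Cu = 48)),
      source_profile("mining_sb", sig(As = 1.5, Sb = 22)),
      source_profile("mining_pbzn", sig(Pb = 2.8, Zn = 900, Cd = 3.2)),
      source_profile("geogenic",
                     sig(Mo = 230, V = 1.2, Cr = 0.1, Ni = 2, Cu = 2,
                         Pb = 0.1, Zn = 20, As = 0.1, Cd = 0.05, Sb = 0.5))),
    crop_2source = list(
      source_profile("agrochemical",
                     sig(Pb = 1.1, Cr = 1.5, Ni = 0.8, Cu = 0.7, Zn = 2.3,
                         As = 0.37, Cd = 0.012, V = 1.9)),
      source_profile("mining", sig(Mo = 0.004, Sb = 0.75))))
}

preset_medium <- c(soil_3source = "soil", water_4source = "surface_water",
                   crop_2source = "crop")

# sdlog of a unit-median lognormal with coefficient of variation cv
lognormal_sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

#' Generate a concentration table from a known source-mixing model
#'
#' C[s, i] = (sum_k a[s, k] * signature[k, i]) * eps[s, i], with per-site
#' mixing coefficients a[s, k] drawn from a gamma distribution with mean 1
#' (right-skewed, non-negative) and multiplicative lognormal noise eps with
#' unit median and the stated coefficient of variation. The generating truth
#' (profiles, mixing matrix, noise level, seed) is returned for
#' parameter-recovery checks.
#'
#' @param profiles list of [source_profile()]s (all sharing one element set).
#' @param n_sites number of sites; must be at least 3 times the number of
#'   profiles.
#' @param noise_cv noise coefficient of variation in percent (>= 0).
#' @param seed integer RNG seed.
#' @param medium medium label for the resulting table.
#' @return list with `samples` (a [sample_table()]) and `truth` (profiles,
#'   site x source `mixing` matrix, `noise_cv`, `seed`, and a
#'   `degenerate_signatures` flag when the signature matrix is rank
#'   deficient).
#' @export
generate_mixture <- function(profiles, n_sites, noise_cv = 20, seed = 1,
                             medium = "soil") {
  stopifnot(length(profiles) >= 1, noise_cv >= 0)
  if (n_sites < 3 * length(profiles))
    stop("n_sites must be at least 3 times the number of profiles")
  S <- do.call(rbind, lapply(profiles, `[[`, "signature"))
  rownames(S) <- vapply(profiles, `[[`, "", "label")
  degenerate <- qr(t(S))$rank < nrow(S)
  if (degenerate) warning("source signatures are linearly dependent")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  A <- vapply(profiles, function(p)
    stats::rgamma(n_sites, shape = p$mix_shape, rate = p$mix_shape),
    numeric(n_sites))
  A <- matrix(A, nrow = n_sites, dimnames = list(NULL, rownames(S)))
  C <- A %*% S
  if (noise_cv > 0) {
    sdlog <- lognormal_sdlog_from_cv(noise_cv / 100)
    C <- C * matrix(stats::rlnorm(length(C), 0, sdlog), nrow = n_sites)
  }
  sites <- sprintf("SYN%03d", seq_len(n_sites))
  rownames(C) <- sites
  list(samples = sample_table(C, medium, sites = sites,
                              elements = colnames(C)),
       truth = list(profiles = profiles, signatures = S, mixing = A,
                    noise_cv = noise_cv, seed = as.integer(seed),
                    degenerate_signatures = degenerate))
}

#' Generate a table matching target per-element means and SDs
#'
#' Draws each element independently from a lognormal distribution
#' moment-matched to the target mean m and standard deviation s:
#' meanlog = ln(m^2 / sqrt(m^2 + s^2)), sdlog^2 = ln(1 + s^2/m^2). A target
#' with s = 0 yields a constant column at the mean. Only the marginal moments
#' are targeted; between-element correlation structure comes from
#' [generate_mixture()] instead.
#'
#' @param targets data.frame with columns `element`, `mean` (> 0), `sd`
#'   (>= 0), e.g. from [concentration_targets()].
#' @param n_sites number of sites to draw.
#' @param seed integer RNG seed.
#' @param medium medium label for the resulting table.
#' @return A [sample_table()].
#' @export
simulate_from_moments <- function(targets, n_sites, seed = 1,
                                  medium = "soil") {
  stopifnot(all(c("element", "mean", "sd") %in% names(targets)),
            all(targets$mean > 0), all(targets$sd >= 0), n_sites >= 1)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cols <- lapply(seq_len(nrow(targets)), function(i) {
    m <- targets$mean[i]; s <- targets$sd[i]
    if (s == 0) return(rep(m, n_sites))
    stats::rlnorm(n_sites,
                  meanlog = log(m^2 / sqrt(m^2 + s^2)),
                  sdlog = sqrt(log(1 + s^2 / m^2)))
  })
  C <- do.call(cbind, cols)
  sites <- sprintf("SYN%03d", seq_len(n_sites))
  dimnames(C) <- list(sites, targets$element)
  sample_table(C, medium, sites = sites, elements = targets$element)
}

#' Published summary-statistic targets per medium
#'
#' Descriptive statistics (mean, max, min, SD, skewness, CV%) of PTE
#' concentrations reported for a mining-impacted river basin in southwestern
#' Henan, China (69 surface-water, 79 soil and 79 crop samples), shipped as
#' emulation targets for [simulate_from_moments()] and as worked examples for
#' the CV computation. Units: ug/L for surface water, mg/kg dry weight
#' otherwise.
#'
#' @param medium one of `"surface_water"`, `"soil"`, `"crop"`.
#' @return data.frame: `element`, `mean`, `max`, `min`, `sd`, `skewness`,
#'   `cv_percent` (the printed integer CV).
#' @export
concentration_targets <- function(medium = c("surface_water", "soil",
                                             "crop")) {
  medium <- match.arg(medium)
  el <- c("Pb", "Cr", "Ni", "Cu", "Zn", "As", "Mo", "Cd", "Sb", "V")
  tab <- switch(medium,
    surface_water = data.frame(element = el,
      mean = c(2.86, 1.22, 51.52, 48.34, 918.12, 1.57, 235.05, 3.21, 21.91, 1.20),
      max = c(42.10, 23.50, 2950, 2910, 31300, 7.99, 3040, 63.70, 239, 7.40),
      min = c(0.09, 0.11, 0.06, 0.56, 0.67, 0.12, 0.12, 0.05, 0.15, 0.10),
      sd = c(8.17, 3.92, 355.39, 350.05, 4214.48, 1.83, 610.58, 11.35, 51.66, 1.34),
      skewness = c(3.50, 5.03, 8.21, 8.27, 6.08, 1.99, 3.30, 3.95, 2.75, 3.55),
      cv_percent = c(286, 320, 690, 724, 459, 117, 260, 353, 236, 112)),
    soil = data.frame(element = el,
      mean = c(21.79, 14.87, 7.85, 6.53, 16.58, 3.70, 0.73, 0.26, 9.62, 22.87),
      max = c(37.42, 19.85, 11.41, 9.27, 22.60, 7.43, 1.75, 0.76, 31.89, 30.06),
      min = c(1.91, 2.58, 1.78, 2.30, 5.67, 0.80, 0.07, 0.03, 1.32, 4.83),
      sd = c(7.99, 3.34, 1.82, 1.50, 3.37, 1.26, 0.36, 0.16, 8.08, 4.70),
      skewness = c(-0.03, -1.12, -0.67, -0.48, -0.83, 1.28, 0.70, 1.34, 1.03, -1.44),
      cv_percent = c(37, 22, 23, 23, 20, 34, 49, 63, 84, 21)),
    crop = data.frame(element = el,
      mean = c(1.10, 1.49, 0.80, 0.69, 2.32, 0.37, 0.003, 0.01, 0.74, 1.88),
      max = c(2.82, 3.83, 1.90, 1.62, 5.49, 1.10, 0.02, 0.04, 2.92, 4.57),
      min = c(0.03, 0.09, 0.05, 0.04, 0.15, 0.02, 0.0005, 0.001, 0.03, 0.15),
      sd = c(0.76, 0.95, 0.51, 0.39, 1.29, 0.22, 0.0158, 0.0121, 0.78, 1.14),
      skewness = c(0.55, 0.64, 0.47, 0.30, 0.26, 0.80, 5.43, 1.37, 1.51, 0.48),
      cv_percent = c(69, 64, 63, 57, 56, 61, 527, 121, 105, 61)))
  tab
}

#' Match recovered components against generating source profiles
#'
#' Rotated loadings are correlations, i.e. they live in a space where every
#' element has unit variance; a source's raw signature (concentration units)
#' must therefore be re-expressed per element before comparison. For source k
#' and element i the comparable quantity is the share of element i's content
#' attributable to source k, signature[k, i] / sum_k' signature[k', i]. This
#' function computes the cosine similarity between each source's share vector
#' and every rotated loading column and reports the best match.
#'
#' @param model a `source_model` from [pca_kaiser()].
#' @param truth the `truth` component returned by [generate_mixture()].
#' @return data.frame: `source`, `component` (best-matching loading column),
#'   `cosine` (similarity of the match).
#' @export
profile_recovery <- function(model, truth) {
  S <- truth$signatures
  el <- rownames(model$loadings)
  S <- S[, el, drop = FALSE]
  shares <- sweep(S, 2, colSums(S), "/")
  shares[is.na(shares)] <- 0
  rows <- lapply(rownames(S), function(k) {
    cs <- apply(model$loadings, 2, function(l) cosine_similarity(shares[k, ], l))
    data.frame(source = k, component = names(which.max(cs)),
               cosine = max(cs))
  })
  do.call(rbind, rows)
}
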