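# Monte Carlo propagation of exposure-parameter uncertainty through the
# exposure model. Concentrations stay fixed; only parameters are sampled.

draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  gen <- function(m) with(spec$params, switch(spec$kind,
    point = rep(value, m),
    normal = stats::rnorm(m, mean, sd),
    lognormal = stats::rlnorm(m, meanlog, sdlog),
    uniform = stats::runif(m, min, max),
    triangular = {
      # inverse-CDF sampling of the triangular distribution
      u <- stats::runif(m)
      fc <- if (max > min) (mode - min) / (max - min) else 0.5
      ifelse(u < fc,
             min + sqrt(u * (max - min) * (mode - min)),
             max - sqrt((1 - u) * (max - min) * (max - mode)))
    }))
  x <- gen(n)
  lo <- spec$lower %||% -Inf
  hi <- spec$upper %||% Inf
  bad <- which(x < lo | x > hi)
  tries <- 0
  while (length(bad)) {   # truncation by rejection
    x[bad] <- gen(length(bad))
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1
    if (tries > 1000)
      stop("truncation bounds exclude essentially all mass of a ", spec$kind,
           " spec")
  }
  x
}

#' Sample exposure parameters for a Monte Carlo run
#'
#' Draws every parameter independently from its distribution spec,
#' truncating by rejection. Point specs yield constant vectors. Identical
#' seeds yield identical draws.
#'
#' @param specs named list of [dist_spec()]s (e.g.
#'   `refs$exposure[["child"]]`).
#' @param n_iter number of iterations (>= 1).
#' @param seed integer RNG seed.
#' @return named list of numeric vectors of length `n_iter`, with attributes
#'   `n_iter` and `seed`.
#' @export
sample_parameters <- function(specs, n_iter, seed) {
  stopifnot(n_iter >= 1)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  draws <- lapply(specs, draw_dist, n = n_iter)
  attr(draws, "n_iter") <- n_iter
  attr(draws, "seed") <- as.integer(seed)
  draws
}

#' Fraction of samples strictly above a threshold
#'
#' @param samples non-empty numeric vector (e.g. simulated risk totals).
#' @param threshold exceedance threshold (1 for NRI, 1e-4 for CRI).
#' @return probability in \[0, 1\].
#' @export
exceedance_probability <- function(samples, threshold) {
  if (length(samples) == 0) stop("empty sample vector")
  mean(samples > threshold)
}

mc_summary <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  c(mean = mean(x), sd = stats::sd(x), p5 = q[1], median = q[2], p95 = q[3])
}

#' Monte Carlo risk simulation for one site
#'
#' Evaluates the full exposure model once per iteration with the sampled
#' parameters, holding the site's concentrations fixed, and summarises the
#' simulated non-carcinogenic (NRI) and carcinogenic (CRI) totals.
#'
#' @param conc named concentration vector for one site (medium units).
#' @param draws parameter draws from [sample_parameters()].
#' @param refs a [reference_bundle()].
#' @param medium `"soil"` or `"surface_water"`.
#' @return An `mc_result`: list with `nri_samples`, `cri_samples`,
#'   `nri_summary`, `cri_summary` (mean/sd/5th/50th/95th), `p_exceed_nri`
#'   (fraction with NRI > 1), `p_exceed_cri` (fraction with CRI > 1e-4), and
#'   `pathway_means` (mean NRI and CRI per pathway).
#' @export
run_mc <- function(conc, draws, refs, medium) {
  use <- intersect(names(conc), names(refs$rfd))
  if (length(use) == 0) stop("no elements with reference doses")
  conc <- conc[use]
  p <- draws
  uf <- refs$unit_factor[[medium]]
  k_nc <- pathway_kernels(p, medium, uf, p$ed * 365)
  k_ca <- pathway_kernels(p, medium, uf, lifetime_years * 365)
  rfd <- lookup_matrix(refs$rfd, use)
  sf <- lookup_matrix(refs$slope, use)
  sf[is.na(sf)] <- 0
  # risk totals are linear in the per-pathway kernels:
  #   NRI(t) = sum_j k_j(t) * w_j(t),  w_j = sum_i C_i * absfac_ij / RfD_ij.
  # Only the dermal weight can vary with t (through ABS); elements with a
  # configured ABS override use their fixed value, the rest share p$abs.
  soil_like <- medium %in% c("soil", "crop")
  ov <- if (soil_like) intersect(names(refs$abs_override), use) else character()
  rest <- setdiff(use, ov)
  derm_w <- function(target) {   # target: per-element 1/RfD_dermal or SF_dermal
    fixed <- sum(conc[ov] * refs$abs_override[ov] * target[ov])
    free <- sum(conc[rest] * target[rest])
    if (soil_like) fixed + p$abs * free else fixed + free
  }
  w_nri <- list(ingestion = sum(conc / rfd[, "ingestion"]),
                dermal = derm_w(1 / rfd[, "dermal"]),
                inhalation = sum(conc / rfd[, "inhalation"]))
  w_cri <- list(ingestion = sum(conc * sf[, "ingestion"]),
                dermal = derm_w(sf[, "dermal"]),
                inhalation = sum(conc * sf[, "inhalation"]))
  nri_path <- lapply(risk_pathways, function(j) k_nc[[j]] * w_nri[[j]])
  cri_path <- lapply(risk_pathways, function(j) k_ca[[j]] * w_cri[[j]])
  names(nri_path) <- names(cri_path) <- risk_pathways
  nri <- Reduce(`+`, nri_path)
  cri <- Reduce(`+`, cri_path)
  structure(list(
    nri_samples = nri, cri_samples = cri,
    nri_summary = mc_summary(nri), cri_summary = mc_summary(cri),
    p_exceed_nri = exceedance_probability(nri, 1),
    p_exceed_cri = exceedance_probability(cri, 1e-4),
    pathway_means = rbind(nri = vapply(nri_path, mean, 0),
                          cri = vapply(cri_path, mean, 0))),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result>", length(x$nri_samples), "iterations\n")
  cat(sprintf(" NRI mean %.3g (P95 %.3g), P(NRI > 1) = %.3f\n",
              x$nri_summary["mean"], x$nri_summary["p95"], x$p_exceed_nri))
  cat(sprintf(" CRI mean %.3g (P95 %.3g), P(CRI > 1e-4) = %.3f\n",
              x$cri_summary["mean"], x$cri_summary["p95"], x$p_exceed_cri))
  invisible(x)
}

# order-stable 31-bit hash of a string, for per-site seed derivation
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

site_seed <- function(master, site, population) {
  as.integer((as.numeric(master) + stable_hash(paste(site, population))) %%
               2147483647)
}

#' Monte Carlo risk simulation for every site in a table
#'
#' Runs [run_mc()] per site with a per-site RNG seed derived from the master
#' seed by stable string hashing of the site identifier and population, so
#' results do not depend on execution order. Also pools all iterations across
#' sites (sites equally weighted) for basin-level exceedance probabilities.
#'
#' @param samples a [sample_table()] (`soil` or `surface_water`).
#' @param refs a [reference_bundle()].
#' @param population population name.
#' @param n_iter iterations per site (default 10000).
#' @param seed master integer seed.
#' @return list with `sites` (named list of `mc_result`), `summary`
#'   (data.frame of per-site means, 95th percentiles and exceedance
#'   probabilities), and `pooled` (pooled `p_exceed_nri`/`p_exceed_cri` and
#'   pooled mean NRI/CRI).
#' @export
mc_assess <- function(samples, refs, population, n_iter = 10000, seed = 1) {
  stopifnot(inherits(samples, "sample_table"))
  specs <- refs$exposure[[population]]
  if (is.null(specs)) stop("unknown population: ", population)
  use <- assessable_elements(samples, refs)
  results <- lapply(samples$sites, function(site) {
    draws <- sample_parameters(specs, n_iter,
                               site_seed(seed, site, population))
    run_mc(samples$values[site, use], draws, refs, samples$medium)
  })
  names(results) <- samples$sites
  summary <- do.call(rbind, lapply(samples$sites, function(site) {
    r <- results[[site]]
    data.frame(site = site, population = population,
               nri_mean = r$nri_summary[["mean"]],
               nri_p95 = r$nri_summary[["p95"]],
               cri_mean = r$cri_summary[["mean"]],
               cri_p95 = r$cri_summary[["p95"]],
               p_exceed_nri = r$p_exceed_nri,
               p_exceed_cri = r$p_exceed_cri)
  }))
  nri_all <- unlist(lapply(results, `[[`, "nri_samples"), use.names = FALSE)
  cri_all <- unlist(lapply(results, `[[`, "cri_samples"), use.names = FALSE)
  list(sites = results, summary = summary,
       pooled = list(p_exceed_nri = exceedance_probability(nri_all, 1),
                     p_exceed_cri = exceedance_probability(cri_all, 1e-4),
                     nri_mean = mean(nri_all), cri_mean = mean(cri_all)))
}

#' Rank-correlation sensitivity of a simulated output to its parameters
#'
#' Spearman rank correlation rho_p between each parameter's draws and the
#' output vector, converted to signed percent contributions
#' sign(rho_p) * 100 * rho_p^2 / sum_q rho_q^2. Constant parameters get
#' contribution 0; absolute contributions sum to 100 over the non-constant
#' parameters. Contributions are invariant to monotone rescaling of the
#' output.
#'
#' @param draws parameter draws from [sample_parameters()].
#' @param outputs numeric vector of simulated outputs, same length as the
#'   draws.
#' @return data.frame sorted by |contribution|: `parameter`, `rho`,
#'   `contribution` (signed percent).
#' @export
sensitivity <- function(draws, outputs) {
  n <- attr(draws, "n_iter") %||% length(outputs)
  if (length(outputs) != n) stop("outputs length must equal n_iter")
  varying <- vapply(draws, function(x) stats::var(x) > 0, TRUE)
  if (!any(varying)) stop("all parameters are constant; nothing to analyse")
  rho <- vapply(names(draws), function(pm) {
    if (!varying[[pm]]) return(0)
    stats::cor(draws[[pm]], outputs, method = "spearman")
  }, 0)
  denom <- sum(rho^2)
  contribution <- if (denom > 0) sign(rho) * 100 * rho^2 / denom else rho * 0
  out <- data.frame(parameter = names(draws), rho = rho,
                    contribution = contribution)
  out <- out[order(-abs(out$contribution)), ]
  rownames(out) <- NULL
  out
}

#' Sensitivity analysis of basin-level risk for one population
#'
#' Convenience wrapper: simulates the risk of the basin-average concentration
#' profile (mean over sites per element) and returns sensitivity tables for
#' the NRI and CRI totals.
#'
#' @inheritParams mc_assess
#' @return list with `nri` and `cri` sensitivity data.frames (see
#'   [sensitivity()]).
#' @export
mc_sensitivity <- function(samples, refs, population, n_iter = 10000,
                           seed = 1) {
  specs <- refs$exposure[[population]]
  if (is.null(specs)) stop("unknown population: ", population)
  use <- assessable_elements(samples, refs)
  conc <- colMeans(samples$values[, use, drop = FALSE])
  draws <- sample_parameters(specs, n_iter,
                             site_seed(seed, "::basin-mean::", population))
  r <- run_mc(conc, draws, refs, samples$medium)
  list(nri = sensitivity(draws, r$nri_samples),
       cri = sensitivity(draws, r$cri_samples))
}
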