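# USEPA-style exposure model. Intakes (ADI, mg/kg/day):
#   ingestion:  C * R_ing * EF * ED / (BW * AT) * unit_factor
#   dermal:     C * SA * AF * ABS * EF * ED / (BW * AT) * unit_factor
#   inhalation: C * R_inh * EF * ED / (PEF * BW * AT)
# AT is ED*365 days for non-carcinogenic risk and 70*365 days for
# carcinogenic risk. For water the dermal skin-adherence*absorption product is
# replaced by an aqueous permeability * exposure-time slot (Kp*ET*CF,
# CF = 1e-3 L/cm3) and inhalation is disabled.

lifetime_years <- 70

risk_pathways <- c("ingestion", "dermal", "inhalation")

#' Average daily intake via ingestion
#'
#' @param c concentration (medium units).
#' @param r_ing intake rate of the medium (mg/day for soil, L/day for water).
#' @param ef exposure frequency (days/year).
#' @param ed exposure duration (years).
#' @param bw body weight (kg), positive.
#' @param at averaging time (days), positive.
#' @param unit_factor mass conversion for the medium (1e-6 for mg/kg media,
#'   1e-3 for ug/L water).
#' @return ADI in mg/kg/day; vectorised.
#' @export
adi_ingestion <- function(c, r_ing, ef, ed, bw, at, unit_factor) {
  if (any(bw <= 0)) stop("body weight must be positive")
  if (any(at <= 0)) stop("averaging time must be positive")
  c * r_ing * ef * ed / (bw * at) * unit_factor
}

#' Average daily intake via dermal contact
#'
#' @inheritParams adi_ingestion
#' @param sa exposed skin area (cm2).
#' @param af skin adherence factor (mg/cm2/day); for water pass the aqueous
#'   permeability-time product Kp*ET*CF instead.
#' @param abs dermal absorption fraction, in (0, 1]; 1 for water.
#' @export
adi_dermal <- function(c, sa, af, abs, ef, ed, bw, at, unit_factor) {
  if (any(bw <= 0)) stop("body weight must be positive")
  if (any(at <= 0)) stop("averaging time must be positive")
  if (any(abs <= 0 | abs > 1)) stop("dermal absorption fraction must be in (0, 1]")
  c * sa * af * abs * ef * ed / (bw * at) * unit_factor
}

#' Average daily intake via inhalation of resuspended particles
#'
#' @inheritParams adi_ingestion
#' @param r_inh air inhalation rate (m3/day).
#' @param pef particle emission factor (m3/kg).
#' @export
adi_inhalation <- function(c, r_inh, ef, ed, pef, bw, at) {
  if (any(bw <= 0)) stop("body weight must be positive")
  if (any(at <= 0)) stop("averaging time must be positive")
  if (any(pef <= 0)) stop("particle emission factor must be positive")
  c * r_inh * ef * ed / (pef * bw * at)
}

#' Deterministic exposure parameter set for a population
#'
#' Collapses each exposure-parameter distribution in the bundle to its
#' central value ([dist_central()]) and derives the averaging times
#' (`at_nc = ed*365`, `at_ca = 70*365`).
#'
#' @param refs a [reference_bundle()].
#' @param population population name present in the bundle.
#' @return named list of scalar parameter values.
#' @export
exposure_params <- function(refs, population) {
  specs <- refs$exposure[[population]]
  if (is.null(specs)) stop("unknown population: ", population)
  p <- lapply(specs, dist_central)
  p$at_nc <- p$ed * 365
  p$at_ca <- lifetime_years * 365
  p
}

# Per-pathway ADI multipliers k such that ADI_el = C_el * k * abs_factor_el.
# Parameters may be equal-length vectors (Monte Carlo draws). `at` selects the
# averaging time. Water: dermal uses Kp*ET with CF = 1e-3 L/cm3; inhalation 0.
pathway_kernels <- function(p, medium, unit_factor, at) {
  base <- p$ef * p$ed / (p$bw * at)
  if (medium == "soil" || medium == "crop") {
    list(ingestion = p$r_ing_soil * base * unit_factor,
         dermal = p$sa * p$af * base * unit_factor,   # * ABS per element
         inhalation = p$r_inh * base / p$pef)
  } else {
    list(ingestion = p$r_ing_water * base * unit_factor,
         dermal = p$sa * p$kp * p$et * 1e-3 * base * unit_factor,
         inhalation = 0 * base)
  }
}

# element-wise dermal absorption factors; 1 for water (absorbed fraction is
# folded into Kp)
abs_factors <- function(elements, p, refs, medium) {
  if (medium != "soil" && medium != "crop")
    return(stats::setNames(rep(1, length(elements)), elements))
  a <- rep(p$abs, length(elements))
  names(a) <- elements
  ov <- intersect(names(refs$abs_override), elements)
  a[ov] <- refs$abs_override[ov]
  a
}

lookup_matrix <- function(tbl, elements, pathways = risk_pathways) {
  m <- matrix(NA_real_, length(elements), length(pathways),
              dimnames = list(elements, pathways))
  for (el in intersect(elements, names(tbl)))
    m[el, intersect(pathways, names(tbl[[el]]))] <-
      tbl[[el]][intersect(pathways, names(tbl[[el]]))]
  m
}

#' Non-carcinogenic and carcinogenic risk indices from intakes
#'
#' NRI_ij = ADI_ij / RfD_ij for every element i and pathway j; CRI_ij =
#' ADI_ij * SF_ij where a slope factor exists (entries without one stay
#' absent, `NA`, and are excluded from totals). Totals are plain sums over
#' elements and pathways.
#'
#' @param adi element x pathway matrix of non-carcinogenic-AT intakes.
#' @param refs a [reference_bundle()] providing `rfd` and `slope`.
#' @param adi_ca optional element x pathway matrix of carcinogenic-AT
#'   intakes; defaults to `adi`.
#' @return list with `nri_by`, `cri_by` (matrices), `nri_total`, `cri_total`,
#'   and logical flags `nri_exceeds` (total > 1) and `cri_exceeds`
#'   (total > 1e-4).
#' @export
risk_indices <- function(adi, refs, adi_ca = adi) {
  elements <- rownames(adi)
  rfd <- lookup_matrix(refs$rfd, elements, colnames(adi))
  missing <- which(is.na(rfd) & adi > 0, arr.ind = TRUE)
  if (nrow(missing))
    stop(sprintf("missing reference dose for (%s, %s)",
                 elements[missing[1, 1]], colnames(adi)[missing[1, 2]]))
  nri <- adi / rfd
  nri[adi == 0 & is.na(rfd)] <- 0
  sf <- lookup_matrix(refs$slope, elements, colnames(adi))
  cri <- adi_ca * sf
  list(nri_by = nri, cri_by = cri,
       nri_total = sum(nri, na.rm = TRUE),
       cri_total = if (all(is.na(cri))) 0 else sum(cri, na.rm = TRUE)) |>
    (\(r) c(r, list(nri_exceeds = r$nri_total > 1,
                    cri_exceeds = r$cri_total > 1e-4)))()
}

assessable_elements <- function(samples, refs) {
  intersect(samples$elements, names(refs$rfd))
}

#' Deterministic health risk assessment of every site in a table
#'
#' Applies the three intake equations and the risk indices to each site with
#' the population's central exposure parameters. Pathways are ingestion,
#' dermal contact and inhalation for soil; ingestion and dermal contact for
#' surface water.
#'
#' @param samples a [sample_table()] (medium `soil` or `surface_water`).
#' @param refs a [reference_bundle()].
#' @param population population name (default bundle: `"child"`, `"adult"`).
#' @param elements optional subset of elements; defaults to all elements with
#'   a reference dose.
#' @return data.frame with one row per site/element/pathway: `site`,
#'   `population`, `element`, `pathway`, `adi` (non-carcinogenic AT),
#'   `adi_ca` (carcinogenic AT), `nri`, `cri` (`NA` when no slope factor).
#' @export
assess_risk <- function(samples, refs, population, elements = NULL) {
  stopifnot(inherits(samples, "sample_table"),
            inherits(refs, "reference_bundle"))
  medium <- samples$medium
  p <- exposure_params(refs, population)
  uf <- refs$unit_factor[[medium]]
  use <- elements %||% assessable_elements(samples, refs)
  if (length(use) == 0) stop("no elements with reference doses to assess")
  k_nc <- pathway_kernels(p, medium, uf, p$at_nc)
  k_ca <- pathway_kernels(p, medium, uf, p$at_ca)
  af <- abs_factors(use, p, refs, medium)
  rows <- lapply(samples$sites, function(site) {
    conc <- samples$values[site, use]
    adi_nc <- cbind(ingestion = conc * k_nc$ingestion,
                    dermal = conc * af * k_nc$dermal,
                    inhalation = conc * k_nc$inhalation)
    adi_ca <- cbind(ingestion = conc * k_ca$ingestion,
                    dermal = conc * af * k_ca$dermal,
                    inhalation = conc * k_ca$inhalation)
    rownames(adi_nc) <- rownames(adi_ca) <- use
    ri <- risk_indices(adi_nc, refs, adi_ca)
    data.frame(site = site, population = population,
               element = rep(use, times = length(risk_pathways)),
               pathway = rep(risk_pathways, each = length(use)),
               adi = as.vector(adi_nc), adi_ca = as.vector(adi_ca),
               nri = as.vector(ri$nri_by), cri = as.vector(ri$cri_by))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site risk totals with threshold flags
#'
#' @param risk data.frame from [assess_risk()].
#' @return data.frame per site: `nri_total`, `cri_total`, `nri_exceeds`
#'   (total > 1), `cri_exceeds` (total > 1e-4).
#' @export
risk_totals <- function(risk) {
  agg <- stats::aggregate(cbind(nri, cri) ~ site + population, data = risk,
                          FUN = function(x) sum(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  names(agg)[3:4] <- c("nri_total", "cri_total")
  agg$nri_exceeds <- agg$nri_total > 1
  agg$cri_exceeds <- agg$cri_total > 1e-4
  agg[order(agg$site), ]
}
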