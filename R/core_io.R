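#' Potentially toxic elements covered by the default configuration
#'
#' Ordered vector of the ten element symbols the package's shipped reference
#' configuration covers: lead, chromium, nickel, copper, zinc, arsenic,
#' molybdenum, cadmium, antimony and vanadium.
#'
#' @export
pte_elements <- c("Pb", "Cr", "Ni", "Cu", "Zn", "As", "Mo", "Cd", "Sb", "V")

#' Media recognised by the package
#' @export
pte_media <- c("surface_water", "soil", "crop")

medium_unit <- function(medium) {
  switch(medium, surface_water = "ug/L", soil = "mg/kg", crop = "mg/kg",
         stop("unknown medium: ", medium))
}

#' Construct a site-by-element concentration table
#'
#' The central data container: one matrix of concentrations for a single
#' environmental medium, with optional below-detection-limit (BDL) flags and
#' per-element detection limits. Water concentrations are in ug/L; soil and
#' crop concentrations in mg/kg dry weight.
#'
#' @param values numeric matrix, sites in rows, elements in columns. Row and
#'   column names are used as site identifiers and element symbols unless
#'   `sites`/`elements` are given.
#' @param medium one of `"surface_water"`, `"soil"`, `"crop"`.
#' @param sites character vector of site identifiers.
#' @param elements character vector of element symbols (no duplicates).
#' @param bdl_flags logical matrix, same shape as `values`; TRUE marks a cell
#'   reported below the detection limit (its stored value is the substituted
#'   one, see [read_samples()]).
#' @param detection_limits named numeric vector of per-element detection
#'   limits (NA where unknown).
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(values, medium, sites = rownames(values),
                         elements = colnames(values), bdl_flags = NULL,
                         detection_limits = NULL) {
  medium <- match.arg(medium, pte_media)
  values <- as.matrix(values)
  if (is.null(sites)) sites <- paste0("S", seq_len(nrow(values)))
  if (is.null(elements)) stop("element names are required")
  if (anyDuplicated(elements)) stop("duplicate element symbols: ",
                                    paste(unique(elements[duplicated(elements)]), collapse = ", "))
  if (length(sites) != nrow(values) || length(elements) != ncol(values))
    stop("dimension mismatch between values and site/element labels")
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("missing concentration values are not allowed")
  if (any(values < 0)) stop("negative concentrations are not allowed")
  if (is.null(bdl_flags)) {
    bdl_flags <- matrix(FALSE, nrow(values), ncol(values))
  }
  bdl_flags <- as.matrix(bdl_flags)
  if (!identical(dim(bdl_flags), dim(values)))
    stop("bdl_flags must have the same shape as values")
  dl <- rep(NA_real_, length(elements))
  names(dl) <- elements
  if (!is.null(detection_limits)) dl[names(detection_limits)] <- detection_limits
  if (any(bdl_flags) && anyNA(dl[colSums(bdl_flags) > 0]))
    stop("BDL-flagged elements need a detection limit: ",
         paste(elements[colSums(bdl_flags) > 0 & is.na(dl)], collapse = ", "))
  dimnames(values) <- dimnames(bdl_flags) <- list(sites, elements)
  structure(
    list(medium = medium, unit = medium_unit(medium), sites = sites,
         elements = elements, values = values, bdl_flags = bdl_flags,
         detection_limits = dl),
    class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %s: %d sites x %d elements [%s]\n",
              x$medium, length(x$sites), length(x$elements), x$unit))
  cat("elements:", paste(x$elements, collapse = ", "), "\n")
  n_bdl <- sum(x$bdl_flags)
  if (n_bdl > 0) cat(n_bdl, "cells below detection limit (substituted)\n")
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$values)

bdl_substitute <- function(dl, bdl_action) {
  switch(bdl_action, half = dl / 2, zero = 0, dl = dl,
         stop("unknown BDL action: ", bdl_action))
}

#' Read a concentration table from delimited text
#'
#' Expects a header row with a site-identifier column (named `site`, case
#' insensitive) followed by one column per element. Cells of the form `<x`
#' mark a measurement below the detection limit `x`; they are substituted with
#' half the detection limit by default (`bdl_action` selects `half`, `zero` or
#' `dl`). Numeric cells below a configured detection limit in
#' `detection_limits` are likewise flagged and substituted.
#'
#' @param path file path to a comma- (default) or tab-delimited text file.
#' @param medium medium of the table (`"surface_water"`, `"soil"`, `"crop"`).
#' @param elements element columns required to be present; defaults to every
#'   non-site column in the file. Missing requested columns are an error.
#' @param detection_limits optional named numeric vector of detection limits.
#' @param bdl_action substitution rule for below-detection cells.
#' @param sep field separator; `","` or `"\t"`.
#' @return A [sample_table()].
#' @export
read_samples <- function(path, medium, elements = NULL,
                         detection_limits = NULL,
                         bdl_action = c("half", "zero", "dl"), sep = ",") {
  bdl_action <- match.arg(bdl_action)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  site_col <- which(tolower(names(raw)) == "site")
  if (length(site_col) != 1) stop("expected exactly one 'site' column in ", path)
  file_elements <- names(raw)[-site_col]
  if (is.null(elements)) elements <- file_elements
  missing <- setdiff(elements, file_elements)
  if (length(missing))
    stop("missing element columns: ", paste(missing, collapse = ", "))
  sites <- raw[[site_col]]
  vals <- matrix(NA_real_, length(sites), length(elements),
                 dimnames = list(sites, elements))
  flags <- matrix(FALSE, length(sites), length(elements),
                  dimnames = list(sites, elements))
  dl <- rep(NA_real_, length(elements))
  names(dl) <- elements
  if (!is.null(detection_limits))
    dl[intersect(names(detection_limits), elements)] <-
      detection_limits[intersect(names(detection_limits), elements)]
  for (el in elements) {
    cells <- trimws(raw[[el]])
    is_bdl <- startsWith(cells, "<")
    num <- suppressWarnings(as.numeric(ifelse(is_bdl, substring(cells, 2), cells)))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell without BDL marker at row %d, column %s: '%s'",
                   bad[1], el, cells[bad[1]]))
    if (any(is_bdl)) {
      # "<x" carries its own detection limit; a configured DL takes precedence
      cell_dl <- if (is.na(dl[el])) num else rep(dl[el], length(num))
      if (is.na(dl[el])) dl[el] <- max(num[is_bdl])
      num[is_bdl] <- bdl_substitute(cell_dl[is_bdl], bdl_action)
    }
    if (!is.na(dl[el])) {
      below <- !is_bdl & num < dl[el]
      if (any(below)) {
        num[below] <- bdl_substitute(dl[el], bdl_action)
        is_bdl <- is_bdl | below
      }
    }
    if (any(num < 0))
      stop("negative concentration in column ", el)
    vals[, el] <- num
    flags[, el] <- is_bdl
  }
  sample_table(vals, medium, sites = sites, elements = elements,
               bdl_flags = flags, detection_limits = dl)
}

#' Write a concentration table to delimited text
#'
#' Inverse of [read_samples()]: below-detection cells are written back as
#' `<DL` using the stored per-element detection limit, so that reading the
#' file with the same substitution rule reproduces values and flags exactly.
#'
#' @param x a [sample_table()].
#' @param path output file path (UTF-8, comma separated).
#' @export
write_samples <- function(x, path) {
  stopifnot(inherits(x, "sample_table"))
  cells <- matrix(formatC(x$values, format = "g", digits = 17),
                  nrow(x$values), ncol(x$values))
  for (j in seq_along(x$elements)) {
    f <- x$bdl_flags[, j]
    if (any(f))
      cells[f, j] <- paste0("<", formatC(x$detection_limits[x$elements[j]],
                                         format = "g", digits = 17))
  }
  out <- cbind(site = x$sites, as.data.frame(cells, stringsAsFactors = FALSE))
  names(out) <- c("site", x$elements)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- distribution specifications -------------------------------------------

#' Specify a univariate parameter distribution
#'
#' Used for Monte Carlo exposure parameters. Supported kinds: `point`
#' (`value`), `normal` (`mean`, `sd`), `lognormal` (`meanlog`, `sdlog`),
#' `uniform` (`min`, `max`), `triangular` (`min`, `mode`, `max`). Optional
#' truncation bounds are enforced by rejection sampling.
#'
#' @param kind distribution kind.
#' @param ... kind-specific parameters (see above).
#' @param lower,upper optional truncation bounds (`lower < upper`).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(kind = c("point", "normal", "lognormal", "uniform",
                               "triangular"), ..., lower = NULL, upper = NULL) {
  kind <- match.arg(kind)
  params <- list(...)
  need <- switch(kind,
                 point = "value", normal = c("mean", "sd"),
                 lognormal = c("meanlog", "sdlog"), uniform = c("min", "max"),
                 triangular = c("min", "mode", "max"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(kind, " spec needs parameter(s): ", paste(missing, collapse = ", "))
  params <- params[need]
  if (kind %in% c("normal", "lognormal") && params[[2]] < 0)
    stop(kind, " scale parameter must be non-negative")
  if (kind == "uniform" && params$min > params$max)
    stop("uniform spec needs min <= max")
  if (kind == "triangular" &&
      !(params$min <= params$mode && params$mode <= params$max))
    stop("triangular spec needs min <= mode <= max")
  if (!is.null(lower) && !is.null(upper) && lower >= upper)
    stop("truncation needs lower < upper")
  structure(list(kind = kind, params = params, lower = lower, upper = upper),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  tr <- if (!is.null(x$lower) || !is.null(x$upper))
    sprintf(" trunc[%s, %s]", x$lower %||% "-Inf", x$upper %||% "Inf") else ""
  cat(sprintf("<dist_spec> %s(%s)%s\n", x$kind, p, tr))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Central (deterministic) value of a distribution spec
#'
#' The value substituted when the Monte Carlo layer is bypassed: the point
#' value, the mean for normal/lognormal/uniform, the mean of the triangular.
#' @param spec a [dist_spec()].
#' @export
dist_central <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  with(spec$params, switch(spec$kind,
    point = value,
    normal = mean,
    lognormal = exp(meanlog + sdlog^2 / 2),
    uniform = (min + max) / 2,
    triangular = (min + mode + max) / 3))
}

# ---- reference bundle ------------------------------------------------------

parse_dist <- function(x, where) {
  if (is.numeric(x) && length(x) == 1) return(dist_spec("point", value = x))
  if (!is.list(x) || is.null(x$kind))
    stop("cannot interpret distribution at ", where)
  args <- x[setdiff(names(x), c("kind", "lower", "upper"))]
  do.call(dist_spec, c(list(kind = x$kind), args,
                       list(lower = x$lower, upper = x$upper)))
}

#' Assemble a reference bundle
#'
#' Bundles everything the assessment needs besides measurements: screening /
#' background values per medium, Hakanson toxicity response coefficients,
#' reference doses and slope factors per exposure pathway, exposure-parameter
#' distributions per population, and the mass-conversion factor applied in
#' the intake equations (1e-6 for mg/kg media, 1e-3 for ug/L water).
#'
#' @param screening named list: medium -> named numeric vector of screening
#'   values S (same units as the medium). Must be strictly positive.
#' @param toxicity named numeric vector of toxicity response coefficients T_r.
#' @param rfd named list: element -> named numeric vector of reference doses
#'   (mg/kg/day) per pathway (`ingestion`, `dermal`, `inhalation`).
#' @param slope like `rfd` but cancer slope factors ((mg/kg/day)^-1); elements
#'   or pathways without a slope factor are simply absent.
#' @param exposure named list: population -> named list of [dist_spec()]s (or
#'   bare numbers, treated as point specs).
#' @param abs_override named numeric vector of element-specific dermal
#'   absorption fractions overriding the population default (e.g. As = 0.03).
#' @param unit_factor named numeric vector: medium -> conversion constant.
#' @return An object of class `reference_bundle`.
#' @export
reference_bundle <- function(screening, toxicity, rfd, slope = list(),
                             exposure, abs_override = numeric(),
                             unit_factor = c(surface_water = 1e-3, soil = 1e-6,
                                             crop = 1e-6)) {
  for (m in names(screening)) {
    s <- unlist(screening[[m]])
    if (any(s <= 0, na.rm = TRUE))
      stop("screening values must be positive (", m, ": ",
           paste(names(s)[which(s <= 0)], collapse = ", "), ")")
    screening[[m]] <- s
  }
  toxicity <- unlist(toxicity)
  if (any(toxicity < 1))
    warning("toxicity response coefficients below 1: ",
            paste(names(toxicity)[toxicity < 1], collapse = ", "))
  rfd <- lapply(rfd, unlist)
  if (any(unlist(rfd) <= 0)) stop("reference doses must be positive")
  slope <- lapply(slope, unlist)
  if (any(unlist(slope) < 0)) stop("slope factors must be non-negative")
  exposure <- lapply(exposure, function(pop)
    lapply(seq_along(pop), function(i) {
      sp <- pop[[i]]
      if (inherits(sp, "dist_spec")) sp else parse_dist(sp, names(pop)[i])
    }) |> stats::setNames(names(pop)))
  structure(list(screening = screening, toxicity = toxicity, rfd = rfd,
                 slope = slope, exposure = exposure,
                 abs_override = unlist(abs_override),
                 unit_factor = unit_factor),
            class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle>\n")
  cat(" screening media:", paste(names(x$screening), collapse = ", "), "\n")
  cat(" toxicity coefficients:", length(x$toxicity), "elements\n")
  cat(" reference doses:", length(x$rfd), "elements; slope factors:",
      length(x$slope), "elements\n")
  cat(" populations:", paste(names(x$exposure), collapse = ", "), "\n")
  invisible(x)
}

#' Read a reference bundle from a YAML configuration file
#'
#' The file must contain sections `screening`, `toxicity`, `rfd`, `exposure`,
#' and may contain `slope`, `abs_override` and `unit_factor`. See the shipped
#' default at `system.file("extdata", "reference_defaults.yaml",
#' package = "pterisk")` for the schema.
#'
#' @param path YAML file path.
#' @return A [reference_bundle()].
#' @export
read_reference_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("screening", "toxicity", "rfd", "exposure")) {
    if (is.null(cfg[[key]])) stop("missing config section: ", key)
  }
  uf <- if (is.null(cfg$unit_factor))
    c(surface_water = 1e-3, soil = 1e-6, crop = 1e-6)
  else unlist(cfg$unit_factor)
  reference_bundle(screening = cfg$screening, toxicity = cfg$toxicity,
                   rfd = cfg$rfd, slope = cfg$slope %||% list(),
                   exposure = cfg$exposure,
                   abs_override = cfg$abs_override %||% numeric(),
                   unit_factor = uf)
}

#' Default reference bundle
#'
#' Conventional, replaceable defaults covering the ten shipped elements:
#' Chinese surface-water Class III-style screening limits, soil background /
#' screening values, food contaminant-style crop limits, Hakanson toxicity
#' response coefficients (Zn 1, Cr 2, Cu/Ni/Pb 5, As 10, Cd 30, plus
#' literature values for Sb, Mo and V), USEPA-conventional reference doses and
#' slope factors, and textbook exposure-parameter distributions for adults and
#' children. Every entry can be overridden through a user YAML file
#' ([read_reference_bundle()]).
#'
#' @return A [reference_bundle()].
#' @export
default_reference_bundle <- function() {
  read_reference_bundle(system.file("extdata", "reference_defaults.yaml",
                                    package = "pterisk", mustWork = TRUE))
}

# ---- validation ------------------------------------------------------------

#' Cross-validate a sample table against a reference bundle
#'
#' Checks element coverage (screening values for the table's medium, toxicity
#' coefficients, reference doses), unit consistency and positivity. Findings
#' are returned in a report, never raised.
#'
#' @param samples a [sample_table()].
#' @param refs a [reference_bundle()].
#' @return A `validation_report`: list with `errors`, `warnings` (each a
#'   data.frame of location/message) and `passed` (TRUE iff no errors).
#' @export
validate_inputs <- function(samples, refs) {
  errors <- list(); warnings <- list()
  add <- function(pool, location, message)
    c(pool, list(data.frame(location = location, message = message)))
  if (!inherits(samples, "sample_table"))
    errors <- add(errors, "samples", "not a sample_table")
  else {
    if (samples$unit != medium_unit(samples$medium))
      errors <- add(errors, "samples$unit",
                    sprintf("unit '%s' inconsistent with medium '%s'",
                            samples$unit, samples$medium))
    if (any(samples$values < 0))
      errors <- add(errors, "samples$values", "negative concentrations")
    scr <- refs$screening[[samples$medium]]
    uncovered <- setdiff(samples$elements, names(scr))
    known <- unique(c(names(refs$toxicity), names(refs$rfd),
                      unlist(lapply(refs$screening, names))))
    for (el in uncovered) {
      if (el %in% known)
        # configured element without a screening value for this medium:
        # deliberately excluded from index calculations (e.g. Mo/V in crops)
        warnings <- add(warnings, paste0("screening$", samples$medium),
                        paste0("element ", el, " has no screening value for ",
                               samples$medium, "; excluded from indices"))
      else
        errors <- add(errors, paste0("screening$", samples$medium),
                      paste0("no screening value for element ", el))
    }
    no_tr <- setdiff(samples$elements, names(refs$toxicity))
    for (el in no_tr)
      warnings <- add(warnings, "toxicity",
                      paste0("no toxicity coefficient for element ", el))
    no_rfd <- setdiff(samples$elements, names(refs$rfd))
    for (el in no_rfd)
      warnings <- add(warnings, "rfd",
                      paste0("no reference dose for element ", el))
    if (is.na(refs$unit_factor[samples$medium]))
      errors <- add(errors, "unit_factor",
                    paste0("no unit factor for medium ", samples$medium))
  }
  bind <- function(pool) if (length(pool)) do.call(rbind, pool)
    else data.frame(location = character(), message = character())
  structure(list(errors = bind(errors), warnings = bind(warnings),
                 passed = length(errors) == 0),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s)\n",
              if (x$passed) "PASSED" else "FAILED",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) print(x$errors)
  if (nrow(x$warnings)) print(x$warnings)
  invisible(x)
}
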