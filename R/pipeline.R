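# End-to-end orchestration: validation -> pollution/ecological indices ->
# deterministic HRA -> Monte Carlo -> PCA source apportionment -> source-risk
# attribution, with deterministic file outputs and a run manifest.

write_csv6 <- function(df, path) {
  # 6 significant digits for human-readable CSVs; machine-precision values
  # live in the JSON sidecars
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Run the full assessment pipeline
#'
#' Executes, per medium: input validation, pollution/ecological indices,
#' deterministic risk assessment and Monte Carlo simulation per population
#' (media `soil` and `surface_water` only), PCA source apportionment, and
#' source-risk attribution. All outputs are written as CSV/JSON under
#' `out_dir`; re-running with an identical configuration reproduces them
#' bit-identically.
#'
#' @param samples named list: medium -> [sample_table()].
#' @param refs a [reference_bundle()]; default [default_reference_bundle()].
#' @param populations populations to assess (default child and adult).
#' @param n_iter Monte Carlo iterations per site (default 10000).
#' @param seed master integer seed.
#' @param rotation,retention passed to [pca_kaiser()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param risk_population population whose Monte Carlo mean risks feed the
#'   source-risk attribution (default `"child"`).
#' @return Invisibly, a manifest list: per-medium stage results and output
#'   file paths, plus `seed` and package version.
#' @export
run_pipeline <- function(samples, refs = default_reference_bundle(),
                         populations = c("child", "adult"), n_iter = 10000,
                         seed = 1, rotation = "varimax", retention = "kaiser",
                         out_dir = NULL, risk_population = "child") {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(out_dir)) return(NULL)
    write_csv6(df, file.path(out_dir, name))
  }
  manifest <- list(seed = as.integer(seed), n_iter = n_iter,
                   package_version = as.character(utils::packageVersion("pterisk")),
                   media = list(), files = character())
  results <- list()
  for (medium in names(samples)) {
    tab <- samples[[medium]]
    stopifnot(inherits(tab, "sample_table"))
    stages <- character()
    vr <- validate_inputs(tab, refs)
    if (!vr$passed)
      stop("validation failed for medium ", medium, ": ",
           paste(vr$errors$message, collapse = "; "))
    stages <- c(stages, "validate")

    idx <- pollution_indices(tab, refs)
    idx_df <- data.frame(site = tab$sites, idx$pi, ni = idx$ni,
                         ni_category = idx$ni_category, peri = idx$peri,
                         peri_category = idx$peri_category,
                         check.names = FALSE)
    f1 <- emit(idx_df, paste0("indices_", medium, ".csv"))
    f2 <- emit(category_shares(idx$ni_category, "NI"),
               paste0("ni_category_shares_", medium, ".csv"))
    stages <- c(stages, "indices")

    risk <- NULL; mc <- list()
    if (medium %in% c("soil", "surface_water")) {
      risk <- lapply(populations, function(pop) assess_risk(tab, refs, pop))
      names(risk) <- populations
      for (pop in populations)
        emit(risk[[pop]], paste0("risk_", medium, "_", pop, ".csv"))
      stages <- c(stages, "hra")
      mc <- lapply(populations, function(pop)
        mc_assess(tab, refs, pop, n_iter = n_iter, seed = seed))
      names(mc) <- populations
      for (pop in populations) {
        emit(mc[[pop]]$summary, paste0("mc_summary_", medium, "_", pop, ".csv"))
        sens <- mc_sensitivity(tab, refs, pop, n_iter = n_iter, seed = seed)
        emit(sens$nri, paste0("sensitivity_nri_", medium, "_", pop, ".csv"))
        emit(sens$cri, paste0("sensitivity_cri_", medium, "_", pop, ".csv"))
      }
      if (!is.null(out_dir)) {
        pooled <- lapply(mc, `[[`, "pooled")
        jsonlite::write_json(pooled,
                             file.path(out_dir,
                                       paste0("exceedance_", medium, ".json")),
                             auto_unbox = TRUE, digits = NA)
      }
      stages <- c(stages, "mc")
    }

    model <- pca_kaiser(standardize(tab$values), rotation = rotation,
                        retention = retention)
    m <- element_source_contributions(model)
    emit(data.frame(component = seq_along(model$eigenvalues),
                    eigenvalue = model$eigenvalues),
         paste0("pca_eigenvalues_", medium, ".csv"))
    emit(data.frame(element = rownames(model$loadings), model$loadings,
                    check.names = FALSE),
         paste0("pca_loadings_", medium, ".csv"))
    emit(data.frame(element = rownames(m), m, check.names = FALSE),
         paste0("pca_m_matrix_", medium, ".csv"))
    stages <- c(stages, "pca")

    src_risk <- NULL
    if (!is.null(risk) && risk_population %in% names(risk)) {
      shares <- element_risk_shares(risk[[risk_population]])
      keep <- intersect(rownames(m), names(shares$np))
      src_risk <- source_risk_contributions(
        m[keep, , drop = FALSE],
        list(np = shares$np[keep] / sum(shares$np[keep]),
             cp = if (!is.null(shares$cp))
               shares$cp[keep] / sum(shares$cp[keep])))
      emit(src_risk, paste0("source_risk_", medium, "_", risk_population,
                            ".csv"))
      stages <- c(stages, "source_risk")
    }
    results[[medium]] <- list(validation = vr, indices = idx, risk = risk,
                              mc = mc, model = model, m_matrix = m,
                              source_risk = src_risk)
    manifest$media[[medium]] <- list(stages = stages,
                                     n_sites = length(tab$sites))
  }
  if (!is.null(out_dir)) {
    manifest$files <- list.files(out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(manifest, list(results = results)))
}
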