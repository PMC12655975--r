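# Couples source apportionment to health risk: per-element shares of the
# total NRI/CRI (NP, CP) and per-source percent contributions
# NQ_k = sum_i M[i,k] * NP_i, CQ_k = sum_i M[i,k] * CP_i.

#' Element-level shares of total non-carcinogenic and carcinogenic risk
#'
#' Sums risk over sites and pathways per element and normalises: NP_i is
#' element i's share of the summed NRI, CP_i its share of the summed CRI
#' (over elements possessing slope factors). By default shares are computed
#' from deterministic risks ([assess_risk()] output); pass per-site Monte
#' Carlo element means in the same layout to use simulated risks.
#'
#' @param risk data.frame with columns `element`, `nri`, `cri` (one row per
#'   site/element/pathway; `cri` may be NA where no slope factor exists).
#' @return list with `np` and `cp`: named vectors summing to 1 (`cp` is NULL
#'   when no element carries a slope factor).
#' @export
element_risk_shares <- function(risk) {
  stopifnot(all(c("element", "nri", "cri") %in% names(risk)))
  nri_by <- tapply(risk$nri, risk$element, sum, na.rm = TRUE)
  total_nri <- sum(nri_by)
  if (total_nri <= 0) stop("total non-carcinogenic risk is zero")
  np <- nri_by / total_nri
  cri_by <- tapply(risk$cri, risk$element, sum, na.rm = TRUE)
  cri_by[is.na(cri_by)] <- 0
  total_cri <- sum(cri_by)
  cp <- if (total_cri > 0) cri_by / total_cri else NULL
  list(np = c(np), cp = if (!is.null(cp)) c(cp))
}

#' Source-level contributions to health risk
#'
#' NQ_k = sum_i M[i, k] * NP_i and CQ_k = sum_i M[i, k] * CP_i, reported as
#' percents. Because M rows and the share vectors each sum to 1, NQ and CQ
#' sum to 100 exactly.
#'
#' @param m element x source contribution matrix from
#'   [element_source_contributions()].
#' @param shares list with `np` (and optionally `cp`) from
#'   [element_risk_shares()].
#' @return data.frame: `source`, `nq_percent`, `cq_percent` (NA when `cp` is
#'   absent).
#' @export
source_risk_contributions <- function(m, shares) {
  np <- shares$np
  diff <- union(setdiff(rownames(m), names(np)),
                setdiff(names(np), rownames(m)))
  if (length(diff))
    stop("element mismatch between M and risk shares: ",
         paste(diff, collapse = ", "))
  np <- np[rownames(m)]
  nq <- 100 * as.vector(crossprod(m, np))
  cq <- rep(NA_real_, ncol(m))
  if (!is.null(shares$cp)) {
    if (length(setdiff(rownames(m), names(shares$cp))) ||
        length(setdiff(names(shares$cp), rownames(m))))
      stop("element mismatch between M and carcinogenic risk shares")
    cq <- 100 * as.vector(crossprod(m, shares$cp[rownames(m)]))
  }
  data.frame(source = colnames(m), nq_percent = nq, cq_percent = cq)
}
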