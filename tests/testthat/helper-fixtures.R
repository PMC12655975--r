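# Fixtures built in code: small tables and bundles for controlled tests.

make_water_table <- function(n_sites = 3, seed = 11) {
  set.seed(seed)
  vals <- matrix(round(stats::rlnorm(n_sites * 10, 1, 1), 4), n_sites, 10,
                 dimnames = list(paste0("W", seq_len(n_sites)), pte_elements))
  sample_table(vals, "surface_water")
}

make_soil_table <- function(n_sites = 4, seed = 12) {
  set.seed(seed)
  base <- c(Pb = 22, Cr = 15, Ni = 8, Cu = 6.5, Zn = 17, As = 3.7, Mo = 0.7,
            Cd = 0.26, Sb = 9.6, V = 23)
  vals <- t(replicate(n_sites, base * stats::rlnorm(10, 0, 0.3)))
  dimnames(vals) <- list(paste0("S", seq_len(n_sites)), pte_elements)
  sample_table(vals, "soil")
}

# bundle with all-point exposure specs so MC must equal the deterministic
# model exactly
point_bundle <- function(refs = default_reference_bundle()) {
  for (pop in names(refs$exposure)) {
    refs$exposure[[pop]] <- lapply(refs$exposure[[pop]], function(sp)
      dist_spec("point", value = dist_central(sp)))
  }
  refs
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
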