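# Shared fixtures: tiny hand-built datasets and a fast estimator config.

toy_hospital <- function() {
  # 2 causes x 2 symptoms; cause a: profiles 00, 01; cause b: 11, 11
  va_data(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 1)),
          cause = c("a", "a", "b", "b"),
          symptom_names = c("s1", "s2"))
}

fast_config <- function(...) {
  estimator_config(n_subsets = 30L, seed = 1L, ...)
}

# Small paired study drawn from one shared model (no misreporting).
small_study <- function(n = 800, J = 4, K = 12, seed = 5L) {
  des <- sim_design(J = J, K = K, n_hospital = n, n_community = n,
                    community_csmf = default_community_csmf(J), seed = seed)
  simulate_study(des)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
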