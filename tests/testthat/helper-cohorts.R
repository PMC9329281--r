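# Small fixtures built in code for the unit tests.

small_manifest <- function(n_shape = 6L, n_first = 3L, n_texture = 6L) {
  default_manifest(n_shape, n_first, n_texture)
}

small_catalogue <- function(sizes = c(A = 10L, B = 10L, C = 10L),
                            n_female = 6L, n_male = 4L) {
  shared <- data.frame(
    variable_id = unlist(lapply(names(sizes), function(s) {
      sprintf("%s_%02d", s, seq_len(sizes[[s]]))
    })),
    category = rep(names(sizes), sizes),
    sex_applicability = "both",
    stringsAsFactors = FALSE
  )
  extra <- data.frame(
    variable_id = c(sprintf("F_%02d", seq_len(n_female)),
                    sprintf("M_%02d", seq_len(n_male))),
    category = rep(c("Female specific", "Male specific"),
                   c(n_female, n_male)),
    sex_applicability = rep(c("female", "male"), c(n_female, n_male)),
    stringsAsFactors = FALSE
  )
  rbind(shared, extra)
}

small_sim <- function(n_women = 150L, n_men = 150L, seed = 1L, ...) {
  simulate_cohort(cohort_config(
    n_women = n_women, n_men = n_men,
    manifest = small_manifest(),
    catalogue = small_catalogue(),
    planted_effects = c(A_01 = 0.3),
    seed = seed, ...
  ))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
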