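#' Names of the 20 synthetic demographic indicators
#'
#' Nine age-group proportions, two gender proportions, eight race/ethnicity
#' proportions and one poverty proportion, mirroring the indicator blocks
#' published for US census tracts in ACS extracts.
#'
#' @return named list of character vectors, one per block
#'   (`age`, `gender`, `race`, `poverty`).
#' @export
census_blocks <- function() {
  list(
    age = c("age_under_5", "age_5_17", "age_18_24", "age_25_34", "age_35_44",
            "age_45_54", "age_55_64", "age_65_74", "age_75_up"),
    gender = c("gender_male", "gender_female"),
    race = c("race_white", "race_black", "race_asian", "race_native",
             "race_pacific", "race_other", "race_two_or_more", "race_hispanic"),
    poverty = "poverty"
  )
}

#' Generate synthetic tract-level demographic proportions
#'
#' Draws, for every tract, Dirichlet-distributed proportions within each of
#' the age (9), gender (2) and race (8) blocks, plus a uniform poverty
#' proportion. By default the Dirichlet is symmetric, so large `concentration`
#' drives every block toward the uniform vector; `block_means` supplies
#' non-uniform expected profiles when wanted.
#'
#' @param tracts a `tract_set`.
#' @param concentration positive Dirichlet concentration. Larger values give
#'   less between-tract variation.
#' @param poverty_range length-2 interval in `[0,1]` for the uniform poverty
#'   proportion.
#' @param seed integer RNG seed.
#' @param block_means optional named list (`age`, `gender`, `race`) of
#'   positive weights (normalised internally) giving expected proportions;
#'   default uniform within each block.
#' @return A `census_table`: data.frame with `tract_id` and 20 proportion
#'   columns (see [census_blocks()]).
#' @export
generate_census <- function(tracts, concentration = 25,
                            poverty_range = c(0.03, 0.35), seed = 1,
                            block_means = NULL) {
  if (!inherits(tracts, "tract_set") || nrow(tracts$tracts) == 0L) {
    stop_invalid("`tracts` must be a non-empty tract_set")
  }
  assert_scalar_num(concentration, "concentration")
  if (concentration <= 0) stop_invalid("`concentration` must be > 0")
  if (length(poverty_range) != 2L || any(poverty_range < 0) ||
      any(poverty_range > 1) || poverty_range[1] > poverty_range[2]) {
    stop_invalid("`poverty_range` must be an interval within [0, 1]")
  }

  blocks <- census_blocks()
  n <- nrow(tracts$tracts)
  with_seed(seed, {
    out <- data.frame(tract_id = tracts$tracts$tract_id,
                      stringsAsFactors = FALSE)
    for (b in c("age", "gender", "race")) {
      cols <- blocks[[b]]
      k <- length(cols)
      mean_w <- block_means[[b]] %||% rep(1, k)
      if (length(mean_w) != k || any(mean_w <= 0)) {
        stop_invalid("`block_means$%s` must be %d positive weights", b, k)
      }
      shape <- concentration * k * (mean_w / sum(mean_w))
      g <- matrix(rgamma(n * k, shape = rep(shape, each = n)), nrow = n)
      p <- g / rowSums(g)
      colnames(p) <- cols
      out <- cbind(out, as.data.frame(p))
    }
    out$poverty <- runif(n, poverty_range[1], poverty_range[2])
    class(out) <- c("census_table", "data.frame")
    out
  })
}

validate_census <- function(census, tol = 1e-9) {
  blocks <- census_blocks()
  for (b in c("age", "gender", "race")) {
    s <- rowSums(census[, blocks[[b]], drop = FALSE])
    if (any(abs(s - 1) > tol)) stop_invalid("%s proportions do not sum to 1", b)
  }
  if (any(census$poverty < 0 | census$poverty > 1)) {
    stop_invalid("poverty proportion outside [0, 1]")
  }
  invisible(census)
}
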