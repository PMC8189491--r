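#' Default generative coefficients for the synthetic outcomes
#'
#' Effects (percentage points per unit of a proportion feature) encoding the
#' dependence structure the estimator is meant to exploit: poverty and dense
#' development raise asthma prevalence; poverty, old age and low-density
#' development raise COPD prevalence. Bases are the national tract-level
#' averages of 9.783% (asthma) and 6.416% (COPD).
#'
#' @return named list: per outcome, a list with `base` (percent) and
#'   `effects` (named numeric over census / land-cover feature names).
#' @export
default_prevalence_model <- function() {
  list(
    asthma = list(
      base = 9.783,
      effects = c(poverty = 10, developed_high = 4, developed_medium = 2,
                  race_black = 3)
    ),
    copd = list(
      base = 6.416,
      effects = c(poverty = 8, age_65_74 = 8, age_75_up = 8,
                  developed_low = 2, forest_deciduous = -1)
    )
  )
}

#' Generate ground-truth tract prevalence percentages
#'
#' Builds, for each outcome, a linear predictor over census proportions and
#' land-cover area proportions, adds a per-state baseline offset and Gaussian
#' noise, and clips to `[0, 100]`:
#' `prev_i = clip(base + sum_f beta_f x_if + state_i + N(0, noise_sd), 0, 100)`.
#' The generative coefficients and state offsets are attached as attributes so
#' recovery tests can compare against them.
#'
#' @param tracts a `tract_set`.
#' @param census a `census_table` for the same tracts.
#' @param landcover a `landcover_raster` covering the tracts.
#' @param model named list per outcome with `base` and `effects`
#'   (see [default_prevalence_model()]); effect names must be census or
#'   land-cover feature names.
#' @param noise_sd i.i.d. Gaussian noise, percentage points.
#' @param state_sd standard deviation of per-state baseline offsets
#'   (percentage points); offsets are drawn once per state.
#' @param seed integer RNG seed.
#' @return A `prevalence_table`: data.frame with `tract_id` and one percent
#'   column per outcome; attributes `model` and `state_offsets`.
#' @export
generate_prevalence <- function(tracts, census, landcover,
                                model = default_prevalence_model(),
                                noise_sd = 1, state_sd = 1.5, seed = 1) {
  stopifnot(inherits(tracts, "tract_set"))
  validate_census(census)
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")

  lc <- landcover_proportions(landcover, tracts)
  feats <- merge(as.data.frame(census), as.data.frame(lc), by = "tract_id")
  feats <- feats[match(tracts$tracts$tract_id, feats$tract_id), , drop = FALSE]
  avail <- setdiff(names(feats), "tract_id")

  n <- nrow(tracts$tracts)
  states <- sort(unique(tracts$tracts$state_code))
  with_seed(seed, {
    offsets <- rnorm(length(states), 0, state_sd)
    names(offsets) <- states
    out <- data.frame(tract_id = tracts$tracts$tract_id,
                      stringsAsFactors = FALSE)
    for (outcome in names(model)) {
      spec_o <- model[[outcome]]
      beta <- spec_o$effects
      unknown <- setdiff(names(beta), avail)
      if (length(unknown)) {
        stop_invalid("unknown coefficient name(s) for %s: %s",
                     outcome, paste(unknown, collapse = ", "))
      }
      lin <- spec_o$base + offsets[tracts$tracts$state_code]
      if (length(beta)) {
        lin <- lin + as.matrix(feats[, names(beta), drop = FALSE]) %*% beta
      }
      prev <- as.numeric(lin) + rnorm(n, 0, noise_sd)
      out[[outcome]] <- pmin(100, pmax(0, prev))
    }
    structure(out, class = c("prevalence_table", "data.frame"),
              model = model, state_offsets = offsets)
  })
}
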