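#' Siler mortality model
#'
#' Five-parameter hazard combining a declining infant component, a
#' constant background, and an exponentially rising senescent component:
#' `mx(x) = a1 exp(-b1 x) + a2 + a3 exp(b3 x)`.
#'
#' @param a1 infant-mortality level at age 0, per person-year.
#' @param b1 rate of decline of the infant component, per year.
#' @param a2 age-independent background rate, per person-year.
#' @param a3 senescent level at age 0, per person-year.
#' @param b3 senescent slope (Gompertz rate), per year.
#' @return A `siler_params` list.
#' @export
siler_params <- function(a1, b1, a2, a3, b3) {
  p <- list(a1 = a1, b1 = b1, a2 = a2, a3 = a3, b3 = b3)
  if (any(unlist(p) <= 0)) stop("all Siler parameters must be positive")
  structure(p, class = "siler_params")
}

#' Documented parameter presets for the epidemiological transition
#'
#' `"pretransition"` is a high-mortality regime (heavy infant and child
#' mortality, life expectancy in the high 30s); `"modern"` is a
#' low-mortality, rectangularized regime (life expectancy in the low 80s).
#'
#' @param name preset name.
#' @return A [siler_params()] object.
#' @export
siler_preset <- function(name = c("pretransition", "modern")) {
  switch(match.arg(name),
         pretransition = siler_params(a1 = 0.25, b1 = 1.0, a2 = 0.010,
                                      a3 = 8e-5, b3 = 0.090),
         modern = siler_params(a1 = 0.0015, b1 = 1.3, a2 = 2e-4,
                               a3 = 2e-5, b3 = 0.100))
}

#' Evaluate the Siler hazard on an age grid
#'
#' @param params a [siler_params()] object.
#' @param ages ages at which to evaluate, default 0:110.
#' @return Vector of death rates `mx(x)`, guaranteed positive and finite
#'   (the rising senescent term is capped at a very large rate so the open
#'   interval never overflows).
#' @export
siler_mx <- function(params, ages = 0:110) {
  stopifnot(inherits(params, "siler_params"))
  mx <- params$a1 * exp(-params$b1 * ages) + params$a2 +
    params$a3 * exp(pmin(params$b3 * ages, 700))
  pmin(mx, 1e6)
}

#' Life table implied by a Siler hazard
#'
#' Builds a single-year period life table from the Siler rates using
#' [build_lifetable_from_mx()]. Within-interval `ax` is 0.3 at age 0
#' (deaths in the first year of life concentrate early) and 0.5 at other
#' closed ages; the open interval uses `1/mx`.
#'
#' @inheritParams siler_mx
#' @param radix starting cohort size.
#' @param year calendar year label.
#' @return A `lifetable`.
#' @export
siler_lifetable <- function(params, ages = 0:110, radix = 1e5,
                            year = NA_integer_) {
  mx <- siler_mx(params, ages)
  ax <- c(0.3, rep(0.5, length(ages) - 1))
  build_lifetable_from_mx(mx, ax = ax, radix = radix, year = year)
}

#' Synthetic life-table panel emulating the epidemiological transition
#'
#' Generates `populations` populations observed over `years` consecutive
#' years. Each Siler parameter moves log-linearly from its value in
#' `start_params` to its value in `end_params`, so life expectancy rises
#' smoothly from a high-mortality to a rectangularized regime; each
#' population carries fixed multiplicative level offsets (log-normal, 10%
#' scale) on `a1`, `a2`, `a3` so populations differ but follow the same
#' transition. A non-decreasing synthetic record-lifespan series rising
#' from 107.26 to 122.45 accompanies the panel. Optionally, sampling noise
#' is added by drawing age-specific death counts from a Poisson law at the
#' given person-years `exposure` and rebuilding the table from the
#' observed rates; as exposure grows the stochastic table converges to the
#' noise-free one.
#'
#' Everything is driven by one seeded RNG stream: the same `seed` gives a
#' bit-identical panel. The seed is recorded in the result.
#'
#' @param start_params,end_params [siler_params()] at the first and last
#'   year; default the `"pretransition"` and `"modern"` presets.
#' @param years number of years (>= 2).
#' @param populations number of populations.
#' @param seed integer RNG seed.
#' @param stochastic logical; add Poisson sampling noise to death counts.
#' @param exposure person-years of exposure per age for the stochastic
#'   mode.
#' @param start_year first calendar year; default 1950.
#' @return List with `tables` (records of `population`, `sex`, `year`,
#'   `lifetable`, consumable by [build_panel()]), `record_series`
#'   (data frame `year`, `omega`), and `seed`.
#' @export
generate_transition_panel <- function(start_params = siler_preset("pretransition"),
                                      end_params = siler_preset("modern"),
                                      years = 70, populations = 2,
                                      seed = 1, stochastic = FALSE,
                                      exposure = 1e6, start_year = 1950) {
  stopifnot(inherits(start_params, "siler_params"),
            inherits(end_params, "siler_params"))
  if (years < 2) stop("need at least two years")
  if (populations < 1) stop("need at least one population")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)

  offsets <- matrix(exp(stats::rnorm(populations * 3, 0, 0.1)),
                    nrow = populations,
                    dimnames = list(NULL, c("a1", "a2", "a3")))
  frac <- seq(0, 1, length.out = years)
  interp <- function(name)
    exp((1 - frac) * log(start_params[[name]]) +
          frac * log(end_params[[name]]))
  par_path <- lapply(c("a1", "b1", "a2", "a3", "b3"), interp)
  names(par_path) <- c("a1", "b1", "a2", "a3", "b3")

  yrs <- start_year + seq_len(years) - 1L
  tables <- list()
  for (p in seq_len(populations)) {
    code <- sprintf("SYN%02d", p)
    for (t in seq_len(years)) {
      params <- siler_params(
        a1 = par_path$a1[t] * offsets[p, "a1"], b1 = par_path$b1[t],
        a2 = par_path$a2[t] * offsets[p, "a2"],
        a3 = par_path$a3[t] * offsets[p, "a3"], b3 = par_path$b3[t])
      lt <- siler_lifetable(params, year = yrs[t])
      if (stochastic) {
        Ex <- exposure * lt$Lx / lt$radix
        deaths <- stats::rpois(length(Ex), lt$mx * Ex)
        mhat <- ifelse(Ex > 0, deaths / Ex, lt$mx)
        n <- length(mhat)
        if (mhat[n] <= 0) mhat[n] <- lt$mx[n]
        lt <- build_lifetable_from_mx(mhat, ax = lt$ax, radix = lt$radix,
                                      year = yrs[t])
      }
      tables[[length(tables) + 1L]] <-
        list(population = code, sex = "female", year = yrs[t],
             lifetable = lt)
    }
  }
  record <- cummax(round(107.26 + (122.45 - 107.26) *
                           pmin(frac / 0.9, 1), 2))
  list(tables = tables,
       record_series = data.frame(year = yrs, omega = record),
       seed = seed)
}

#' Canonical worked fixtures
#'
#' Small exact constructions used throughout the documentation and tests:
#' `two_point(e0, omega)` — the maximal-inequality benchmark distribution;
#' `degenerate(age)` — all deaths at one exact age; `uniform(top)` — equal
#' point masses on ages `0..top`; `worked_toy` — a three-age toy life
#' table (ages 0, 1, open at 2; survivors 100000/90000/80000; `ax` 0.3,
#' 0.5, 5.0) whose mean age at death is 5.78.
#'
#' @return Named list of fixture constructors / objects.
#' @export
fixtures <- function() {
  worked_toy <- new_lifetable(
    ages = 0:2,
    mx = c(10000 / 93000, 10000 / 85000, 0.2),
    qx = c(0.1, 1 / 9, 1),
    ax = c(0.3, 0.5, 5.0),
    lx = c(1e5, 9e4, 8e4),
    dx = c(1e4, 1e4, 8e4),
    Lx = c(93000, 85000, 400000),
    Tx = c(578000, 485000, 400000),
    ex = c(5.78, 485000 / 90000, 5.0),
    year = 2000L)
  list(
    two_point = function(e0, omega = 122)
      max_inequality_distribution(e0, omega)$dist,
    degenerate = function(age)
      aad_from_counts(age, 1, point_mass = TRUE),
    uniform = function(top = 9)
      aad_from_counts(0:top, rep(1, top + 1), point_mass = TRUE),
    worked_toy = worked_toy)
}
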