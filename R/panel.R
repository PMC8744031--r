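#' Compute all inequality indices for a panel of life tables
#'
#' Builds the tidy table behind longevity-inequality analyses: one row per
#' (population, sex, year) holding `e0` and every index. The maximal
#' lifespan used for the normalized Gini follows the omega policy: a fixed
#' value (default 122), or a record-lifespan series giving the bound per
#' year.
#'
#' @param tables a list of records, each a list with fields `population`,
#'   `sex`, `year` (optional if the life table carries one) and `lifetable`
#'   (a `lifetable`); the output of
#'   [generate_transition_panel()]`$tables` has this shape.
#' @param omega fixed maximal lifespan, years. Ignored when `omega_series`
#'   is supplied.
#' @param omega_series optional data frame with columns `year` and `omega`
#'   (a record-lifespan series); each record uses its year's bound.
#' @return A data frame with columns `population`, `sex`, `year`, `omega`,
#'   `e0`, `AID`, `G`, `sigma`, `CV`, `edagger`, `H`, `Gstar`, ordered by
#'   population, sex, year.
#' @export
build_panel <- function(tables, omega = 122, omega_series = NULL) {
  if (!length(tables)) stop("domain error: empty collection of tables")
  rows <- lapply(tables, function(rec) {
    lt <- rec$lifetable
    stopifnot(inherits(lt, "lifetable"))
    yr <- if (!is.null(rec$year)) rec$year else lt$year
    w <- omega
    if (!is.null(omega_series)) {
      hit <- match(yr, omega_series$year)
      if (is.na(hit))
        stop("domain error: year ", yr, " missing from the omega series")
      w <- omega_series$omega[hit]
    }
    dist <- deaths_distribution(lt)
    if (!isTRUE(dist$e0 < w) || any(dist$xbar[dist$d > 0] > w + 1e-9))
      stop("domain error: omega policy violated for population '",
           rec$population, "', year ", yr,
           " (omega = ", w, ", e0 = ", round(dist$e0, 2), ")")
    data.frame(population = rec$population,
               sex = if (!is.null(rec$sex)) rec$sex else NA_character_,
               year = yr, omega = w, e0 = dist$e0,
               AID = aid(dist), G = gini(dist), sigma = lifespan_sd(dist),
               CV = lifespan_cv(dist), edagger = e_dagger(lt),
               H = life_table_entropy(lt),
               Gstar = normalized_gini(dist, omega = w))
  })
  out <- do.call(rbind, rows)
  out[order(out$population, out$sex, out$year), , drop = FALSE]
}

#' Ratio of life expectancy to the record lifespan
#'
#' @param panel a data frame from [build_panel()] (needs `population`,
#'   `sex`, `year`, `e0`).
#' @param record_series data frame with columns `year`, `omega`
#'   (non-decreasing record-lifespan series).
#' @return The panel rows with columns `omega_record` and
#'   `ratio = e0 / omega_record`.
#' @export
ratio_series <- function(panel, record_series) {
  hit <- match(panel$year, record_series$year)
  if (anyNA(hit))
    stop("domain error: record series missing year(s): ",
         paste(unique(panel$year[is.na(hit)]), collapse = ", "))
  out <- panel[c("population", "sex", "year", "e0")]
  out$omega_record <- record_series$omega[hit]
  out$ratio <- out$e0 / out$omega_record
  out
}

#' Rolling correlation between longevity and an inequality index
#'
#' For each center year T present in the panel, pools every
#' country-year observation with year in `[T - h, T + h]`
#' (`h = (window - 1)/2`) and reports the Pearson correlation between `e0`
#' and the index. Windows with fewer than 3 observations, or with zero
#' variance in either variable, yield `NA` with a diagnostic.
#'
#' @param panel a data frame from [build_panel()].
#' @param index column name of the index, e.g. `"G"` or `"Gstar"`.
#' @param window window width in years, odd; default 5.
#' @return Data frame with columns `year`, `r`, `n`, `diagnostic`.
#' @export
rolling_correlation <- function(panel, index = "G", window = 5) {
  if (!index %in% names(panel)) stop("unknown index column: ", index)
  if (window %% 2 != 1) stop("window must be odd")
  h <- (window - 1) / 2
  years <- sort(unique(panel$year))
  rows <- lapply(years, function(T) {
    w <- panel[panel$year >= T - h & panel$year <= T + h, ]
    n <- nrow(w)
    if (n < 3)
      return(data.frame(year = T, r = NA_real_, n = n,
                        diagnostic = "fewer than 3 observations"))
    if (stats::sd(w$e0) == 0 || stats::sd(w[[index]]) == 0)
      return(data.frame(year = T, r = NA_real_, n = n,
                        diagnostic = "zero variance in window"))
    data.frame(year = T, r = stats::cor(w$e0, w[[index]]), n = n,
               diagnostic = NA_character_)
  })
  do.call(rbind, rows)
}

#' Joint-change quadrant shares for longevity and inequality
#'
#' For every (population, sex) and every pair of consecutive years from
#' `from_year` onwards, computes the relative change of `e0` and of the
#' index, classifies the pair into one of four quadrants, and reports the
#' share of occurrences per quadrant. The normatively desirable direction
#' is rising longevity with falling inequality (`e0_up_index_down`). Pairs
#' where either change is exactly zero are excluded from the four shares
#' and reported under `ties`.
#'
#' @param panel a data frame from [build_panel()].
#' @param index index column name.
#' @param from_year first year of change pairs to include (pair `(t, t+1)`
#'   enters when `t >= from_year`); default 1980.
#' @param change `"relative"` (`(v[t+1] - v[t]) / v[t]`, default) or
#'   `"log"` (`log(v[t+1] / v[t])`).
#' @return List with `shares` (named fractions over the four quadrants,
#'   summing to 1), `counts`, `ties`, `n_pairs`.
#' @export
joint_change_quadrants <- function(panel, index = "G", from_year = 1980,
                                   change = c("relative", "log")) {
  change <- match.arg(change)
  if (!index %in% names(panel)) stop("unknown index column: ", index)
  delta <- function(v) if (change == "log") log(v[-1] / v[-length(v)])
                       else (v[-1] - v[-length(v)]) / v[-length(v)]
  de <- di <- numeric(0)
  for (key in split(panel, list(panel$population, panel$sex), drop = TRUE)) {
    key <- key[order(key$year), ]
    consec <- which(diff(key$year) == 1 &
                      key$year[-nrow(key)] >= from_year)
    if (!length(consec)) next
    de <- c(de, delta(key$e0)[consec])
    di <- c(di, delta(key[[index]])[consec])
  }
  if (!length(de)) stop("domain error: no consecutive-year change pairs")
  tie <- de == 0 | di == 0
  counts <- c(e0_up_index_up = sum(de > 0 & di > 0),
              e0_up_index_down = sum(de > 0 & di < 0),
              e0_down_index_up = sum(de < 0 & di > 0),
              e0_down_index_down = sum(de < 0 & di < 0))
  list(shares = counts / sum(counts), counts = counts,
       ties = sum(tie), n_pairs = length(de))
}

#' Maximal-inequality curve over a grid of life expectancies
#'
#' The benchmark curve superimposed on longevity-inequality scatters:
#' `I(M(e0, omega))` per grid point. For the AID it is an inverted parabola
#' peaking at `e0 = omega / 2`; for the Gini a straight line reaching 0 at
#' `e0 = omega`.
#'
#' @param index index identifier (see [max_index()]).
#' @param omega maximal lifespan, years.
#' @param e0_grid life-expectancy grid, all within `(0, omega)`.
#' @return Numeric vector of maximal index values along the grid.
#' @export
max_inequality_curve <- function(index, omega = 122,
                                 e0_grid = seq(1, omega - 1, by = 1)) {
  vapply(e0_grid, function(e0) max_index(index, e0, omega), numeric(1))
}
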