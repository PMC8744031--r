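#' Age-at-death distributions
#'
#' An `aad_dist` is the object all inequality indices consume: death shares
#' `d` over the age grid (summing to 1) together with `xbar`, the mean age
#' at death within each interval, and the implied mean age at death `e0`.
#'
#' @param ages integer ages.
#' @param d death shares, non-negative, summing to 1 within `1e-9`.
#' @param xbar mean age at death within each interval.
#' @return An object of class `aad_dist` with fields `ages`, `d`, `xbar`,
#'   `e0` (`= sum(d * xbar)` by construction).
#' @export
new_aad_dist <- function(ages, d, xbar) {
  if (length(d) != length(ages) || length(xbar) != length(ages))
    stop("ages, d and xbar must have the same length")
  if (any(d < 0)) stop("domain error: negative death share")
  if (abs(sum(d) - 1) > 1e-9) stop("death shares must sum to 1")
  if (any(xbar < 0)) stop("domain error: negative mean age at death")
  structure(list(ages = ages, d = as.numeric(d), xbar = as.numeric(xbar),
                 e0 = sum(d * xbar)),
            class = "aad_dist")
}

#' Age-at-death distribution of a life table
#'
#' Normalizes the life-table deaths column into death shares and attaches
#' the within-interval mean ages `xbar = x + ax`. The mean age at death `e0`
#' is recomputed as `sum(d * xbar)`; for a consistent life table this equals
#' the `ex` column at age 0 up to the file's printed rounding.
#'
#' @param lt a `lifetable`.
#' @return An `aad_dist`.
#' @examples
#' lt <- build_lifetable_from_mx(c(0.02, 0.01, 0.4))
#' deaths_distribution(lt)$e0
#' @export
deaths_distribution <- function(lt) {
  stopifnot(inherits(lt, "lifetable"))
  tot <- sum(lt$dx)
  if (!isTRUE(tot > 0)) stop("degenerate input: all-zero deaths column")
  new_aad_dist(lt$ages, lt$dx / tot, lt$ages + lt$ax)
}

#' Build an age-at-death distribution from weights
#'
#' Constructor for synthetic and worked examples. Weights are normalized to
#' shares. By default deaths within the interval `[x, x+1)` are placed at
#' its midpoint (`xbar = x + 0.5`); with `point_mass = TRUE` they sit
#' exactly at `x`, the convention used by the two-point maximal-inequality
#' benchmark.
#'
#' @param ages ages (need not be contiguous).
#' @param weights non-negative weights with positive sum.
#' @param xbar optional explicit within-interval mean ages.
#' @param point_mass logical; place all mass exactly at `ages`.
#' @return An `aad_dist`.
#' @examples
#' aad_from_counts(0:9, rep(1, 10), point_mass = TRUE)$e0  # 4.5
#' @export
aad_from_counts <- function(ages, weights, xbar = NULL, point_mass = FALSE) {
  if (any(weights < 0)) stop("domain error: negative weight")
  tot <- sum(weights)
  if (!isTRUE(tot > 0)) stop("weights must have positive sum")
  if (is.null(xbar)) xbar <- if (point_mass) ages else ages + 0.5
  new_aad_dist(ages, weights / tot, xbar)
}

#' Coerce to an age-at-death distribution
#'
#' @param x an `aad_dist` (returned unchanged) or a `lifetable`
#'   (run through [deaths_distribution()]).
#' @return An `aad_dist`.
#' @export
as_aad_dist <- function(x) {
  if (inherits(x, "aad_dist")) return(x)
  if (inherits(x, "lifetable")) return(deaths_distribution(x))
  stop("cannot coerce object of class '", paste(class(x), collapse = "/"),
       "' to an age-at-death distribution")
}

#' @export
print.aad_dist <- function(x, ...) {
  cat(sprintf("<aad_dist> %d ages (%g-%g), e0 = %.3f\n", length(x$ages),
              min(x$ages), max(x$ages), x$e0))
  invisible(x)
}

#' Export an age-at-death distribution as CSV
#'
#' Writes columns `age`, `d`, `xbar`.
#'
#' @param dist an `aad_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aad_csv <- function(dist, path) {
  utils::write.csv(data.frame(age = dist$ages, d = dist$d, xbar = dist$xbar),
                   path, row.names = FALSE)
  invisible(path)
}
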