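#' Construct a period life table object
#'
#' Bundles the standard single-year life-table columns into a `lifetable`
#' object. Ages run from 0 to the start of the open interval (`open_age`);
#' the last row is the open interval `[open_age, Inf)`. Validation enforces
#' the usual life-table identities (see [validate_lifetable()]).
#'
#' @param ages integer age grid, contiguous from 0; the last age opens the
#'   terminal interval.
#' @param mx age-specific death rates (per person-year).
#' @param qx conditional probabilities of death; 1 at the open interval.
#' @param ax average years lived in the interval by those dying in it; the
#'   open interval uses the `1/mx` convention.
#' @param lx survivors at exact age x (radix scale).
#' @param dx life-table deaths in each interval.
#' @param Lx,Tx person-years lived in the interval / above exact age x.
#' @param ex remaining life expectancy at exact age x, years.
#' @param year calendar year label (optional).
#' @param validate logical; run [validate_lifetable()] on the result.
#' @return An object of class `lifetable`: a list with the columns above plus
#'   `radix` (detected as `lx[1]`) and `open_age`.
#' @seealso [build_lifetable_from_mx()], [read_hmd_lifetable()]
#' @export
new_lifetable <- function(ages, mx, qx, ax, lx, dx, Lx, Tx, ex,
                          year = NA_integer_, validate = TRUE) {
  n <- length(ages)
  cols <- list(mx = mx, qx = qx, ax = ax, lx = lx, dx = dx,
               Lx = Lx, Tx = Tx, ex = ex)
  bad <- names(cols)[vapply(cols, length, 1L) != n]
  if (length(bad))
    stop("life-table columns with length != length(ages): ",
         paste(bad, collapse = ", "))
  if (!all(ages == seq(0L, n - 1L)))
    stop("ages must be contiguous integers starting at 0")
  lt <- structure(
    c(list(year = year, ages = as.integer(ages)), cols,
      list(radix = lx[1], open_age = as.integer(ages[n]))),
    class = "lifetable")
  if (validate) validate_lifetable(lt)
  lt
}

#' Validate life-table identities
#'
#' Checks that `qx` lies in `[0, 1]` and equals 1 at the open interval, that
#' `lx` is non-increasing with non-negative `dx` summing to the radix, that
#' `ax` lies within its interval, and that `ex` is non-negative with the open
#' interval's expectancy matching its `ax` (the `1/mx` convention).
#'
#' @param lt a `lifetable`.
#' @param tol relative tolerance for the radix identity.
#' @return `lt`, invisibly; stops with a validation error otherwise.
#' @export
validate_lifetable <- function(lt, tol = 1e-6) {
  stopifnot(inherits(lt, "lifetable"))
  n <- length(lt$ages)
  eps <- 1e-9
  if (any(lt$qx < -eps | lt$qx > 1 + eps))
    stop("validation error: qx outside [0, 1]")
  if (abs(lt$qx[n] - 1) > eps)
    stop("validation error: qx at the open interval must equal 1")
  if (any(diff(lt$lx) > lt$radix * tol))
    stop("validation error: lx must be non-increasing")
  if (any(lt$dx < -lt$radix * tol))
    stop("validation error: negative dx")
  if (abs(sum(lt$dx) - lt$lx[1]) > lt$radix * max(tol, 1e-4))
    stop("validation error: sum(dx) does not match the radix l0")
  if (any(lt$ax[-n] < -eps | lt$ax[-n] > 1 + eps))
    stop("validation error: closed-interval ax outside [0, 1]")
  if (any(lt$ex < -eps))
    stop("validation error: negative ex")
  if (is.finite(lt$ex[n]) && is.finite(lt$ax[n]) && lt$lx[n] > 0 &&
      abs(lt$ex[n] - lt$ax[n]) > 0.05)
    stop("validation error: ex at the open age must match its ax (1/mx)")
  invisible(lt)
}

#' Build a life table from age-specific death rates
#'
#' Standard period life-table construction on a single-year grid: for closed
#' intervals `qx = mx / (1 + (1 - ax) mx)` (capped at 1), `qx = 1` at the
#' open interval, survivorship and person-years by the usual recursion, and
#' the open interval closed out with `ax = Lx/lx = 1/mx`.
#'
#' @param mx death rates, one per age starting at age 0; the last entry is
#'   the open interval and must be positive.
#' @param ax average years lived in the interval by those dying in it;
#'   defaults to 0.5 for closed intervals. The open-interval entry is always
#'   recomputed as `1/mx` regardless of input.
#' @param radix starting cohort size, default 100000.
#' @param year calendar year label.
#' @return A `lifetable`.
#' @examples
#' lt <- build_lifetable_from_mx(c(0.02, 0.01, 0.01, 0.5))
#' lt$ex[1]
#' @export
build_lifetable_from_mx <- function(mx, ax = NULL, radix = 1e5,
                                    year = NA_integer_) {
  n <- length(mx)
  if (n < 2) stop("need at least one closed age and the open interval")
  if (any(mx < 0)) stop("domain error: negative mx")
  if (mx[n] <= 0) stop("domain error: open-interval mx must be positive")
  if (is.null(ax)) ax <- rep(0.5, n)
  if (length(ax) != length(mx)) stop("ax and mx lengths differ")
  ax[n] <- 1 / mx[n]
  closed <- seq_len(n - 1L)
  qx <- numeric(n)
  qx[closed] <- pmin(1, mx[closed] / (1 + (1 - ax[closed]) * mx[closed]))
  qx[n] <- 1
  lx <- radix * cumprod(c(1, 1 - qx[closed]))
  dx <- lx * qx
  Lx <- numeric(n)
  Lx[closed] <- lx[closed] - (1 - ax[closed]) * dx[closed]
  Lx[n] <- if (lx[n] > 0) lx[n] / mx[n] else 0
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  new_lifetable(ages = seq(0L, n - 1L), mx = mx, qx = qx, ax = ax,
                lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex, year = year)
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("<lifetable> year %s, ages 0-%d+ (radix %g), e0 = %.2f\n",
              ifelse(is.na(x$year), "?", x$year), x$open_age, x$radix,
              x$ex[1]))
  invisible(x)
}

#' @export
as.data.frame.lifetable <- function(x, ...) {
  data.frame(Year = x$year, Age = x$ages, mx = x$mx, qx = x$qx, ax = x$ax,
             lx = x$lx, dx = x$dx, Lx = x$Lx, Tx = x$Tx, ex = x$ex)
}
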