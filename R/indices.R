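#' Average inter-individual difference (absolute Gini) in age at death
#'
#' The AID is half the expected absolute difference between the ages at
#' death of two individuals drawn independently from the distribution:
#' `AID = 1/2 * sum_x sum_y d_x d_y |xbar_x - xbar_y|`, in years. The
#' default evaluation sorts the support and uses the cumulative-share form
#' (O(n log n)); `method = "double_sum"` evaluates the O(n^2) double sum
#' directly. The two agree to machine precision.
#'
#' @param x an `aad_dist`, or a `lifetable` (coerced via
#'   [deaths_distribution()]).
#' @param method `"sorted"` (default) or `"double_sum"`.
#' @return AID in years.
#' @examples
#' u <- aad_from_counts(0:9, rep(1, 10), point_mass = TRUE)
#' aid(u)  # 1.65
#' @export
aid <- function(x, method = c("sorted", "double_sum")) {
  method <- match.arg(method)
  dist <- as_aad_dist(x)
  d <- dist$d; v <- dist$xbar
  if (method == "double_sum")
    return(0.5 * sum(outer(d, d) * abs(outer(v, v, "-"))))
  o <- order(v)
  d <- d[o]; v <- v[o]
  F1 <- cumsum(d)
  F0 <- c(0, F1[-length(F1)])
  sum(d * v * (F1 + F0 - 1))
}

#' Gini coefficient of the age-at-death distribution
#'
#' Relative lifespan inequality: `G = AID / e0`, dimensionless in `[0, 1]`.
#'
#' @inheritParams aid
#' @return G, dimensionless.
#' @export
gini <- function(x) {
  dist <- as_aad_dist(x)
  if (!isTRUE(dist$e0 > 0))
    stop("undefined index: Gini requires a positive mean age at death")
  aid(dist) / dist$e0
}

#' Standard deviation and coefficient of variation of age at death
#'
#' `lifespan_sd()` is `sqrt(sum(d * (xbar - e0)^2))` in years;
#' `lifespan_cv()` divides by `e0`.
#'
#' @inheritParams aid
#' @return Standard deviation in years / CV dimensionless.
#' @export
lifespan_sd <- function(x) {
  dist <- as_aad_dist(x)
  sqrt(sum(dist$d * (dist$xbar - dist$e0)^2))
}

#' @rdname lifespan_sd
#' @export
lifespan_cv <- function(x) {
  dist <- as_aad_dist(x)
  if (!isTRUE(dist$e0 > 0))
    stop("undefined index: CV requires a positive mean age at death")
  lifespan_sd(dist) / dist$e0
}

#' Life expectancy lost at death (e-dagger) and life-table entropy
#'
#' e-dagger is the average remaining life expectancy at the age of death:
#' `sum_x d_x e(xbar_x)`, in years. The life-table entropy is
#' `H = e_dagger / e0`.
#'
#' For a `lifetable` the remaining expectancy at the fractional death age
#' `x + ax` is obtained from the `ex` column, by default by linear
#' interpolation between integer ages (`method = "interpolated"`, clamped
#' at the grid ends); `method = "integer"` reads `ex` at the integer age of
#' the interval instead. For a bare `aad_dist` the survival function and
#' remaining expectancies are reconstructed from the point masses at
#' `xbar`, with the convention `e(a) = E[X - a | X >= a]`.
#'
#' @inheritParams aid
#' @param method expectancy-at-death-age convention for life tables.
#' @return Years (`e_dagger`) / dimensionless (`life_table_entropy`).
#' @export
e_dagger <- function(x, method = c("interpolated", "integer")) {
  method <- match.arg(method)
  if (inherits(x, "lifetable")) {
    if (anyNA(x$ex)) stop("e-dagger needs a complete ex column")
    tot <- sum(x$dx)
    if (!isTRUE(tot > 0)) stop("degenerate input: all-zero deaths column")
    d <- x$dx / tot
    e_at <- if (method == "integer") x$ex
            else stats::approx(x$ages, x$ex, xout = x$ages + x$ax,
                               rule = 2)$y
    return(sum(d * e_at))
  }
  dist <- as_aad_dist(x)
  o <- order(dist$xbar)
  d <- dist$d[o]; v <- dist$xbar[o]
  tail_mass <- rev(cumsum(rev(d)))
  tail_sum <- rev(cumsum(rev(d * v)))
  r <- ifelse(tail_mass > 0, (tail_sum - v * tail_mass) / tail_mass, 0)
  sum(d * r)
}

#' @rdname e_dagger
#' @export
life_table_entropy <- function(x, method = c("interpolated", "integer")) {
  e0 <- if (inherits(x, "lifetable")) {
    tot <- sum(x$dx)
    if (!isTRUE(tot > 0)) stop("degenerate input: all-zero deaths column")
    sum(x$dx / tot * (x$ages + x$ax))
  } else as_aad_dist(x)$e0
  if (!isTRUE(e0 > 0))
    stop("undefined index: entropy requires a positive mean age at death")
  e_dagger(x, method = match.arg(method)) / e0
}

# Index dispatch shared by normalization, decomposition and the panel.
# Canonical identifiers: AID, G, sigma, CV, edagger, H (plus Gstar/AIDstar
# where normalization applies).
.base_indices <- c("AID", "G", "sigma", "CV", "edagger", "H")

.index_fun <- function(index) {
  switch(index,
         AID = aid,
         G = gini,
         sigma = lifespan_sd,
         CV = lifespan_cv,
         edagger = e_dagger,
         H = life_table_entropy,
         stop("unknown index identifier: ", index))
}

#' Evaluate a lifespan-inequality index by identifier
#'
#' Dispatch helper used by the panel and decomposition layers. Identifiers:
#' `"AID"`, `"G"`, `"sigma"`, `"CV"`, `"edagger"`, `"H"`, and the
#' normalized `"Gstar"` / `"AIDstar"` (which need `omega`).
#'
#' @inheritParams aid
#' @param index index identifier.
#' @param omega maximal lifespan bound, used by normalized indices.
#' @return The index value (years for AID, sigma, edagger; dimensionless
#'   otherwise).
#' @export
lifespan_index <- function(x, index, omega = 122) {
  if (index %in% c("Gstar", "AIDstar"))
    return(normalized_gini(x, omega = omega))
  .index_fun(index)(x)
}
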