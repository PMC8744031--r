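#' Robustness of a normalized-Gini comparison to the maximal lifespan
#'
#' For two populations A and B, the normalized Gini curves
#' `Gstar(omega) = G * omega / (omega - e0)` either keep the same order for
#' every admissible `omega` (complete robustness) or swap exactly once at a
#' unique threshold `omega_star` (partial robustness). When `G_A != G_B`
#' the crossing solves `G_A omega/(omega - e0_A) = G_B omega/(omega - e0_B)`
#' in closed form:
#' `omega_star = (G_A e0_B - G_B e0_A) / (G_A - G_B)`.
#' The comparison is partial iff `omega_star > omega_min`; otherwise the
#' order at `omega_min` holds throughout. Equal Gini with different means
#' is always complete (the larger mean has the larger normalized value);
#' equal Gini and equal mean is a tie.
#'
#' @param e0_a,e0_b life expectancies, years; each in `(0, omega_min)`.
#' @param g_a,g_b classical Gini coefficients, `>= 0`.
#' @param omega_min lower bound of the admissible `omega` range; default
#'   122, the highest validated human age at death.
#' @return An `omega_comparison`: list with `verdict` (one of
#'   `"complete_A_higher"`, `"complete_B_higher"`, `"partial"`, `"tie"`),
#'   `omega_star` (the crossing, `NA` unless partial), `omega_min`, and
#'   `gstar_at_crossing` (`NA` unless partial).
#' @examples
#' omega_star_gini(84, 0.100, 85, 0.099)$omega_star  # 184
#' @export
omega_star_gini <- function(e0_a, g_a, e0_b, g_b, omega_min = 122) {
  stopifnot(g_a >= 0, g_b >= 0)
  if (!(e0_a > 0 && e0_a < omega_min && e0_b > 0 && e0_b < omega_min))
    stop("domain error: life expectancies must lie in (0, omega_min)")
  gstar <- function(g, e0, w) g * w / (w - e0)
  res <- function(verdict, omega_star = NA_real_, gx = NA_real_)
    structure(list(verdict = verdict, omega_star = omega_star,
                   omega_min = omega_min, gstar_at_crossing = gx,
                   e0_a = e0_a, g_a = g_a, e0_b = e0_b, g_b = g_b),
              class = "omega_comparison")

  if (g_a == g_b) {
    if (e0_a == e0_b) return(res("tie"))
    if (g_a == 0) return(res("tie"))  # both identically zero for all omega
    return(res(if (e0_a > e0_b) "complete_A_higher" else "complete_B_higher"))
  }
  omega_star <- (g_a * e0_b - g_b * e0_a) / (g_a - g_b)
  if (is.finite(omega_star) && omega_star > omega_min) {
    return(res("partial", omega_star, gstar(g_a, e0_a, omega_star)))
  }
  # no crossing in the admissible range: order is decided at omega_min
  # (or just above it, if the curves touch exactly at the boundary)
  w <- omega_min
  da <- gstar(g_a, e0_a, w) - gstar(g_b, e0_b, w)
  if (da == 0) da <- gstar(g_a, e0_a, w + 1) - gstar(g_b, e0_b, w + 1)
  if (da == 0) return(res("tie"))
  res(if (da > 0) "complete_A_higher" else "complete_B_higher")
}

#' @export
print.omega_comparison <- function(x, ...) {
  cat(sprintf("<omega_comparison> %s", x$verdict))
  if (identical(x$verdict, "partial"))
    cat(sprintf(" at omega* = %.4f (G* = %.4f)", x$omega_star,
                x$gstar_at_crossing))
  cat(sprintf(" [omega >= %g]\n", x$omega_min))
  invisible(x)
}

#' Compare two age-at-death distributions across all maximal lifespans
#'
#' Computes `(e0, G)` for each distribution and delegates to
#' [omega_star_gini()].
#'
#' @param dist_a,dist_b `aad_dist` or `lifetable` objects.
#' @inheritParams omega_star_gini
#' @return An `omega_comparison`.
#' @export
compare_distributions <- function(dist_a, dist_b, omega_min = 122) {
  a <- as_aad_dist(dist_a); b <- as_aad_dist(dist_b)
  omega_star_gini(a$e0, gini(a), b$e0, gini(b), omega_min = omega_min)
}

.panel_e0_g <- function(panel) {
  if (is.data.frame(panel)) {
    if (!all(c("e0", "G") %in% names(panel)))
      stop("panel data frame needs columns 'e0' and 'G'")
    return(panel[c("e0", "G")])
  }
  if (is.list(panel) && length(panel) &&
      all(vapply(panel, function(p)
        inherits(p, "aad_dist") || inherits(p, "lifetable"), TRUE))) {
    dists <- lapply(panel, as_aad_dist)
    return(data.frame(e0 = vapply(dists, function(d) d$e0, 1),
                      G = vapply(dists, gini, 1)))
  }
  stop("domain error: panel must be a data frame with e0 and G or a ",
       "non-empty list of distributions/life tables")
}

#' Proportion of pairs ranked consistently over an omega range
#'
#' A pair of populations is consistently ranked on `[omega_lo, omega_hi]`
#' when its normalized-Gini comparison is complete (or a tie), or when the
#' crossing threshold `omega_star` falls outside the open interval
#' `(omega_lo, omega_hi)`. Returns the share of consistent unordered pairs.
#'
#' @param panel a data frame with columns `e0` and `G`, or a list of
#'   `aad_dist`/`lifetable` objects (at least 2 entries).
#' @param omega_lo,omega_hi admissible `omega` range; `omega_lo` must be at
#'   least the largest `e0`.
#' @return Proportion in `[0, 1]`.
#' @export
rank_consistency <- function(panel, omega_lo = 122, omega_hi = 250) {
  eg <- .panel_e0_g(panel)
  n <- nrow(eg)
  if (n < 2) stop("domain error: need at least two populations")
  if (omega_hi < omega_lo) stop("domain error: omega_hi < omega_lo")
  if (omega_lo <= max(eg$e0))
    stop("domain error: omega_lo must exceed every e0")
  if (omega_hi == omega_lo) return(1)
  pairs <- utils::combn(n, 2)
  consistent <- apply(pairs, 2, function(ij) {
    cmp <- omega_star_gini(eg$e0[ij[1]], eg$G[ij[1]],
                           eg$e0[ij[2]], eg$G[ij[2]], omega_min = omega_lo)
    cmp$verdict != "partial" || cmp$omega_star >= omega_hi
  })
  mean(consistent)
}

#' Rank populations by normalized Gini at a given maximal lifespan
#'
#' Rank 1 is the lowest `Gstar`. Exact ties in `Gstar` are broken by the
#' smaller `e0` first; remaining ties keep input order.
#'
#' @inheritParams rank_consistency
#' @param omega maximal lifespan at which to rank.
#' @return Integer rank vector, one entry per population.
#' @export
ranking_by_omega <- function(panel, omega = 122) {
  eg <- .panel_e0_g(panel)
  if (!nrow(eg)) stop("domain error: empty panel")
  if (omega <= max(eg$e0)) stop("domain error: omega must exceed every e0")
  gstar <- eg$G * omega / (omega - eg$e0)
  order(order(gstar, eg$e0))
}
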