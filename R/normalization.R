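#' The maximal-inequality benchmark distribution M(e0, omega)
#'
#' Among all age-at-death distributions with mean `e0` and support within
#' `[0, omega]`, inequality is maximized by the two-point distribution in
#' which a share `s1 = 1 - e0/omega` dies at exact age 0 and the remaining
#' share dies at exact age `omega` — the extreme-rectangularization
#' benchmark. Its mean is `e0` by construction.
#'
#' @param e0 mean age at death, years; must satisfy `0 < e0 < omega`.
#' @param omega maximal lifespan bound, years. The default 122 is the
#'   highest age at death ever validated for a human.
#' @return A `max_ineq_benchmark`: list with `e0`, `omega`, `s1`, and
#'   `dist` (the two-point `aad_dist`, point-mass convention).
#' @examples
#' max_inequality_distribution(61, 122)$s1  # 0.5
#' @export
max_inequality_distribution <- function(e0, omega = 122) {
  if (!isTRUE(e0 > 0)) stop("domain error: e0 must be positive")
  if (!isTRUE(e0 < omega))
    stop("domain error: e0 must be below omega (no room for variability)")
  s1 <- 1 - e0 / omega
  structure(list(e0 = e0, omega = omega, s1 = s1,
                 dist = aad_from_counts(c(0, omega), c(s1, 1 - s1),
                                        point_mass = TRUE)),
            class = "max_ineq_benchmark")
}

#' @export
print.max_ineq_benchmark <- function(x, ...) {
  cat(sprintf("<max_ineq_benchmark> e0 = %g, omega = %g, s1 = %.4f\n",
              x$e0, x$omega, x$s1))
  invisible(x)
}

#' Maximal index values given mean and maximal lifespan
#'
#' Closed forms of each inequality index evaluated on the two-point
#' benchmark `M(e0, omega)`:
#' `AID: e0 (omega - e0) / omega`; `G: (omega - e0) / omega`;
#' `sigma: sqrt(e0 (omega - e0))`; `CV: sqrt((omega - e0) / e0)`;
#' `edagger: e0 (omega - e0) / omega`; `H: (omega - e0) / omega`.
#' Each equals direct evaluation of the index on the benchmark
#' distribution (unit-tested to machine precision).
#'
#' @inheritParams max_inequality_distribution
#' @param index index identifier (see [lifespan_index()]).
#' @return The maximal index value.
#' @export
max_index <- function(index, e0, omega = 122) {
  if (any(!(e0 > 0)) || any(!(e0 < omega)))
    stop("domain error: need 0 < e0 < omega")
  switch(index,
         AID = ,
         edagger = e0 * (omega - e0) / omega,
         G = ,
         H = (omega - e0) / omega,
         sigma = sqrt(e0 * (omega - e0)),
         CV = sqrt((omega - e0) / e0),
         stop("unknown index identifier: ", index))
}

#' @rdname max_index
#' @export
max_aid <- function(e0, omega = 122) max_index("AID", e0, omega)

#' Normalized lifespan-inequality index
#'
#' Divides the observed index value `I(A)` by the maximal value the index
#' can attain in a distribution with the same mean and support bounded by
#' `omega`, i.e. by `I(M(e0(A), omega))`. For the AID, Gini, standard
#' deviation and CV the benchmark is the true maximizer, so the result
#' lies in `[0, 1]`: 0 for a degenerate distribution, 1 for the two-point
#' benchmark itself. For e-dagger and the entropy the ratio is still taken
#' against the benchmark's value, but the two-point distribution does not
#' maximize e-dagger (a near-geometric survival curve can exceed it), so
#' those ratios can exceed 1; see the methods vignette. Requires every
#' death to occur at or below `omega`.
#'
#' @inheritParams aid
#' @param index index identifier: `"AID"`, `"G"`, `"sigma"`, `"CV"`,
#'   `"edagger"`, `"H"`.
#' @param omega maximal lifespan bound, years.
#' @return Dimensionless value in `[0, 1]`.
#' @examples
#' m <- max_inequality_distribution(70, 122)
#' normalized_index(m$dist, "G")  # 1
#' @export
normalized_index <- function(x, index, omega = 122) {
  val <- lifespan_index(x, index)
  dist <- as_aad_dist(x)
  .check_omega(dist, omega)
  val / max_index(index, dist$e0, omega)
}

.check_omega <- function(dist, omega) {
  live <- dist$d > 0
  if (any(dist$xbar[live] > omega + 1e-9))
    stop("domain error: death mass beyond the maximal lifespan omega = ",
         omega)
  if (!isTRUE(dist$e0 < omega))
    stop("domain error: e0 must lie strictly below omega")
  if (!isTRUE(dist$e0 > 0))
    stop("domain error: e0 must be positive")
  invisible(dist)
}

#' Normalized Gini index
#'
#' `Gstar(A, omega) = G(A) / ((omega - e0(A)) / omega)`, equivalently the
#' AID divided by its maximum `e0 (omega - e0) / omega`. Applying the
#' normalization to the absolute and the relative Gini gives the identical
#' quantity, so `normalized_aid()` is an alias. As `omega` grows without
#' bound, `Gstar` decreases monotonically to the classical Gini `G`.
#'
#' @inheritParams aid
#' @param omega maximal lifespan bound, years.
#' @return Dimensionless value in `[0, 1]`.
#' @export
normalized_gini <- function(x, omega = 122) {
  dist <- as_aad_dist(x)
  .check_omega(dist, omega)
  gini(dist) / ((omega - dist$e0) / omega)
}

#' @rdname normalized_gini
#' @export
normalized_aid <- function(x, omega = 122) {
  dist <- as_aad_dist(x)
  .check_omega(dist, omega)
  aid(dist) / max_aid(dist$e0, omega)
}
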