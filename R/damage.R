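#' Dot-product damage of a drug profile on a cell type
#'
#' The damage a drug with affinity profile `r` inflicts on a cell type with
#' isotype profile `q`, modeled as the dot product `sum_i r_i * q_i`.  Being
#' an average of the entries of `q` weighted by the simplex vector `r`, the
#' value always lies in `[min(q), max(q)]`, and it is symmetric in its
#' arguments.
#'
#' @param r Drug affinity profile ([isotype_profile()]).
#' @param q Cell isotype profile ([isotype_profile()]).
#' @return Dimensionless damage score (numeric scalar).
#' @examples
#' u <- isotype_profile(rep(1 / 8, 8))
#' dot_damage(u, isotype_profile(c(0.6, 0.3, 0.1, 0, 0, 0, 0, 0)))  # 0.125
#' @export
dot_damage <- function(r, q) {
  r <- as_profile(r, "r")
  q <- as_profile(q, "q")
  sum(unclass(r) * unclass(q))
}

#' Kullback-Leibler damage of a drug profile on a cell type
#'
#' The negative Kullback-Leibler divergence of the drug profile `r` from
#' the cell profile `q`,
#' `D_KL(r, q) = -sum_{i: r_i > 0} r_i * log(r_i / q_i)` (natural log,
#' with the convention `0 * log 0 = 0`).  Always non-positive, and zero
#' exactly when the two profiles coincide.  Under this model the most damaging drug is the
#' one whose affinities match the cell's isotype usage proportionally,
#' rather than the one hammering the single most abundant isotype.
#'
#' @param r,q Isotype profiles.
#' @param on_unsupported What to do when `r` puts mass on an isotype that
#'   `q` does not express: `"neg_inf"` (default) returns `-Inf` with a
#'   warning of class `otip_unsupported_target`; `"error"` raises an error.
#' @return Non-positive numeric scalar (possibly `-Inf`).
#' @examples
#' q <- isotype_profile(c(0.25, 0.75, 0, 0, 0, 0, 0, 0))
#' kl_damage(q, q)  # 0
#' @export
kl_damage <- function(r, q, on_unsupported = c("neg_inf", "error")) {
  on_unsupported <- match.arg(on_unsupported)
  r <- unclass(as_profile(r, "r"))
  q <- unclass(as_profile(q, "q"))
  pos <- r > 0
  if (any(pos & q == 0)) {
    bad <- OTIP_ISOTYPES[pos & q == 0]
    msg <- paste0("unsupported-target: drug binds isotype(s) absent from ",
                  "the cell profile: ", paste(bad, collapse = ", "))
    if (on_unsupported == "error") stop(msg, call. = FALSE)
    warning(warningCondition(msg,
                             class = c("otip_unsupported_target", "warning")))
    return(-Inf)
  }
  # + 0 normalizes IEEE -0 (exact zero point) to +0
  -sum(r[pos] * log(r[pos] / q[pos])) + 0
}
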