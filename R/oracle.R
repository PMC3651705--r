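#' Brute-force grid oracle for profile optimization
#'
#' An independent verification oracle: enumerates every point of the
#' probability simplex with coordinates that are multiples of `grid_step`
#' (a grid that contains all simplex vertices), restricted to the isotypes
#' actually expressed by the cancer or any constraint tissue, filters by
#' the tissue caps and returns the best surviving point.  Intended for
#' testing the LP and convex solvers on small instances; the grid is
#' combinatorial, so at most 4 expressed isotypes are allowed.
#'
#' Isotypes expressed by nobody contribute nothing to the objective or any
#' constraint, so they are interchangeable; with `include_slack = TRUE`
#' they are pooled (exactly, not approximately) into a single extra grid
#' coordinate, which lets the oracle discover optima that park probability
#' mass outside the expressed isotypes to relax the caps.  With the
#' default `include_slack = FALSE` the search is restricted to the
#' expressed isotypes, making the oracle a lower bound on the true
#' optimum.
#'
#' @param cancer_q Cancer isotype profile.
#' @param constraints An [otip_constraints()] object or `NULL`.
#' @param grid_step Grid resolution in `(0, 0.1]`; `1/grid_step` is
#'   rounded to an integer denominator.
#' @param model `"dot"` or `"kl"` objective.
#' @param include_slack Pool unexpressed isotypes into one extra grid
#'   coordinate (see above).
#' @return An `otip_result` (status `"optimal"` or `"infeasible"`) whose
#'   `objective` is the best grid value.
#' @export
brute_force_oracle <- function(cancer_q, constraints = NULL,
                               grid_step = 0.01,
                               model = c("dot", "kl"),
                               include_slack = FALSE) {
  model <- match.arg(model)
  qc <- unclass(as_profile(cancer_q, "cancer_q"))
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 0.1)
    stop("grid_step must lie in (0, 0.1]", call. = FALSE)
  n <- as.integer(round(1 / grid_step))
  A <- constraint_matrix(constraints)
  w <- if (is.null(constraints)) numeric(0) else constraints$caps
  support <- which(qc > 0 | colSums(A) > 0)
  if (length(support) > 4L)
    stop("grid oracle supports at most 4 expressed isotypes (got ",
         length(support), ")", call. = FALSE)
  dims <- support
  slack <- include_slack && length(support) < 8L
  obj <- qc[dims]
  Ad <- A[, dims, drop = FALSE]
  if (slack) {  # one pooled coordinate: zero objective, zero constraint use
    obj <- c(obj, 0)
    Ad <- cbind(Ad, rep(0, nrow(Ad)))
  }
  if (model == "kl" && slack)
    stop("include_slack is not meaningful for the KL objective ",
         "(mass outside the tumor support scores -Inf)", call. = FALSE)
  res <- if (model == "dot")
    grid_search_dot(obj, Ad, w, n, 1e-9)
  else
    grid_search_kl(qc[dims], Ad, w, n, 1e-9)
  if (!res$feasible)
    return(new_otip_result(NULL, damage = NA_real_, status = "infeasible",
                           active = character(), model = model,
                           message = "no feasible grid point"))
  r <- numeric(8L)
  r[dims] <- res$counts[seq_along(dims)] / n
  if (slack && res$counts[length(res$counts)] > 0L) {
    sink <- setdiff(seq_len(8L), support)[1L]
    r[sink] <- res$counts[length(res$counts)] / n
  }
  rp <- isotype_profile(r, label = "grid_oracle")
  dmg <- if (model == "dot") dot_damage(rp, isotype_profile(qc))
         else res$objective
  new_otip_result(rp, damage = dmg, status = "optimal",
                  active = active_constraint_ids(constraints, rp,
                                                 tol = grid_step),
                  model = model, objective = res$objective)
}
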