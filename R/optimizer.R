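new_otip_result <- function(profile, damage, status, active, model,
                            objective = NA_real_, message = NULL) {
  structure(list(optimal_profile = profile, damage = damage,
                 status = status, active_constraints = active,
                 objective_model = model, objective = objective,
                 message = message),
            class = "otip_result")
}

#' @export
print.otip_result <- function(x, ...) {
  cat("<otip_result> status=", x$status, ", model=", x$objective_model,
      "\n", sep = "")
  if (x$status == "optimal") {
    p <- unclass(x$optimal_profile)
    nz <- p > 5e-3
    cat("  profile: ",
        paste0(round(100 * p[nz]), "% ", OTIP_ISOTYPES[nz],
               collapse = ", "), "\n", sep = "")
    cat("  damage on cancer: ", format(x$damage), "\n", sep = "")
    if (length(x$active_constraints))
      cat("  active constraints: ",
          paste(x$active_constraints, collapse = ", "), "\n", sep = "")
  } else if (!is.null(x$message)) cat("  ", x$message, "\n", sep = "")
  invisible(x)
}

active_constraint_ids <- function(constraints, r, tol = 1e-7) {
  if (is.null(constraints) || length(constraints) == 0L) return(character())
  A <- constraint_matrix(constraints)
  d <- drop(A %*% unclass(r))
  constraints$tissues[abs(d - constraints$caps) <= tol]
}

#' Optimal isotype profile under per-tissue damage caps
#'
#' Solves the linear program at the heart of the framework: find the drug
#' affinity profile `r` on the probability simplex maximizing the
#' dot-product damage to the cancer profile `q(c)`, subject to the damage
#' on each healthy tissue `t_h` staying at or below its cap `w_h`:
#' `max_r q(c)' r  s.t.  q(t_h)' r <= w_h  for all h,  r >= 0, sum r = 1`.
#'
#' With no constraints the optimum puts all mass on the single most
#' expressed isotype of the cancer (ties broken canonically) and the
#' damage equals `max(q(c))`.  With constraints the optimum typically
#' spreads over two or more isotypes; constraints met with equality are
#' reported as active, flagging the tissues that limit the achievable
#' damage.  The LP is solved with the two-phase simplex method of
#' `boot::simplex()` under a fixed tolerance, so results are deterministic;
#' when the optimal face is degenerate the solver's vertex is returned.
#'
#' @param cancer_q Cancer isotype profile.
#' @param constraints An [otip_constraints()] object (or `NULL` for the
#'   unconstrained problem).
#' @return An object of class `otip_result` with fields
#'   `optimal_profile`, `damage` (dot damage on `cancer_q`), `status`
#'   (`"optimal"` or `"infeasible"`), `active_constraints`,
#'   `objective_model = "dot"` and `objective`.
#' @examples
#' qc <- isotype_profile(c(0.6, 0.3, 0.1, 0, 0, 0, 0, 0))
#' qh <- isotype_profile(c(0.8, 0.1, 0.1, 0, 0, 0, 0, 0))
#' otip_optimize(qc, otip_constraints(list(liver = qh), caps = 0.2))
#' @export
otip_optimize <- function(cancer_q, constraints = NULL) {
  qc <- as_profile(cancer_q, "cancer_q")
  if (!is.null(constraints) && !inherits(constraints, "otip_constraints"))
    stop("constraints must be an otip_constraints object or NULL",
         call. = FALSE)
  if (is.null(constraints) || length(constraints) == 0L) {
    i <- which.max(unclass(qc))
    r <- isotype_profile(replace(numeric(8L), i, 1), label = "otip")
    return(new_otip_result(r, damage = unclass(qc)[[i]],
                           status = "optimal", active = character(),
                           model = "dot", objective = unclass(qc)[[i]]))
  }
  A <- constraint_matrix(constraints)
  sol <- boot::simplex(a = unclass(qc), A1 = A, b1 = constraints$caps,
                       A3 = matrix(1, 1L, 8L), b3 = 1,
                       maxi = TRUE, eps = 1e-10, n.iter = 200L)
  if (sol$solved == -1L)
    return(new_otip_result(NULL, damage = NA_real_, status = "infeasible",
                           active = character(), model = "dot",
                           message = paste0(
                             "no profile on the simplex satisfies all ",
                             length(constraints), " tissue cap(s)")))
  if (sol$solved != 1L)
    stop("LP solver failed to converge (not an infeasibility)",
         call. = FALSE)
  r_raw <- pmax(as.numeric(sol$soln[seq_len(8L)]), 0)
  r <- isotype_profile(r_raw / sum(r_raw), label = "otip")
  viol <- drop(A %*% unclass(r)) - constraints$caps
  if (any(viol > 1e-7))
    stop("LP solution violates constraints beyond tolerance", call. = FALSE)
  dmg <- dot_damage(r, qc)
  new_otip_result(r, damage = dmg, status = "optimal",
                  active = active_constraint_ids(constraints, r),
                  model = "dot", objective = dmg)
}

#' Penalized net-benefit profile optimization
#'
#' Instead of hard caps, subtracts weighted healthy-tissue damage from the
#' cancer damage and maximizes the net benefit
#' `D(r, q(c)) - sum_h v_h D(r, q(t_h))` over the simplex.  The objective
#' is linear in `r`, so the optimum is the vertex (pure isotype) with the
#' largest net-benefit coefficient `q(c) - sum_h v_h q(t_h)`; ties break
#' to the first isotype in canonical order.  Larger `v_h` means more
#' protection for tissue `h` (the soft analogue of decreasing a cap).
#'
#' @param cancer_q Cancer isotype profile.
#' @param penalties An [otip_constraints()] object whose `caps` slot holds
#'   the penalty weights `v_h >= 0` (or `NULL` for none).
#' @return An `otip_result` with `objective_model = "sum"`; `damage` is
#'   the dot damage of the chosen profile on `cancer_q` and `objective`
#'   the net benefit.
#' @export
otip_sum_optimize <- function(cancer_q, penalties = NULL) {
  qc <- as_profile(cancer_q, "cancer_q")
  net <- unclass(qc)
  if (!is.null(penalties) && length(penalties) > 0L) {
    stopifnot(inherits(penalties, "otip_constraints"))
    A <- constraint_matrix(penalties)
    net <- net - drop(penalties$caps %*% A)
  }
  i <- which.max(net)  # first max = canonical tie-break
  r <- isotype_profile(replace(numeric(8L), i, 1), label = "otip_sum")
  new_otip_result(r, damage = unclass(qc)[[i]], status = "optimal",
                  active = character(), model = "sum",
                  objective = net[[i]])
}

#' KL-damage profile optimization under per-tissue caps
#'
#' Maximizes the Kullback-Leibler damage `D_KL(r, q(c))` (a concave
#' objective, see [kl_damage()]) subject to the same linear dot-product
#' caps on healthy tissues as [otip_optimize()].  Unconstrained, the
#' optimum is exactly the tumor profile itself, `r* = q(c)` with objective
#' 0 -- the "disrupt all isotypes proportionally" philosophy.  The
#' constrained problem is convex and solved through its smooth dual:
#' the optimum has the closed form `r_i ~ q_i * exp(-(A' lambda)_i)` with
#' multipliers `lambda >= 0` found by L-BFGS-B on the dual function.
#'
#' @inheritParams otip_optimize
#' @return An `otip_result` with `objective_model = "kl"`; `damage` and
#'   `objective` are the (non-positive) KL damage of `r*` on `cancer_q`.
#' @export
otip_kl_optimize <- function(cancer_q, constraints = NULL) {
  qc <- as_profile(cancer_q, "cancer_q")
  q <- unclass(qc)
  if (is.null(constraints) || length(constraints) == 0L) {
    r <- isotype_profile(q, label = "otip_kl")
    return(new_otip_result(r, damage = 0, status = "optimal",
                           active = character(), model = "kl",
                           objective = 0))
  }
  stopifnot(inherits(constraints, "otip_constraints"))
  A <- constraint_matrix(constraints)
  w <- constraints$caps
  # caps of exactly 0 force r_i = 0 wherever the tissue expresses isotype i
  forced0 <- rep(FALSE, 8L)
  for (h in which(w == 0)) forced0 <- forced0 | (A[h, ] > 0)
  S <- which(q > 0 & !forced0)
  infeas <- function(msg) new_otip_result(
    NULL, damage = NA_real_, status = "infeasible", active = character(),
    model = "kl", message = msg)
  if (length(S) == 0L)
    return(infeas("every isotype expressed by the tumor is capped to zero"))
  keep <- which(w > 0)
  # LP feasibility check on the admissible support
  feas <- boot::simplex(a = rep(0, length(S)),
                        A1 = A[keep, S, drop = FALSE], b1 = w[keep],
                        A3 = matrix(1, 1L, length(S)), b3 = 1,
                        maxi = TRUE, eps = 1e-10, n.iter = 200L)
  if (feas$solved == -1L)
    return(infeas("tissue caps admit no profile supported on the tumor's isotypes"))
  if (length(keep) == 0L) {
    lam <- numeric(0)
  } else {
    As <- A[keep, S, drop = FALSE]
    ws <- w[keep]
    logq <- log(q[S])
    dual <- function(lam) {
      z <- logq - drop(lam %*% As)
      m <- max(z)
      m + log(sum(exp(z - m))) + sum(lam * ws)
    }
    dual_grad <- function(lam) {
      z <- logq - drop(lam %*% As)
      z <- exp(z - max(z))
      r <- z / sum(z)
      ws - drop(As %*% r)
    }
    opt <- stats::optim(rep(0, length(keep)), fn = dual, gr = dual_grad,
                        method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 1000L, factr = 10))
    lam <- opt$par
  }
  z <- log(q[S]) - (if (length(lam)) drop(lam %*% A[keep, S, drop = FALSE])
                    else 0)
  z <- exp(z - max(z))
  rS <- z / sum(z)
  r_full <- replace(numeric(8L), S, rS)
  viol <- drop(A %*% r_full) - w
  if (any(viol > 1e-7))
    stop("KL dual solver did not reach a feasible primal point ",
         "(max violation ", format(max(viol)), ")", call. = FALSE)
  r <- isotype_profile(r_full, label = "otip_kl")
  obj <- kl_damage(r, qc)
  new_otip_result(r, damage = obj, status = "optimal",
                  active = active_constraint_ids(constraints, r,
                                                 tol = 1e-6),
                  model = "kl", objective = obj)
}

#' Screen a drug profile against a treatment context
#'
#' Checks a concrete drug's affinity profile against every healthy-tissue
#' cap (a drug violating any cap is eliminated), and scores its damage on
#' the cancer, optionally relative to the computed optimum.
#'
#' @param drug_r Drug affinity profile.
#' @param cancer_q Cancer isotype profile.
#' @param constraints An [otip_constraints()] object (or `NULL`).
#' @param reference Optional `otip_result` from [otip_optimize()]; when
#'   supplied, `fraction_of_optimum` is the ratio of the drug's cancer
#'   damage to the optimum's, clamped to `[0, 1]` (0 when the optimum's
#'   damage is 0).
#' @return An object of class `drug_evaluation`: list with `drug`,
#'   `feasible`, `violations` (data frame tissue/damage/cap),
#'   `tissue_damage` (named numeric), `cancer_damage` and
#'   `fraction_of_optimum`.
#' @export
evaluate_drug <- function(drug_r, cancer_q, constraints = NULL,
                          reference = NULL) {
  r <- as_profile(drug_r, "drug_r")
  qc <- as_profile(cancer_q, "cancer_q")
  if (!is.null(constraints) && length(constraints) > 0L) {
    stopifnot(inherits(constraints, "otip_constraints"))
    A <- constraint_matrix(constraints)
    dmg <- drop(A %*% unclass(r))
    names(dmg) <- constraints$tissues
    bad <- which(dmg > constraints$caps + 1e-9)
    violations <- data.frame(tissue = constraints$tissues[bad],
                             damage = unname(dmg[bad]),
                             cap = constraints$caps[bad],
                             stringsAsFactors = FALSE)
  } else {
    dmg <- stats::setNames(numeric(0), character(0))
    violations <- data.frame(tissue = character(), damage = numeric(),
                             cap = numeric(), stringsAsFactors = FALSE)
  }
  cd <- dot_damage(r, qc)
  frac <- NA_real_
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "otip_result"))
    if (reference$status != "optimal" || reference$damage <= 0) frac <- 0
    else frac <- min(max(cd / reference$damage, 0), 1)
  }
  structure(list(drug = attr(r, "label"),
                 feasible = nrow(violations) == 0L,
                 violations = violations,
                 tissue_damage = dmg,
                 cancer_damage = cd,
                 fraction_of_optimum = frac),
            class = "drug_evaluation")
}

#' @export
print.drug_evaluation <- function(x, ...) {
  cat("<drug_evaluation> ", sQuote(x$drug),
      if (x$feasible) ": feasible" else ": INFEASIBLE",
      ", cancer damage ", format(round(x$cancer_damage, 6)), sep = "")
  if (!is.na(x$fraction_of_optimum))
    cat(" (", round(100 * x$fraction_of_optimum), "% of optimum)", sep = "")
  cat("\n")
  if (nrow(x$violations)) {
    cat("  cap violations:\n")
    print(x$violations)
  }
  invisible(x)
}

#' Serialize an optimization result to JSON
#'
#' Stable key order: `status`, `model`, `optimal_profile`, `damage`,
#' `objective`, `active_constraints`, `context`.
#'
#' @param res An `otip_result`.
#' @param ctx Optional [cancer_context()] recorded alongside the result.
#' @param path Optional output file; when given, JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
result_to_json <- function(res, ctx = NULL, path = NULL) {
  stopifnot(inherits(res, "otip_result"))
  obj <- list(
    status = res$status,
    model = res$objective_model,
    optimal_profile = if (is.null(res$optimal_profile)) NULL else
      list(label = attr(res$optimal_profile, "label"),
           values = as.list(unclass(res$optimal_profile))),
    damage = res$damage,
    objective = res$objective,
    active_constraints = as.list(res$active_constraints),
    context = if (is.null(ctx)) NULL else
      list(cancer = ctx$cancer, route = ctx$route, gender = ctx$gender,
           aggressiveness = ctx$aggressiveness,
           extra_protection = as.list(ctx$extra_protection),
           target_organ = ctx$target_organ)
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Validate the structure of a result JSON document
#'
#' Structural schema check used by the command-line tools: required keys,
#' value types, status enumeration, and (for optimal results) that the
#' profile values form a probability 8-tuple.
#'
#' @param txt JSON string or path to a JSON file.
#' @return `TRUE`, or an error describing the first violation.
#' @export
validate_result_json <- function(txt) {
  if (length(txt) == 1L && file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  need <- c("status", "model", "damage", "active_constraints")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("result JSON missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!obj$status %in% c("optimal", "infeasible"))
    stop("invalid status: ", obj$status, call. = FALSE)
  if (!obj$model %in% c("dot", "kl", "sum"))
    stop("invalid model: ", obj$model, call. = FALSE)
  if (obj$status == "optimal") {
    v <- unlist(obj$optimal_profile$values)
    if (length(v) != 8L || any(v < -1e-12) || abs(sum(v) - 1) > 1e-9)
      stop("optimal_profile is not a probability 8-tuple", call. = FALSE)
  }
  TRUE
}
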