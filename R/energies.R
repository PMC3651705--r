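#' Per-isotype binding free energies of a drug
#'
#' @param energies Numeric vector of 8 binding free energies, one per
#'   canonical isotype (named vectors are re-ordered like in
#'   [isotype_profile()]).  More negative means stronger binding.  `+Inf`
#'   is accepted and means "no binding at all" (Boltzmann weight 0); `NA`,
#'   `NaN` and `-Inf` are rejected.
#' @param drug_label Drug name.
#' @param unit Energy unit: `"kJ/mol"`, `"kcal/mol"`, `"kT"` (already in
#'   thermal units), or `"unspecified"` for literature tables whose unit is
#'   not stated (such tables can still be used for ranking, but converting
#'   them to an affinity profile requires an explicit unit).
#' @return An object of class `binding_energy`.
#' @export
binding_energy <- function(energies, drug_label = "",
                           unit = c("unspecified", "kJ/mol", "kcal/mol",
                                    "kT")) {
  unit <- match.arg(unit)
  if (!is.numeric(energies) || length(energies) != 8L)
    stop("need exactly 8 energies", call. = FALSE)
  v <- as.numeric(energies)
  if (!is.null(names(energies))) {
    canon <- match_isotype(names(energies))
    if (anyDuplicated(canon)) stop("duplicated isotype names", call. = FALSE)
    v <- v[match(OTIP_ISOTYPES, canon)]
  }
  names(v) <- OTIP_ISOTYPES
  if (any(is.na(v)) || any(v == -Inf))
    stop("binding energies must be finite or +Inf (no binding)",
         call. = FALSE)
  structure(v, drug_label = as.character(drug_label)[1L], unit = unit,
            class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  cat("<binding_energy> ", sQuote(attr(x, "drug_label")),
      " [", attr(x, "unit"), "]\n", sep = "")
  print(unclass(x)[seq_len(8L)])
  invisible(x)
}

#' Thermodynamic context for energy-to-affinity conversion
#'
#' Holds the temperature and the energy unit used to form the inverse
#' thermal energy `beta = 1 / (R * T)`.  The gas constant is fixed at
#' `R = 8.31 J/(mol K)`.
#'
#' @param temperature Temperature in Kelvin (default 310 K, body
#'   temperature).
#' @param unit Energy unit of the energies this context will be applied to;
#'   `"kT"` means the energies are already expressed in units of `R*T`
#'   (so `beta = 1`).
#' @return An object of class `thermo_context` with fields `temperature`,
#'   `unit`, `gas_constant` (J/(mol K)) and `beta` (per energy unit).
#' @export
thermo_context <- function(temperature = 310,
                           unit = c("kJ/mol", "kcal/mol", "kT")) {
  unit <- match.arg(unit)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive scalar in Kelvin", call. = FALSE)
  R <- 8.31  # J/(mol K)
  rt_joule <- R * temperature
  beta <- switch(unit,
    "kJ/mol"   = 1000 / rt_joule,
    "kcal/mol" = 4184 / rt_joule,
    "kT"       = 1
  )
  structure(list(temperature = temperature, unit = unit,
                 gas_constant = R, beta = beta),
            class = "thermo_context")
}

#' Linear binding-energy score of a drug on a cell type
#'
#' The expected binding free energy of drug `d` in cell `c`,
#' `DeltaG(d, c) = sum_i q_i(c) * DeltaG_i(d)`, which is proportional to
#' `-(1/RT) * log IC50(c, d)`: lower (more negative) values predict a more
#' cytotoxic drug for that cell line.  Only the linear score and its
#' ordering are exposed; the proportionality constant to absolute IC50 is
#' not calibrated.
#'
#' @param q Cell isotype profile.
#' @param dg A [binding_energy()] vector.
#' @return Numeric scalar in the unit of `dg`.
#' @export
predicted_binding_energy <- function(q, dg) {
  q <- unclass(as_profile(q, "q"))
  stopifnot(inherits(dg, "binding_energy"))
  e <- unclass(dg)
  # +Inf energy on an unexpressed isotype contributes 0, not NaN
  contrib <- ifelse(q == 0, 0, q * e)
  sum(contrib)
}

#' Boltzmann affinity profile from binding free energies
#'
#' Converts per-isotype binding free energies into a binding-probability
#' profile via an Arrhenius/Boltzmann form,
#' `r_i = exp(-beta * dG_i) / sum_j exp(-beta * dG_j)`.  Computed with
#' max-shift (softmax) for numerical stability; the result is invariant
#' under adding a constant to all energies, so tables reported relative to
#' an arbitrary reference state are fine.  An energy of `+Inf` yields
#' exactly zero affinity for that isotype.
#'
#' @param dg A [binding_energy()] vector; its unit must be declared (either
#'   on the vector itself or via `ctx`), not `"unspecified"`.
#' @param ctx A [thermo_context()].  Its unit overrides an
#'   `"unspecified"` unit on `dg`; a contradiction between two declared
#'   units is an error.
#' @return An [isotype_profile()] labelled after the drug.
#' @export
binding_profile_from_energies <- function(dg, ctx = thermo_context()) {
  stopifnot(inherits(dg, "binding_energy"), inherits(ctx, "thermo_context"))
  du <- attr(dg, "unit")
  if (du != "unspecified" && du != ctx$unit)
    stop("energy unit mismatch: table says ", sQuote(du),
         ", context says ", sQuote(ctx$unit), call. = FALSE)
  e <- unclass(dg)
  x <- -ctx$beta * e             # +Inf energy -> -Inf log-weight -> 0
  m <- max(x[is.finite(x)])
  if (!is.finite(m))
    stop("no isotype with finite binding energy", call. = FALSE)
  w <- exp(x - m)
  isotype_profile(w / sum(w), label = attr(dg, "drug_label"),
                  normalize = FALSE)
}

#' Specify a drug combination
#'
#' @param profiles List of drug affinity profiles.
#' @param coefficients Convex mixing coefficients: non-negative, summing to
#'   1 within `1e-9`.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(profiles, coefficients) {
  if (!is.list(profiles) || length(profiles) == 0L)
    stop("need at least one component profile", call. = FALSE)
  profiles <- lapply(profiles, as_profile)
  a <- as.numeric(coefficients)
  if (length(a) != length(profiles))
    stop("one coefficient per profile required", call. = FALSE)
  if (any(!is.finite(a)) || any(a < 0) || abs(sum(a) - 1) > 1e-9)
    stop("coefficients must be non-negative and sum to 1", call. = FALSE)
  structure(list(profiles = profiles, coefficients = a),
            class = "mixture_spec")
}

#' Cumulative profile of a drug combination
#'
#' The affinity profile of a cocktail of non-interacting drugs taken in
#' proportions `alpha_k` is the convex combination
#' `sum_k alpha_k * r(d_k)`.  Dot-product damage is linear, so the
#' combination's damage on any cell equals the same convex combination of
#' the component damages.
#'
#' @param mix A [mixture_spec()], or a list of profiles if `coefficients`
#'   is also given.
#' @param coefficients Optional, see [mixture_spec()].
#' @param label Label for the combined profile.
#' @return An [isotype_profile()].
#' @examples
#' pure <- function(i) isotype_profile(replace(numeric(8), i, 1))
#' combine_profiles(list(pure(1), pure(2), pure(3)), c(0.5, 0.25, 0.25))
#' @export
combine_profiles <- function(mix, coefficients = NULL, label = "combination") {
  if (!inherits(mix, "mixture_spec"))
    mix <- mixture_spec(mix, coefficients)
  m <- vapply(mix$profiles, unclass, numeric(8L))
  isotype_profile(drop(m %*% mix$coefficients), label = label)
}

#' Read a per-isotype binding free-energy table
#'
#' Expected layout: a header row, first column `drug`, then 8 isotype
#' columns (any accepted spelling), and optionally a `unit` column.
#'
#' @param path File path.
#' @param delimiter Field separator.
#' @param unit Default unit for rows without a `unit` column.
#' @return A list of [binding_energy()] vectors, named by drug.
#' @export
read_energy_table <- function(path, delimiter = "\t",
                              unit = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "",
                          fileEncoding = "UTF-8")
  cols <- colnames(df)
  if (tolower(cols[1L]) != "drug")
    stop("first column of an energy table must be 'drug'", call. = FALSE)
  unit_col <- which(tolower(cols) == "unit")
  iso_cols <- setdiff(seq_along(cols)[-1L], unit_col)
  canon <- match_isotype(cols[iso_cols])
  if (length(canon) != 8L || anyDuplicated(canon))
    stop("energy table must have exactly the 8 isotype columns",
         call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    e <- as.numeric(df[i, iso_cols])
    names(e) <- canon
    u <- if (length(unit_col)) as.character(df[i, unit_col]) else unit
    out[[df[i, 1L]]] <- binding_energy(e, drug_label = df[i, 1L], unit = u)
  }
  out
}
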