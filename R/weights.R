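OTIP_ROUTES <- c("iv", "local", "oral", "inhalant")
OTIP_GENDERS <- c("male", "female")
OTIP_AGGRESSIVENESS <- c("conservative", "normal", "aggressive")
OTIP_GENDER_SPEC <- c("both", "male_only", "female_only")

#' Describe a cancer treatment context
#'
#' Bundles the cancer label, route of administration and patient
#' characteristics that together determine the per-tissue damage caps.
#'
#' @param cancer Cancer label (must match a profile label in the cancer
#'   expression table when used end-to-end).
#' @param route One of `"iv"`, `"local"`, `"oral"`, `"inhalant"`.
#'   Inhalant delivery is treated as a local route with the lung as an
#'   additional target organ.
#' @param gender `"male"` or `"female"`; gender-specific organs of the
#'   other gender are dropped from the constraint set.
#' @param aggressiveness `"conservative"` (caps tightened to 75% of
#'   normal), `"normal"`, or `"aggressive"` (caps set to 150% of normal).
#' @param extra_protection Character vector of tissue ids the clinician
#'   wants protected beyond the baseline.
#' @param target_organ Tissue id of the tumor site; required for local and
#'   inhalant routes, where it is heavily protected.
#' @return An object of class `cancer_context`.
#' @export
cancer_context <- function(cancer, route = "iv", gender = "male",
                           aggressiveness = "normal",
                           extra_protection = character(),
                           target_organ = NULL) {
  route <- match.arg(route, OTIP_ROUTES)
  gender <- match.arg(gender, OTIP_GENDERS)
  aggressiveness <- match.arg(aggressiveness, OTIP_AGGRESSIVENESS)
  if (route %in% c("local", "inhalant") && is.null(target_organ))
    stop("target_organ is required for route ", sQuote(route), call. = FALSE)
  structure(list(cancer = as.character(cancer)[1L], route = route,
                 gender = gender, aggressiveness = aggressiveness,
                 extra_protection = as.character(extra_protection),
                 target_organ = target_organ),
            class = "cancer_context")
}

#' Construct a tissue-weight configuration
#'
#' Encodes baseline per-tissue, per-route damage caps plus the
#' multiplicative modifiers applied for route, aggressiveness and
#' patient-specific protection.  Baselines are stored for the routes iv,
#' local and oral; the inhalant route reuses the local baselines.
#'
#' @param baseline Named list: `tissue -> list(iv =, local =, oral =)` of
#'   caps in `[0, 1]`.
#' @param gender Named character vector/list mapping tissues to
#'   `"male_only"`, `"female_only"` or `"both"` (tissues not listed default
#'   to `"both"`).
#' @param modifiers Named list of multiplicative factors; defaults:
#'   `conservative_factor = 0.75`, `aggressive_factor = 1.5`,
#'   `local_relaxation_factor = 1.2` (non-target organs under local
#'   delivery tolerate 20% more damage), `target_protection_factor = 0.25`
#'   (the tumor site is heavily protected under local delivery),
#'   `extra_protection_factor = 0.5` (clinician-flagged organs).
#' @return An object of class `weight_config`.
#' @seealso [default_weight_config()], [weight_for()]
#' @export
weight_config <- function(baseline, gender = list(), modifiers = list()) {
  def_mod <- list(conservative_factor = 0.75, aggressive_factor = 1.5,
                  local_relaxation_factor = 1.2,
                  target_protection_factor = 0.25,
                  extra_protection_factor = 0.5)
  modifiers <- utils::modifyList(def_mod, as.list(modifiers))
  bad <- setdiff(names(modifiers), names(def_mod))
  if (length(bad))
    stop("unknown modifier(s): ", paste(bad, collapse = ", "), call. = FALSE)
  mf <- unlist(modifiers)
  if (any(!is.finite(mf)) || any(mf < 0))
    stop("modifier factors must be non-negative", call. = FALSE)
  if (!is.list(baseline) || length(baseline) == 0L || is.null(names(baseline)))
    stop("baseline must be a named list of tissues", call. = FALSE)
  baseline <- lapply(baseline, function(b) {
    b <- as.list(b)
    miss <- setdiff(c("iv", "local", "oral"), names(b))
    if (length(miss))
      stop("baseline entries need iv/local/oral caps (missing: ",
           paste(miss, collapse = ", "), ")", call. = FALSE)
    b <- b[c("iv", "local", "oral")]
    v <- unlist(b)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("baseline caps must lie in [0, 1]", call. = FALSE)
    b
  })
  gender <- as.list(gender)
  if (length(gender)) {
    if (!all(unlist(gender) %in% OTIP_GENDER_SPEC))
      stop("gender specificity must be one of ",
           paste(OTIP_GENDER_SPEC, collapse = "/"), call. = FALSE)
    if (!all(names(gender) %in% names(baseline)))
      stop("gender entries for tissues absent from baseline", call. = FALSE)
  }
  structure(list(baseline = baseline, gender = gender,
                 modifiers = modifiers),
            class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat("<weight_config> ", length(x$baseline), " tissue(s); modifiers: ",
      paste(names(x$modifiers), unlist(x$modifiers), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tissues known to a weight configuration
#' @param cfg A [weight_config()].
#' @return Character vector of tissue ids.
#' @export
config_tissues <- function(cfg) names(cfg$baseline)

# The numeric values here are ILLUSTRATIVE defaults, not measured data.
# They encode the qualitative ordering: liver and kidney (metabolism and
# excretion expose them most) get the smallest caps; brain and heart are
# vital organs with small caps; colon and small intestine are further
# protected under oral delivery; everything else gets a permissive cap.
otip_default_panel <- function() {
  tiers <- c(
    tonsil = 0.40, esophagus = 0.40, stomach = 0.40, skin = 0.40,
    muscle = 0.40, spleen = 0.40, thymus = 0.40, lymph_node = 0.40,
    testis = 0.40, prostate = 0.40, breast = 0.40, ovary = 0.40,
    placenta = 0.40, lung = 0.40,
    brain = 0.20, heart = 0.20,
    colon = 0.40, small_intestine = 0.40,
    liver = 0.10, kidney = 0.10
  )
  oral <- tiers
  oral[c("colon", "small_intestine")] <- 0.10
  stats::setNames(lapply(names(tiers), function(t)
    list(iv = unname(tiers[t]), local = unname(tiers[t]),
         oral = unname(oral[t]))), names(tiers))
}

#' Illustrative default weight configuration
#'
#' Ships a four-tier panel of baseline caps over a standard healthy-tissue
#' panel: liver/kidney 0.10, brain/heart 0.20, colon/small intestine 0.10
#' under oral delivery (0.40 otherwise), all other tissues 0.40.  These
#' numbers are illustrative placeholders encoding only the intended
#' ordering of organ protection; every value can be overridden via a user
#' config file ([read_weight_config()]).
#'
#' @return A [weight_config()].
#' @export
default_weight_config <- function() {
  weight_config(
    baseline = otip_default_panel(),
    gender = list(testis = "male_only", prostate = "male_only",
                  breast = "female_only", ovary = "female_only",
                  placenta = "female_only")
  )
}

#' Read a weight configuration from YAML or JSON
#'
#' Schema: top-level keys `baseline` (tissue -> route -> cap; a bare
#' number is expanded to all three stored routes), optional `gender`
#' (tissue -> male_only/female_only/both) and optional `modifiers`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [weight_config()].
#' @export
read_weight_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
  if (is.null(obj$baseline))
    stop("weight config must contain a 'baseline' section", call. = FALSE)
  baseline <- lapply(obj$baseline, function(b) {
    if (is.numeric(b) && length(b) == 1L)
      list(iv = b, local = b, oral = b)
    else b
  })
  weight_config(baseline = baseline,
                gender = obj$gender %||% list(),
                modifiers = obj$modifiers %||% list())
}

#' Write a weight configuration to YAML
#' @param cfg A [weight_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "weight_config"))
  yaml::write_yaml(list(baseline = cfg$baseline, gender = cfg$gender,
                        modifiers = cfg$modifiers), path)
  invisible(path)
}

#' Damage cap for one healthy tissue in a treatment context
#'
#' Computes `w_h = w(t_h; c, a, p)` through a fixed pipeline:
#' \enumerate{
#'   \item gender mask: a tissue whose gender specificity conflicts with
#'     the patient's gender is ABSENT (returns `NA`, no constraint);
#'   \item start from the baseline cap for the tissue and route (inhalant
#'     uses the local baseline);
#'   \item local/inhalant routes: the target organ(s) (the tumor site,
#'     plus the lung for inhalant) are multiplied by
#'     `target_protection_factor`; all other tissues by
#'     `local_relaxation_factor` (damage allowance elevated by 20%);
#'   \item aggressiveness: conservative caps are tightened to 75%,
#'     aggressive caps raised to 150% of normal;
#'   \item tissues in the patient's `extra_protection` set are multiplied
#'     by `extra_protection_factor`;
#'   \item the result is clamped to `[0, 1]` (a cap above 1 is vacuous
#'     since dot damage never exceeds `max(q) <= 1`).
#' }
#' Steps 3-5 are a pure product, so their order is immaterial.
#'
#' @param tissue Tissue id (must be present in `cfg`).
#' @param ctx A [cancer_context()].
#' @param cfg A [weight_config()].
#' @return Cap in `[0, 1]`, or `NA` if the tissue is absent for this
#'   patient.
#' @export
weight_for <- function(tissue, ctx, cfg) {
  stopifnot(inherits(ctx, "cancer_context"), inherits(cfg, "weight_config"))
  if (!tissue %in% names(cfg$baseline))
    stop("unknown tissue: ", sQuote(tissue), call. = FALSE)
  gs <- cfg$gender[[tissue]] %||% "both"
  if ((gs == "male_only" && ctx$gender != "male") ||
      (gs == "female_only" && ctx$gender != "female"))
    return(NA_real_)
  route_key <- if (ctx$route == "inhalant") "local" else ctx$route
  w <- cfg$baseline[[tissue]][[route_key]]
  mod <- cfg$modifiers
  if (ctx$route %in% c("local", "inhalant")) {
    targets <- ctx$target_organ
    if (ctx$route == "inhalant") targets <- unique(c(targets, "lung"))
    w <- w * if (tissue %in% targets) mod$target_protection_factor
             else mod$local_relaxation_factor
  }
  w <- w * switch(ctx$aggressiveness,
                  conservative = mod$conservative_factor,
                  normal = 1,
                  aggressive = mod$aggressive_factor)
  if (tissue %in% ctx$extra_protection)
    w <- w * mod$extra_protection_factor
  min(max(w, 0), 1)
}

#' Build the healthy-tissue constraint set for an optimization
#'
#' Pairs every healthy-tissue profile with its context-specific damage
#' cap.  Tissues masked by gender are skipped (with a message).
#'
#' @param healthy An [expression_table()] of healthy-tissue profiles whose
#'   labels are tissue ids known to `cfg`.
#' @param ctx A [cancer_context()].
#' @param cfg A [weight_config()].
#' @return An object of class `otip_constraints`: list with `tissues`
#'   (character), `profiles` (list of [isotype_profile()]) and `caps`
#'   (numeric), in input-table order.
#' @export
build_constraint_set <- function(healthy, ctx, cfg = default_weight_config()) {
  stopifnot(inherits(healthy, "expression_table"))
  if (length(healthy$profiles) == 0L)
    stop("healthy table is empty", call. = FALSE)
  tissues <- names(healthy$profiles)
  caps <- vapply(tissues, weight_for, numeric(1L), ctx = ctx, cfg = cfg)
  skipped <- tissues[is.na(caps)]
  if (length(skipped))
    message("skipping gender-masked tissue(s): ",
            paste(skipped, collapse = ", "))
  keep <- !is.na(caps)
  otip_constraints(profiles = healthy$profiles[keep],
                   caps = unname(caps[keep]),
                   tissues = tissues[keep])
}

#' Constraint container for the profile optimizer
#'
#' @param profiles List of healthy-tissue isotype profiles.
#' @param caps Numeric vector of damage caps, one per profile, each
#'   `>= 0`.
#' @param tissues Optional tissue ids (default: profile labels).
#' @return An object of class `otip_constraints`.
#' @export
otip_constraints <- function(profiles, caps, tissues = NULL) {
  profiles <- lapply(profiles, as_profile)
  caps <- as.numeric(caps)
  if (length(caps) != length(profiles))
    stop("one cap per profile required", call. = FALSE)
  if (any(!is.finite(caps)) || any(caps < 0))
    stop("caps must be finite and >= 0", call. = FALSE)
  if (is.null(tissues)) {
    tissues <- names(profiles) %||%
      vapply(profiles, attr, "", "label")
  }
  if (length(tissues) != length(profiles))
    stop("one tissue id per profile required", call. = FALSE)
  structure(list(tissues = as.character(tissues), profiles = profiles,
                 caps = caps),
            class = "otip_constraints")
}

#' @export
print.otip_constraints <- function(x, ...) {
  cat("<otip_constraints> ", length(x$caps), " tissue constraint(s)\n",
      sep = "")
  if (length(x$caps))
    print(data.frame(tissue = x$tissues, cap = x$caps))
  invisible(x)
}

#' @export
length.otip_constraints <- function(x) length(x$caps)

constraint_matrix <- function(constraints) {
  if (is.null(constraints) || length(constraints) == 0L)
    return(matrix(numeric(0), 0L, 8L,
                  dimnames = list(NULL, OTIP_ISOTYPES)))
  t(vapply(constraints$profiles, unclass, numeric(8L)))
}
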