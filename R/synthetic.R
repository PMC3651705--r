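#' Specification for the synthetic profile generator
#'
#' Profiles are probability tuples, so they are drawn from a Dirichlet
#' distribution (via normalized gamma variates), optionally sparsified by
#' zeroing isotypes at random and renormalizing -- mimicking assays in
#' which some isotypes fall below detection.  A fixed seed fixes every
#' output exactly.
#'
#' @param seed Integer RNG seed.
#' @param n_cancer,n_healthy Number of cancer / healthy profiles to draw.
#' @param concentration Dirichlet concentration 8-vector (positive);
#'   the default `rep(2, 8)` gives moderately heterogeneous profiles.
#' @param sparsity Expected fraction of zeroed isotypes per profile, in
#'   `[0, 0.75]`.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_cancer = 3L, n_healthy = 12L,
                           concentration = rep(2, 8L), sparsity = 0) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("seed must be a single integer", call. = FALSE)
  if (length(concentration) != 8L || any(!is.finite(concentration)) ||
      any(concentration <= 0))
    stop("concentration must be 8 positive values", call. = FALSE)
  if (sparsity < 0 || sparsity > 0.75)
    stop("sparsity must lie in [0, 0.75]", call. = FALSE)
  structure(list(seed = as.integer(seed), n_cancer = as.integer(n_cancer),
                 n_healthy = as.integer(n_healthy),
                 concentration = as.numeric(concentration),
                 sparsity = sparsity),
            class = "generator_spec")
}

rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  g / sum(g)
}

#' Sample a synthetic expression table
#'
#' @param spec A [generator_spec()].
#' @param kind `"cancer"` or `"healthy"`; selects the corresponding count
#'   from `spec` and a kind-specific seed stream, so cancer and healthy
#'   tables drawn from one spec are independent but each reproducible.
#' @return An [expression_table()] with labels `cancer_01`, ... or
#'   `healthy_01`, ...
#' @export
sample_profiles <- function(spec, kind = c("healthy", "cancer")) {
  stopifnot(inherits(spec, "generator_spec"))
  kind <- match.arg(kind)
  n <- if (kind == "cancer") spec$n_cancer else spec$n_healthy
  if (n < 1L) stop("nothing to sample: n < 1", call. = FALSE)
  offset <- if (kind == "cancer") 0L else 500000L
  seed <- (spec$seed + offset) %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  profs <- list()
  for (i in seq_len(n)) {
    v <- NULL
    for (attempt in seq_len(100L)) {
      x <- rdirichlet1(spec$concentration)
      if (spec$sparsity > 0)
        x[stats::runif(8L) < spec$sparsity] <- 0
      if (sum(x) > 0) { v <- x; break }
      message("all-zero draw, regenerating (attempt ", attempt, ")")
    }
    if (is.null(v))
      stop("failed to draw a non-degenerate profile in 100 attempts",
           call. = FALSE)
    lab <- sprintf("%s_%02d", kind, i)
    profs[[lab]] <- normalize_profile(v, label = lab)
  }
  expression_table(profs, source_kind = kind)
}

#' Illustrative demonstration panel
#'
#' A fixed, synthetic toy panel (NOT measured data) shaped like a typical
#' use case: one cancer table, a healthy-tissue panel covering both
#' genders and all routes of the default weight configuration, plus ready
#' treatment contexts.  The `cap_zero` context pairs with
#' `config_infeasible`, in which the liver -- which in this panel
#' expresses every isotype -- has its caps set to 0, making the
#' optimization provably infeasible.
#'
#' @return A list with elements `cancer` and `healthy`
#'   ([expression_table()]s), `config` and `config_infeasible`
#'   ([weight_config()]s), and `contexts` (named list of
#'   [cancer_context()]s: `iv_male`, `oral_female`, `local_male`,
#'   `inhalant_female`, `cap_zero`).
#' @export
demo_panel <- function() {
  p <- function(...) normalize_profile(c(...))
  cancer <- expression_table(list(
    demo_larynx  = p(10, 35, 5, 25, 0, 5, 20, 0),
    demo_renal   = p(45, 10, 5, 10, 0, 10, 20, 0),
    demo_lung    = p(15, 30, 5, 30, 5, 5, 10, 0)
  ), source_kind = "cancer")
  healthy <- expression_table(list(
    tonsil          = p(30, 10, 5, 5, 5, 25, 20, 0),
    skin            = p(25, 15, 10, 5, 5, 25, 15, 0),
    lymph_node      = p(35, 10, 5, 5, 0, 30, 15, 0),
    testis          = p(20, 10, 10, 10, 5, 25, 15, 5),
    prostate        = p(30, 15, 5, 5, 5, 25, 15, 0),
    breast          = p(25, 15, 10, 5, 5, 25, 15, 0),
    ovary           = p(25, 10, 10, 10, 5, 25, 15, 0),
    placenta        = p(30, 10, 5, 5, 5, 30, 15, 0),
    liver           = p(40, 10, 5, 5, 5, 20, 10, 5),
    kidney          = p(35, 10, 5, 5, 5, 25, 15, 0),
    heart           = p(25, 10, 5, 5, 15, 25, 15, 0),
    brain           = p(15, 20, 10, 20, 10, 15, 10, 0),
    colon           = p(30, 10, 5, 5, 5, 30, 15, 0),
    small_intestine = p(30, 10, 10, 5, 5, 25, 15, 0),
    lung            = p(25, 15, 5, 10, 5, 25, 15, 0)
  ), source_kind = "healthy")
  config <- default_weight_config()
  strict <- config
  strict$baseline$liver <- list(iv = 0, local = 0, oral = 0)
  contexts <- list(
    iv_male = cancer_context("demo_larynx", route = "iv", gender = "male"),
    oral_female = cancer_context("demo_renal", route = "oral",
                                 gender = "female"),
    local_male = cancer_context("demo_renal", route = "local",
                                gender = "male", target_organ = "kidney"),
    inhalant_female = cancer_context("demo_lung", route = "inhalant",
                                     gender = "female",
                                     target_organ = "lung"),
    cap_zero = cancer_context("demo_larynx", route = "iv", gender = "male")
  )
  list(cancer = cancer, healthy = healthy, config = config,
       config_infeasible = strict, contexts = contexts)
}

#' Published binding-energy fixture for peloruside A and laulimalide
#'
#' The two literature rows of per-isotype binding energy differences for
#' peloruside A (PELA) and laulimalide (LAU) that ship with the package
#' (see `inst/extdata/table3_binding_energies.tsv`).  The values are
#' relative energies with an unstated reference state and unit; the
#' Boltzmann conversion ([binding_profile_from_energies()]) is invariant
#' to the reference shift, but cross-drug comparison of absolute scores is
#' not, so the unit is recorded as `"unspecified"` and callers must
#' declare one explicitly to build affinity profiles.
#'
#' @return A named list of two [binding_energy()] vectors (`PELA`, `LAU`).
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_binding_energies.tsv",
                      package = "otip", mustWork = TRUE)
  read_energy_table(path, delimiter = "\t", unit = "unspecified")
}
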