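# shared fixtures and instance generators (all built in code)

# bare numeric vector of a profile (drops class, names and label)
pvec <- function(p) as.vector(unclass(p))

pure_profile <- function(i, label = paste0("pure_", i)) {
  isotype_profile(replace(numeric(8L), i, 1), label = label)
}

uniform_profile <- function(label = "uniform") {
  isotype_profile(rep(1 / 8, 8L), label = label)
}

rand_simplex <- function(k = 8L, dims = seq_len(k)) {
  v <- numeric(8L)
  v[dims] <- rgamma(length(dims), shape = 1, rate = 1)
  isotype_profile(v / sum(v))
}

# random constrained instance supported on `k` random isotypes; caps are
# drawn around the damage of a random feasible reference point so that
# instances are usually feasible but constraints often bind
rand_instance <- function(k = 3L, m = 2L) {
  dims <- sort(sample(8L, k))
  qc <- rand_simplex(dims = dims)
  r0 <- rand_simplex(dims = dims)
  profs <- replicate(m, rand_simplex(dims = dims), simplify = FALSE)
  names(profs) <- paste0("tissue_", seq_len(m))
  caps <- vapply(profs, function(qh) dot_damage(r0, qh), 0) *
    runif(m, 0.8, 1.4)
  list(qc = qc, constraints = otip_constraints(profs, caps = caps),
       dims = dims)
}

write_demo_tables <- function(dir = NULL, envir = parent.frame()) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = envir)
  d <- demo_panel()
  write_expression_table(d$cancer, file.path(dir, "cancer.tsv"))
  write_expression_table(d$healthy, file.path(dir, "healthy.tsv"))
  write_weight_config(d$config, file.path(dir, "weights.yaml"))
  write_weight_config(d$config_infeasible,
                      file.path(dir, "weights_capzero.yaml"))
  dir
}
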