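# single-tissue config with a 0.4 baseline, for the worked modifier examples
base04 <- weight_config(baseline = list(
  organ = list(iv = 0.4, local = 0.4, oral = 0.4),
  site = list(iv = 0.4, local = 0.4, oral = 0.4)
))

test_that("modifier pipeline reproduces the stated factors", {
  expect_equal(weight_for("organ", cancer_context(
    "c", route = "iv", aggressiveness = "conservative"), base04), 0.30)
  expect_equal(weight_for("organ", cancer_context(
    "c", route = "iv", aggressiveness = "aggressive"), base04), 0.60)
  expect_equal(weight_for("organ", cancer_context(
    "c", route = "local", target_organ = "site"), base04), 0.48)
  expect_equal(weight_for("site", cancer_context(
    "c", route = "local", target_organ = "site"), base04), 0.10)
  # inhalant = local with lung as an additional target organ
  cfg <- default_weight_config()
  ctx <- cancer_context("c", route = "inhalant", gender = "male",
                        target_organ = "tonsil")
  expect_equal(weight_for("lung", ctx, cfg), 0.4 * 0.25)
  expect_equal(weight_for("tonsil", ctx, cfg), 0.4 * 0.25)
  expect_equal(weight_for("skin", ctx, cfg), 0.4 * 1.2)
  # extra protection halves the cap
  ctx2 <- cancer_context("c", route = "iv", extra_protection = "organ")
  expect_equal(weight_for("organ", ctx2, base04), 0.20)
})

test_that("gender masking", {
  cfg <- default_weight_config()
  expect_true(is.na(weight_for("testis",
                               cancer_context("c", gender = "female"), cfg)))
  expect_true(is.na(weight_for("ovary",
                               cancer_context("c", gender = "male"), cfg)))
  expect_equal(weight_for("testis", cancer_context("c", gender = "male"),
                          cfg), 0.40)
  # non-gender-specific tissues are unaffected by gender
  for (t in c("liver", "brain", "colon"))
    expect_equal(weight_for(t, cancer_context("c", gender = "male"), cfg),
                 weight_for(t, cancer_context("c", gender = "female"), cfg))
})

test_that("caps are clamped to [0, 1] and never negative", {
  cfg <- weight_config(baseline = list(
    big = list(iv = 0.9, local = 0.9, oral = 0.9)))
  expect_equal(weight_for("big", cancer_context(
    "c", aggressiveness = "aggressive"), cfg), 1)  # 1.35 clamped
  set.seed(3)
  cfgd <- default_weight_config()
  for (t in config_tissues(cfgd))
    for (a in c("conservative", "normal", "aggressive")) {
      w <- weight_for(t, cancer_context("c", route = "oral", gender = "male",
                                        aggressiveness = a), cfgd)
      if (!is.na(w)) { expect_gte(w, 0); expect_lte(w, 1) }
    }
})

test_that("multiplicative steps commute (pipeline equals the pure product)", {
  cfg <- default_weight_config()
  mods <- cfg$modifiers
  routes <- c("iv", "local", "oral", "inhalant")
  for (t in c("liver", "brain", "colon", "lung", "tonsil"))
    for (rt in routes)
      for (a in c("conservative", "normal", "aggressive"))
        for (ep in list(character(), t)) {
          ctx <- cancer_context("c", route = rt, gender = "male",
                                aggressiveness = a, extra_protection = ep,
                                target_organ = if (rt %in%
                                  c("local", "inhalant")) "colon")
          got <- weight_for(t, ctx, cfg)
          # independent product reconstruction, factors in another order
          rk <- if (rt == "inhalant") "local" else rt
          f <- 1
          if (t %in% ep) f <- f * mods$extra_protection_factor
          f <- f * switch(a, conservative = mods$conservative_factor,
                          normal = 1, aggressive = mods$aggressive_factor)
          if (rt %in% c("local", "inhalant")) {
            tg <- c("colon", if (rt == "inhalant") "lung")
            f <- f * if (t %in% tg) mods$target_protection_factor
                     else mods$local_relaxation_factor
          }
          want <- min(max(cfg$baseline[[t]][[rk]] * f, 0), 1)
          expect_equal(got, want)
        }
})

test_that("aggressiveness ordering: conservative <= normal <= aggressive", {
  cfg <- default_weight_config()
  for (rt in c("iv", "oral", "local")) {
    ctxs <- lapply(c("conservative", "normal", "aggressive"), function(a)
      cancer_context("c", route = rt, gender = "female", aggressiveness = a,
                     target_organ = if (rt == "local") "liver"))
    for (t in config_tissues(cfg)) {
      w <- vapply(ctxs, function(ctx) weight_for(t, ctx, cfg), 0)
      if (!anyNA(w)) {
        expect_lte(w[1], w[2])
        expect_lte(w[2], w[3])
      }
    }
  }
})

test_that("build_constraint_set masks by gender and scales by modifiers", {
  d <- demo_panel()
  male <- build_constraint_set(d$healthy,
                               cancer_context("demo_larynx", gender = "male"),
                               d$config)
  expect_false(any(c("breast", "ovary", "placenta") %in% male$tissues))
  expect_true(all(c("testis", "prostate", "liver") %in% male$tissues))
  female <- suppressMessages(build_constraint_set(
    d$healthy, cancer_context("demo_larynx", gender = "female"), d$config))
  expect_false(any(c("testis", "prostate") %in% female$tissues))
  expect_true("ovary" %in% female$tissues)

  cons <- suppressMessages(build_constraint_set(
    d$healthy, cancer_context("demo_larynx", gender = "male",
                              aggressiveness = "conservative"), d$config))
  norm <- suppressMessages(build_constraint_set(
    d$healthy, cancer_context("demo_larynx", gender = "male"), d$config))
  expect_equal(cons$tissues, norm$tissues)
  expect_equal(cons$caps, 0.75 * norm$caps)

  # vacuous caps admit every drug
  allone <- weight_config(baseline = stats::setNames(lapply(
    norm$tissues, function(t) list(iv = 1, local = 1, oral = 1)),
    norm$tissues))
  vac <- build_constraint_set(
    expression_table(d$healthy$profiles[norm$tissues],
                     source_kind = "healthy"),
    cancer_context("demo_larynx", gender = "male"), allone)
  set.seed(21)
  for (i in 1:10)
    expect_true(evaluate_drug(rand_simplex(), d$cancer$profiles$demo_larynx,
                              vac)$feasible)
})

test_that("weight config I/O and validation", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "w.yaml")
  cfg <- default_weight_config()
  write_weight_config(cfg, f)
  back <- read_weight_config(f)
  expect_equal(back$baseline, cfg$baseline)
  expect_equal(back$modifiers, cfg$modifiers)
  # scalar baselines expand to all routes
  writeLines(c("baseline:", "  liver: 0.1"), f)
  expect_equal(read_weight_config(f)$baseline$liver,
               list(iv = 0.1, local = 0.1, oral = 0.1))
  # schema violations
  writeLines(c("baseline:", "  liver:", "    iv: 1.5", "    local: 0.1",
               "    oral: 0.1"), f)
  expect_error(read_weight_config(f), "\\[0, 1\\]")
  writeLines("modifiers: {conservative_factor: 0.75}", f)
  expect_error(read_weight_config(f), "baseline")
  expect_error(weight_config(baseline = list(
    x = list(iv = 0.1, local = 0.1, oral = 0.1)),
    gender = list(x = "sometimes")), "gender specificity")
  expect_error(cancer_context("c", route = "local"), "target_organ")
})
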