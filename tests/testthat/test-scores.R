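test_that("CPIS component banding follows the published bands with half-open edges", {
  # temperature: 2 at the extremes, 1 in [38.5, 39), 0 elsewhere incl. the
  # unprinted gap (36.0, 36.5)
  temp_cases <- list(
    list(36.0, 2L), list(35.0, 2L), list(39.0, 2L), list(39.2, 2L),
    list(38.5, 1L), list(38.9, 1L), list(38.7, 1L),
    list(36.5, 0L), list(37.0, 0L), list(38.4, 0L), list(36.2, 0L))
  for (cs in temp_cases)
    expect_identical(cpis_component_points("temperature", cs[[1]]), cs[[2]],
                     label = sprintf("temperature %.1f", cs[[1]]))

  expect_identical(cpis_component_points("leukocytes", 9000), 0L)
  expect_identical(cpis_component_points("leukocytes", 3000), 1L)
  expect_identical(cpis_component_points("leukocytes", 15000, bands = 600), 2L)
  expect_identical(cpis_component_points("leukocytes", 15000, bands = 499), 1L)
  expect_identical(cpis_component_points("leukocytes", 9000, bands = 900), 0L)
  expect_identical(cpis_component_points("leukocytes", 4000), 0L)  # band edge inclusive
  expect_identical(cpis_component_points("leukocytes", 11000), 0L)

  expect_identical(cpis_component_points("oxygenation", 200, ards = TRUE), 0L)
  expect_identical(cpis_component_points("oxygenation", 200, ards = FALSE), 2L)
  expect_identical(cpis_component_points("oxygenation", 241), 0L)
  expect_identical(cpis_component_points("oxygenation", 240), 2L)

  expect_identical(cpis_component_points("secretions", "absent_minimal"), 0L)
  expect_identical(cpis_component_points("secretions", "non_purulent"), 1L)
  expect_identical(cpis_component_points("secretions", "purulent"), 2L)
  expect_identical(cpis_component_points("radiography", "localized"), 2L)
  expect_identical(cpis_component_points("microbiology", "positive_with_gram_match"), 2L)

  expect_error(cpis_component_points("temperature", 50), "domain")
  expect_error(cpis_component_points("leukocytes", -1), "non-negative")
  expect_error(cpis_component_points("bogus", 1))
})

test_that("PCT banding is 0/1/2 at 0.5 and 1 ng/mL with NA propagation", {
  expect_identical(pct_points(0.4), 0L)
  expect_identical(pct_points(0.5), 1L)
  expect_identical(pct_points(0.99), 1L)
  expect_identical(pct_points(1.0), 2L)
  expect_identical(pct_points(0), 0L)
  expect_true(is.na(pct_points(NA)))
  expect_error(pct_points(-0.1), "non-negative")
})

test_that("LUS sub-score sums the four finding points", {
  worst <- lus_points(lus_exam("lobar", "gt20", "unilateral", "dynamic"))
  expect_identical(worst$subscore, 9L)
  expect_identical(sum(worst$breakdown), worst$subscore)
  expect_identical(lus_points(lus_exam())$subscore, 0L)
  expect_identical(
    lus_points(lus_exam("subpleural", "lt15", "bilateral", "static"))$subscore, 3L)
  expect_error(lus_exam("none", "gt20", "none", "none"), "none")
  expect_error(lus_exam("none", "none", "unilateral", "none"), "none")
})

test_that("compute_scores reproduces a hand-worked episode and the zero case", {
  p <- patient_record("x1", TRUE, temperature = 38.7, wbc = 15000,
                      pf_ratio = 180, secretions = "purulent",
                      radiography = "localized",
                      microbiology = "positive_with_gram_match", pct = 0.7,
                      lus = lus_exam("lobar", "gt20", "unilateral", "dynamic"))
  panel <- compute_scores(p)
  # 1 (temp) + 1 (wbc) + 2 (oxy) + 2 (secr) + 2 (micro) + 1 (pct) + 9 (lus)
  expect_identical(panel$cpis_plus, 18L)
  expect_identical(panel$cpis, 10L)       # with radiography 2
  expect_identical(panel$cpis_lus, 17L)
  expect_identical(panel$cpis_pct, 11L)
  expect_identical(panel$lus_score, 9L)

  normal <- patient_record("x2", FALSE, temperature = 37, wbc = 8000,
                           pf_ratio = 300, secretions = "absent_minimal",
                           radiography = "no_infiltrate",
                           microbiology = "negative")
  zp <- compute_scores(normal)
  expect_identical(zp$cpis, 0L)
  expect_true(is.na(zp$cpis_plus))  # no PCT, no LUS
})

test_that("missing inputs make exactly the dependent composites undefined", {
  no_lus <- patient_record("m1", TRUE, temperature = 39.5, wbc = 15000,
                           pf_ratio = 180, secretions = "purulent",
                           radiography = "localized", microbiology = "positive",
                           pct = 1.4)
  panel <- compute_scores(no_lus)
  expect_false(is.na(panel$cpis))
  expect_false(is.na(panel$cpis_pct))
  expect_true(is.na(panel$lus_score))
  expect_true(is.na(panel$cpis_lus))
  expect_true(is.na(panel$cpis_plus))

  no_cxr <- patient_record("m2", TRUE, temperature = 39.5, wbc = 15000,
                           pf_ratio = 180, secretions = "purulent",
                           microbiology = "positive", pct = 1.4,
                           lus = lus_exam("lobar", "gt20", "unilateral", "dynamic"))
  panel2 <- compute_scores(no_cxr)
  expect_true(is.na(panel2$cpis))        # radiography is a CPIS component
  expect_true(is.na(panel2$cpis_pct))
  expect_false(is.na(panel2$cpis_lus))   # radiography-free composites survive
  expect_false(is.na(panel2$cpis_plus))
})

test_that("classification handles the gt/ge rules and undefined scores", {
  panel <- list(cpis_plus = 12L, cpis = 6L)
  class(panel) <- "score_panel"
  expect_identical(classify(panel, threshold_rule("cpis_plus", 12, "ge")), "positive")
  expect_identical(classify(panel, threshold_rule("cpis", 6, "gt")), "negative")
  panel$cpis_plus <- NA_integer_
  expect_identical(classify(panel, threshold_rule("cpis_plus", 12, "ge")), "undetermined")
  expect_identical(classify(c(5, 7, NA), threshold_rule("cpis", 6, "gt")),
                   c("negative", "positive", "undetermined"))
  expect_error(threshold_rule("cpis", 13), "range")
})

test_that("attainable score ranges are exactly [0,12], [0,9], [0,19], [0,14], [0,21]", {
  # enumerate attainable per-component point sets through the banding code
  temp_pts <- unique(vapply(c(35, 37, 38.7, 39.5), function(t)
    cpis_component_points("temperature", t), integer(1)))
  leuk_pts <- unique(c(cpis_component_points("leukocytes", 9000),
                       cpis_component_points("leukocytes", 15000),
                       cpis_component_points("leukocytes", 15000, bands = 600)))
  oxy_pts <- unique(c(cpis_component_points("oxygenation", 300),
                      cpis_component_points("oxygenation", 200)))
  secr_pts <- vapply(c("absent_minimal", "non_purulent", "purulent"),
                     function(l) cpis_component_points("secretions", l), integer(1))
  rad_pts <- vapply(c("no_infiltrate", "patchy_diffuse", "localized"),
                    function(l) cpis_component_points("radiography", l), integer(1))
  mic_pts <- vapply(c("negative", "positive", "positive_with_gram_match"),
                    function(l) cpis_component_points("microbiology", l), integer(1))
  pct_pts <- unique(pct_points(c(0.1, 0.7, 2)))
  exam_grid <- expand.grid(ty = c("subpleural", "lobar"),
                           sz = c("none", "lt15", "s15to20", "gt20"),
                           lt = c("none", "bilateral", "unilateral"),
                           bg = c("none", "static", "dynamic"),
                           stringsAsFactors = FALSE)
  lus_pts <- unique(c(lus_points(lus_exam())$subscore,
                      mapply(function(ty, sz, lt, bg)
                               lus_points(lus_exam(ty, sz, lt, bg))$subscore,
                             exam_grid$ty, exam_grid$sz, exam_grid$lt, exam_grid$bg)))

  cpis_all <- outer(outer(outer(temp_pts, leuk_pts, "+"), c(outer(oxy_pts, secr_pts, "+")), "+"),
                    c(outer(rad_pts, mic_pts, "+")), "+")
  expect_setequal(sort(unique(c(cpis_all))), 0:12)
  expect_setequal(sort(lus_pts), 0:9)
  cpis5 <- c(outer(c(outer(outer(temp_pts, leuk_pts, "+"), oxy_pts, "+")),
                   c(outer(secr_pts, mic_pts, "+")), "+"))
  expect_setequal(sort(unique(c(outer(cpis5, lus_pts, "+")))), 0:19)       # cpis_lus
  expect_setequal(sort(unique(c(outer(c(cpis_all), pct_pts, "+")))), 0:14) # cpis_pct
  expect_setequal(sort(unique(c(outer(c(outer(cpis5, pct_pts, "+")), lus_pts, "+")))),
                  0:21)                                                    # cpis_plus
})

test_that("worsening any input never decreases a composite containing it", {
  base <- patient_record("b", TRUE, temperature = 37, wbc = 8000,
                         pf_ratio = 300, secretions = "absent_minimal",
                         radiography = "no_infiltrate", microbiology = "negative",
                         pct = 0.2, lus = lus_exam("subpleural", "lt15",
                                                   "bilateral", "static"))
  worse <- list(
    function(p) { p$pct <- 1.5; p },
    function(p) { p$temperature <- 39.5; p },
    function(p) { p$secretions <- "purulent"; p },
    function(p) { p$lus <- lus_exam("lobar", "lt15", "bilateral", "static"); p },
    function(p) { p$lus <- lus_exam("subpleural", "lt15", "bilateral", "dynamic"); p })
  ref <- compute_scores(base)
  for (mod in worse) {
    p2 <- mod(base)
    class(p2) <- "patient_record"
    panel <- compute_scores(p2)
    for (s in c("cpis_lus", "cpis_pct", "cpis_plus"))
      expect_gte(panel[[s]], ref[[s]])
  }
})

test_that("every composite equals the sum of its component breakdown on random cohorts", {
  cohort <- generate_cohort(n = 150, seed = 11)
  scored <- score_cohort(cohort)
  for (i in seq_len(nrow(cohort))) {
    panel <- compute_scores(as_patient_record(cohort[i, ]))
    bd <- panel$component_breakdown
    cpis5 <- sum(bd[c("temperature", "leukocytes", "oxygenation",
                      "secretions", "microbiology")])
    expect_identical(panel$cpis, as.integer(cpis5 + bd[["radiography"]]))
    if (!is.na(panel$cpis_plus))
      expect_identical(panel$cpis_plus,
                       as.integer(cpis5 + bd[["pct"]] +
                                  sum(bd[grep("^lus_", names(bd))])))
    # the vectorised cohort path agrees with the per-patient path
    for (s in c("cpis", "lus_score", "cpis_lus", "cpis_pct", "cpis_plus"))
      expect_identical(scored[[s]][i], as.integer(panel[[s]]),
                       label = sprintf("row %d score %s", i, s))
  }
})
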