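test_that("the golden message passes every Minimal rule", {
  rep <- run_compliance(golden_figure3(), tier = "Minimal")
  expect_s3_class(rep, "hla_compliance_report")
  expect_equal(unname(attr(rep, "verdicts")["Minimal"]), "pass")
  expect_true(all(tidy(rep)$outcome == "pass"))
  expect_setequal(tidy(rep)$rule_id, c("M1", "M2", "M3", "M4", "M5"))
})

test_that("removing the database version flips exactly the version rule", {
  msg <- golden_figure3()
  msg$samples[[1]]$typings[[1]]$assignment$allele_version <- NA_character_
  rep <- run_compliance(msg, tier = "Minimal", catalog = toy_catalog())
  out <- minimal_outcomes(rep)
  expect_equal(unname(out["M3"]), "fail")
  expect_true(all(out[setdiff(names(out), "M3")] == "pass"))
  expect_equal(unname(attr(rep, "verdicts")["Minimal"]), "fail")
  # evidence quotes the offending element location
  expect_match(tidy(rep)$evidence[tidy(rep)$rule_id == "M3"],
               "sample\\[1 'IHW9224'\\]/typing\\[1\\]")
})

test_that("tier verdicts nest: passing a higher tier implies the lower ones", {
  corpus <- c(list(character(0)),
              as.list(c("M1", "M2", "M3", "M4", "M5",
                        "G1", "G2", "G3", "O1", "O2")))
  for (i in seq_along(corpus)) {
    msg <- gen_hml(gen_config(seed = 20 + i, defects = corpus[[i]]))
    v <- attr(run_compliance(msg, tier = "Optional", catalog = toy_catalog()),
              "verdicts")
    if (v["Optional"] == "pass") expect_equal(unname(v["General"]), "pass")
    if (v["General"] == "pass") expect_equal(unname(v["Minimal"]), "pass")
  }
})

test_that("a missing catalog downgrades catalog membership to not-evaluated", {
  msg <- gen_hml(gen_config(seed = 2))
  rep <- run_compliance(msg, tier = "General")  # no catalog supplied
  t <- tidy(rep)
  expect_equal(t$outcome[t$rule_id == "G3"], "not_evaluated")
  expect_match(t$evidence[t$rule_id == "G3"], "no allele catalog")
  # and a catalog for a different release is likewise not silently passed
  other <- toy_catalog(); other$release <- release_version("3.99.0")
  t2 <- tidy(run_compliance(msg, tier = "General", catalog = other))
  expect_equal(t2$outcome[t2$rule_id == "G3"], "not_evaluated")
})

test_that("reports serialise to the published JSON schema shape", {
  rep <- run_compliance(golden_figure3(), tier = "Optional",
                        catalog = toy_catalog())
  j <- jsonlite::fromJSON(report_to_json(rep), simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(system.file("extdata", "compliance_report.schema.json",
                                           package = "hlakit"),
                               simplifyVector = FALSE)
  for (key in unlist(schema$required)) expect_true(key %in% names(j), info = key)
  expect_equal(j$message_ref, "MSG-IHW9224-0001")
  expect_equal(j$verdicts$Minimal, "pass")
  expect_length(j$rules, 10L)
  expect_true(all(vapply(j$rules, function(r) {
    all(c("rule_id", "tier", "severity", "outcome", "evidence",
          "description", "corrective_action") %in% names(r))
  }, logical(1))))

  # two runs differ only in the timestamp
  rep2 <- run_compliance(golden_figure3(), tier = "Optional",
                         catalog = toy_catalog())
  strip_ts <- function(x) sub("\"timestamp\": \"[^\"]*\"", "", x)
  expect_identical(strip_ts(report_to_json(rep)), strip_ts(report_to_json(rep2)))
})

test_that("the rule catalog is data with enforced invariants", {
  rules <- default_rules()
  expect_equal(nrow(rules$rules), 10L)
  expect_true(all(rules$rules$severity[rules$rules$tier == "Minimal"] == "error"))

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("catalog_version: '0.0.1'",
               "rules:",
               "  - id: M1",
               "    tier: Minimal",
               "    severity: warning",
               "    description: x",
               "    corrective_action: fix it"), bad)
  expect_error(read_rule_catalog(bad), "Minimal rule")

  unknown <- tempfile(fileext = ".yaml")
  writeLines(c("catalog_version: '0.0.1'",
               "rules:",
               "  - id: Z9",
               "    tier: Optional",
               "    severity: error",
               "    description: x",
               "    corrective_action: fix it"), unknown)
  expect_error(read_rule_catalog(unknown), "no check predicate")
})

test_that("retention profiles return documented minima", {
  expect_equal(retention_minimum("HIPAA"), 6)
  expect_error(retention_minimum("XYZ"), "available: HIPAA")
  expect_true(all(retention_profiles()$years > 0))
})

test_that("MIRING capability tracks the 1.0 version threshold", {
  expect_true(miring_capable("1.0"))
  expect_false(miring_capable("0.9"))
  expect_true(miring_capable("1.0.1"))
  expect_true(miring_capable("2.3"))
  expect_error(miring_capable("one-point-oh"), class = "hla_parse_error")
})

test_that("glance and tidy summarise a report the broom way", {
  rep <- run_compliance(golden_figure3(), tier = "General", catalog = toy_catalog())
  g <- glance(rep)
  expect_equal(nrow(g), 1L)
  expect_equal(g$verdict_minimal, "pass")
  expect_equal(g$verdict_general, "fail")   # golden message has no typing method
  expect_equal(g$n_rules, 8L)
  t <- tidy(rep)
  expect_false(inherits(t, "hla_compliance_report"))
  expect_equal(nrow(t), 8L)
})
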