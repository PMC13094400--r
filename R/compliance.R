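#' Read a compliance rule catalog
#'
#' The rule catalog is data, not code: a YAML file assigning each rule id a
#' tier (`Minimal`, `General`, `Optional`), a severity (`error`, `warning`,
#' `info`), a description and a corrective-action text. The check predicates
#' are keyed by rule id inside the package; re-mapping a rule's tier or
#' severity is an edit to the file, not to code. The bundled default catalog
#' implements the tiered data-exchange recommendations: patient and center
#' identifiers, reference-database version, a parseable GL String and
#' official nomenclature at the Minimal tier; machine-readable method,
#' locus consistency and catalog membership at General; consensus sequences
#' and MAC-free payloads at Optional.
#'
#' Every Minimal rule must have severity `error` (they are the floor of the
#' tier system); this is asserted on load.
#'
#' @param path YAML catalog; defaults to the bundled catalog.
#' @return An `hla_rule_catalog`: list with `catalog_version` and `rules`
#'   (a tibble).
#' @export
read_rule_catalog <- function(path = system.file("extdata", "compliance_rules.yaml",
                                                 package = "hlakit")) {
  raw <- yaml::read_yaml(path)
  rules <- tibble::tibble(
    rule_id = vapply(raw$rules, `[[`, character(1), "id"),
    tier = vapply(raw$rules, `[[`, character(1), "tier"),
    severity = vapply(raw$rules, `[[`, character(1), "severity"),
    description = vapply(raw$rules, `[[`, character(1), "description"),
    corrective_action = vapply(raw$rules, `[[`, character(1), "corrective_action")
  )
  if (anyDuplicated(rules$rule_id)) stop("duplicate rule ids in catalog")
  if (!all(rules$tier %in% names(.tier_rank))) {
    stop("unknown tier in catalog: ",
         paste(setdiff(rules$tier, names(.tier_rank)), collapse = ", "))
  }
  if (!all(rules$severity %in% c("error", "warning", "info"))) {
    stop("unknown severity in catalog")
  }
  if (any(rules$tier == "Minimal" & rules$severity != "error")) {
    stop("every Minimal rule must have severity 'error'")
  }
  unknown <- setdiff(rules$rule_id, names(.rule_checks))
  if (length(unknown)) {
    stop("catalog names rules with no check predicate: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(catalog_version = raw$catalog_version, rules = rules),
            class = "hla_rule_catalog")
}

.tier_rank <- c(Minimal = 1L, General = 2L, Optional = 3L)

# ---- check predicates -------------------------------------------------------
# Each takes (msg, ctx) and returns list(outcome = "pass"|"fail"|"not_evaluated",
# evidence = chr). ctx carries $catalog, $mac_table and $parsed (per-typing
# parse results, shared so dependent rules agree on what parsed).

.typing_walk <- function(msg, fn) {
  out <- list()
  for (si in seq_along(msg$samples)) {
    s <- msg$samples[[si]]
    for (ti in seq_along(s$typings)) {
      out <- c(out, list(fn(s, s$typings[[ti]],
                            sprintf("sample[%d '%s']/typing[%d]", si, s$sample_id, ti))))
    }
  }
  out
}

.check_result <- function(failures, none_msg = NULL) {
  failures <- unlist(failures)
  if (length(failures) == 0L) {
    list(outcome = "pass", evidence = if (is.null(none_msg)) "" else none_msg)
  } else {
    list(outcome = "fail", evidence = paste(failures, collapse = "; "))
  }
}

.prop_missing <- function(msg, key) {
  unlist(lapply(seq_along(msg$samples), function(si) {
    s <- msg$samples[[si]]
    v <- s$properties[key]
    if (is.null(names(v)) || is.na(v) || !nzchar(v)) {
      sprintf("sample[%d '%s'] lacks property '%s'", si, s$sample_id, key)
    }
  }))
}

.rule_checks <- list(
  M1 = function(msg, ctx) .check_result(.prop_missing(msg, "patient-ref")),
  M2 = function(msg, ctx) {
    .check_result(c(.prop_missing(msg, "lab-ref"), .prop_missing(msg, "tc-ref")))
  },
  M3 = function(msg, ctx) {
    .check_result(.typing_walk(msg, function(s, t, at) {
      a <- t$assignment
      if (is.null(a$allele_db) || is.na(a$allele_db) || !nzchar(a$allele_db)) {
        return(paste0(at, " lacks allele-db"))
      }
      if (is.null(a$allele_version) || is.na(a$allele_version)) {
        return(paste0(at, " lacks allele-version"))
      }
      tryCatch({ release_version(a$allele_version); NULL },
               error = function(e) paste0(at, " allele-version '", a$allele_version,
                                          "' does not parse"))
    }))
  },
  M4 = function(msg, ctx) {
    .check_result(.typing_walk(msg, function(s, t, at) {
      gl <- t$assignment$glstring
      if (is.null(gl) || is.na(gl) || !nzchar(gl)) return(paste0(at, " lacks a GL String"))
      tryCatch({ parse_glstring(gl, allow_mac = TRUE, allow_g = TRUE); NULL },
               error = function(e) paste0(at, " GL String does not parse: ",
                                          conditionMessage(e)))
    }))
  },
  # Evaluated only over typings whose GL String parses; an unparseable
  # payload is M4's finding, and letting it fail M5 too would double-report
  # one defect. MAC leaves are out of scope here (O2 owns them).
  M5 = function(msg, ctx) {
    any_parsed <- FALSE
    failures <- .typing_walk(msg, function(s, t, at) {
      ast <- .try_parse_gl(t, ctx)
      if (is.null(ast)) return(NULL)
      any_parsed <<- TRUE
      bad <- Filter(function(l) !l$official, gl_leaves(ast))
      if (length(bad)) {
        paste0(at, " uses unofficial name(s): ",
               paste(vapply(bad, format, character(1)), collapse = ", "))
      }
    })
    if (!any_parsed) return(list(outcome = "not_evaluated",
                                 evidence = "no parseable GL String to inspect"))
    .check_result(failures)
  },
  G1 = function(msg, ctx) {
    .check_result(.typing_walk(msg, function(s, t, at) {
      if (is.null(t$method)) paste0(at, " has no machine-readable typing method")
    }))
  },
  G2 = function(msg, ctx) {
    any_parsed <- FALSE
    failures <- .typing_walk(msg, function(s, t, at) {
      ast <- .try_parse_gl(t, ctx)
      if (is.null(ast)) return(NULL)
      any_parsed <<- TRUE
      loci <- loci_of(ast, strict = FALSE)
      out <- character(0)
      if (anyNA(loci)) {
        out <- c(out, paste0(at, " has locus block(s) mixing gene symbols"))
      }
      fams <- unique(vapply(gl_leaves(ast), `[[`, character(1), "prefix"))
      gf <- t$gene_family
      if (!is.null(gf) && !is.na(gf) && !all(fams == gf)) {
        out <- c(out, paste0(at, " gene-family '", gf, "' does not match GL String ",
                             "namespace(s) ", paste(fams, collapse = ", ")))
      }
      if (length(out)) out
    })
    if (!any_parsed) return(list(outcome = "not_evaluated",
                                 evidence = "no parseable GL String to inspect"))
    .check_result(failures)
  },
  G3 = function(msg, ctx) {
    if (is.null(ctx$catalog)) {
      return(list(outcome = "not_evaluated",
                  evidence = "no allele catalog supplied"))
    }
    any_checked <- FALSE
    failures <- .typing_walk(msg, function(s, t, at) {
      ast <- .try_parse_gl(t, ctx)
      if (is.null(ast)) return(NULL)
      v <- tryCatch(release_version(t$assignment$allele_version),
                    error = function(e) NULL)
      if (is.null(v) || format(v) != format(ctx$catalog$release)) return(NULL)
      leaves <- Filter(function(l) is.na(l$mac) && l$official, gl_leaves(ast))
      if (length(leaves) == 0L) return(NULL)
      any_checked <<- TRUE
      misses <- Filter(function(l) {
        .catalog_lookup(l, ctx$catalog)$status != "found"
      }, leaves)
      if (length(misses)) {
        paste0(at, " name(s) absent from release ", format(ctx$catalog$release), ": ",
               paste(unique(vapply(misses, format, character(1))), collapse = ", "))
      }
    })
    if (!any_checked && length(unlist(failures)) == 0L) {
      return(list(outcome = "not_evaluated",
                  evidence = paste0("no typing declares catalog release ",
                                    format(ctx$catalog$release))))
    }
    .check_result(failures)
  },
  O1 = function(msg, ctx) {
    .check_result(.typing_walk(msg, function(s, t, at) {
      if (is.null(t$consensus)) paste0(at, " reports no consensus sequence")
    }))
  },
  O2 = function(msg, ctx) {
    any_parsed <- FALSE
    failures <- .typing_walk(msg, function(s, t, at) {
      ast <- .try_parse_gl(t, ctx)
      if (is.null(ast)) return(NULL)
      any_parsed <<- TRUE
      macs <- Filter(function(l) !is.na(l$mac), gl_leaves(ast))
      if (length(macs)) {
        paste0(at, " carries Multiple Allele Code(s): ",
               paste(unique(vapply(macs, `[[`, character(1), "mac")), collapse = ", "))
      }
    })
    if (!any_parsed) return(list(outcome = "not_evaluated",
                                 evidence = "no parseable GL String to inspect"))
    .check_result(failures)
  }
)

# Several rules inspect the same payload; parse once per distinct GL String
# per run (the cache environment lives in ctx).
.try_parse_gl <- function(t, ctx = NULL) {
  gl <- t$assignment$glstring
  if (is.null(gl) || is.na(gl) || !nzchar(gl)) return(NULL)
  cache <- if (!is.null(ctx)) ctx$cache
  if (!is.null(cache) && !is.null(cache[[gl]])) {
    return(if (isFALSE(cache[[gl]])) NULL else cache[[gl]])
  }
  ast <- tryCatch(parse_glstring(gl, allow_mac = TRUE, allow_g = TRUE),
                  error = function(e) NULL)
  if (!is.null(cache)) cache[[gl]] <- if (is.null(ast)) FALSE else ast
  ast
}

#' Evaluate a message against the tiered rule catalog
#'
#' Runs every rule of tier at or below `tier` against the message and
#' returns an auditable report. All failures are reported (no fail-fast),
#' matching audit use. A rule whose inputs are unavailable -- the catalog
#' for the membership rule, a parseable GL String for the nomenclature
#' inspections -- is reported as `"not_evaluated"`, never as a silent pass.
#'
#' The verdict for a tier T is pass iff every severity-`error` rule of tier
#' at or below T has outcome `"pass"` or `"not_evaluated"`; because tiers
#' nest, passing General implies passing Minimal.
#'
#' @param msg An `hla_hml_message`.
#' @param tier Evaluation tier: `"Minimal"`, `"General"` or `"Optional"`.
#' @param catalog Optional `hla_allele_catalog` for the catalog-membership
#'   rule.
#' @param mac_table Optional `hla_mac_table` (reserved for MAC-aware
#'   deployments).
#' @param rules Rule catalog from [read_rule_catalog()].
#' @return An `hla_compliance_report`: a tibble of per-rule outcomes
#'   (`rule_id`, `tier`, `severity`, `outcome`, `evidence`,
#'   `description`, `corrective_action`) with report metadata in
#'   attributes; see [glance.hla_compliance_report()] for the verdicts.
#' @examples
#' run_compliance(golden_figure3(), tier = "Minimal")
#' @export
run_compliance <- function(msg, tier = c("Minimal", "General", "Optional"),
                           catalog = NULL, mac_table = NULL,
                           rules = read_rule_catalog()) {
  tier <- match.arg(tier)
  .hml_check(msg)
  stopifnot(inherits(rules, "hla_rule_catalog"))
  ctx <- list(catalog = catalog, mac_table = mac_table,
              cache = new.env(parent = emptyenv()))

  sel <- rules$rules[.tier_rank[rules$rules$tier] <= .tier_rank[tier], ]
  results <- lapply(sel$rule_id, function(id) .rule_checks[[id]](msg, ctx))
  report <- tibble::tibble(
    rule_id = sel$rule_id,
    tier = sel$tier,
    severity = sel$severity,
    outcome = vapply(results, `[[`, character(1), "outcome"),
    evidence = vapply(results, `[[`, character(1), "evidence"),
    description = sel$description,
    corrective_action = sel$corrective_action
  )

  verdicts <- vapply(names(.tier_rank)[.tier_rank <= .tier_rank[tier]], function(tt) {
    sub <- report[.tier_rank[report$tier] <= .tier_rank[tt] &
                    report$severity == "error", ]
    if (all(sub$outcome != "fail")) "pass" else "fail"
  }, character(1))

  structure(report,
            class = c("hla_compliance_report", class(report)),
            message_ref = msg$header$message_id,
            tier_requested = tier,
            verdicts = verdicts,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
            toolkit_version = as.character(utils::packageVersion("hlakit")),
            catalog_version = rules$catalog_version,
            reference_release = if (!is.null(catalog)) format(catalog$release)
                                else NA_character_)
}

#' @export
print.hla_compliance_report <- function(x, ...) {
  v <- attr(x, "verdicts")
  cat("<hla_compliance_report> message ", attr(x, "message_ref"),
      ", tier ", attr(x, "tier_requested"), "\n", sep = "")
  cat("  verdicts: ", paste(names(v), v, sep = "=", collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Tidy a compliance report
#'
#' `tidy()` returns the per-rule outcome table as a plain tibble; `glance()`
#' returns a one-row summary with the tier verdicts and report metadata.
#'
#' @param x An `hla_compliance_report`.
#' @param ... Ignored.
#' @export
tidy.hla_compliance_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.hla_compliance_report
#' @export
glance.hla_compliance_report <- function(x, ...) {
  v <- attr(x, "verdicts")
  out <- tibble::tibble(
    message_ref = attr(x, "message_ref"),
    tier_requested = attr(x, "tier_requested"),
    n_rules = nrow(x),
    n_fail = sum(x$outcome == "fail"),
    n_not_evaluated = sum(x$outcome == "not_evaluated"),
    toolkit_version = attr(x, "toolkit_version"),
    catalog_version = attr(x, "catalog_version")
  )
  for (tt in names(v)) out[[paste0("verdict_", tolower(tt))]] <- v[[tt]]
  out
}

#' Generic for tidy and glance (broom-compatible)
#'
#' @param x Object to summarise.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Serialise a compliance report as JSON
#'
#' Stable, self-describing schema (shipped at
#' `system.file("extdata", "compliance_report.schema.json",
#' package = "hlakit")`): two runs on the same input differ only in the
#' timestamp. The report records the toolkit and rule-catalog versions so a
#' verdict can be reproduced later from its recorded inputs.
#'
#' @param report An `hla_compliance_report`.
#' @param path Optional file to also write to.
#' @return JSON text.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "hla_compliance_report"))
  v <- attr(report, "verdicts")
  model <- .sorted_list(
    catalog_version = attr(report, "catalog_version"),
    message_ref = attr(report, "message_ref"),
    reference_release = attr(report, "reference_release"),
    rules = lapply(seq_len(nrow(report)), function(i) {
      .sorted_list(corrective_action = report$corrective_action[i],
                   description = report$description[i],
                   evidence = report$evidence[i],
                   outcome = report$outcome[i],
                   rule_id = report$rule_id[i],
                   severity = report$severity[i],
                   tier = report$tier[i])
    }),
    tier_requested = attr(report, "tier_requested"),
    timestamp = attr(report, "timestamp"),
    toolkit_version = attr(report, "toolkit_version"),
    verdicts = as.list(v))
  text <- paste0(as.character(jsonlite::toJSON(model, auto_unbox = TRUE,
                                               pretty = 2L)), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Minimum retention periods for compliance documentation
#'
#' Regulatory profiles map to minimum retention periods for
#' compliance-related documentation. The built-in `"HIPAA"` profile is 6
#' years (policies and procedures must be retained for a minimum of 6 years
#' from creation or last effective date, whichever is later); stricter
#' local law always wins, so treat these as floors.
#'
#' @param profile_name Profile name, e.g. `"HIPAA"`.
#' @return `retention_minimum()`: the period in years;
#'   `retention_profiles()`: a tibble of all shipped profiles.
#' @examples
#' retention_minimum("HIPAA")
#' @export
retention_minimum <- function(profile_name) {
  profiles <- retention_profiles()
  hit <- match(profile_name, profiles$profile)
  if (is.na(hit)) {
    stop("unknown retention profile '", profile_name, "'; available: ",
         paste(profiles$profile, collapse = ", "))
  }
  profiles$years[hit]
}

#' @rdname retention_minimum
#' @export
retention_profiles <- function() {
  tibble::tibble(profile = "HIPAA", years = 6,
                 basis = "compliance documentation, from creation or last in effect")
}

#' Is an HML version a structured MIRING implementation?
#'
#' HML versions 1.0 and later are structured implementations of the MIRING
#' reporting guideline; earlier versions are not.
#'
#' @param hml_version Version string such as `"1.0.1"`.
#' @return Logical scalar.
#' @examples
#' miring_capable("1.0.1")
#' miring_capable("0.9")
#' @export
miring_capable <- function(hml_version) {
  stopifnot(is.character(hml_version), length(hml_version) == 1L)
  v <- tryCatch(numeric_version(hml_version),
                error = function(e) .stop_parse("malformed version string", hml_version))
  v >= numeric_version("1.0")
}
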