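golden_path <- function() system.file("extdata", "figure3_minimal.hml.xml",
                                      package = "hlakit")

test_that("the golden minimal message parses to the documented values", {
  msg <- read_hml_xml(golden_path())
  s <- msg$samples[[1]]
  expect_equal(unname(s$properties["lab-ref"]), "NUTTT")
  expect_equal(unname(s$properties["tc-ref"]), "NLUT1")
  expect_equal(unname(s$properties["patient-ref"]), "IHW9224")
  a <- s$typings[[1]]$assignment
  expect_equal(a$allele_db, "IPD-IMGT/HLA")
  expect_equal(a$allele_version, "3.57.0")
  expect_equal(a$date, "2024-11-20")
  # the reference typing was taken from the database: no typing method
  expect_null(s$typings[[1]]$method)
  expect_identical(msg, golden_figure3())
})

test_that("XML writing is deterministic and byte-stable", {
  msg <- golden_figure3()
  outs <- vapply(1:10, function(i) write_hml_xml(msg), character(1))
  expect_length(unique(outs), 1L)
  expect_identical(outs[1], paste(readLines(golden_path()), collapse = "\n") |>
                     paste0("\n"))
})

test_that("XML round-trips losslessly through the model", {
  for (seed in c(1, 5, 9)) {
    msg <- gen_hml(gen_config(seed = seed))
    expect_identical(read_hml_xml(write_hml_xml(msg)), msg)
  }
  msg <- read_hml_xml(golden_path())
  expect_identical(read_hml_xml(write_hml_xml(msg)), msg)
})

test_that("unknown elements survive read/write verbatim (extras bag)", {
  xml <- write_hml_xml(golden_figure3())
  xml <- sub("</sample>",
             "<custom-annotation source=\"LIMS\">keep me</custom-annotation></sample>",
             xml)
  msg <- read_hml_xml(xml)
  expect_length(msg$samples[[1]]$extras, 1L)
  expect_match(msg$samples[[1]]$extras, "custom-annotation")
  rewritten <- write_hml_xml(msg)
  expect_match(rewritten, "<custom-annotation source=\"LIMS\">keep me</custom-annotation>",
               fixed = TRUE)
  expect_identical(read_hml_xml(rewritten), msg)
})

test_that("structural defects are structured errors with element paths", {
  expect_error(read_hml_xml("this is not xml"), "not well-formed",
               class = "hla_hml_error")
  expect_error(read_hml_xml("<hml version=\"1.0.1\"><hmlid extension=\"x\"/></hml>"),
               "no <sample>", class = "hla_hml_error")
  dup <- sub("</sample>",
             "<property name=\"lab-ref\" value=\"AGAIN\"/></sample>",
             write_hml_xml(golden_figure3()))
  err <- tryCatch(read_hml_xml(dup), error = function(e) e)
  expect_s3_class(err, "hla_hml_error")
  expect_match(conditionMessage(err), "duplicate property key 'lab-ref'")
  expect_match(conditionMessage(err), "/hml/sample/property")
})

test_that("the writer refuses invariant-violating messages", {
  expect_error(hml_message("MSG", "2024-11-20", "LAB", samples = list()),
               "at least one sample")
  expect_error(hml_message("", "2024-11-20", "LAB",
                           samples = list(hml_sample("S1"))),
               "nonempty")
  expect_error(
    hml_message("MSG", "2024-11-20", "LAB", samples = list(
      hml_sample("S1", typings = list(hml_typing(
        "HLA", "IPD-IMGT/HLA", "3.57.0", "2024-11-20", "HLA-A*01:01",
        method = list(description = "")))))),
    "description")
})

test_that("typographic glyphs are normalised to ASCII on read", {
  fancy <- gsub("IPD-IMGT/HLA", "IPD‐IMGT/HLA",
                gsub("2024-11-20", "2024‐11‐20",
                     write_hml_xml(golden_figure3())))
  msg <- read_hml_xml(fancy)
  expect_equal(msg$samples[[1]]$typings[[1]]$assignment$allele_db, "IPD-IMGT/HLA")
  expect_equal(msg$samples[[1]]$typings[[1]]$assignment$date, "2024-11-20")
})

test_that("JSON mirrors the XML model one-to-one", {
  for (seed in c(2, 4)) {
    msg <- gen_hml(gen_config(seed = seed))
    expect_identical(hml_from_json(hml_to_json(msg)), msg)
  }
  # tri-format: XML -> model -> JSON -> model -> XML equals the golden parse
  msg <- read_hml_xml(golden_path())
  back <- hml_from_json(hml_to_json(msg))
  expect_identical(back, msg)
  expect_identical(write_hml_xml(back), write_hml_xml(msg))
  # the bundled JSON twin is the canonical serialisation of the same message
  expect_identical(
    hml_from_json(system.file("extdata", "figure3_minimal.hml.json",
                              package = "hlakit")),
    msg)
})

test_that("emitted JSON has canonically sorted keys and is byte-stable", {
  msg <- golden_figure3()
  j1 <- hml_to_json(msg); j2 <- hml_to_json(msg)
  expect_identical(j1, j2)
  top <- names(jsonlite::fromJSON(j1, simplifyVector = FALSE)$hml)
  expect_identical(top, sort(top))
})

test_that("schema-invalid JSON errors name the missing paths", {
  expect_error(hml_from_json("{\"nothml\": {}}"), "\\$/hml",
               class = "hla_hml_error")
  j <- jsonlite::fromJSON(hml_to_json(golden_figure3()), simplifyVector = FALSE)
  j$hml$samples[[1]]$typings[[1]]$allele_assignment <- NULL
  broken <- as.character(jsonlite::toJSON(j, auto_unbox = TRUE))
  err <- tryCatch(hml_from_json(broken), error = function(e) e)
  expect_s3_class(err, "hla_hml_error")
  expect_match(conditionMessage(err), "typings\\[1\\]/allele_assignment")
  expect_error(hml_from_json("{not json"), "not valid JSON",
               class = "hla_hml_error")
})

test_that("consensus payloads export as FASTA records", {
  msg <- gen_hml(gen_config(seed = 11))
  out <- tempfile(fileext = ".fasta")
  n <- export_consensus_fasta(msg, out)
  expect_equal(n, 1L)
  lines <- readLines(out)
  expect_match(lines[1], "^>SAMP-")
  expect_equal(paste(lines[-1], collapse = ""),
               msg$samples[[1]]$typings[[1]]$consensus)

  # method-less golden message has no consensus: empty FASTA, zero records
  out2 <- tempfile(fileext = ".fasta")
  expect_equal(export_consensus_fasta(golden_figure3(), out2), 0L)
})
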