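test_that("the grammar nests ambiguity levels as the delimiters dictate", {
  # the classic exon-2-identical pair as an allele list
  ast <- parse_glstring("HLA-DRB1*14:01/HLA-DRB1*14:54")
  expect_length(ast, 1L)                       # one locus block
  expect_length(ast[[1]], 1L)                  # one genotype alternative
  expect_length(ast[[1]][[1]], 1L)             # one haplotype
  expect_length(ast[[1]][[1]][[1]], 1L)        # one allele list
  expect_length(ast[[1]][[1]][[1]][[1]], 2L)   # two alleles

  # degenerate nesting: a bare allele is single at every level
  one <- parse_glstring("HLA-A*01:01:01:01")
  expect_length(one, 1L)
  expect_length(one[[1]][[1]][[1]][[1]], 1L)
  expect_equal(serialize_glstring(one), "HLA-A*01:01:01:01")

  # two locus blocks of two haplotypes each
  two <- parse_glstring("HLA-A*01:01+HLA-A*02:01^HLA-B*07:02+HLA-B*08:01")
  expect_length(two, 2L)
  expect_length(two[[1]][[1]], 2L)
  expect_length(two[[2]][[1]], 2L)
  expect_equal(loci_of(two), c("A", "B"))
})

test_that("parse errors carry character offsets and reject empty segments", {
  expect_error(parse_glstring(""), "empty", class = "hla_parse_error")
  expect_error(parse_glstring("HLA-A*01:01//HLA-A*01:02"), "empty segment",
               class = "hla_parse_error")
  expect_error(parse_glstring("HLA-A*01:01+"), "empty segment",
               class = "hla_parse_error")
  expect_error(parse_glstring("^HLA-A*01:01"), "empty segment",
               class = "hla_parse_error")
  err <- tryCatch(parse_glstring("HLA-A*01:01/HLA-A*01:xx"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "character 13")
})

test_that("whitespace is illegal unless lenient mode strips it", {
  expect_error(parse_glstring("HLA-A*01:01 /HLA-A*01:02"),
               "whitespace", class = "hla_parse_error")
  expect_warning(ast <- parse_glstring("HLA-A*01:01 /HLA-A*01:02", lenient = TRUE),
                 "stripping")
  expect_equal(serialize_glstring(ast), "HLA-A*01:01/HLA-A*01:02")
})

test_that("serialisation preserves author ordering and round-trips", {
  # alternatives joined in input order, no sorting
  s <- "HLA-B*08:01|HLA-B*07:02"
  expect_equal(serialize_glstring(parse_glstring(s)), s)

  for (seed in 1:100) {
    txt <- gen_glstring(gen_config(seed = seed))
    expect_equal(serialize_glstring(parse_glstring(txt)), txt)
  }
})

test_that("recursive-descent parse agrees with split-order oracle", {
  fixtures <- c(
    "HLA-A*01:01:01:01",
    "HLA-DRB1*14:01/HLA-DRB1*14:54",
    "HLA-A*01:01+HLA-A*02:01^HLA-B*07:02+HLA-B*08:01",
    "HLA-B*07:02~HLA-B*08:01+HLA-B*15:01|HLA-B*27:05+HLA-B*44:02",
    vapply(1:50, function(s) gen_glstring(gen_config(seed = s)), character(1)))
  for (txt in fixtures) {
    expect_true(ast_matches_oracle(parse_glstring(txt), oracle_parse_gl(txt)),
                info = txt)
  }
})

test_that("genotype enumeration matches the brute-force Cartesian oracle", {
  # (a/b)+(c/d) -> 4
  expect_length(enumerate_genotypes(
    "HLA-A*01:01/HLA-A*01:02+HLA-A*02:01/HLA-A*02:05"), 4L)
  # unambiguous -> 1
  expect_length(enumerate_genotypes("HLA-A*01:01+HLA-A*02:01"), 1L)
  # a/b + a/b -> 3 after unordered-genotype normalisation
  expect_length(enumerate_genotypes(
    "HLA-A*01:01/HLA-A*01:02+HLA-A*01:01/HLA-A*01:02"), 3L)

  for (seed in 1:50) {
    txt <- gen_glstring(gen_config(seed = seed, max_allele_list = 4))
    tree <- oracle_parse_gl(txt)
    for (b in seq_along(tree)) {
      got <- enumerate_genotypes(txt, locus_index = b, cap = 1e6)
      want <- oracle_enumerate(tree[[b]])
      expect_setequal(got, want)
      expect_lte(length(got), oracle_expansion_count_raw(tree[[b]]))
    }
  }
})

test_that("expansion above the cap is an explicit overflow error", {
  big <- paste(rep("HLA-A*01:01/HLA-A*01:02/HLA-A*02:01/HLA-A*02:05", 2),
               collapse = "+")
  expect_error(enumerate_genotypes(big, cap = 10L), "cap")
  expect_length(enumerate_genotypes(big, cap = 16L), 10L)  # 16 raw, 10 unordered
  expect_error(enumerate_genotypes("HLA-A*01:01", locus_index = 2L), "out of range")
})

test_that("a locus block mixing gene symbols is a consistency error", {
  mixed <- parse_glstring("HLA-A*01:01+HLA-B*07:02")
  expect_error(loci_of(mixed), "mixes gene symbols")
  expect_true(is.na(loci_of(mixed, strict = FALSE)))
})

test_that("GL String Codes carry namespace and release context", {
  code <- parse_glcode("hla#3.57.0#HLA-A*01:01:01:01")
  expect_equal(code$namespace, "hla")
  expect_equal(format(code$version), "3.57.0")
  expect_equal(serialize_glstring(code$ast), "HLA-A*01:01:01:01")
  expect_equal(serialize_glcode(code), "hla#3.57.0#HLA-A*01:01:01:01")

  # round-trip identity over generated payloads
  for (seed in 1:10) {
    txt <- paste0("hla#3.57.0#", gen_glstring(gen_config(seed = seed)))
    expect_equal(serialize_glcode(parse_glcode(txt)), txt)
  }

  expect_error(parse_glcode("3.57.0#HLA-A*01:01"), "3 '#'-separated",
               class = "hla_parse_error")
  expect_error(parse_glcode("hla#notaversion#HLA-A*01:01"),
               class = "hla_parse_error")
  expect_error(parse_glcode("HLA#3.57.0#HLA-A*01:01"), "lowercase",
               class = "hla_parse_error")
})
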