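#' Parse a WHO HLA nomenclature allele name
#'
#' Splits an allele designation such as `"HLA-A*01:01:01:01"` into its
#' structured parts: namespace prefix, locus symbol, one to four
#' colon-separated numeric fields, an optional expression suffix
#' (`N`/`L`/`S`/`C`/`A`/`Q`) and an optional official group suffix (`G`/`P`).
#' Field strings are kept verbatim (`"01"` is not `"1"`): nomenclature fields
#' are labels, not numbers, and comparison is string-based on the canonical
#' form.
#'
#' Names without the `"HLA-"` prefix are accepted with a warning and
#' normalised to the prefixed canonical form, since GL Strings in the wild
#' vary while the canonical serialisation must be single. Unofficial
#' "little-g" group forms (a lowercase `g` suffix) are rejected unless
#' `allow_g = TRUE`, because only official WHO nomenclature should be used in
#' exchanged data; when allowed they are carried with `official = FALSE` so a
#' validator can report them. With `allow_mac = TRUE` the final field may be
#' an NMDP Multiple Allele Code (two or more uppercase letters) instead of a
#' digit string.
#'
#' @param text A single allele-name string.
#' @param allow_mac Accept a Multiple Allele Code in final-field position.
#' @param allow_g Accept (and flag) unofficial little-g group names.
#' @return An object of class `hla_allele_name` with elements `prefix`,
#'   `gene`, `fields` (character vector), `expression_suffix`,
#'   `group_suffix`, `mac` (code or `NA`), and `official`.
#' @examples
#' parse_allele_name("HLA-A*01:01:01:01")
#' resolution_of(parse_allele_name("HLA-DRB1*14:54"))
#' @export
parse_allele_name <- function(text, allow_mac = FALSE, allow_g = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- .ascii_normalize(text)
  if (!nzchar(text)) .stop_parse("empty allele name")
  if (grepl("[[:space:]]", text)) {
    .stop_parse("whitespace inside allele name", text,
                offset = regexpr("[[:space:]]", text))
  }

  star <- regexpr("*", text, fixed = TRUE)
  if (star < 0L) .stop_parse("missing '*' separator between locus and fields", text)
  head_part <- substr(text, 1L, star - 1L)
  tail_part <- substr(text, star + 1L, nchar(text))

  prefix <- "HLA"
  if (grepl("-", head_part, fixed = TRUE)) {
    dash <- regexpr("-", head_part, fixed = TRUE)
    prefix <- substr(head_part, 1L, dash - 1L)
    gene <- substr(head_part, dash + 1L, nchar(head_part))
    if (!identical(prefix, "HLA")) {
      .stop_parse(sprintf("unknown namespace prefix '%s'", prefix), text, offset = 1L)
    }
  } else {
    gene <- head_part
    warning(sprintf("allele name '%s' lacks the 'HLA-' prefix; normalising", text),
            call. = FALSE)
  }
  if (!grepl("^[A-Z][A-Z0-9]*$", gene)) {
    .stop_parse(sprintf("invalid locus symbol '%s'", gene), text, offset = 1L)
  }
  if (!nzchar(tail_part)) .stop_parse("no fields after '*'", text, offset = star + 1L)

  # Peel a trailing suffix letter off the field block, if any.
  expression_suffix <- NA_character_
  group_suffix <- NA_character_
  official <- TRUE
  last <- substr(tail_part, nchar(tail_part), nchar(tail_part))
  if (last %in% c("N", "L", "S", "C", "A", "Q")) {
    expression_suffix <- last
    tail_part <- substr(tail_part, 1L, nchar(tail_part) - 1L)
  } else if (last %in% c("G", "P")) {
    group_suffix <- last
    tail_part <- substr(tail_part, 1L, nchar(tail_part) - 1L)
  } else if (identical(last, "g")) {
    if (!allow_g) {
      .stop_parse(paste0("unofficial little-g group name; the use of unofficial ",
                         "groupings is discouraged - use WHO nomenclature G/P groups"),
                  text, offset = nchar(text))
    }
    group_suffix <- "g"
    official <- FALSE
    tail_part <- substr(tail_part, 1L, nchar(tail_part) - 1L)
  }

  fields <- strsplit(tail_part, ":", fixed = TRUE)[[1L]]
  if (length(fields) == 0L || any(!nzchar(fields))) {
    .stop_parse("empty field between ':' separators", text, offset = star + 1L)
  }
  if (length(fields) > 4L) {
    .stop_parse(sprintf("%d fields exceed the 4-field maximum", length(fields)),
                text, offset = star + 1L)
  }

  mac <- NA_character_
  n <- length(fields)
  ok_digit <- grepl("^[0-9]+$", fields)
  if (!all(ok_digit[-n]) ) {
    bad <- which(!ok_digit[-n])[1L]
    .stop_parse(sprintf("non-numeric field '%s' in position %d", fields[bad], bad), text)
  }
  if (!ok_digit[n]) {
    if (allow_mac && grepl("^[A-Z]{2,}$", fields[n])) {
      mac <- fields[n]
    } else {
      .stop_parse(sprintf("non-numeric final field '%s'", fields[n]), text)
    }
  }
  if (!is.na(group_suffix) && group_suffix %in% c("G", "P") && n < 2L) {
    .stop_parse("G/P group names require at least 2 fields", text)
  }

  structure(
    list(prefix = prefix, gene = gene, fields = fields,
         expression_suffix = expression_suffix, group_suffix = group_suffix,
         mac = mac, official = official),
    class = "hla_allele_name"
  )
}

#' Canonical serialisation of an allele name
#'
#' Inverse of [parse_allele_name()]: emits `prefix-gene*f1:f2[:f3[:f4]]` plus
#' any suffix, so `format(parse_allele_name(x))` is the canonical form of `x`.
#'
#' @param x An `hla_allele_name`.
#' @param ... Ignored.
#' @export
format.hla_allele_name <- function(x, ...) {
  suffix <- ""
  if (!is.na(x$expression_suffix)) suffix <- x$expression_suffix
  if (!is.na(x$group_suffix)) suffix <- x$group_suffix
  paste0(x$prefix, "-", x$gene, "*", paste(x$fields, collapse = ":"), suffix)
}

#' @export
print.hla_allele_name <- function(x, ...) {
  cat("<hla_allele_name> ", format(x), "  (", resolution_of(x), "-field",
      if (!x$official) ", unofficial" else "", ")\n", sep = "")
  invisible(x)
}

#' Typing resolution of an allele name
#'
#' The number of reported fields (1-4); field count encodes typing resolution
#' (2-field, 3-field, ...).
#'
#' @param name An `hla_allele_name` or a string to parse.
#' @return Integer field count.
#' @export
resolution_of <- function(name) {
  if (is.character(name)) name <- parse_allele_name(name, allow_mac = TRUE)
  stopifnot(inherits(name, "hla_allele_name"))
  length(name$fields)
}
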