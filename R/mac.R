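#' Read an NMDP Multiple Allele Code table
#'
#' Multiple Allele Codes (MACs) are uppercase letter codes that stand for a
#' set of allele possibilities in the final position of an allele name --
#' a registry-era shorthand for long ambiguity strings. A code is either
#' *generic* (its expansions are final-field values, valid after any first
#' field) or *allele-specific* (its expansions are full `first:second` field
#' pairs that replace both trailing fields).
#'
#' The table file is tab-separated: code, `/`-joined expansions, and an
#' optional third column holding `*` to mark allele-specific codes. `#`
#' lines are comments. The bundled table is a synthetic five-code toy; the
#' real registry is maintained by NMDP and is pluggable via `path`.
#'
#' @param path Table file; defaults to the bundled toy table.
#' @return An `hla_mac_table`: tibble with columns `code`, `expansions`
#'   (list of character vectors) and `allele_specific`.
#' @export
read_mac_table <- function(path = system.file("extdata", "toy_mac_table.tsv",
                                              package = "hlakit")) {
  lines <- .ascii_normalize(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)

  code <- vapply(parts, `[[`, character(1), 1L)
  if (!all(grepl("^[A-Z]{2,}$", code))) {
    stop("MAC codes must be >=2 uppercase letters: ",
         paste(code[!grepl("^[A-Z]{2,}$", code)], collapse = ", "))
  }
  if (anyDuplicated(code)) {
    stop("duplicate MAC codes: ", paste(unique(code[duplicated(code)]), collapse = ", "))
  }
  expansions <- lapply(parts, function(p) strsplit(p[2L], "/", fixed = TRUE)[[1L]])
  if (any(vapply(expansions, length, integer(1)) == 0L)) {
    stop("MAC expansion lists must be nonempty")
  }
  allele_specific <- vapply(parts, function(p) length(p) >= 3L && p[3L] == "*",
                            logical(1))
  for (i in seq_along(code)) {
    pat <- if (allele_specific[i]) "^[0-9]+:[0-9]+$" else "^[0-9]+$"
    if (!all(grepl(pat, expansions[[i]]))) {
      stop("malformed expansion for code ", code[i], ": ",
           paste(expansions[[i]], collapse = "/"))
    }
  }
  structure(tibble::tibble(code = code, expansions = expansions,
                           allele_specific = allele_specific),
            class = c("hla_mac_table", class(tibble::tibble())))
}

#' Expand a Multiple Allele Code into an allele list
#'
#' Replaces the MAC in the final field of `name_with_code` by each of its
#' expansions, returning the `/`-joined GL String allele list. Generic codes
#' substitute the final field; allele-specific codes replace the last two
#' fields (the documented NMDP convention), and if the typed first field
#' disagrees with an expansion's first field a warning is raised rather than
#' the mismatch being silently accepted.
#'
#' @param name_with_code Allele name whose final field is a MAC,
#'   e.g. `"HLA-A*01:AB"`.
#' @param table An `hla_mac_table` from [read_mac_table()].
#' @return The expanded allele list as GL String text.
#' @examples
#' expand_mac("HLA-A*01:AB", read_mac_table())
#' @export
expand_mac <- function(name_with_code, table = read_mac_table()) {
  stopifnot(inherits(table, "hla_mac_table"))
  name <- parse_allele_name(name_with_code, allow_mac = TRUE)
  if (is.na(name$mac)) {
    stop("'", format(name), "' carries no Multiple Allele Code in final position")
  }
  hit <- match(name$mac, table$code)
  if (is.na(hit)) {
    stop("unknown Multiple Allele Code '", name$mac, "'")
  }
  stem_fields <- name$fields[-length(name$fields)]
  exps <- table$expansions[[hit]]
  if (table$allele_specific[hit]) {
    if (length(stem_fields) < 1L) {
      stop("allele-specific code '", name$mac, "' needs a typed first field")
    }
    typed_first <- stem_fields[length(stem_fields)]
    firsts <- sub(":.*$", "", exps)
    if (!all(firsts == typed_first)) {
      warning("allele-specific code '", name$mac, "' overrides typed first field '",
              typed_first, "'", call. = FALSE)
    }
    stem_fields <- stem_fields[-length(stem_fields)]
    tails <- exps
  } else {
    tails <- exps
  }
  prefix <- paste0(name$prefix, "-", name$gene, "*")
  stem <- if (length(stem_fields)) paste0(paste(stem_fields, collapse = ":"), ":") else ""
  paste0(prefix, stem, tails, collapse = "/")
}

#' Does a GL String contain a Multiple Allele Code?
#'
#' True iff any leaf allele name's final field is a MAC (two or more
#' uppercase letters). Standardised interoperable exchange should exclude
#' legacy encodings such as MACs, so compliance rules use this to flag
#' MAC-bearing payloads.
#'
#' @param text GL String text (or a single allele name).
#' @return Logical scalar.
#' @examples
#' contains_mac("HLA-A*01:AB/HLA-A*02:01")
#' @export
contains_mac <- function(text) {
  leaves <- gl_leaves(parse_glstring(text, allow_mac = TRUE, allow_g = TRUE))
  any(vapply(leaves, function(l) !is.na(l$mac), logical(1)))
}
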