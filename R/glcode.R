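#' GL String Codes: GL Strings with reference context
#'
#' A GL String is only interpretable against the reference-database release
#' it was called under. The GL String Code (GLSC) wire form binds that
#' context to the payload as three `#`-separated parts:
#' `namespace#version#glstring`, e.g.
#' `"hla#3.57.0#HLA-A*01:01:01:01"`. The namespace is a lowercase
#' gene-family token (`hla`, `kir`, ...), the version an IPD-IMGT/HLA release
#' version, and the payload a GL String.
#'
#' Cross-release translation of allele names is deliberately not offered:
#' accuracy depends on the reference release, so the toolkit refuses rather
#' than translates.
#'
#' @param text A GL String Code.
#' @param code An `hla_gl_code`.
#' @param allow_mac,allow_g Passed to [parse_glstring()] for the payload.
#' @return `parse_glcode()` returns an `hla_gl_code` (list with `namespace`,
#'   `version`, `ast`); `serialize_glcode()` its canonical text.
#' @examples
#' parse_glcode("hla#3.57.0#HLA-DRB1*14:01/HLA-DRB1*14:54")
#' @export
parse_glcode <- function(text, allow_mac = FALSE, allow_g = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- .ascii_normalize(text)
  parts <- strsplit(text, "#", fixed = TRUE)[[1L]]
  if (length(parts) != 3L || endsWith(text, "#")) {
    .stop_parse(sprintf("a GL String Code has 3 '#'-separated parts, got %d",
                        if (endsWith(text, "#")) length(parts) + 1L else length(parts)),
                text)
  }
  if (!grepl("^[a-z][a-z0-9-]*$", parts[1L])) {
    .stop_parse(sprintf("namespace '%s' must be a lowercase token", parts[1L]), text)
  }
  structure(
    list(namespace = parts[1L],
         version = release_version(parts[2L]),
         ast = parse_glstring(parts[3L], allow_mac = allow_mac, allow_g = allow_g)),
    class = "hla_gl_code"
  )
}

#' @rdname parse_glcode
#' @export
serialize_glcode <- function(code) {
  stopifnot(inherits(code, "hla_gl_code"))
  paste(code$namespace, format(code$version), serialize_glstring(code$ast),
        sep = "#")
}

#' @export
format.hla_gl_code <- function(x, ...) serialize_glcode(x)

#' @export
print.hla_gl_code <- function(x, ...) {
  cat("<hla_gl_code> ", serialize_glcode(x), "\n", sep = "")
  invisible(x)
}
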