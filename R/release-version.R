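#' IPD-IMGT/HLA release versions and repository branches
#'
#' The IPD-IMGT/HLA database is released under `major.minor.patch` versions,
#' and each release is mirrored by a repository branch whose name is the
#' digits of the version concatenated without separators: branch `3570`
#' carries release 3.57.0. `release_version()` builds/parses the dotted form,
#' [version_to_branch()] and [branch_to_version()] convert between the two.
#'
#' The branch form does not delimit its parts, so the inverse mapping needs a
#' width convention: the last digit is the patch, the preceding one or two
#' digits are the minor (two whenever enough digits remain), and the
#' remainder is the major. This matches current release numbering (single
#' digit major, minor up to two digits, patch below ten) and makes
#' `branch_to_version(version_to_branch(v))` the identity on that range.
#'
#' @param x Dotted version string like `"3.57.0"`, or an `hla_release_version`.
#' @param major,minor,patch Non-negative integers.
#' @return `release_version()` returns an `hla_release_version`;
#'   `version_to_branch()` a branch string; `branch_to_version()` an
#'   `hla_release_version`.
#' @examples
#' version_to_branch(release_version("3.57.0"))  # "3570"
#' branch_to_version("3570")                     # 3.57.0
#' @export
release_version <- function(x = NULL, major = NULL, minor = NULL, patch = NULL) {
  if (!is.null(x)) {
    if (inherits(x, "hla_release_version")) return(x)
    stopifnot(is.character(x), length(x) == 1L)
    x <- .ascii_normalize(x)
    if (!grepl("^[0-9]+\\.[0-9]+\\.[0-9]+$", x)) {
      .stop_parse("release version must be 'major.minor.patch' with numeric parts", x)
    }
    parts <- as.integer(strsplit(x, ".", fixed = TRUE)[[1L]])
    major <- parts[1L]; minor <- parts[2L]; patch <- parts[3L]
  }
  stopifnot(length(major) == 1L, length(minor) == 1L, length(patch) == 1L)
  major <- as.integer(major); minor <- as.integer(minor); patch <- as.integer(patch)
  if (any(is.na(c(major, minor, patch))) || any(c(major, minor, patch) < 0L)) {
    stop("version parts must be non-negative integers")
  }
  structure(list(major = major, minor = minor, patch = patch),
            class = "hla_release_version")
}

#' @export
format.hla_release_version <- function(x, ...) {
  sprintf("%d.%d.%d", x$major, x$minor, x$patch)
}

#' @export
print.hla_release_version <- function(x, ...) {
  cat("<hla_release_version> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname release_version
version_to_branch <- function(x) {
  v <- release_version(x)
  paste0(v$major, v$minor, v$patch)
}

#' @export
#' @rdname release_version
branch_to_version <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl("^[0-9]+$", x)) .stop_parse("branch must be all digits", x)
  n <- nchar(x)
  if (n < 3L) .stop_parse("branch needs at least 3 digits (major, minor, patch)", x)
  patch <- substr(x, n, n)
  rest <- substr(x, 1L, n - 1L)
  minor_width <- min(2L, nchar(rest) - 1L)
  minor <- substr(rest, nchar(rest) - minor_width + 1L, nchar(rest))
  major <- substr(rest, 1L, nchar(rest) - minor_width)
  release_version(major = as.integer(major), minor = as.integer(minor),
                  patch = as.integer(patch))
}
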