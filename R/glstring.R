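#' GL Strings: the genotype-list grammar for HLA typing ambiguity
#'
#' A GL String is a gene-agnostic text encoding for genotyping results that
#' carries every layer of ambiguity a typing can have: which allele within a
#' list, which haplotype phase, which genotype among alternatives, and which
#' loci were typed. Allele names alone encode resolution (field count) but no
#' nomenclature rule can express "this call OR that call"; the GL grammar
#' does, with five delimiters, loosest to tightest binding:
#'
#' * `^` joins locus blocks into a multilocus genotype,
#' * `|` separates alternative genotypes at one locus,
#' * `+` joins the haplotypes (gene copies) of a genotype,
#' * `~` joins alleles in phase into a haplotype,
#' * `/` separates ambiguous alternatives within an allele list.
#'
#' The parse result is a nested list-of-lists AST mirroring that hierarchy:
#' multilocus > locus block > genotype > haplotype > allele list > allele
#' name. Serialisation preserves author ordering at every level (no sorting
#' on the wire) and round-trips: `serialize_glstring(parse_glstring(s))`
#' equals `s` for canonical input.
#'
#' Whitespace inside a GL String is illegal in strict mode (the default);
#' `lenient = TRUE` strips it with a warning.
#'
#' @param text A single GL String.
#' @param allow_mac Permit NMDP Multiple Allele Codes as final fields of
#'   leaf names (see [expand_mac()]).
#' @param allow_g Permit (and flag) unofficial little-g leaf names.
#' @param lenient Strip whitespace with a warning instead of erroring.
#' @return `parse_glstring()` returns an `hla_gl_ast`; `serialize_glstring()`
#'   its canonical text.
#' @examples
#' ast <- parse_glstring("HLA-A*01:01+HLA-A*02:01^HLA-B*07:02+HLA-B*08:01")
#' loci_of(ast)
#' enumerate_genotypes(parse_glstring("HLA-DRB1*14:01/HLA-DRB1*14:54+HLA-DRB1*01:01"))
#' @export
parse_glstring <- function(text, allow_mac = FALSE, allow_g = FALSE,
                           lenient = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- .ascii_normalize(text)
  if (grepl("[[:space:]]", text)) {
    if (!lenient) {
      .stop_parse("whitespace is illegal inside a GL String", text,
                  offset = regexpr("[[:space:]]", text))
    }
    warning("stripping whitespace from GL String (lenient mode)", call. = FALSE)
    text <- gsub("[[:space:]]+", "", text)
  }
  if (!nzchar(text)) .stop_parse("empty GL String")
  ast <- .gl_parse_level(text, 1L, offset = 0L,
                         allow_mac = allow_mac, allow_g = allow_g)
  structure(ast, class = "hla_gl_ast")
}

.gl_delims <- c("^", "|", "+", "~", "/")

# Recursive descent over the delimiter hierarchy: level 1 splits on '^',
# level 5 on '/', level 6 parses a leaf allele name. `offset` tracks the
# character position of `text` within the original string for error reports.
.gl_parse_level <- function(text, level, offset, allow_mac, allow_g) {
  if (level > length(.gl_delims)) {
    if (!nzchar(text)) .stop_parse("empty allele name segment", offset = offset + 1L)
    leaf <- tryCatch(
      parse_allele_name(text, allow_mac = allow_mac, allow_g = allow_g),
      hla_parse_error = function(e) {
        .stop_parse(sprintf("invalid allele name '%s': %s", text, conditionMessage(e)),
                    offset = offset + 1L)
      }
    )
    return(leaf)
  }
  delim <- .gl_delims[level]
  if (endsWith(text, delim)) {
    .stop_parse(sprintf("empty segment next to '%s'", delim),
                offset = offset + nchar(text))
  }
  pieces <- strsplit(text, delim, fixed = TRUE)[[1L]]
  if (length(pieces) == 0L || any(!nzchar(pieces))) {
    .stop_parse(sprintf("empty segment next to '%s'", delim), offset = offset + 1L)
  }
  starts <- offset + c(0L, cumsum(nchar(pieces) + 1L)[-length(pieces)])
  Map(function(piece, start) {
    .gl_parse_level(piece, level + 1L, start, allow_mac, allow_g)
  }, pieces, starts) |> unname()
}

#' @param ast An `hla_gl_ast`.
#' @rdname parse_glstring
#' @export
serialize_glstring <- function(ast) {
  stopifnot(inherits(ast, "hla_gl_ast"))
  .gl_serialize_level(unclass(ast), 1L)
}

.gl_serialize_level <- function(node, level) {
  if (level > length(.gl_delims)) return(format(node))
  if (!is.list(node) || length(node) == 0L) {
    stop("malformed GL AST: empty or non-list node at level ", level)
  }
  paste(vapply(node, .gl_serialize_level, character(1), level = level + 1L),
        collapse = .gl_delims[level])
}

#' @export
format.hla_gl_ast <- function(x, ...) serialize_glstring(x)

#' @export
print.hla_gl_ast <- function(x, ...) {
  cat("<hla_gl_ast> ", serialize_glstring(x), "\n  loci: ",
      paste(loci_of(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Locus symbols of a GL String
#'
#' Returns the gene symbol of each locus block, in block order. A block whose
#' leaves mix gene symbols is internally inconsistent; with
#' `strict = TRUE` (default) this is an error, with `strict = FALSE` the
#' offending block is reported as `NA` so compliance rules can flag it
#' without aborting.
#'
#' @param ast An `hla_gl_ast` or GL String text.
#' @param strict Error on a mixed-gene locus block.
#' @return Character vector of locus symbols, one per block.
#' @export
loci_of <- function(ast, strict = TRUE) {
  if (is.character(ast)) ast <- parse_glstring(ast, allow_mac = TRUE, allow_g = TRUE)
  stopifnot(inherits(ast, "hla_gl_ast"))
  vapply(seq_along(ast), function(i) {
    genes <- unique(vapply(gl_leaves_of_block(ast[[i]]), `[[`, character(1), "gene"))
    if (length(genes) != 1L) {
      if (strict) {
        stop("locus block ", i, " mixes gene symbols: ",
             paste(genes, collapse = ", "))
      }
      return(NA_character_)
    }
    genes
  }, character(1))
}

# Flatten one locus block to its leaf allele names.
gl_leaves_of_block <- function(block) {
  out <- list()
  for (genotype in block)
    for (haplotype in genotype)
      for (allele_list in haplotype)
        out <- c(out, allele_list)
  out
}

#' All leaf allele names of a GL String
#'
#' @param ast An `hla_gl_ast` or GL String text.
#' @return List of `hla_allele_name` leaves in serialisation order.
#' @export
gl_leaves <- function(ast) {
  if (is.character(ast)) ast <- parse_glstring(ast, allow_mac = TRUE, allow_g = TRUE)
  stopifnot(inherits(ast, "hla_gl_ast"))
  do.call(c, lapply(ast, gl_leaves_of_block))
}

#' Expand the ambiguity of one locus into unambiguous genotypes
#'
#' Cartesian expansion of every allele-list and genotype-alternative
#' ambiguity at one locus block: each result is a genotype string with fully
#' resolved allele lists (haplotypes joined by `+`, in-phase alleles by
#' `~`). Genotypes are unordered, so expansions that differ only in haplotype
#' order are deduplicated after sorting haplotypes lexicographically;
#' `"a/b+a/b"` therefore yields 3 genotypes (aa, ab, bb), not 4. The sort is
#' applied only during enumeration/comparison, never to serialised output.
#'
#' The expansion count before deduplication is the sum over genotype
#' alternatives of the product of allele-list sizes across haplotypes; if
#' that exceeds `cap` the function stops with an overflow error rather than
#' silently truncating.
#'
#' @param ast An `hla_gl_ast` or GL String text.
#' @param locus_index Which locus block to expand (1-based).
#' @param cap Maximum number of raw expansions permitted.
#' @return Character vector of unambiguous genotype strings.
#' @export
enumerate_genotypes <- function(ast, locus_index = 1L, cap = 10000L) {
  if (is.character(ast)) ast <- parse_glstring(ast, allow_mac = TRUE, allow_g = TRUE)
  stopifnot(inherits(ast, "hla_gl_ast"))
  if (locus_index < 1L || locus_index > length(ast)) {
    stop("locus_index ", locus_index, " out of range 1..", length(ast))
  }
  block <- ast[[locus_index]]

  raw_total <- sum(vapply(block, function(genotype) {
    prod(vapply(genotype, function(haplotype) {
      prod(vapply(haplotype, length, numeric(1)))
    }, numeric(1)))
  }, numeric(1)))
  if (raw_total > cap) {
    stop("expansion of locus block ", locus_index, " would produce ", raw_total,
         " genotypes, above the cap of ", cap,
         "; raise `cap` explicitly to proceed")
  }

  out <- character(0)
  for (genotype in block) {
    # Each haplotype expands to all combinations of its allele-list choices.
    hap_choices <- lapply(genotype, function(haplotype) {
      lists <- lapply(haplotype, function(al) vapply(al, format, character(1)))
      grid <- expand.grid(rev(lists), stringsAsFactors = FALSE)
      apply(grid[, rev(seq_along(lists)), drop = FALSE], 1L, paste, collapse = "~")
    })
    grid <- expand.grid(rev(hap_choices), stringsAsFactors = FALSE)
    combos <- apply(grid[, rev(seq_along(hap_choices)), drop = FALSE], 1L,
                    function(haps) paste(sort(haps), collapse = "+"))
    out <- c(out, combos)
  }
  unique(out)
}
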