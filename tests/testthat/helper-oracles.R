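# Independent oracles used across the suite. These deliberately avoid the
# package's recursive-descent parser and enumerator: the GL grammar oracle is
# plain nested strsplit in delimiter order, and the expansion oracle is a
# direct expand.grid product over leaf strings.

# Split-order parse of a GL String into nested lists of leaf strings:
# ^ then | then + then ~ then /.
oracle_parse_gl <- function(text) {
  split1 <- function(x, d) strsplit(x, d, fixed = TRUE)[[1L]]
  lapply(split1(text, "^"), function(block) {
    lapply(split1(block, "|"), function(genotype) {
      lapply(split1(genotype, "+"), function(haplotype) {
        lapply(split1(haplotype, "~"), function(allele_list) {
          split1(allele_list, "/")
        })
      })
    })
  })
}

# Serialise the oracle's nested-list form back to text.
oracle_serialize_gl <- function(tree) {
  paste(vapply(tree, function(block) {
    paste(vapply(block, function(genotype) {
      paste(vapply(genotype, function(haplotype) {
        paste(vapply(haplotype, paste, character(1), collapse = "/"),
              collapse = "~")
      }, character(1)), collapse = "+")
    }, character(1)), collapse = "|")
  }, character(1)), collapse = "^")
}

# Raw (pre-deduplication) expansion count of one locus block: sum over
# genotype alternatives of the product of allele-list sizes.
oracle_expansion_count_raw <- function(block) {
  sum(vapply(block, function(genotype) {
    prod(vapply(genotype, function(haplotype) {
      prod(vapply(haplotype, length, numeric(1)))
    }, numeric(1)))
  }, numeric(1)))
}

# Brute-force expansion of one locus block with unordered-genotype
# deduplication, built directly on expand.grid.
oracle_enumerate <- function(block) {
  out <- character(0)
  for (genotype in block) {
    haps <- lapply(genotype, function(haplotype) {
      grid <- expand.grid(haplotype, stringsAsFactors = FALSE)
      apply(grid, 1L, paste, collapse = "~")
    })
    grid <- expand.grid(haps, stringsAsFactors = FALSE)
    out <- c(out, apply(grid, 1L, function(row) paste(sort(row), collapse = "+")))
  }
  unique(out)
}

# Structural equality between a package AST and the oracle's nested lists.
ast_matches_oracle <- function(ast, tree) {
  if (length(ast) != length(tree)) return(FALSE)
  for (b in seq_along(ast)) {
    if (length(ast[[b]]) != length(tree[[b]])) return(FALSE)
    for (g in seq_along(ast[[b]])) {
      if (length(ast[[b]][[g]]) != length(tree[[b]][[g]])) return(FALSE)
      for (h in seq_along(ast[[b]][[g]])) {
        if (length(ast[[b]][[g]][[h]]) != length(tree[[b]][[g]][[h]])) return(FALSE)
        for (al in seq_along(ast[[b]][[g]][[h]])) {
          got <- vapply(ast[[b]][[g]][[h]][[al]], format, character(1))
          if (!identical(unname(got), tree[[b]][[g]][[h]][[al]])) return(FALSE)
        }
      }
    }
  }
  TRUE
}

toy_catalog <- function() read_allele_catalog()
toy_macs <- function() read_mac_table()
default_rules <- function() read_rule_catalog()

minimal_outcomes <- function(report) {
  t <- tidy(report)
  stats::setNames(t$outcome, t$rule_id)[t$tier == "Minimal"]
}
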