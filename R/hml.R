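#' Construct a minimal HML message
#'
#' The histoimmunogenetics markup language (HML) is the XML message standard
#' for HLA genotyping results. This package implements a stripped-down
#' *minimal* profile carrying the essential elements for clinical exchange:
#' a header (message id, creation timestamp, reporting-center id), one or
#' more samples identified by registry-style properties (`lab-ref` for the
#' typing center, `tc-ref` for the transplant center, `patient-ref` for the
#' patient identifier), and per-sample typings whose allele assignment names
#' the reference database, its release version, the assignment date and a GL
#' String. A typing may additionally carry a machine-readable typing method
#' and a consensus sequence (held verbatim; sequence validation is out of
#' scope).
#'
#' Unrecognised XML elements encountered on read are preserved in `extras`
#' bags at each level and re-emitted on write, so reading and re-writing a
#' message is lossless even for content outside the minimal profile.
#'
#' @param message_id Nonempty message identifier.
#' @param created Creation timestamp (ISO-8601, timezone-free).
#' @param reporting_center Reporting-center identifier.
#' @param samples List of samples from [hml_sample()].
#' @param version HML standard version string (versions 1.0 and later are
#'   structured implementations of the MIRING reporting guideline).
#' @param extras Character vector of verbatim XML fragments.
#' @return An `hla_hml_message`.
#' @seealso [read_hml_xml()], [write_hml_xml()], [hml_to_json()]
#' @export
hml_message <- function(message_id, created, reporting_center, samples,
                        version = "1.0.1", extras = character(0)) {
  msg <- structure(
    list(version = version,
         header = list(message_id = message_id, created = created,
                       reporting_center = reporting_center),
         samples = samples, extras = extras),
    class = "hla_hml_message")
  .hml_check(msg)
  msg
}

#' @param sample_id Nonempty sample identifier.
#' @param properties Named character vector (unique keys), e.g.
#'   `c("lab-ref" = "NUTTT", "tc-ref" = "NLUT1", "patient-ref" = "IHW9224")`.
#' @param typings List of typings from [hml_typing()].
#' @rdname hml_message
#' @export
hml_sample <- function(sample_id, properties = character(0), typings = list(),
                       extras = character(0)) {
  if (length(properties)) properties <- properties[order(names(properties))]
  list(sample_id = sample_id, properties = properties, typings = typings,
       extras = extras)
}

#' @param gene_family Gene-family token, e.g. `"HLA"`.
#' @param allele_db Reference database name, e.g. `"IPD-IMGT/HLA"`.
#' @param allele_version Database release version text, e.g. `"3.57.0"`.
#' @param date Assignment date (ISO-8601 calendar date).
#' @param glstring GL String text for the assignment.
#' @param method `NULL`, or a list with `description` (required when
#'   present), `platform`, `exons_targeted` (integer vector), `software`,
#'   `software_version`.
#' @param consensus `NULL` or a consensus-sequence string (carried verbatim).
#' @rdname hml_message
#' @export
hml_typing <- function(gene_family, allele_db, allele_version, date, glstring,
                       method = NULL, consensus = NULL, extras = character(0)) {
  list(gene_family = gene_family,
       assignment = list(allele_db = allele_db, allele_version = allele_version,
                         date = date, glstring = glstring),
       method = method, consensus = consensus, extras = extras)
}

# Structural invariants shared by the XML and JSON writers; violations are
# refusals, not warnings.
.hml_check <- function(msg) {
  stopifnot(inherits(msg, "hla_hml_message"))
  h <- msg$header
  if (is.null(h$message_id) || is.na(h$message_id) || !nzchar(h$message_id)) {
    stop("message id must be nonempty")
  }
  if (length(msg$samples) == 0L) stop("an HML message needs at least one sample")
  for (s in msg$samples) {
    if (is.null(s$sample_id) || !nzchar(s$sample_id)) stop("sample id must be nonempty")
    keys <- names(s$properties)
    if (length(s$properties) && (is.null(keys) || anyDuplicated(keys))) {
      stop("duplicate or unnamed property keys in sample '", s$sample_id, "'")
    }
    for (t in s$typings) {
      if (is.null(t$assignment)) stop("typing without allele-assignment in sample '",
                                      s$sample_id, "'")
      if (!is.null(t$method) &&
          (is.null(t$method$description) || is.na(t$method$description) ||
           !nzchar(t$method$description))) {
        stop("typing method present but description empty in sample '",
             s$sample_id, "'")
      }
    }
  }
  invisible(msg)
}

#' @export
print.hla_hml_message <- function(x, ...) {
  cat("<hla_hml_message> id ", x$header$message_id, ", ",
      length(x$samples), " sample(s)\n", sep = "")
  for (s in x$samples) {
    cat("  sample ", s$sample_id, ": ",
        paste(names(s$properties), s$properties, sep = "=", collapse = ", "),
        "\n", sep = "")
    for (t in s$typings) {
      cat("    ", t$gene_family, " ", t$assignment$allele_db, " ",
          t$assignment$allele_version, " ", t$assignment$glstring, "\n", sep = "")
    }
  }
  invisible(x)
}

.hml_known <- list(
  sample = c("property", "typing"),
  typing = c("allele-assignment", "typing-method", "consensus-sequence"),
  hml = c("hmlid", "reporting-center", "sample")
)

.attr_or_na <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_character_ else .ascii_normalize(v)
}

.hml_error <- function(msg, node = NULL) {
  if (!is.null(node)) msg <- paste0(msg, " (at ", xml2::xml_path(node), ")")
  stop(errorCondition(msg, class = c("hla_hml_error", "error")))
}

#' Read a minimal HML message from XML
#'
#' Accepts documents with or without an XML namespace (namespaces are
#' stripped). Typographic hyphens and quotes -- typesetting artifacts in
#' published message excerpts -- are normalised to ASCII. Elements outside
#' the minimal profile are preserved verbatim in `extras` bags so that
#' [write_hml_xml()] round-trips losslessly.
#'
#' @param x XML text, a file path, or an `xml_document`.
#' @return An `hla_hml_message`.
#' @examples
#' msg <- read_hml_xml(system.file("extdata", "figure3_minimal.hml.xml",
#'                                 package = "hlakit"))
#' msg$samples[[1]]$properties[["patient-ref"]]
#' @export
read_hml_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) {
    x
  } else {
    tryCatch(xml2::read_xml(x),
             error = function(e) .hml_error(paste0("not well-formed XML: ",
                                                   conditionMessage(e))))
  }
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "hml") .hml_error("root element must be <hml>", root)

  extras <- character(0)
  message_id <- NA_character_; reporting_center <- NA_character_
  samples <- list()
  for (child in xml2::xml_children(root)) {
    nm <- xml2::xml_name(child)
    if (nm == "hmlid") {
      message_id <- .attr_or_na(child, "extension")
    } else if (nm == "reporting-center") {
      reporting_center <- .attr_or_na(child, "reporting-center-id")
    } else if (nm == "sample") {
      samples <- c(samples, list(.read_hml_sample(child)))
    } else {
      extras <- c(extras, as.character(child))
    }
  }
  if (length(samples) == 0L) .hml_error("no <sample> section in message", root)
  if (is.na(message_id)) .hml_error("missing <hmlid extension=...> message id", root)

  hml_message(message_id = message_id,
              created = .attr_or_na(root, "created"),
              reporting_center = reporting_center,
              samples = samples,
              version = .attr_or_na(root, "version"),
              extras = extras)
}

.read_hml_sample <- function(node) {
  sample_id <- .attr_or_na(node, "id")
  if (is.na(sample_id)) .hml_error("sample without id attribute", node)
  properties <- character(0)
  typings <- list()
  extras <- character(0)
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "property") {
      key <- .attr_or_na(child, "name")
      if (is.na(key)) .hml_error("property without name", child)
      if (key %in% names(properties)) {
        .hml_error(paste0("duplicate property key '", key, "'"), child)
      }
      properties[key] <- .attr_or_na(child, "value")
    } else if (nm == "typing") {
      typings <- c(typings, list(.read_hml_typing(child)))
    } else {
      extras <- c(extras, as.character(child))
    }
  }
  hml_sample(sample_id, properties, typings, extras)
}

.read_hml_typing <- function(node) {
  assignment <- NULL; method <- NULL; consensus <- NULL
  extras <- character(0)
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "allele-assignment") {
      gl <- xml2::xml_find_first(child, "./glstring")
      assignment <- list(
        allele_db = .attr_or_na(child, "allele-db"),
        allele_version = .attr_or_na(child, "allele-version"),
        date = .attr_or_na(child, "date"),
        glstring = if (inherits(gl, "xml_missing")) NA_character_
                   else .ascii_normalize(xml2::xml_text(gl)))
    } else if (nm == "typing-method") {
      sw <- xml2::xml_find_first(child, "./software")
      exons <- xml2::xml_find_first(child, "./exons-targeted")
      method <- list(
        description = .ascii_normalize(
          xml2::xml_text(xml2::xml_find_first(child, "./description"))),
        platform = .ascii_normalize(
          xml2::xml_text(xml2::xml_find_first(child, "./platform"))),
        exons_targeted = if (inherits(exons, "xml_missing")) integer(0)
          else as.integer(strsplit(xml2::xml_text(exons), ",", fixed = TRUE)[[1L]]),
        software = if (inherits(sw, "xml_missing")) NA_character_
          else .attr_or_na(sw, "name"),
        software_version = if (inherits(sw, "xml_missing")) NA_character_
          else .attr_or_na(sw, "version"))
    } else if (nm == "consensus-sequence") {
      consensus <- xml2::xml_text(child)
    } else {
      extras <- c(extras, as.character(child))
    }
  }
  if (is.null(assignment)) .hml_error("typing without <allele-assignment>", node)
  list(gene_family = .attr_or_na(node, "gene-family"),
       assignment = assignment, method = method, consensus = consensus,
       extras = extras)
}

.xml_escape <- function(x, attr = FALSE) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  if (attr) x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.xml_attrs <- function(...) {
  kv <- c(...)
  kv <- kv[!is.na(kv)]
  if (length(kv) == 0L) return("")
  paste0(" ", paste0(names(kv), "=\"", .xml_escape(kv, attr = TRUE), "\"",
                     collapse = " "))
}

#' Write a minimal HML message as XML
#'
#' Serialisation is deterministic and byte-stable across runs: header first,
#' samples in input order, properties sorted by key, two-space indentation.
#' Extras bags are re-emitted verbatim. Invariant violations (no samples,
#' empty message id, duplicate property keys, method without description)
#' are refusals.
#'
#' @param msg An `hla_hml_message`.
#' @param path Optional file path; when given, the text is also written there.
#' @return The XML text, invisibly when `path` is given.
#' @export
write_hml_xml <- function(msg, path = NULL) {
  .hml_check(msg)
  h <- msg$header
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<hml", .xml_attrs(version = msg$version, created = h$created), ">"),
    paste0("  <hmlid", .xml_attrs(extension = h$message_id), "/>"),
    if (!is.na(h$reporting_center)) {
      paste0("  <reporting-center",
             .xml_attrs(`reporting-center-id` = h$reporting_center), "/>")
    },
    unlist(lapply(msg$samples, .write_hml_sample)),
    vapply(msg$extras, function(e) paste0("  ", e), character(1), USE.NAMES = FALSE),
    "</hml>"
  )
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

.write_hml_sample <- function(s) {
  props <- s$properties[order(names(s$properties))]
  c(paste0("  <sample", .xml_attrs(id = s$sample_id), ">"),
    vapply(seq_along(props), function(i) {
      paste0("    <property", .xml_attrs(name = names(props)[i], value = props[[i]]),
             "/>")
    }, character(1)),
    unlist(lapply(s$typings, .write_hml_typing)),
    vapply(s$extras, function(e) paste0("    ", e), character(1), USE.NAMES = FALSE),
    "  </sample>")
}

.write_hml_typing <- function(t) {
  a <- t$assignment
  lines <- c(
    paste0("    <typing", .xml_attrs(`gene-family` = t$gene_family), ">"),
    paste0("      <allele-assignment",
           .xml_attrs(`allele-db` = a$allele_db, `allele-version` = a$allele_version,
                      date = a$date), ">"),
    if (!is.null(a$glstring) && !is.na(a$glstring)) {
      paste0("        <glstring>", .xml_escape(a$glstring), "</glstring>")
    },
    "      </allele-assignment>")
  if (!is.null(t$method)) {
    m <- t$method
    lines <- c(lines,
      "      <typing-method>",
      paste0("        <description>", .xml_escape(m$description), "</description>"),
      if (!is.null(m$platform) && !is.na(m$platform)) {
        paste0("        <platform>", .xml_escape(m$platform), "</platform>")
      },
      if (length(m$exons_targeted)) {
        paste0("        <exons-targeted>",
               paste(m$exons_targeted, collapse = ","), "</exons-targeted>")
      },
      if (!is.null(m$software) && !is.na(m$software)) {
        paste0("        <software",
               .xml_attrs(name = m$software, version = m$software_version), "/>")
      },
      "      </typing-method>")
  }
  if (!is.null(t$consensus)) {
    lines <- c(lines,
               paste0("      <consensus-sequence>", .xml_escape(t$consensus),
                      "</consensus-sequence>"))
  }
  c(lines,
    vapply(t$extras, function(e) paste0("      ", e), character(1), USE.NAMES = FALSE),
    "    </typing>")
}

#' Export consensus-sequence payloads as FASTA
#'
#' Writes every consensus sequence in the message to `path`, one record per
#' typing, with headers `<sample_id>|<gene_family>|<index>`. FASTA is the
#' field's plain-sequence reporting format, so this is the interoperability
#' escape hatch for the verbatim payloads an HML message carries.
#'
#' @param msg An `hla_hml_message`.
#' @param path Output file.
#' @return Invisibly, the number of records written.
#' @export
export_consensus_fasta <- function(msg, path) {
  .hml_check(msg)
  seqs <- list(); names_out <- character(0)
  for (s in msg$samples) {
    i <- 0L
    for (t in s$typings) {
      i <- i + 1L
      if (!is.null(t$consensus)) {
        seqs <- c(seqs, list(gsub("[[:space:]]", "", t$consensus)))
        names_out <- c(names_out, paste(s$sample_id, t$gene_family, i, sep = "|"))
      }
    }
  }
  if (length(seqs) == 0L) {
    writeLines(character(0), path)
    return(invisible(0L))
  }
  if (requireNamespace("seqinr", quietly = TRUE)) {
    seqinr::write.fasta(sequences = lapply(seqs, function(x) {
      strsplit(x, "")[[1L]]
    }), names = names_out, file.out = path, nbchar = 60)
  } else {
    lines <- unlist(Map(function(nm, sq) {
      c(paste0(">", nm), substring(sq, seq(1L, nchar(sq), 60L),
                                   pmin(seq(1L, nchar(sq), 60L) + 59L, nchar(sq))))
    }, names_out, seqs))
    writeLines(lines, path)
  }
  invisible(length(seqs))
}
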