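#' Convert a minimal HML message to and from JSON
#'
#' XML and JSON are alternative serialisations of the same data model: the
#' structure and semantics of the message do not change between the two, so
#' `hml_from_json(hml_to_json(msg))` is the identity and XML -> JSON -> XML
#' round trips losslessly (including extras bags, carried as verbatim XML
#' fragment strings). Emitted JSON uses canonically sorted object keys and
#' is byte-stable across runs; a JSON schema describing the layout ships at
#' `system.file("extdata", "hml_message.schema.json", package = "hlakit")`.
#'
#' `hml_from_json()` reports schema violations as structured errors naming
#' the missing paths.
#'
#' @param msg An `hla_hml_message`.
#' @param text JSON text (or a file path for `hml_from_json`).
#' @param path Optional file to also write the JSON to.
#' @return `hml_to_json()` returns JSON text; `hml_from_json()` an
#'   `hla_hml_message`.
#' @export
hml_to_json <- function(msg, path = NULL) {
  .hml_check(msg)
  h <- msg$header
  model <- .sorted_list(
    hml = .sorted_list(
      created = h$created,
      extras = as.list(msg$extras),
      message_id = h$message_id,
      reporting_center = h$reporting_center,
      samples = lapply(msg$samples, .sample_to_model),
      version = msg$version))
  text <- as.character(jsonlite::toJSON(model, auto_unbox = TRUE, null = "null",
                                        na = "null", pretty = 2L))
  text <- paste0(text, "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

.sorted_list <- function(...) {
  x <- list(...)
  x[vapply(x, function(v) length(v) == 1L && !is.list(v) && is.na(v), logical(1))] <- NULL
  x[order(names(x))]
}

.sample_to_model <- function(s) {
  props <- as.list(s$properties)
  .sorted_list(
    extras = as.list(s$extras),
    properties = props[order(names(props))],
    sample_id = s$sample_id,
    typings = lapply(s$typings, .typing_to_model))
}

.typing_to_model <- function(t) {
  a <- t$assignment
  model <- .sorted_list(
    allele_assignment = .sorted_list(allele_db = a$allele_db,
                                     allele_version = a$allele_version,
                                     date = a$date, glstring = a$glstring),
    extras = as.list(t$extras),
    gene_family = t$gene_family)
  if (!is.null(t$method)) {
    m <- t$method
    model$typing_method <- .sorted_list(
      description = m$description, platform = m$platform,
      exons_targeted = as.list(m$exons_targeted),
      software = m$software, software_version = m$software_version)
    model <- model[order(names(model))]
  }
  if (!is.null(t$consensus)) {
    model$consensus_sequence <- t$consensus
    model <- model[order(names(model))]
  }
  model
}

.json_require <- function(x, keys, at) {
  missing <- keys[!keys %in% names(x)]
  if (length(missing)) {
    stop(errorCondition(
      paste0("JSON message missing required path(s): ",
             paste(paste0(at, "/", missing), collapse = ", ")),
      class = c("hla_hml_error", "error")))
  }
}

.chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)

#' @rdname hml_to_json
#' @export
hml_from_json <- function(text) {
  if (length(text) == 1L && !grepl("[{\\[]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e) {
                  stop(errorCondition(paste0("not valid JSON: ", conditionMessage(e)),
                                      class = c("hla_hml_error", "error")))
                })
  .json_require(x, "hml", at = "$")
  m <- x$hml
  .json_require(m, c("message_id", "samples"), at = "$/hml")
  samples <- lapply(seq_along(m$samples), function(i) {
    s <- m$samples[[i]]
    at <- paste0("$/hml/samples[", i, "]")
    .json_require(s, "sample_id", at = at)
    typings <- lapply(seq_along(s$typings), function(j) {
      t <- s$typings[[j]]
      at_t <- paste0(at, "/typings[", j, "]")
      .json_require(t, "allele_assignment", at = at_t)
      a <- t$allele_assignment
      method <- if (!is.null(t$typing_method)) {
        mm <- t$typing_method
        list(description = .chr1(mm$description), platform = .chr1(mm$platform),
             exons_targeted = as.integer(unlist(mm$exons_targeted)),
             software = .chr1(mm$software),
             software_version = .chr1(mm$software_version))
      }
      hml_typing(gene_family = .chr1(t$gene_family),
                 allele_db = .chr1(a$allele_db),
                 allele_version = .chr1(a$allele_version),
                 date = .chr1(a$date),
                 glstring = .chr1(a$glstring),
                 method = method,
                 consensus = if (is.null(t$consensus_sequence)) NULL
                             else as.character(t$consensus_sequence),
                 extras = as.character(unlist(t$extras)))
    })
    props <- vapply(s$properties, as.character, character(1))
    hml_sample(sample_id = .chr1(s$sample_id),
               properties = if (length(props)) props else character(0),
               typings = typings,
               extras = as.character(unlist(s$extras)))
  })
  hml_message(message_id = .chr1(m$message_id),
              created = .chr1(m$created),
              reporting_center = .chr1(m$reporting_center),
              samples = samples,
              version = .chr1(m$version),
              extras = as.character(unlist(m$extras)))
}
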