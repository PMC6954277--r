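# Packaged signature fixture and JSON (de)serialisation of signatures.

#' The published RPN signature
#'
#' Loads the packaged resting-state pain sensitivity network (RPN)
#' signature: the 21 non-zero partial-correlation weights of the published
#' connectome model of individual pain sensitivity, with region labels,
#' large-scale network (RSN) labels and atlas indices. The published model
#' does not include its feature-scaling parameters or intercept, so the
#' fixture is a weights-only signature: scores it produces are meaningful
#' up to an affine transformation (ranking and correlation are preserved;
#' the absolute scale is not).
#'
#' @return A `pain_signature` in `"weights_only"` mode with 21 entries.
#' @examples
#' sig <- rpn_signature()
#' nrow(sig)                    # 21 connections
#' max(abs(sig$weight))         # strongest connection weight
#' node_predictive_strength(sig)
#' @export
rpn_signature <- function() {
  read_signature_json(system.file("extdata", "rpn_signature.json",
                                  package = "rpnsig", mustWork = TRUE))
}

#' Read a signature from its JSON schema
#'
#' @param path Path to a signature JSON file (see [write_signature_json()]
#'   for the schema).
#' @return A `pain_signature`.
#' @export
read_signature_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as_tibble(j$entries)
  if (!"feature_index" %in% names(entries)) entries$feature_index <- NA_integer_
  if (!"median" %in% names(entries)) entries$median <- NA_real_
  if (!"iqr" %in% names(entries)) entries$iqr <- NA_real_
  hp <- if (is.null(j$hyperparams)) NULL else {
    pipeline_hp(j$hyperparams$k_best, j$hyperparams$l1_ratio, j$hyperparams$alpha)
  }
  new_pain_signature(entries, mode = j$mode,
                     intercept = j$intercept,
                     hyperparams = hp,
                     provenance = as.list(j$provenance))
}

#' Write a signature to JSON
#'
#' Versioned schema: `{schema_version, mode, intercept?, hyperparams?,
#' entries: [{label_i, label_j, weight, median?, iqr?, ...}], provenance}`.
#'
#' @param sig A `pain_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_json <- function(sig, path) {
  stopifnot(inherits(sig, "pain_signature"))
  hp <- attr(sig, "hyperparams")
  out <- list(
    schema_version = 1,
    mode = attr(sig, "mode"),
    intercept = attr(sig, "intercept"),
    hyperparams = if (is.null(hp)) NULL else unclass(hp),
    provenance = attr(sig, "provenance"),
    entries = as.data.frame(unclass(sig))
  )
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
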