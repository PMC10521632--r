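#' Controlled vocabulary of biomedical entity types
#'
#' Eleven entity-type codes are recognised throughout the package:
#' genes/proteins (GEN), cell lines (CLL), tissues (TIS), small molecule
#' compounds (CPD), diseases (DIS), pharmacological classes (PHC),
#' chemical entities (CHE), pathways (PWY), cellular components (CMP),
#' protein domains (DOM) and molecular functions (MFN).  Any other code
#' is rejected at parse time.
#'
#' @return A tibble with columns `code` and `description`, one row per
#'   recognised entity type.
#' @examples
#' entity_types()
#' @export
entity_types <- function() {
  tibble::tibble(
    code = c("GEN", "CLL", "TIS", "CPD", "DIS", "PHC",
             "CHE", "PWY", "CMP", "DOM", "MFN"),
    description = c(
      "genes/proteins", "cell lines", "tissues",
      "small molecule compounds", "diseases", "pharmacological classes",
      "chemical entities", "pathways", "cellular components",
      "protein domains", "molecular functions"
    )
  )
}

entity_type_codes <- function() entity_types()$code

#' Test whether codes are valid entity types
#'
#' @param x Character vector of candidate codes.
#' @return Logical vector, `TRUE` where the code is one of the 11
#'   recognised entity-type codes.
#' @examples
#' is_entity_type(c("GEN", "FOO"))
#' @export
is_entity_type <- function(x) {
  x %in% entity_type_codes()
}

# Abort naming the first offending value and (optionally) its row.
assert_entity_type <- function(x, what = "entity type") {
  bad <- which(!is_entity_type(x))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "unknown %s '%s' (row %d); valid codes: %s",
      what, x[bad[1]], bad[1],
      paste(entity_type_codes(), collapse = ", ")
    ))
  }
  invisible(x)
}
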