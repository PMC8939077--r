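#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# C-locale sort so output ordering never depends on the session locale
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

is_curie <- function(x) grepl("^[A-Za-z]+:[0-9]+$", x)

curie_prefix <- function(x) sub(":.*$", "", x)

curie_digits <- function(x) as.integer(sub("^.*:", "", x))

#' Convert a CURIE to an OBO PURL IRI
#'
#' Uses the OBO Foundry PURL convention,
#' `http://purl.obolibrary.org/obo/<PREFIX>_<digits>`.
#'
#' @param curie character vector of CURIEs (`PREFIX:digits`).
#' @return character vector of IRIs.
#' @export
curie_to_iri <- function(curie) {
  paste0("http://purl.obolibrary.org/obo/", sub(":", "_", curie, fixed = TRUE))
}

# deterministic seed scope: run code under a seed, restore global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
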