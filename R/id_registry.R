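# Stable identifier minting and obsoletion bookkeeping. The registry is a
# flat TSV ledger committed alongside the instance tables; an issued
# (pattern, bindings) pair keeps its id forever and ids are never reused.

#' Create an id registry
#'
#' @param prefix CURIE prefix for minted ids (e.g. `"XPO"`).
#' @param width digit count; minted ids are zero-padded to this width.
#' @param next_id first numeric id to issue.
#' @return an object of class `id_registry`.
#' @export
id_registry <- function(prefix = "XPO", width = 7L, next_id = 1L) {
  structure(list(prefix = prefix, width = as.integer(width),
                 next_id = as.integer(next_id),
                 issued = data.frame(id = character(0), pattern = character(0),
                                     bindings = character(0),
                                     issued_on = character(0),
                                     stringsAsFactors = FALSE)),
            class = "id_registry")
}

#' @export
print.id_registry <- function(x, ...) {
  cat("<id_registry> prefix ", x$prefix, ", width ", x$width,
      ", next id ", x$next_id, ", ", nrow(x$issued), " issued\n", sep = "")
  invisible(x)
}

format_minted_id <- function(registry, n) {
  sprintf("%s:%0*d", registry$prefix, registry$width, n)
}

#' Read an id registry from its TSV ledger
#'
#' The ledger has a `# prefix=<p> width=<w> next_id=<n>` comment line
#' followed by a TSV with columns `id`, `pattern`, `bindings`, `issued_on`.
#'
#' @param path ledger path.
#' @return an `id_registry`.
#' @export
read_id_registry <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  m <- regmatches(lines[1], regexec(
    "^#\\s*prefix=(\\S+)\\s+width=(\\d+)\\s+next_id=(\\d+)\\s*$", lines[1]))[[1]]
  if (length(m) == 0)
    stop("registry ledger missing '# prefix=... width=... next_id=...' line",
         call. = FALSE)
  reg <- id_registry(m[2], as.integer(m[3]), as.integer(m[4]))
  if (length(lines) > 1) {
    tab <- utils::read.delim(text = paste(lines[-1], collapse = "\n"),
                             colClasses = "character", na.strings = NULL,
                             stringsAsFactors = FALSE)
    reg$issued <- tab
    if (nrow(tab)) {
      if (anyDuplicated(tab$id))
        stop("registry ledger has duplicate ids", call. = FALSE)
      reg$next_id <- max(reg$next_id, max(curie_digits(tab$id)) + 1L)
    }
  }
  reg
}

#' Write an id registry ledger
#' @param registry an `id_registry`.
#' @param path output path.
#' @export
write_id_registry <- function(registry, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  head_line <- sprintf("# prefix=%s width=%d next_id=%d",
                       registry$prefix, registry$width, registry$next_id)
  body <- c(paste(names(registry$issued), collapse = "\t"),
            if (nrow(registry$issued))
              apply(registry$issued, 1L, paste, collapse = "\t"))
  writeBin(charToRaw(enc2utf8(paste0(paste(c(head_line, body),
                                           collapse = "\n"), "\n"))), con)
  invisible(path)
}

#' Mint ids for new instance-table rows
#'
#' Rows with existing ids are untouched (and verified against the registry's
#' recorded bindings); blank ids are filled with consecutive new CURIEs in
#' deterministic row order, except that a (pattern, bindings) tuple already
#' in the registry gets its original id back. Idempotent on its own output.
#'
#' @param tables named list, pattern id -> instance table.
#' @param registry an `id_registry`.
#' @param issued_on provenance string recorded with new issuances (empty by
#'   default so rebuilds are byte-identical).
#' @return `list(tables =, registry =)`.
#' @export
mint_ids <- function(tables, registry, issued_on = "") {
  stopifnot(inherits(registry, "id_registry"))
  issued <- registry$issued
  keys0 <- if (nrow(issued)) paste0(issued$pattern, "::", issued$bindings)
           else character(0)
  by_key <- setNames(issued$id, keys0)
  by_id <- setNames(keys0, issued$id)
  claimed <- character(0)  # ids seen in this run, for cross-table collisions
  for (pid in sort_c(names(tables))) {
    tab <- tables[[pid]]
    if (!nrow(tab)) next
    var_cols <- table_var_columns(tab)
    for (i in seq_len(nrow(tab))) {
      bindings <- as.list(unlist(tab[i, var_cols, drop = FALSE]))
      names(bindings) <- var_cols
      key <- paste0(pid, "::", binding_key(bindings))
      cur <- tab$defined_class[i]
      if (nzchar(cur)) {
        if (cur %in% claimed)
          stop("id collision: ", cur, " claimed by more than one row",
               call. = FALSE)
        rec <- if (cur %in% names(by_id)) by_id[[cur]] else NULL
        if (!is.null(rec) && !identical(rec, key))
          stop("provenance mismatch for ", cur, ": registry has '", rec,
               "', table row has '", key, "'", call. = FALSE)
        if (is.null(rec)) {
          # adopt a pre-existing id into the ledger
          issued <- rbind(issued, data.frame(
            id = cur, pattern = pid, bindings = binding_key(bindings),
            issued_on = issued_on, stringsAsFactors = FALSE))
          by_id[[cur]] <- key
          by_key[[key]] <- cur
          if (identical(curie_prefix(cur), registry$prefix))
            registry$next_id <- max(registry$next_id, curie_digits(cur) + 1L)
        }
        claimed <- c(claimed, cur)
        next
      }
      prior <- if (key %in% names(by_key)) by_key[[key]] else NULL
      if (!is.null(prior)) {
        new_id <- prior
      } else {
        new_id <- format_minted_id(registry, registry$next_id)
        registry$next_id <- registry$next_id + 1L
        issued <- rbind(issued, data.frame(
          id = new_id, pattern = pid, bindings = binding_key(bindings),
          issued_on = issued_on, stringsAsFactors = FALSE))
        by_id[[new_id]] <- key
        by_key[[key]] <- new_id
      }
      if (new_id %in% claimed)
        stop("id collision: ", new_id, " claimed by more than one row",
             call. = FALSE)
      tab$defined_class[i] <- new_id
      claimed <- c(claimed, new_id)
    }
    tables[[pid]] <- tab
  }
  registry$issued <- issued
  list(tables = tables, registry = registry)
}

#' Read an obsoletion table from TSV
#'
#' Columns `id`, `replaced_by` (may be empty), `reason`.
#' @param path TSV path.
#' @return data frame.
#' @export
read_obsoletions <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                           stringsAsFactors = FALSE)
  need <- c("id", "replaced_by", "reason")
  missing_c <- setdiff(need, names(tab))
  if (length(missing_c))
    stop("obsoletion table missing column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  tab[need]
}

#' Apply obsoletions to generated classes
#'
#' Obsoleted classes keep their id, get their label prefixed with
#' `"obsolete "`, lose their logical definition, and gain `replaced_by`;
#' they remain in the release. A `replaced_by` target must be a live class
#' — pointing at a class that is obsolete, or is itself obsoleted in the
#' same run, is an error (no transitive resolution).
#'
#' @param classes named list of `phenotype_class` objects (by id).
#' @param obsoletions data frame with columns `id`, `replaced_by`, `reason`.
#' @return the updated class list.
#' @export
apply_obsoletions <- function(classes, obsoletions) {
  if (is.null(names(classes)))
    names(classes) <- vapply(classes, `[[`, character(1), "id")
  if (!nrow(obsoletions)) return(classes)
  unknown <- setdiff(obsoletions$id, names(classes))
  if (length(unknown))
    stop("cannot obsolete unknown id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  batch <- obsoletions$id
  for (i in seq_len(nrow(obsoletions))) {
    id <- obsoletions$id[i]
    rb <- obsoletions$replaced_by[i]
    if (nzchar(rb)) {
      if (rb %in% batch)
        stop("replaced_by target ", rb, " is itself obsoleted in this run",
             call. = FALSE)
      if (!rb %in% names(classes))
        stop("replaced_by target ", rb, " is not in the build", call. = FALSE)
      if (isTRUE(classes[[rb]]$obsolete))
        stop("replaced_by target ", rb, " is an obsolete class", call. = FALSE)
    }
    cl <- classes[[id]]
    if (!isTRUE(cl$obsolete)) {
      cl$label <- paste0("obsolete ", cl$label)
      cl$obsolete <- TRUE
    }
    cl$logical_definition <- NULL
    cl$replaced_by <- if (nzchar(rb)) rb else NULL
    classes[[id]] <- cl
  }
  classes
}
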