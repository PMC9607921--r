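# Turtle persistence for the repository's triples. Writer and reader cover
# exactly the subset the repository emits: @prefix declarations followed by
# one full triple per line (prefixed names or <IRI>s, plain or
# ^^-typed/quoted literals with \\, \", \n, \t escapes). This keeps the
# on-disk form trivially diffable and independently parseable by any
# conforming Turtle library.

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[[j]] == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt, n = "\n", t = "\t", "\\" = "\\", "\"" = "\"",
                             paste0("\\", nxt)))
        j <- j + 2L
      } else {
        buf <- c(buf, chars[[j]])
        j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

render_object <- function(o, o_kind, dtype) {
  if (o_kind == "iri") return(o)
  s <- paste0("\"", escape_literal(o), "\"")
  if (!is.na(dtype)) s <- paste0(s, "^^", dtype)
  s
}

#' Write triples (or a repository) to a Turtle file
#'
#' @param x A triple data frame from [build_base_ontology()] or an
#'   [new_repository()] object.
#' @param path Output `.ttl` path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(x, path) {
  triples <- if (inherits(x, "ehr_repository")) x$triples else x
  stopifnot(is.data.frame(triples))
  lines <- c(
    sprintf("@prefix %s: <%s> .", names(RDF_PREFIXES), unname(RDF_PREFIXES)),
    "",
    sprintf("%s %s %s .", triples$s, triples$p,
            mapply(render_object, triples$o, triples$o_kind, triples$dtype,
                   USE.NAMES = FALSE))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a Turtle file written by [write_ontology()]
#'
#' Parses the line-oriented subset this package emits (prefix declarations
#' plus one triple per line) back into a triple data frame.
#'
#' @param path `.ttl` file path.
#' @return List with `prefixes` (named character vector) and `triples`
#'   (data frame `s`, `p`, `o`, `o_kind`, `dtype`).
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prefixes <- character(0)
  rows <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^@prefix", ln)) {
      m <- regmatches(ln, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9_-]*):\\s+<([^>]*)>\\s+\\.$", ln))[[1]]
      if (length(m) != 3L) stop("malformed @prefix line: ", ln, call. = FALSE)
      prefixes[m[[2]]] <- m[[3]]
      next
    }
    if (!grepl("\\s\\.$", ln)) stop("malformed triple line (no terminating '.'): ",
                                    ln, call. = FALSE)
    body <- sub("\\s+\\.$", "", ln)
    m <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)\\s+(.*)$", body))[[1]]
    if (length(m) != 4L) stop("malformed triple line: ", ln, call. = FALSE)
    s <- m[[2]]; p <- m[[3]]; otok <- m[[4]]
    if (startsWith(otok, "\"")) {
      om <- regmatches(otok, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(\\S+))?$',
                                     otok))[[1]]
      if (length(om) != 3L) stop("malformed literal object: ", otok, call. = FALSE)
      rows[[length(rows) + 1L]] <- triple_frame(
        s, p, unescape_literal(om[[2]]), "literal",
        if (nzchar(om[[3]])) om[[3]] else NA_character_)
    } else {
      rows[[length(rows) + 1L]] <- triple_frame(s, p, otok, "iri", NA_character_)
    }
  }
  for (pn in c(rows_prefixes <- unique(sub(":.*$", "", unlist(lapply(rows, function(r)
    c(r$s, r$p, if (r$o_kind == "iri" && !startsWith(r$o, "<")) r$o))))))) {
    if (!startsWith(pn, "<") && !pn %in% names(prefixes)) {
      stop("undeclared prefix '", pn, ":' in ", path, call. = FALSE)
    }
  }
  list(prefixes = prefixes, triples = do.call(rbind, c(rows, list(triple_frame())))
  )
}
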