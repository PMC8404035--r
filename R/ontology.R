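#' Ontology objects
#'
#' An `ontology` is a set of CURIE-identified classes (e.g. `OCIMIDO:00141`)
#' with labels, provenance-tagged synonyms, cross-references to other
#' terminologies (SNOMED-CT, ICD-10, Read, DOID, HPO, ORDO, PATO, UBERON),
#' an `is_a` parent hierarchy, typed relationships (part-of, adjacent-to,
#' investigated-by, ...), free-text comments, and equivalence/disjointness
#' axiom annotations. Axioms are stored and structurally validated (a class
#' cannot be both equivalent and disjoint to the same class); no
#' description-logic reasoning is performed.
#'
#' Invariants enforced on construction, read and write: unique ids; non-empty
#' labels; no synonym equal to its class label (case-insensitive); an acyclic
#' parent graph. Parent/relationship targets that do not resolve to a class
#' are collected in the `dangling` report attribute, not fatal.
#'
#' @param classes Tibble with columns `id`, `label`.
#' @param synonyms Tibble `class_id`, `term`, `source`, `scope` (scope one of
#'   exact/narrow/broad/related/unspecified).
#' @param xrefs Tibble `class_id`, `xref`.
#' @param parents Tibble `class_id`, `parent`.
#' @param relationships Tibble `class_id`, `relation`, `target`.
#' @param comments Tibble `class_id`, `comment`.
#' @param axioms Tibble `class_id`, `axiom` (`equivalent_to`/`disjoint_from`),
#'   `target`.
#' @param relation_types Tibble `id`, `label` of relation typedefs.
#' @return An `ontology` object.
#' @export
ontology <- function(classes = NULL, synonyms = NULL, xrefs = NULL,
                     parents = NULL, relationships = NULL, comments = NULL,
                     axioms = NULL, relation_types = NULL) {
  o <- structure(list(
    classes = tidy_tbl(classes, c(id = "character", label = "character")),
    synonyms = tidy_tbl(synonyms, c(class_id = "character", term = "character",
                                    source = "character", scope = "character")),
    xrefs = tidy_tbl(xrefs, c(class_id = "character", xref = "character")),
    parents = tidy_tbl(parents, c(class_id = "character", parent = "character")),
    relationships = tidy_tbl(relationships, c(class_id = "character",
                                              relation = "character",
                                              target = "character")),
    comments = tidy_tbl(comments, c(class_id = "character", comment = "character")),
    axioms = tidy_tbl(axioms, c(class_id = "character", axiom = "character",
                                target = "character")),
    relation_types = tidy_tbl(relation_types, c(id = "character", label = "character"))
  ), class = "ontology")
  validate_ontology(o)
}

tidy_tbl <- function(x, spec) {
  if (is.data.frame(x) && ncol(x) == 0) x <- NULL  # e.g. bind_rows(list())
  if (is.null(x)) {
    cols <- lapply(spec, function(type) vector(type, 0))
    return(tibble::as_tibble(cols))
  }
  x <- tibble::as_tibble(x)
  missing <- setdiff(names(spec), names(x))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x[names(spec)]
}

valid_curie <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.-]*:\\S+$", x)

validate_ontology <- function(o) {
  cl <- o$classes
  if (anyDuplicated(cl$id)) {
    stop("duplicate class id: ", cl$id[duplicated(cl$id)][1], call. = FALSE)
  }
  if (any(!valid_curie(cl$id))) {
    stop("invalid CURIE id: ", cl$id[!valid_curie(cl$id)][1], call. = FALSE)
  }
  if (any(!nzchar(cl$label) | is.na(cl$label))) {
    stop("class labels must be non-empty", call. = FALSE)
  }
  if (nrow(o$synonyms) > 0) {
    bad_scope <- setdiff(unique(o$synonyms$scope),
                         c("exact", "narrow", "broad", "related", "unspecified"))
    if (length(bad_scope) > 0) {
      stop("unknown synonym scope: ", bad_scope[1], call. = FALSE)
    }
    lab <- cl$label[match(o$synonyms$class_id, cl$id)]
    clash <- !is.na(lab) & tolower(o$synonyms$term) == tolower(lab)
    if (any(clash)) {
      stop("synonym equals its class label: ", o$synonyms$term[clash][1],
           call. = FALSE)
    }
  }
  if (nrow(o$axioms) > 0) {
    key <- paste(pmin(o$axioms$class_id, o$axioms$target),
                 pmax(o$axioms$class_id, o$axioms$target))
    conflict <- tapply(o$axioms$axiom, key, function(a) length(unique(a)) > 1)
    if (any(conflict)) {
      stop("class pair both equivalent and disjoint: ",
           names(conflict)[conflict][1], call. = FALSE)
    }
  }
  check_parent_acyclic(o)
  # dangling references are a report, not an error
  dang <- character()
  if (nrow(o$parents) > 0) {
    dang <- c(dang, setdiff(o$parents$parent, cl$id))
  }
  if (nrow(o$relationships) > 0) {
    dang <- c(dang, setdiff(o$relationships$target, cl$id))
  }
  attr(o, "dangling") <- unique(dang)
  o
}

check_parent_acyclic <- function(o) {
  edges <- o$parents
  if (nrow(edges) == 0) return(invisible(TRUE))
  nodes <- unique(c(edges$class_id, edges$parent))
  remaining <- edges
  repeat {
    # drop nodes with no outgoing is_a edge (roots), iteratively
    srcs <- unique(remaining$class_id)
    sinks <- setdiff(nodes, srcs)
    if (length(sinks) == 0) break
    remaining <- remaining[!(remaining$parent %in% sinks), , drop = FALSE]
    nodes <- setdiff(nodes, sinks)
    if (nrow(remaining) == 0) return(invisible(TRUE))
  }
  cyc <- sort(unique(remaining$class_id))
  stop("cycle in parent graph involving: ", paste(cyc, collapse = ", "),
       call. = FALSE)
}

#' @export
print.ontology <- function(x, ...) {
  s <- ontology_stats(x)
  cat(sprintf(
    "<ontology> %d classes, %d synonyms, %d xrefs, %d relationships\n",
    s$n_classes, s$n_synonyms, s$n_xrefs, s$n_relationships))
  invisible(x)
}

#' Structural counts for an ontology
#'
#' Relationship count covers `is_a` parents, typed relationships, and
#' equivalence/disjointness axioms. Annotation count covers synonyms,
#' cross-references and comments.
#'
#' @param ontology An [ontology()].
#' @return List with `n_classes`, `n_synonyms`, `n_xrefs`, `n_relationships`,
#'   `n_annotations`, and `synonyms_by_source` (named integer vector).
#' @export
ontology_stats <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  by_src <- if (nrow(ontology$synonyms) > 0) {
    tab <- table(ontology$synonyms$source)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  list(
    n_classes = nrow(ontology$classes),
    n_synonyms = nrow(ontology$synonyms),
    n_xrefs = nrow(ontology$xrefs),
    n_relationships = nrow(ontology$parents) + nrow(ontology$relationships) +
      nrow(ontology$axioms),
    n_annotations = nrow(ontology$synonyms) + nrow(ontology$xrefs) +
      nrow(ontology$comments),
    synonyms_by_source = by_src
  )
}

#' Attach a synonym to a class
#'
#' Appends a provenance-tagged synonym. Re-adding an existing (class, term)
#' pair is a warning no-op; a term equal to the class label is likewise
#' skipped with a warning (labels already match in the term index).
#'
#' @param ontology An [ontology()].
#' @param class_id Target class CURIE (must exist).
#' @param term Synonym surface form (non-empty).
#' @param source Provenance tag, e.g. a forum name.
#' @param scope One of `"exact"`, `"narrow"`, `"broad"`, `"related"`,
#'   `"unspecified"` (default: synonyms are stored unclassified).
#' @return The updated ontology.
#' @export
add_synonym <- function(ontology, class_id, term, source,
                        scope = "unspecified") {
  stopifnot(inherits(ontology, "ontology"))
  if (!class_id %in% ontology$classes$id) {
    stop("unknown class id: ", class_id, call. = FALSE)
  }
  if (!nzchar(term)) stop("synonym term must be non-empty", call. = FALSE)
  if (!nzchar(source)) stop("synonym source must be non-empty", call. = FALSE)
  scope <- match.arg(scope, c("unspecified", "exact", "narrow", "broad", "related"))
  label <- ontology$classes$label[ontology$classes$id == class_id]
  if (tolower(term) == tolower(label)) {
    warning("synonym '", term, "' equals the label of ", class_id,
            "; not added", call. = FALSE)
    return(ontology)
  }
  dup <- ontology$synonyms$class_id == class_id &
    tolower(ontology$synonyms$term) == tolower(term)
  if (any(dup)) {
    warning("synonym '", term, "' already present on ", class_id, call. = FALSE)
    return(ontology)
  }
  ontology$synonyms <- dplyr::bind_rows(
    ontology$synonyms,
    tibble::tibble(class_id = class_id, term = term, source = source,
                   scope = scope)
  )
  validate_ontology(ontology)
}

#' Add a new class
#'
#' Allocates the next free local id under `prefix` (zero-padded to 5 digits)
#' unless `id` is given.
#'
#' @param ontology An [ontology()].
#' @param label Class label (non-empty).
#' @param id Optional explicit CURIE.
#' @param prefix CURIE prefix for automatic allocation.
#' @return The updated ontology; the new id is in `attr(, "new_id")`.
#' @export
add_class <- function(ontology, label, id = NULL, prefix = NULL) {
  stopifnot(inherits(ontology, "ontology"))
  if (!nzchar(label)) stop("class label must be non-empty", call. = FALSE)
  if (is.null(id)) {
    if (is.null(prefix)) {
      prefix <- if (nrow(ontology$classes) > 0) {
        sub(":.*$", "", ontology$classes$id[1])
      } else "ONTO"
    }
    locals <- suppressWarnings(as.integer(sub("^[^:]*:", "",
      ontology$classes$id[startsWith(ontology$classes$id, paste0(prefix, ":"))])))
    nxt <- if (length(locals) == 0 || all(is.na(locals))) 1L else max(locals, na.rm = TRUE) + 1L
    id <- sprintf("%s:%05d", prefix, nxt)
  }
  if (id %in% ontology$classes$id) stop("duplicate class id: ", id, call. = FALSE)
  ontology$classes <- dplyr::bind_rows(ontology$classes,
                                       tibble::tibble(id = id, label = label))
  out <- validate_ontology(ontology)
  attr(out, "new_id") <- id
  out
}

# ---------------------------------------------------------------------------
# OBO 1.4 flat-file dialect

#' Read an ontology
#'
#' Two dialects: OBO 1.4 flat-file stanzas (`id`, `name`, `is_a`, `synonym`
#' with optional scope keyword and a provenance source in the trailing
#' bracket list, `xref`, `relationship`, `comment`, `equivalent_to`,
#' `disjoint_from`, plus `[Typedef]` stanzas), and a flat TSV with columns
#' `id`, `label`, `parents` (|-separated), `synonyms` (|-separated
#' `term@source@scope`, source/scope optional) and `xrefs` (|-separated).
#' A synonym line without a scope keyword reads back as scope
#' `"unspecified"`. Dangling parent/relationship targets are reported in
#' `attr(, "dangling")`, not fatal; duplicate ids and parent cycles are.
#'
#' @param path File path.
#' @param format `"obo"` or `"tsv"` (default from extension).
#' @return An [ontology()].
#' @export
read_ontology <- function(path, format = c("obo", "tsv")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (length(format) == 1) {
    format <- match.arg(format, c("obo", "tsv"))
  } else {
    format <- if (tolower(tools::file_ext(path)) == "tsv") "tsv" else "obo"
  }
  if (format == "obo") read_obo(path) else read_onto_tsv(path)
}

read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  stanza <- NULL
  cur <- NULL
  terms <- list(); typedefs <- list()
  flush <- function() {
    if (is.null(cur)) return()
    if (stanza == "Term") terms[[length(terms) + 1]] <<- cur
    if (stanza == "Typedef") typedefs[[length(typedefs) + 1]] <<- cur
  }
  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "!")) next
    if (grepl("^\\[", ln)) {
      flush()
      stanza <- sub("^\\[(.*)\\]$", "\\1", ln)
      cur <- list()
      next
    }
    if (is.null(stanza) || !grepl(":", ln, fixed = TRUE)) next
    tag <- sub(":.*$", "", ln)
    val <- trimws(sub("^[^:]*:", "", ln))
    val <- sub("\\s*!.*$", "", val)  # trailing OBO comment
    if (!nzchar(val)) next
    cur[[length(cur) + 1]] <- c(tag = tag, value = val)
  }
  flush()

  cls <- list(); syn <- list(); xr <- list(); par <- list(); rel <- list()
  com <- list(); axs <- list()
  for (t in terms) {
    tags <- vapply(t, `[[`, character(1), "tag")
    vals <- vapply(t, `[[`, character(1), "value")
    id <- vals[tags == "id"][1]
    if (is.na(id)) stop("Term stanza without id", call. = FALSE)
    name <- vals[tags == "name"]
    cls[[length(cls) + 1]] <- tibble::tibble(
      id = id, label = if (length(name) > 0) name[1] else NA_character_)
    for (v in vals[tags == "synonym"]) {
      m <- regmatches(v, regexec(
        '^"(.*)"\\s*(EXACT|NARROW|BROAD|RELATED)?\\s*(?:\\[([^]]*)\\])?\\s*$', v))[[1]]
      if (length(m) == 0) stop("malformed synonym line: ", v, call. = FALSE)
      scope <- if (nzchar(m[3])) tolower(m[3]) else "unspecified"
      source <- if (length(m) >= 4 && nzchar(m[4])) m[4] else "imported"
      syn[[length(syn) + 1]] <- tibble::tibble(
        class_id = id, term = m[2], source = source, scope = scope)
    }
    for (v in vals[tags == "xref"]) {
      xr[[length(xr) + 1]] <- tibble::tibble(class_id = id, xref = v)
    }
    for (v in vals[tags == "is_a"]) {
      par[[length(par) + 1]] <- tibble::tibble(class_id = id, parent = v)
    }
    for (v in vals[tags == "relationship"]) {
      parts <- strsplit(v, "\\s+")[[1]]
      if (length(parts) < 2) stop("malformed relationship line: ", v, call. = FALSE)
      rel[[length(rel) + 1]] <- tibble::tibble(
        class_id = id, relation = parts[1], target = parts[2])
    }
    for (v in vals[tags == "comment"]) {
      com[[length(com) + 1]] <- tibble::tibble(class_id = id, comment = v)
    }
    for (v in vals[tags == "equivalent_to"]) {
      axs[[length(axs) + 1]] <- tibble::tibble(
        class_id = id, axiom = "equivalent_to", target = v)
    }
    for (v in vals[tags == "disjoint_from"]) {
      axs[[length(axs) + 1]] <- tibble::tibble(
        class_id = id, axiom = "disjoint_from", target = v)
    }
  }
  rt <- list()
  for (t in typedefs) {
    tags <- vapply(t, `[[`, character(1), "tag")
    vals <- vapply(t, `[[`, character(1), "value")
    id <- vals[tags == "id"][1]
    name <- vals[tags == "name"]
    rt[[length(rt) + 1]] <- tibble::tibble(
      id = id, label = if (length(name) > 0) name[1] else id)
  }
  ontology(classes = dplyr::bind_rows(cls), synonyms = dplyr::bind_rows(syn),
           xrefs = dplyr::bind_rows(xr), parents = dplyr::bind_rows(par),
           relationships = dplyr::bind_rows(rel),
           comments = dplyr::bind_rows(com), axioms = dplyr::bind_rows(axs),
           relation_types = dplyr::bind_rows(rt))
}

read_onto_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  need <- c("id", "label")
  if (!all(need %in% names(df))) {
    stop("ontology TSV needs columns id, label", call. = FALSE)
  }
  split_bar <- function(x) if (is.null(x) || is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
  syn <- list(); par <- list(); xr <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$id[i]
    for (p in split_bar(df$parents[i])) {
      par[[length(par) + 1]] <- tibble::tibble(class_id = id, parent = p)
    }
    for (s in split_bar(df$synonyms[i])) {
      parts <- strsplit(s, "@", fixed = TRUE)[[1]]
      syn[[length(syn) + 1]] <- tibble::tibble(
        class_id = id, term = parts[1],
        source = if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else "imported",
        scope = if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else "unspecified")
    }
    for (x in split_bar(df$xrefs[i])) {
      xr[[length(xr) + 1]] <- tibble::tibble(class_id = id, xref = x)
    }
  }
  ontology(classes = tibble::tibble(id = df$id, label = df$label),
           synonyms = dplyr::bind_rows(syn), parents = dplyr::bind_rows(par),
           xrefs = dplyr::bind_rows(xr))
}

#' Write an ontology
#'
#' Inverse of [read_ontology()]: read-after-write reproduces the ontology
#' (stanzas sorted by id). The TSV dialect carries classes, parents,
#' synonyms and xrefs only; typed relationships, comments and axioms
#' round-trip through OBO.
#'
#' @param ontology An [ontology()].
#' @param path Output path.
#' @param format `"obo"` or `"tsv"`.
#' @export
write_ontology <- function(ontology, path, format = c("obo", "tsv")) {
  stopifnot(inherits(ontology, "ontology"))
  validate_ontology(ontology)
  if (length(format) == 1) {
    format <- match.arg(format, c("obo", "tsv"))
  } else {
    format <- if (tolower(tools::file_ext(path)) == "tsv") "tsv" else "obo"
  }
  if (format == "obo") write_obo(ontology, path) else write_onto_tsv(ontology, path)
  invisible(path)
}

write_obo <- function(o, path) {
  out <- c("format-version: 1.4", "")
  rt <- o$relation_types[order(o$relation_types$id), , drop = FALSE]
  for (i in seq_len(nrow(rt))) {
    out <- c(out, "[Typedef]", paste0("id: ", rt$id[i]),
             paste0("name: ", rt$label[i]), "")
  }
  scope_kw <- c(exact = "EXACT", narrow = "NARROW", broad = "BROAD",
                related = "RELATED", unspecified = "")
  ids <- sort(o$classes$id)
  for (id in ids) {
    lab <- o$classes$label[o$classes$id == id]
    block <- c("[Term]", paste0("id: ", id), paste0("name: ", lab))
    p <- sort(o$parents$parent[o$parents$class_id == id])
    if (length(p) > 0) block <- c(block, paste0("is_a: ", p))
    sy <- o$synonyms[o$synonyms$class_id == id, , drop = FALSE]
    if (nrow(sy) > 0) {
      sy <- sy[order(sy$term), , drop = FALSE]
      kw <- scope_kw[sy$scope]
      block <- c(block, paste0(
        "synonym: \"", sy$term, "\"",
        ifelse(nzchar(kw), paste0(" ", kw), ""),
        " [", sy$source, "]"))
    }
    xr <- sort(o$xrefs$xref[o$xrefs$class_id == id])
    if (length(xr) > 0) block <- c(block, paste0("xref: ", xr))
    re <- o$relationships[o$relationships$class_id == id, , drop = FALSE]
    if (nrow(re) > 0) {
      re <- re[order(re$relation, re$target), , drop = FALSE]
      block <- c(block, paste0("relationship: ", re$relation, " ", re$target))
    }
    cm <- o$comments$comment[o$comments$class_id == id]
    if (length(cm) > 0) block <- c(block, paste0("comment: ", cm))
    ax <- o$axioms[o$axioms$class_id == id, , drop = FALSE]
    if (nrow(ax) > 0) {
      ax <- ax[order(ax$axiom, ax$target), , drop = FALSE]
      block <- c(block, paste0(ax$axiom, ": ", ax$target))
    }
    out <- c(out, block, "")
  }
  writeLines(out, path, useBytes = TRUE)
}

write_onto_tsv <- function(o, path) {
  ids <- sort(o$classes$id)
  join_for <- function(id) {
    sy <- o$synonyms[o$synonyms$class_id == id, , drop = FALSE]
    if (nrow(sy) == 0) return("")
    sy <- sy[order(sy$term), , drop = FALSE]
    paste(paste0(sy$term, "@", sy$source, "@", sy$scope), collapse = "|")
  }
  df <- data.frame(
    id = ids,
    label = o$classes$label[match(ids, o$classes$id)],
    parents = vapply(ids, function(i)
      paste(sort(o$parents$parent[o$parents$class_id == i]), collapse = "|"),
      character(1)),
    synonyms = vapply(ids, join_for, character(1)),
    xrefs = vapply(ids, function(i)
      paste(sort(o$xrefs$xref[o$xrefs$class_id == i]), collapse = "|"),
      character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

# ---------------------------------------------------------------------------

#' Build the surface-term index for the tagger
#'
#' Maps every lowercase label (and synonym, when `include_synonyms`) to its
#' class id, so that e.g. "blurred vision" and its synonym "blurry" resolve
#' to the same identifier. Multiword terms are preserved; the index is
#' sorted longest-first, the order the tagger tries candidates in. A term
#' claimed by two different classes is ambiguous: it is excluded from the
#' index and listed in `attr(, "ambiguous")`.
#'
#' @param ontology An [ontology()].
#' @param include_synonyms Include synonym surface forms (default `TRUE`).
#' @return A `term_index` tibble with columns `term`, `class_id`, `kind`.
#' @export
build_term_index <- function(ontology, include_synonyms = TRUE) {
  stopifnot(inherits(ontology, "ontology"))
  entries <- tibble::tibble(term = tolower(ontology$classes$label),
                            class_id = ontology$classes$id,
                            kind = "label")
  if (include_synonyms && nrow(ontology$synonyms) > 0) {
    entries <- dplyr::bind_rows(entries, tibble::tibble(
      term = tolower(ontology$synonyms$term),
      class_id = ontology$synonyms$class_id,
      kind = "synonym"))
  }
  entries <- dplyr::distinct(entries, .data$term, .data$class_id,
                             .keep_all = TRUE)
  n_classes <- tapply(entries$class_id, entries$term,
                      function(x) length(unique(x)))
  ambiguous <- names(n_classes)[n_classes > 1]
  if (length(ambiguous) > 0) {
    warning("ambiguous term(s) dropped from index: ",
            paste(ambiguous, collapse = ", "), call. = FALSE)
    entries <- entries[!(entries$term %in% ambiguous), , drop = FALSE]
  }
  entries <- entries[order(-nchar(entries$term), entries$term), , drop = FALSE]
  structure(entries, class = c("term_index", class(entries)),
            ambiguous = ambiguous)
}
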