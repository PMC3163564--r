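# The functional-group vocabulary: group classes, their hierarchy, and the
# SMARTS patterns that detect them.  Loaded from a YAML config:
#
#   classes:
#     - name: Alcohol
#       parents: [Hydroxy_Compound]
#       ubiquitous: false
#   patterns:
#     - id: alcohol
#       smarts: "[OX2H1][CX4]"
#       class: Alcohol
#
# A class flagged `ubiquitous` (for substructures present in overwhelming
# numbers, such as the bare carbon atom) is reported at most once per
# molecule and carries only a "at least one" witness, never an exact count.

#' Load a functional-group pattern library
#'
#' Reads and validates a YAML pattern-library config.  Every SMARTS pattern
#' is compiled once at load; malformed SMARTS, unknown parent classes,
#' unknown pattern classes and cyclic hierarchies are load errors naming the
#' offending record.  Patterns are ordered lexicographically by id so that
#' loading is deterministic and idempotent.
#'
#' @param path Path to the YAML config.  Defaults to the library shipped
#'   with the package.
#' @return An object of class `pattern_library` with elements `classes`
#'   (data frame: `name`, `ubiquitous`), `parents` (named list of parent
#'   name vectors), and `patterns` (list of records with `id`, `smarts`,
#'   `class`, `compiled`).
#' @examples
#' lib <- load_pattern_library()
#' lib$classes$name
#' @export
load_pattern_library <- function(path = default_pattern_library()) {
  if (!file.exists(path)) stop(sprintf("pattern library file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cls <- cfg$classes %||% list()
  pats <- cfg$patterns %||% list()

  names_ <- vapply(cls, function(x) as.character(x$name %||% ""), character(1))
  if (any(!nzchar(names_))) stop("pattern library: class record without a name")
  if (anyDuplicated(names_)) {
    stop(sprintf("pattern library: duplicate class name '%s'",
                 names_[duplicated(names_)][1]))
  }
  parents <- lapply(cls, function(x) as.character(unlist(x$parents %||% list())))
  names(parents) <- names_
  for (nm in names_) {
    bad <- setdiff(parents[[nm]], names_)
    if (length(bad)) {
      stop(sprintf("pattern library: class '%s' has unknown parent '%s'",
                   nm, bad[1]))
    }
  }
  # cycle check by repeated leaf-stripping over the parent graph
  remaining <- names_
  repeat {
    roots <- remaining[vapply(remaining, function(nm)
      length(intersect(parents[[nm]], remaining)) == 0L, logical(1))]
    if (length(roots) == 0L) {
      if (length(remaining)) {
        stop(sprintf("pattern library: cyclic class hierarchy involving '%s'",
                     remaining[1]))
      }
      break
    }
    remaining <- setdiff(remaining, roots)
    if (length(remaining) == 0L) break
  }

  ubiq <- vapply(cls, function(x) isTRUE(x$ubiquitous), logical(1))

  pat_ids <- vapply(pats, function(x) as.character(x$id %||% ""), character(1))
  if (any(!nzchar(pat_ids))) stop("pattern library: pattern record without an id")
  if (anyDuplicated(pat_ids)) {
    stop(sprintf("pattern library: duplicate pattern id '%s'",
                 pat_ids[duplicated(pat_ids)][1]))
  }
  patterns <- lapply(pats, function(x) {
    if (is.null(x$smarts) || !nzchar(x$smarts)) {
      stop(sprintf("pattern library: pattern '%s' has no smarts", x$id))
    }
    if (is.null(x$class) || !(x$class %in% names_)) {
      stop(sprintf("pattern library: pattern '%s' references unknown class '%s'",
                   x$id, x$class %||% ""))
    }
    compiled <- tryCatch(compile_smarts(x$smarts), error = function(e) {
      stop(sprintf("pattern library: pattern '%s' has malformed SMARTS: %s",
                   x$id, conditionMessage(e)), call. = FALSE)
    })
    list(id = as.character(x$id), smarts = as.character(x$smarts),
         class = as.character(x$class), compiled = compiled)
  })
  patterns <- patterns[order(vapply(patterns, `[[`, character(1), "id"),
                             method = "radix")]

  structure(list(
    classes = data.frame(name = names_, ubiquitous = ubiq,
                         stringsAsFactors = FALSE),
    parents = parents,
    patterns = patterns,
    path = path
  ), class = "pattern_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the shipped functional-group pattern library
#' @return A file path.
#' @export
default_pattern_library <- function() {
  system.file("extdata", "patterns.yaml", package = "lipidclassr",
              mustWork = TRUE)
}

.check_class <- function(lib, name) {
  if (!(name %in% lib$classes$name)) {
    stop(sprintf("unknown functional-group class '%s'", name))
  }
}

#' Reflexive-transitive subclass closure of a functional-group class
#'
#' @param lib A `pattern_library`.
#' @param name A class name in the library.
#' @return Character vector of class names: `name` plus all its declared
#'   descendants.
#' @examples
#' lib <- load_pattern_library()
#' subclasses_of(lib, "Hydroxy_Compound")
#' @export
subclasses_of <- function(lib, name) {
  stopifnot(inherits(lib, "pattern_library"))
  .check_class(lib, name)
  out <- name
  repeat {
    kids <- lib$classes$name[vapply(lib$classes$name, function(nm)
      length(intersect(lib$parents[[nm]], out)) > 0L, logical(1))]
    nxt <- union(out, kids)
    if (length(nxt) == length(out)) break
    out <- nxt
  }
  sort(out)
}

#' Reflexive-transitive superclass closure of a functional-group class
#'
#' @inheritParams subclasses_of
#' @return Character vector: `name` plus all its declared ancestors.
#' @export
superclasses_of <- function(lib, name) {
  stopifnot(inherits(lib, "pattern_library"))
  .check_class(lib, name)
  out <- name
  repeat {
    ups <- unique(unlist(lib$parents[out], use.names = FALSE))
    nxt <- union(out, ups)
    if (length(nxt) == length(out)) break
    out <- nxt
  }
  sort(out)
}

#' Is a functional-group class ubiquitous?
#'
#' Ubiquitous classes (e.g. the bare carbon atom) occur in overwhelming
#' numbers; the annotator reports at most one witness occurrence and their
#' counts are lower bounds, so exact-cardinality restrictions over them are
#' rejected.
#'
#' @inheritParams subclasses_of
#' @return Logical.
#' @export
is_ubiquitous <- function(lib, name) {
  .check_class(lib, name)
  lib$classes$ubiquitous[match(name, lib$classes$name)]
}

#' @export
print.pattern_library <- function(x, ...) {
  cat(sprintf("<pattern_library> %d classes, %d SMARTS patterns\n",
              nrow(x$classes), length(x$patterns)))
  ub <- x$classes$name[x$classes$ubiquitous]
  if (length(ub)) cat("  ubiquitous:", paste(ub, collapse = ", "), "\n")
  invisible(x)
}
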