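# The lipid class ontology: named classes with definitional expressions
# (equivalences -- necessary and sufficient), an asserted subclass
# hierarchy, and LIPID MAPS mappings with category roll-up.

#' Load a lipid class ontology
#'
#' Reads a YAML ontology file and cross-validates it against a pattern
#' library: every functional-group class referenced by a definition must
#' resolve in the library (directly or through a subclass that carries a
#' pattern), and exact-cardinality restrictions over ubiquitous classes are
#' rejected at load.
#'
#' File format: a `classes` list of records with `name`, optional `parent`
#' (another class name), optional `lm_id` (LIPID MAPS class identifier such
#' as FA0301), and optional `definition` (an expression in the
#' [parse_expression()] grammar; classes without one are asserted-only
#' hierarchy nodes, usable as pruning/evaluation ancestors but never
#' returned as satisfied).
#'
#' @param path Path to the ontology YAML.  Defaults to the eicosanoid
#'   ontology fixture shipped with the package.
#' @param lib A `pattern_library` to validate against.
#' @return An object of class `lipid_ontology`: `classes` (named list of
#'   records with `name`, `parent`, `lm_id`, `definition`, `terminal`) and
#'   `lm_categories` (named character vector of category labels by
#'   two-letter code).
#' @examples
#' lib <- load_pattern_library()
#' ont <- load_ontology(lib = lib)
#' names(ont$classes)
#' @export
load_ontology <- function(path = default_ontology(), lib) {
  stopifnot(inherits(lib, "pattern_library"))
  if (!file.exists(path)) stop(sprintf("ontology file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  recs <- cfg$classes %||% list()

  names_ <- vapply(recs, function(x) as.character(x$name %||% ""), character(1))
  if (any(!nzchar(names_))) stop("ontology: class record without a name")
  if (anyDuplicated(names_)) {
    stop(sprintf("ontology: duplicate class name '%s'",
                 names_[duplicated(names_)][1]))
  }

  classes <- list()
  for (x in recs) {
    parent <- x$parent %||% NA_character_
    if (!is.na(parent) && !(parent %in% names_)) {
      stop(sprintf("ontology: class '%s' has unknown parent '%s'",
                   x$name, parent))
    }
    lm_id <- x$lm_id %||% NA_character_
    def <- NULL
    if (!is.null(x$definition)) {
      def <- tryCatch(parse_expression(x$definition), error = function(e) {
        stop(sprintf("ontology: class '%s': %s", x$name, conditionMessage(e)),
             call. = FALSE)
      })
      .validate_definition(def, lib, x$name)
    }
    classes[[x$name]] <- list(name = as.character(x$name),
                              parent = as.character(parent),
                              lm_id = as.character(lm_id),
                              definition = def)
  }

  # acyclicity of the asserted hierarchy
  for (nm in names_) {
    seen <- character(0)
    cur <- nm
    while (!is.na(classes[[cur]]$parent)) {
      if (cur %in% seen) {
        stop(sprintf("ontology: cyclic parent chain involving '%s'", nm))
      }
      seen <- c(seen, cur)
      cur <- classes[[cur]]$parent
    }
  }

  lm_ids <- vapply(classes, function(x) x$lm_id, character(1))
  dup <- lm_ids[!is.na(lm_ids)][duplicated(lm_ids[!is.na(lm_ids)])]
  if (length(dup)) {
    stop(sprintf("ontology: duplicate LIPID MAPS id '%s'", dup[1]))
  }

  parents <- vapply(classes, function(x) x$parent, character(1))
  for (nm in names_) {
    classes[[nm]]$terminal <- !(nm %in% parents[!is.na(parents)])
  }

  lm_categories <- unlist(cfg$lm_categories %||%
                            list(FA = "Fatty Acyls"))

  structure(list(classes = classes, lm_categories = lm_categories,
                 path = path),
            class = "lipid_ontology")
}

# every referenced functional-group class must exist in the library, and
# 'exactly' fillers must not reach a ubiquitous class
.validate_definition <- function(expr, lib, class_name) {
  walk <- function(e, under_exactly) {
    switch(e$kind,
      named = {
        if (!(e$name %in% lib$classes$name)) {
          stop(sprintf(
            "ontology: class '%s' references undefined functional-group class '%s'",
            class_name, e$name), call. = FALSE)
        }
      },
      union = ,
      intersection = for (m in e$members) walk(m, under_exactly),
      some = walk(e$filler, FALSE),
      min = walk(e$filler, FALSE),
      exactly = {
        walk(e$filler, TRUE)
        members <- .filler_members(e$filler)
        closure <- unique(unlist(lapply(members, function(m)
          subclasses_of(lib, m))))
        ub <- closure[vapply(closure, function(cl)
          is_ubiquitous(lib, cl), logical(1))]
        if (length(ub)) {
          stop(sprintf(
            "ontology: class '%s' uses exact cardinality over ubiquitous class '%s'",
            class_name, ub[1]), call. = FALSE)
        }
      }
    )
    invisible(NULL)
  }
  walk(expr, FALSE)
}

#' Path to the shipped eicosanoid ontology fixture
#' @return A file path.
#' @export
default_ontology <- function() {
  system.file("extdata", "leo.yaml", package = "lipidclassr", mustWork = TRUE)
}

.check_lipid_class <- function(ont, name) {
  if (!(name %in% names(ont$classes))) {
    stop(sprintf("unknown lipid class '%s'", name))
  }
}

#' Asserted ancestors of a lipid class
#'
#' @param ont A `lipid_ontology`.
#' @param name A lipid class name.
#' @param strict Drop `name` itself from the result?
#' @return Character vector of ancestor class names, nearest first.
#' @export
lipid_ancestors <- function(ont, name, strict = TRUE) {
  stopifnot(inherits(ont, "lipid_ontology"))
  .check_lipid_class(ont, name)
  out <- character(0)
  cur <- name
  while (!is.na(ont$classes[[cur]]$parent)) {
    cur <- ont$classes[[cur]]$parent
    out <- c(out, cur)
  }
  if (strict) out else c(name, out)
}

#' LIPID MAPS class id of a lipid class
#'
#' @param ont A `lipid_ontology`.
#' @param lipro_class A lipid class name.
#' @return The stored LIPID MAPS class id (e.g. "FA0301"), or
#'   `NA_character_` when the class carries no mapping.
#' @examples
#' lib <- load_pattern_library()
#' ont <- load_ontology(lib = lib)
#' lm_mapping(ont, "LC_Prostaglandin")
#' @export
lm_mapping <- function(ont, lipro_class) {
  stopifnot(inherits(ont, "lipid_ontology"))
  .check_lipid_class(ont, lipro_class)
  ont$classes[[lipro_class]]$lm_id
}

#' LIPID MAPS category of a class identifier
#'
#' Rolls a LIPID MAPS class id up to its higher-level category by the
#' nomenclature's prefix convention: the first two letters name the
#' category (FA0301 belongs to FA, "Fatty Acyls").
#'
#' @param ont A `lipid_ontology` (supplies the known category codes).
#' @param lm_id A LIPID MAPS class id such as "FA0301".
#' @return A named character scalar: the category label, named by its code.
#' @examples
#' lib <- load_pattern_library()
#' ont <- load_ontology(lib = lib)
#' lm_category(ont, "FA0301")
#' @export
lm_category <- function(ont, lm_id) {
  stopifnot(inherits(ont, "lipid_ontology"))
  if (!is.character(lm_id) || length(lm_id) != 1L ||
      !grepl("^[A-Z]{2}[0-9]{2,}$", lm_id)) {
    stop(sprintf("malformed LIPID MAPS class id: '%s'", lm_id))
  }
  code <- substr(lm_id, 1, 2)
  if (!(code %in% names(ont$lm_categories))) {
    stop(sprintf("unknown LIPID MAPS category code '%s' in id '%s'",
                 code, lm_id))
  }
  stats::setNames(ont$lm_categories[[code]], code)
}

#' Terminal (leaf) classes of the ontology
#' @param ont A `lipid_ontology`.
#' @return Character vector of class names with no children.
#' @export
terminal_classes <- function(ont) {
  stopifnot(inherits(ont, "lipid_ontology"))
  nm <- names(ont$classes)
  nm[vapply(ont$classes, function(x) x$terminal, logical(1))]
}

#' Export the ontology to OWL (functional-style syntax)
#'
#' Writes the named classes, their asserted hierarchy and their definitional
#' equivalences as an OWL 2 functional-syntax document over an
#' object property `hasProperPart`, for interchange with external
#' description-logic reasoners.
#'
#' @param ont A `lipid_ontology`.
#' @param path Output file path; when `NULL` the document is returned as a
#'   character vector of lines.
#' @return Invisibly, the document lines.
#' @export
export_ontology_owl <- function(ont, path = NULL) {
  stopifnot(inherits(ont, "lipid_ontology"))
  iri <- function(x) sprintf("<http://example.org/leo#%s>", x)
  prop <- iri("hasProperPart")
  to_owl <- function(e) {
    switch(e$kind,
      named = iri(e$name),
      union = sprintf("ObjectUnionOf(%s)",
                      paste(vapply(e$members, to_owl, character(1)),
                            collapse = " ")),
      intersection = sprintf("ObjectIntersectionOf(%s)",
                             paste(vapply(e$members, to_owl, character(1)),
                                   collapse = " ")),
      some = sprintf("ObjectSomeValuesFrom(%s %s)", prop, to_owl(e$filler)),
      exactly = sprintf("ObjectExactCardinality(%d %s %s)", e$n, prop,
                        to_owl(e$filler)),
      min = sprintf("ObjectMinCardinality(%d %s %s)", e$n, prop,
                    to_owl(e$filler)),
      stop("unknown expression kind")
    )
  }
  lines <- c(
    "Prefix(:=<http://example.org/leo#>)",
    "Ontology(<http://example.org/leo>",
    sprintf("Declaration(ObjectProperty(%s))", prop)
  )
  for (cls in ont$classes) {
    lines <- c(lines, sprintf("Declaration(Class(%s))", iri(cls$name)))
    if (!is.na(cls$parent)) {
      lines <- c(lines, sprintf("SubClassOf(%s %s)", iri(cls$name),
                                iri(cls$parent)))
    }
    if (!is.null(cls$definition)) {
      lines <- c(lines, sprintf("EquivalentClasses(%s %s)", iri(cls$name),
                                to_owl(cls$definition)))
    }
  }
  lines <- c(lines, ")")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.lipid_ontology <- function(x, ...) {
  n <- length(x$classes)
  nterm <- sum(vapply(x$classes, function(c) c$terminal, logical(1)))
  cat(sprintf("<lipid_ontology> %d classes (%d terminal)\n", n, nterm))
  for (cls in x$classes) {
    cat(sprintf("  %-32s %-8s parent=%s\n", cls$name,
                ifelse(is.na(cls$lm_id), "-", cls$lm_id),
                ifelse(is.na(cls$parent), "(root)", cls$parent)))
  }
  invisible(x)
}
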