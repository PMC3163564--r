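# Classification: from a functional-group profile to the most specific
# satisfied lipid classes and their LIPID MAPS mappings.

#' Build the closed-world anonymous class expression for a profile
#'
#' Converts a profile into the molecule's anonymous description: an
#' intersection with one `part exactly N C` conjunct per exactly counted
#' class and one `part min 1 C` conjunct per present ubiquitous class, in
#' lexicographic class order, carrying a closure marker (attribute
#' `closed`) meaning "no other functional-group parts exist and all
#' occurrences are mutually distinct".
#'
#' @param profile An `fg_profile`.
#' @return A `class_expression` of kind intersection (possibly with zero
#'   members for an empty profile: the closure-only expression).
#' @examples
#' lib <- load_pattern_library()
#' p <- profile_from_counts(c(Alkenyl_Group = 3, Carboxylic_Acid = 1), lib)
#' format_expression(build_molecule_expression(p))
#' @export
build_molecule_expression <- function(profile) {
  stopifnot(inherits(profile, "fg_profile"))
  present <- sort(names(profile$counts))
  members <- lapply(present, function(cl) {
    if (profile$exact[[cl]]) ce_exactly(profile$counts[[cl]], ce_named(cl))
    else ce_min(1L, ce_named(cl))
  })
  expr <- structure(list(kind = "intersection", members = members),
                    class = "class_expression")
  attr(expr, "closed") <- TRUE
  expr
}

#' Prune a set of satisfied classes to the most specific ones
#'
#' Removes every class that is an asserted strict ancestor of another
#' member.  Incomparable classes are all kept, so dual classification
#' (e.g. structurally indistinguishable sibling classes) is preserved.
#'
#' @param satisfied Character vector of lipid class names.
#' @param ont A `lipid_ontology`.
#' @return Character vector (sorted) forming an antichain in the asserted
#'   hierarchy.
#' @export
prune_to_most_specific <- function(satisfied, ont) {
  stopifnot(inherits(ont, "lipid_ontology"))
  for (nm in satisfied) .check_lipid_class(ont, nm)
  satisfied <- unique(satisfied)
  ancestors <- unique(unlist(lapply(satisfied, function(nm)
    lipid_ancestors(ont, nm, strict = TRUE))))
  sort(setdiff(satisfied, ancestors))
}

#' Classify a profile against a lipid ontology
#'
#' Checks, for each named lipid class with a definition, whether the class
#' subsumes the molecule's closed-world description (evaluated as
#' [satisfies()]), prunes the satisfied set to the most specific classes,
#' and maps those to LIPID MAPS class ids and categories.
#'
#' @param profile An `fg_profile`.
#' @param ont A `lipid_ontology`.
#' @param lib A `pattern_library`.
#' @return An object of class `classification_result`: `uri`, `satisfied`
#'   (sorted character), `most_specific` (sorted character antichain), and
#'   `lm_classes` (data frame: `class`, `lm_id`, `category_code`,
#'   `category`, rows for mapped most-specific classes).
#' @examples
#' lib <- load_pattern_library()
#' ont <- load_ontology(lib = lib)
#' profile <- annotate("CCCCCC1OC1C=CC=CC=CCCCCCC(=O)O", lib)
#' classify(profile, ont, lib)
#' @export
classify <- function(profile, ont, lib) {
  stopifnot(inherits(profile, "fg_profile"), inherits(ont, "lipid_ontology"),
            inherits(lib, "pattern_library"))
  satisfied <- character(0)
  for (cls in ont$classes) {
    if (is.null(cls$definition)) next   # asserted-only nodes are never satisfied
    sat <- tryCatch(satisfies(profile, cls$definition, lib, ont),
                    error = function(e) {
                      stop(sprintf("evaluating class '%s': %s", cls$name,
                                   conditionMessage(e)), call. = FALSE)
                    })
    if (isTRUE(sat)) satisfied <- c(satisfied, cls$name)
  }
  satisfied <- sort(satisfied)
  most_specific <- prune_to_most_specific(satisfied, ont)

  lm <- do.call(rbind, lapply(most_specific, function(nm) {
    id <- lm_mapping(ont, nm)
    if (is.na(id)) return(NULL)
    cat_ <- lm_category(ont, id)
    data.frame(class = nm, lm_id = id, category_code = names(cat_),
               category = unname(cat_), stringsAsFactors = FALSE)
  }))
  if (is.null(lm)) {
    lm <- data.frame(class = character(0), lm_id = character(0),
                     category_code = character(0), category = character(0),
                     stringsAsFactors = FALSE)
  } else {
    lm <- lm[order(lm$lm_id, method = "radix"), , drop = FALSE]
    rownames(lm) <- NULL
  }

  structure(list(uri = profile$molecule$uri, satisfied = satisfied,
                 most_specific = most_specific, lm_classes = lm),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s\n", x$uri))
  if (length(x$most_specific) == 0L) {
    cat("  no lipid class satisfied\n")
  } else {
    for (nm in x$most_specific) {
      row <- x$lm_classes[x$lm_classes$class == nm, ]
      lm <- if (nrow(row)) sprintf(" [%s, %s]", row$lm_id, row$category) else ""
      cat(sprintf("  %s%s\n", nm, lm))
    }
    pruned <- setdiff(x$satisfied, x$most_specific)
    if (length(pruned)) {
      cat("  (pruned superclasses:", paste(pruned, collapse = ", "), ")\n")
    }
  }
  invisible(x)
}

#' Tabular form of classification results
#'
#' One row per molecule: uri, semicolon-joined most-specific classes, their
#' LIPID MAPS ids and the category codes.
#'
#' @param results A list of `classification_result` objects.
#' @return A data frame with columns `uri`, `lipro_classes`, `lm_ids`,
#'   `categories`.
#' @export
classification_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      uri = r$uri,
      lipro_classes = paste(r$most_specific, collapse = ";"),
      lm_ids = paste(r$lm_classes$lm_id, collapse = ";"),
      categories = paste(unique(r$lm_classes$category_code), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
}
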