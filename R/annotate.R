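# Functional-group annotation: from a SMILES to a closed-world profile of
# unique, non-overlapping substructure occurrences.

#' Select a maximum set of pairwise atom-disjoint matches
#'
#' From a deduplicated list of match atom sets, keeps a maximum-cardinality
#' subset of pairwise disjoint sets.  For up to `exact_limit` matches the
#' maximum independent set of the overlap graph is computed exactly by
#' branch-and-bound; beyond that a greedy pass in ascending
#' sorted-atom-index order is used.  Ties are broken by preferring the
#' lexicographically smallest sorted index sequences, so the output is
#' deterministic.
#'
#' @param matches List of sorted integer vectors (as from [find_matches()]).
#' @param exact_limit Largest match count for which the exact search runs.
#' @return A sublist of `matches`, in canonical (lexicographic) order.
#' @examples
#' select_disjoint(list(c(1, 2), c(2, 3), c(3, 4)))
#' @export
select_disjoint <- function(matches, exact_limit = 20L) {
  n <- length(matches)
  if (n <= 1L) return(matches)
  matches <- matches[.order_sets(matches)]

  overlap <- matrix(FALSE, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      if (length(intersect(matches[[a]], matches[[b]])) > 0L) {
        overlap[a, b] <- overlap[b, a] <- TRUE
      }
    }
  }

  if (n <= exact_limit) {
    # depth-first over canonical order, include-before-exclude: the first
    # solution found at any size is the lexicographically smallest, so only
    # strictly larger solutions replace the incumbent
    best <- integer(0)
    recurse <- function(i, chosen) {
      if (length(chosen) + (n - i + 1L) <= length(best)) return(invisible(NULL))
      if (i > n) {
        if (length(chosen) > length(best)) best <<- chosen
        return(invisible(NULL))
      }
      if (!any(overlap[i, chosen])) recurse(i + 1L, c(chosen, i))
      recurse(i + 1L, chosen)
      invisible(NULL)
    }
    recurse(1L, integer(0))
    matches[best]
  } else {
    chosen <- integer(0)
    for (i in seq_len(n)) {
      if (!any(overlap[i, chosen])) chosen <- c(chosen, i)
    }
    matches[chosen]
  }
}

#' Annotate a molecule with functional-group occurrences
#'
#' Runs every library pattern over the molecule, keeps unique (deduplicated
#' by atom set) and non-overlapping (maximum pairwise-disjoint within each
#' pattern) occurrences, and assembles a closed-world functional-group
#' profile: the profile asserts that these are all the functional-group
#' parts of the molecule and that all occurrences are mutually distinct
#' individuals.  For a ubiquitous class, at most one witness occurrence is
#' emitted and its count is flagged inexact (a lower bound).
#'
#' @param record A molecule: either a single SMILES string, or a list/row
#'   with `uri` and `smiles` (see [read_molecule_rdf()]).
#' @param lib A `pattern_library`.
#' @return An object of class `fg_profile`: `molecule` (list with `uri`,
#'   `smiles`), `occurrences` (data frame: `pattern_id`, `group_class`,
#'   `atoms` list-column of 1-based atom index vectors), `counts` (named
#'   integer per present class), `exact` (named logical; `FALSE` for
#'   ubiquitous classes).
#' @examples
#' lib <- load_pattern_library()
#' annotate("CCO", lib)$counts
#' @export
annotate <- function(record, lib) {
  stopifnot(inherits(lib, "pattern_library"))
  if (is.character(record) && length(record) == 1L) {
    record <- list(uri = paste0("urn:smiles:", record), smiles = record)
  }
  if (is.null(record$smiles)) stop("'record' must carry a smiles field")
  mol <- parse_molecule(record$smiles)

  occ_pattern <- character(0)
  occ_class <- character(0)
  occ_atoms <- list()
  ubiq_seen <- character(0)

  for (pat in lib$patterns) {
    ubiq <- is_ubiquitous(lib, pat$class)
    if (ubiq && pat$class %in% ubiq_seen) next
    matches <- find_matches(mol, pat)
    if (length(matches) == 0L) next
    if (ubiq) {
      keep <- matches[1]
      ubiq_seen <- c(ubiq_seen, pat$class)
    } else {
      keep <- select_disjoint(matches)
    }
    for (m in keep) {
      occ_pattern <- c(occ_pattern, pat$id)
      occ_class <- c(occ_class, pat$class)
      occ_atoms <- c(occ_atoms, list(m))
    }
  }

  present <- sort(unique(occ_class))
  counts <- vapply(present, function(cl) sum(occ_class == cl), integer(1))
  exact <- !vapply(present, function(cl) is_ubiquitous(lib, cl), logical(1))
  names(counts) <- names(exact) <- present

  structure(list(
    molecule = list(uri = record$uri %||% paste0("urn:smiles:", record$smiles),
                    smiles = record$smiles),
    occurrences = .occurrence_frame(occ_pattern, occ_class, occ_atoms),
    counts = counts,
    exact = exact
  ), class = "fg_profile")
}

.occurrence_frame <- function(pattern_id, group_class, atoms) {
  df <- data.frame(pattern_id = as.character(pattern_id),
                   group_class = as.character(group_class),
                   stringsAsFactors = FALSE)
  df$atoms <- atoms
  df
}

#' Build a profile directly from class counts
#'
#' Constructs an `fg_profile` without a molecule, for desk checks of class
#' definitions (e.g. testing a printed class expression against a stated
#' functional-group inventory).  Occurrences get synthetic singleton atom
#' sets, pairwise disjoint.
#'
#' @param counts Named integer vector: occurrences per functional-group
#'   class.
#' @param lib A `pattern_library`; determines which classes are ubiquitous
#'   (their counts are capped at one and flagged inexact).
#' @param uri Identifier for the synthetic profile.
#' @return An `fg_profile`.
#' @examples
#' lib <- load_pattern_library()
#' profile_from_counts(c(Alkenyl_Group = 3, Carboxylic_Acid = 1), lib)
#' @export
profile_from_counts <- function(counts, lib, uri = "urn:profile:manual") {
  stopifnot(inherits(lib, "pattern_library"), length(counts) > 0 || TRUE)
  if (length(counts) && is.null(names(counts))) {
    stop("'counts' must be a named vector of class counts")
  }
  counts <- counts[counts > 0]
  occ_class <- character(0)
  occ_atoms <- list()
  next_atom <- 1L
  for (cl in names(counts)) {
    .check_class(lib, cl)
    k <- if (is_ubiquitous(lib, cl)) 1L else as.integer(counts[[cl]])
    for (i in seq_len(k)) {
      occ_class <- c(occ_class, cl)
      occ_atoms <- c(occ_atoms, list(next_atom))
      next_atom <- next_atom + 1L
    }
  }
  present <- sort(unique(occ_class))
  cnt <- vapply(present, function(cl) sum(occ_class == cl), integer(1))
  exact <- !vapply(present, function(cl) is_ubiquitous(lib, cl), logical(1))
  names(cnt) <- names(exact) <- present
  structure(list(
    molecule = list(uri = uri, smiles = NA_character_),
    occurrences = .occurrence_frame(sprintf("manual_%d", seq_along(occ_class)),
                                    occ_class, occ_atoms),
    counts = cnt,
    exact = exact
  ), class = "fg_profile")
}

#' @export
print.fg_profile <- function(x, ...) {
  cat(sprintf("<fg_profile> %s\n", x$molecule$uri))
  if (length(x$counts) == 0L) {
    cat("  (no functional groups)\n")
  } else {
    for (cl in names(x$counts)) {
      cat(sprintf("  %-28s %s%d\n", cl,
                  if (x$exact[[cl]]) "" else ">= ", x$counts[[cl]]))
    }
  }
  invisible(x)
}
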