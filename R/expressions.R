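# Lipid class definitions as expression trees over the 'has proper part'
# relation, and their closed-world evaluation against functional-group
# profiles.
#
# A definition is an intersection of restrictions:
#   part exactly N <Class>     exactly N parts of that type
#   part min N <Class>         at least N parts
#   part some <Class>          at least one part
# where the restriction filler is a functional-group class name or a
# disjunction `(A or B or ...)`.  Because a profile is a fully specified,
# closed description of the molecule's parts (all occurrences listed, all
# mutually distinct), checking whether a class definition subsumes the
# molecule's anonymous description reduces to directly evaluating the
# definition's restrictions against the profile.

ce_named <- function(name) {
  structure(list(kind = "named", name = name), class = "class_expression")
}
ce_union <- function(members) {
  stopifnot(length(members) >= 1L)
  structure(list(kind = "union", members = members), class = "class_expression")
}
ce_intersection <- function(members) {
  stopifnot(length(members) >= 1L)
  structure(list(kind = "intersection", members = members),
            class = "class_expression")
}
ce_some <- function(filler) {
  structure(list(kind = "some", filler = filler), class = "class_expression")
}
ce_exactly <- function(n, filler) {
  stopifnot(is.numeric(n), n >= 0)
  structure(list(kind = "exactly", n = as.integer(n), filler = filler),
            class = "class_expression")
}
ce_min <- function(n, filler) {
  stopifnot(is.numeric(n), n >= 0)
  structure(list(kind = "min", n = as.integer(n), filler = filler),
            class = "class_expression")
}

.tokenize_expression <- function(text) {
  pat <- "'[^']*'|\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(text, gregexpr(pat, text))[[1]]
}

.unquote_name <- function(tok) {
  if (startsWith(tok, "'") && endsWith(tok, "'")) {
    substr(tok, 2, nchar(tok) - 1L)
  } else tok
}

#' Parse a lipid class definition expression
#'
#' Grammar (keywords are case-sensitive; class names may be single-quoted):
#' \preformatted{
#'   expr   := term ("and" term)*
#'   term   := "part" "exactly" INT filler
#'           | "part" "min" INT filler
#'           | "part" "some" filler
#'           | NAME                     # a named lipid class
#'   filler := NAME | "(" NAME ("or" NAME)+ ")"
#' }
#' Parsing round-trips through [format_expression()].
#'
#' @param text Definition string.
#' @return A `class_expression`.
#' @examples
#' parse_expression("part some (Alcohol or Hydroperoxide or Peroxide)")
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .tokenize_expression(text)
  if (length(toks) == 0L) stop("empty class expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  err <- function(msg) {
    stop(sprintf("class expression syntax error at token %d ('%s'): %s",
                 pos, peek(), msg))
  }

  parse_filler <- function() {
    if (peek() == "(") {
      take()
      members <- list(ce_named(.unquote_name(take())))
      while (peek() == "or") {
        take()
        members <- c(members, list(ce_named(.unquote_name(take()))))
      }
      if (peek() != ")") err("expected 'or' or ')' in disjunctive filler")
      take()
      if (length(members) == 1L) members[[1]] else ce_union(members)
    } else if (nzchar(peek()) && !(peek() %in% c("and", "part", ")"))) {
      ce_named(.unquote_name(take()))
    } else err("expected a class name or '(' filler")
  }

  parse_term <- function() {
    if (peek() == "part") {
      take()
      op <- take()
      if (op == "some") {
        ce_some(parse_filler())
      } else if (op %in% c("exactly", "min")) {
        ntok <- take()
        n <- suppressWarnings(as.integer(ntok))
        if (is.na(n) || !grepl("^[0-9]+$", ntok)) {
          err(sprintf("'%s' requires a non-negative integer", op))
        }
        if (op == "exactly") ce_exactly(n, parse_filler())
        else ce_min(n, parse_filler())
      } else err(sprintf("unknown restriction operator '%s'", op))
    } else if (nzchar(peek()) && !(peek() %in% c("and", "(", ")"))) {
      ce_named(.unquote_name(take()))
    } else err("expected 'part' restriction or class name")
  }

  members <- list(parse_term())
  while (peek() == "and") {
    take()
    members <- c(members, list(parse_term()))
  }
  if (pos <= length(toks)) err("unexpected trailing tokens")
  if (length(members) == 1L) members[[1]] else ce_intersection(members)
}

.format_name <- function(name) {
  if (grepl("^[A-Za-z0-9_]+$", name)) name else paste0("'", name, "'")
}

#' Print a class expression back to its concrete syntax
#'
#' @param expr A `class_expression`.
#' @return A single string; `parse_expression(format_expression(e))` is
#'   structurally equal to `e`.
#' @export
format_expression <- function(expr) {
  stopifnot(inherits(expr, "class_expression"))
  filler_str <- function(f) {
    if (f$kind == "named") .format_name(f$name)
    else paste0("(", paste(vapply(f$members, function(m)
      .format_name(m$name), character(1)), collapse = " or "), ")")
  }
  switch(expr$kind,
    named = .format_name(expr$name),
    some = paste("part some", filler_str(expr$filler)),
    exactly = paste("part exactly", expr$n, filler_str(expr$filler)),
    min = paste("part min", expr$n, filler_str(expr$filler)),
    intersection = paste(vapply(expr$members, format_expression, character(1)),
                         collapse = " and "),
    union = filler_str(expr),
    stop("unknown expression kind")
  )
}

#' @export
print.class_expression <- function(x, ...) {
  cat("<class_expression>", format_expression(x), "\n")
  invisible(x)
}

.filler_members <- function(filler) {
  if (filler$kind == "named") filler$name
  else if (filler$kind == "union") {
    vapply(filler$members, function(m) {
      if (m$kind != "named") stop("restriction fillers must be class names or disjunctions of class names")
      m$name
    }, character(1))
  } else stop("restriction fillers must be class names or disjunctions of class names")
}

#' Count a profile's instances of a restriction filler
#'
#' Hierarchy-aware counting: an occurrence counts towards a filler if its
#' group class lies in the reflexive-transitive subclass closure of any
#' filler member.  The count is exact unless the closure contains a
#' ubiquitous library class, in which case it is only a lower bound
#' (ubiquitous occurrences are single witnesses).
#'
#' @param profile An `fg_profile`.
#' @param filler A `class_expression` of kind named or union-of-named.
#' @param lib A `pattern_library`.
#' @return A list with `count` (integer) and `exact` (logical).
#' @export
count_instances <- function(profile, filler, lib) {
  stopifnot(inherits(profile, "fg_profile"), inherits(lib, "pattern_library"))
  members <- .filler_members(filler)
  closure <- unique(unlist(lapply(members, function(m) subclasses_of(lib, m))))
  cnt <- sum(profile$occurrences$group_class %in% closure)
  exact <- !any(vapply(closure, function(cl) is_ubiquitous(lib, cl), logical(1)))
  list(count = as.integer(cnt), exact = exact)
}

#' Closed-world satisfaction of a class expression by a profile
#'
#' Evaluates whether the molecule described by the profile is an instance of
#' the expression, under the closed-world reading of the profile (its
#' occurrences are all the functional-group parts and are mutually
#' distinct).  For fully specified individuals this is equivalent to asking
#' a description-logic reasoner whether the class subsumes the molecule's
#' anonymous class expression.
#'
#' @param profile An `fg_profile`.
#' @param expr A `class_expression`.
#' @param lib A `pattern_library`.
#' @param ont Optionally a `lipid_ontology`, needed to resolve named lipid
#'   classes appearing as expressions.
#' @return Logical.  Exact-cardinality restrictions over fillers whose
#'   subclass closure contains a ubiquitous class raise an error: their
#'   counts are lower bounds, so equality is undecidable.
#' @examples
#' lib <- load_pattern_library()
#' p <- profile_from_counts(c(Alkenyl_Group = 3, Carboxylic_Acid = 1), lib)
#' satisfies(p, parse_expression("part exactly 3 Alkenyl_Group"), lib)
#' @export
satisfies <- function(profile, expr, lib, ont = NULL) {
  stopifnot(inherits(profile, "fg_profile"), inherits(expr, "class_expression"))
  switch(expr$kind,
    intersection = all(vapply(expr$members, function(m)
      satisfies(profile, m, lib, ont), logical(1))),
    some = count_instances(profile, expr$filler, lib)$count >= 1L,
    min = count_instances(profile, expr$filler, lib)$count >= expr$n,
    exactly = {
      ci <- count_instances(profile, expr$filler, lib)
      if (!ci$exact) {
        stop(sprintf(
          "exact cardinality over ubiquitous class: 'part exactly %d %s' is undecidable (count is a lower bound)",
          expr$n, format_expression(expr$filler)))
      }
      ci$count == expr$n
    },
    named = {
      if (is.null(ont)) {
        stop(sprintf("named class '%s' cannot be evaluated without an ontology",
                     expr$name))
      }
      def <- ont$classes[[expr$name]]$definition
      if (is.null(def)) {
        stop(sprintf("lipid class '%s' has no definition", expr$name))
      }
      satisfies(profile, def, lib, ont)
    },
    union = any(vapply(expr$members, function(m)
      satisfies(profile, m, lib, ont), logical(1))),
    stop("unknown expression kind")
  )
}

#' Brute-force satisfaction oracle over the explicit finite model
#'
#' Independent reference implementation of [satisfies()]: materializes one
#' individual per occurrence, types it with its group class and all asserted
#' superclasses, and checks each restriction by direct set comprehension
#' over the individuals.  Used by the test suite to validate the evaluator;
#' must agree with [satisfies()] on all supported inputs.
#'
#' @inheritParams satisfies
#' @return Logical.
#' @export
oracle_satisfies <- function(profile, expr, lib, ont = NULL) {
  stopifnot(inherits(profile, "fg_profile"), inherits(expr, "class_expression"))
  individuals <- lapply(profile$occurrences$group_class, function(cl)
    superclasses_of(lib, cl))

  n_instances <- function(filler) {
    members <- .filler_members(filler)
    for (m in members) .check_class(lib, m)
    sum(vapply(individuals, function(types)
      any(members %in% types), logical(1)))
  }
  filler_touches_ubiquitous <- function(filler) {
    members <- .filler_members(filler)
    ub <- lib$classes$name[lib$classes$ubiquitous]
    any(vapply(ub, function(u)
      any(members %in% superclasses_of(lib, u)), logical(1)))
  }

  switch(expr$kind,
    intersection = all(vapply(expr$members, function(m)
      oracle_satisfies(profile, m, lib, ont), logical(1))),
    some = n_instances(expr$filler) >= 1L,
    min = n_instances(expr$filler) >= expr$n,
    exactly = {
      if (filler_touches_ubiquitous(expr$filler)) {
        stop(sprintf(
          "exact cardinality over ubiquitous class: 'part exactly %d %s' is undecidable (count is a lower bound)",
          expr$n, format_expression(expr$filler)))
      }
      n_instances(expr$filler) == expr$n
    },
    named = {
      if (is.null(ont)) {
        stop(sprintf("named class '%s' cannot be evaluated without an ontology",
                     expr$name))
      }
      def <- ont$classes[[expr$name]]$definition
      if (is.null(def)) {
        stop(sprintf("lipid class '%s' has no definition", expr$name))
      }
      oracle_satisfies(profile, def, lib, ont)
    },
    union = any(vapply(expr$members, function(m)
      oracle_satisfies(profile, m, lib, ont), logical(1))),
    stop("unknown expression kind")
  )
}
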