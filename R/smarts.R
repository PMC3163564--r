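# A compiler and matcher for the SMARTS subset used by the functional-group
# pattern library.
#
# Supported syntax: bare atoms (C N O S P B F I Cl Br, lowercase aromatic
# c n o s p, wildcard *), bracket atoms with primitives #<z>, element symbols,
# a/A (aromatic/aliphatic), X<n> (total connectivity), H<n> (total hydrogen
# count), D<n> (heavy-atom degree), R/R0/R<n> (ring membership), +/- (formal
# charge), combined with ! (not), & or juxtaposition (and), , (or) and ;
# (low-precedence and); bonds - = # : ~ (/ and \ are treated as single);
# branches in parentheses; ring-closure digits and %nn.  Recursive SMARTS
# ($(...)), isotopes and atom maps are not supported and raise an error at
# compile time.  Matching is constitution-only: stereo bond symbols are
# accepted but carry no constraint.

#' Compile a SMARTS pattern
#'
#' Parses a SMARTS string (see the package vignette for the exact supported
#' subset) into a query graph usable by [find_matches()].
#'
#' @param smarts A single SMARTS string.
#' @return An object of class `smarts_pattern`.
#' @examples
#' compile_smarts("[OX2H1][CX4]")
#' @export
compile_smarts <- function(smarts) {
  if (!is.character(smarts) || length(smarts) != 1L || !nzchar(smarts)) {
    stop("'smarts' must be a single non-empty string")
  }
  st <- new.env(parent = emptyenv())
  st$s <- strsplit(smarts, "")[[1]]
  st$pos <- 1L
  st$atoms <- list()
  st$bonds <- list()      # list(i, j, spec)
  st$prev <- NA_integer_
  st$stack <- integer(0)
  st$pending_bond <- NULL
  st$ring <- list()       # closure label -> list(atom, spec)

  err <- function(msg) {
    stop(sprintf("invalid SMARTS '%s' at position %d: %s", smarts, st$pos, msg))
  }
  peek <- function() if (st$pos <= length(st$s)) st$s[st$pos] else ""
  take <- function() { ch <- peek(); st$pos <- st$pos + 1L; ch }
  take_digits <- function() {
    d <- ""
    while (grepl("^[0-9]$", peek())) d <- paste0(d, take())
    d
  }

  add_atom <- function(expr) {
    st$atoms[[length(st$atoms) + 1L]] <- expr
    idx <- length(st$atoms)
    if (!is.na(st$prev)) {
      spec <- if (is.null(st$pending_bond)) "default" else st$pending_bond
      st$bonds[[length(st$bonds) + 1L]] <- list(i = st$prev, j = idx, spec = spec)
    }
    st$pending_bond <- NULL
    st$prev <- idx
  }

  close_ring <- function(label) {
    spec <- if (is.null(st$pending_bond)) "default" else st$pending_bond
    st$pending_bond <- NULL
    if (is.na(st$prev)) err("ring closure before any atom")
    open <- st$ring[[label]]
    if (is.null(open)) {
      st$ring[[label]] <- list(atom = st$prev, spec = spec)
    } else {
      sp <- if (spec != "default") spec else open$spec
      st$bonds[[length(st$bonds) + 1L]] <-
        list(i = open$atom, j = st$prev, spec = sp)
      st$ring[[label]] <- NULL
    }
  }

  prim_elem <- function(sym, aromatic) {
    z <- .element_z[[sym]]
    if (is.null(z)) err(sprintf("unknown element '%s'", sym))
    list(op = "prim", kind = "elem", z = z, arom = aromatic)
  }

  # bracket-atom expression, precedence (low to high): ';'  ','  '&'  '!'
  parse_bracket <- function() {
    parse_semi <- function() {
      x <- parse_comma()
      while (peek() == ";") { take(); x <- list(op = "and", a = x, b = parse_comma()) }
      x
    }
    parse_comma <- function() {
      x <- parse_amp()
      while (peek() == ",") { take(); x <- list(op = "or", a = x, b = parse_amp()) }
      x
    }
    starts_unary <- function() {
      ch <- peek()
      ch %in% c("!", "#", "*", "a", "A", "X", "H", "D", "R", "+", "-") ||
        grepl("^[A-Za-z]$", ch)
    }
    parse_amp <- function() {
      x <- parse_unary()
      repeat {
        if (peek() == "&") { take(); x <- list(op = "and", a = x, b = parse_unary()) }
        else if (starts_unary()) x <- list(op = "and", a = x, b = parse_unary())
        else break
      }
      x
    }
    parse_unary <- function() {
      ch <- peek()
      if (ch == "!") { take(); return(list(op = "not", a = parse_unary())) }
      if (ch == "$") err("recursive SMARTS '$(...)' is not supported")
      if (ch == "#") {
        take()
        d <- take_digits()
        if (!nzchar(d)) err("'#' must be followed by an atomic number")
        return(list(op = "prim", kind = "elem", z = as.integer(d), arom = NA))
      }
      if (ch == "*") { take(); return(list(op = "prim", kind = "any")) }
      if (ch == "a") { take(); return(list(op = "prim", kind = "arom")) }
      if (ch == "A") { take(); return(list(op = "prim", kind = "aliph")) }
      if (ch %in% c("X", "D", "H")) {
        take()
        d <- take_digits()
        n <- if (nzchar(d)) as.integer(d) else 1L
        return(list(op = "prim", kind = ch, n = n))
      }
      if (ch == "R") {
        take()
        d <- take_digits()
        flag <- !(nzchar(d) && as.integer(d) == 0L)
        return(list(op = "prim", kind = "ring", flag = flag))
      }
      if (ch %in% c("+", "-")) {
        take()
        d <- take_digits()
        q <- if (nzchar(d)) as.integer(d) else 1L
        if (ch == "-") q <- -q
        return(list(op = "prim", kind = "charge", q = q))
      }
      two <- paste0(ch, if (st$pos + 1L <= length(st$s)) st$s[st$pos + 1L] else "")
      if (two %in% c("Cl", "Br")) { take(); take(); return(prim_elem(two, FALSE)) }
      if (grepl("^[A-Z]$", ch)) { take(); return(prim_elem(ch, FALSE)) }
      if (grepl("^[a-z]$", ch)) { take(); return(prim_elem(toupper(ch), TRUE)) }
      err(sprintf("unexpected character '%s' in bracket atom", ch))
    }
    x <- parse_semi()
    if (peek() != "]") err("expected ']'")
    take()
    x
  }

  while (st$pos <= length(st$s)) {
    ch <- peek()
    if (ch == "[") {
      take()
      add_atom(parse_bracket())
    } else if (ch == "(") {
      take()
      if (is.na(st$prev)) err("branch before any atom")
      st$stack <- c(st$stack, st$prev)
    } else if (ch == ")") {
      take()
      if (length(st$stack) == 0L) err("unmatched ')'")
      st$prev <- st$stack[length(st$stack)]
      st$stack <- st$stack[-length(st$stack)]
    } else if (ch %in% c("-", "/", "\\")) {
      take(); st$pending_bond <- "single"
    } else if (ch == "=") {
      take(); st$pending_bond <- "double"
    } else if (ch == "#") {
      take(); st$pending_bond <- "triple"
    } else if (ch == ":") {
      take(); st$pending_bond <- "arom"
    } else if (ch == "~") {
      take(); st$pending_bond <- "any"
    } else if (grepl("^[0-9]$", ch)) {
      take(); close_ring(ch)
    } else if (ch == "%") {
      take()
      lab <- paste0(take(), take())
      if (!grepl("^[0-9][0-9]$", lab)) err("'%' must be followed by two digits")
      close_ring(lab)
    } else {
      two <- paste0(ch, if (st$pos + 1L <= length(st$s)) st$s[st$pos + 1L] else "")
      if (two %in% c("Cl", "Br")) {
        take(); take(); add_atom(prim_elem(two, FALSE))
      } else if (grepl("^[BCNOSPFI]$", ch)) {
        take(); add_atom(prim_elem(ch, FALSE))
      } else if (grepl("^[cnosp]$", ch)) {
        take(); add_atom(prim_elem(toupper(ch), TRUE))
      } else if (ch == "*") {
        take(); add_atom(list(op = "prim", kind = "any"))
      } else {
        err(sprintf("unexpected character '%s'", ch))
      }
    }
  }
  if (length(st$ring) > 0L) err("unclosed ring bond")
  if (length(st$stack) > 0L) err("unclosed branch")
  if (length(st$atoms) == 0L) err("no atoms")

  np <- length(st$atoms)
  bonds <- if (length(st$bonds)) {
    data.frame(
      i = vapply(st$bonds, `[[`, integer(1), "i"),
      j = vapply(st$bonds, `[[`, integer(1), "j"),
      spec = vapply(st$bonds, `[[`, character(1), "spec"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(i = integer(0), j = integer(0), spec = character(0))
  }
  # matching order: BFS from atom 1; patterns must be connected
  padj <- vector("list", np)
  for (k in seq_len(nrow(bonds))) {
    padj[[bonds$i[k]]] <- c(padj[[bonds$i[k]]], bonds$j[k])
    padj[[bonds$j[k]]] <- c(padj[[bonds$j[k]]], bonds$i[k])
  }
  seen <- logical(np); seen[1] <- TRUE; ord <- 1L; queue <- 1L
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nx in padj[[cur]]) if (!seen[nx]) {
      seen[nx] <- TRUE; ord <- c(ord, nx); queue <- c(queue, nx)
    }
  }
  if (!all(seen)) err("disconnected SMARTS patterns are not supported")

  structure(list(smarts = smarts, atoms = st$atoms, bonds = bonds,
                 natoms = np, order = ord, adj = padj),
            class = "smarts_pattern")
}

#' @export
print.smarts_pattern <- function(x, ...) {
  cat(sprintf("<smarts_pattern> %s (%d atoms, %d bonds)\n",
              x$smarts, x$natoms, nrow(x$bonds)))
  invisible(x)
}

.eval_atom_expr <- function(expr, atoms, ai) {
  switch(expr$op,
    and = .eval_atom_expr(expr$a, atoms, ai) && .eval_atom_expr(expr$b, atoms, ai),
    or  = .eval_atom_expr(expr$a, atoms, ai) || .eval_atom_expr(expr$b, atoms, ai),
    not = !.eval_atom_expr(expr$a, atoms, ai),
    prim = switch(expr$kind,
      any    = TRUE,
      arom   = atoms$aromatic[ai],
      aliph  = !atoms$aromatic[ai],
      elem   = atoms$Z[ai] == expr$z &&
               (is.na(expr$arom) || atoms$aromatic[ai] == expr$arom),
      X      = atoms$X[ai] == expr$n,
      D      = atoms$degree[ai] == expr$n,
      H      = atoms$nH[ai] == expr$n,
      ring   = atoms$in_ring[ai] == expr$flag,
      charge = expr$q == 0L,   # formal charges are not modelled; atoms neutral
      stop("unknown primitive kind")
    ),
    stop("unknown expression op")
  )
}

.eval_bond_spec <- function(spec, order, aromatic) {
  switch(spec,
    default = aromatic || order == 1,
    single  = !aromatic && order == 1,
    double  = !aromatic && order == 2,
    triple  = order == 3,
    arom    = aromatic,
    any     = TRUE,
    stop("unknown bond spec")
  )
}

# order a list of sorted integer vectors lexicographically
.order_sets <- function(sets) {
  if (length(sets) <= 1L) return(seq_along(sets))
  keys <- vapply(sets, function(v) paste(sprintf("%08d", v), collapse = ","),
                 character(1))
  order(keys, method = "radix")
}

#' Find all unique matches of a pattern in a molecule
#'
#' Enumerates every embedding of the pattern's query graph in the molecular
#' graph by backtracking subgraph-isomorphism search, then deduplicates by
#' matched atom set: symmetric (automorphic) embeddings hitting the same
#' atoms count once.  The result is deterministically ordered by the sorted
#' atom-index sequences.
#'
#' @param mol A `molecule_graph` from [parse_molecule()].
#' @param pattern A SMARTS string, a compiled `smarts_pattern`, or a pattern
#'   record from a [load_pattern_library()] library.
#' @return A list of sorted integer vectors of 1-based atom indices.
#' @examples
#' find_matches(parse_molecule("C=CC=C"), "C=C")
#' @export
find_matches <- function(mol, pattern) {
  stopifnot(inherits(mol, "molecule_graph"))
  pat <- if (inherits(pattern, "smarts_pattern")) pattern
         else if (is.character(pattern)) compile_smarts(pattern)
         else if (is.list(pattern) && inherits(pattern$compiled, "smarts_pattern"))
           pattern$compiled
         else stop("'pattern' must be a SMARTS string or compiled pattern")

  n <- mol$natoms
  np <- pat$natoms
  if (np > n) return(list())
  atoms <- mol$atoms

  # per-pattern-atom candidate mask
  ok <- matrix(FALSE, nrow = np, ncol = n)
  for (p in seq_len(np)) {
    for (a in seq_len(n)) ok[p, a] <- .eval_atom_expr(pat$atoms[[p]], atoms, a)
  }
  if (any(rowSums(ok) == 0)) return(list())

  # molecule bond lookup
  bond_idx <- matrix(0L, n, n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      bond_idx[mol$bonds$i[k], mol$bonds$j[k]] <- k
      bond_idx[mol$bonds$j[k], mol$bonds$i[k]] <- k
    }
  }
  # pattern edges anchored to earlier atoms in matching order
  pos_in_order <- match(seq_len(np), pat$order)
  anchors <- vector("list", np)   # by order step: data.frame(other, spec)
  for (k in seq_len(nrow(pat$bonds))) {
    i <- pat$bonds$i[k]; j <- pat$bonds$j[k]; spec <- pat$bonds$spec[k]
    later <- if (pos_in_order[i] > pos_in_order[j]) i else j
    earlier <- if (later == i) j else i
    step <- pos_in_order[later]
    anchors[[step]] <- rbind(anchors[[step]],
                             data.frame(other = earlier, spec = spec,
                                        stringsAsFactors = FALSE))
  }

  asn <- integer(np)
  used <- logical(n)
  found <- new.env(parent = emptyenv())
  found$sets <- list()
  found$seen <- character(0)

  recurse <- function(step) {
    if (step > np) {
      s <- sort(asn)
      key <- paste(s, collapse = ",")
      if (!(key %in% found$seen)) {
        found$seen <- c(found$seen, key)
        found$sets[[length(found$sets) + 1L]] <- s
      }
      return(invisible(NULL))
    }
    p <- pat$order[step]
    anc <- anchors[[step]]
    cands <- if (is.null(anc)) seq_len(n)
             else mol$adj[[asn[anc$other[1]]]]
    for (a in cands) {
      if (used[a] || !ok[p, a]) next
      fine <- TRUE
      if (!is.null(anc)) {
        for (r in seq_len(nrow(anc))) {
          b <- bond_idx[a, asn[anc$other[r]]]
          if (b == 0L ||
              !.eval_bond_spec(anc$spec[r], mol$bonds$order[b],
                               mol$bonds$aromatic[b])) { fine <- FALSE; break }
        }
      }
      if (!fine) next
      asn[p] <<- a
      used[a] <<- TRUE
      recurse(step + 1L)
      used[a] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)
  found$sets[.order_sets(found$sets)]
}
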