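# Turtle RDF input and output in the SIO vocabulary.
#
# A molecule arrives as a subject linked through 'has attribute'
# (sio:SIO_000008) to a SMILES descriptor node typed sio:CHEMINF_000018
# whose string value hangs off 'has value' (sio:SIO_000300).  Annotation
# output links the molecule to one blank node per functional-group
# occurrence through 'has proper part' (sio:SIO_000053); classification
# output uses ont:lipidHasLiProClass and lmo:lipidHasLMClass, with each
# LIPID MAPS class node carrying an identifier attribute (sio:SIO_000115
# node with a literal value).
#
# The reader/writer handle the Turtle subset these documents use: @prefix
# declarations, IRIs, prefixed names, quoted literals, 'a', blank nodes in
# square brackets, and ';'/',' lists.  This is not a general Turtle parser.

#' SIO vocabulary constants and namespace prefixes
#'
#' The single place all emitted IRIs come from.  The undeclared "sios:"
#' prefix occasionally seen in input documents is read as "sio:".
#'
#' @return A list with `prefixes` (named character of namespace IRIs) and
#'   `terms` (named character of CURIEs).
#' @export
leo_vocab <- function() {
  list(
    prefixes = c(
      lipro = "http://example.org/lipro#",
      lmo   = "http://example.org/lmo#",
      ont   = "http://example.org/ont#",
      rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
      sio   = "http://semanticscience.org/resource/",
      ss    = "http://semanticscience.org/"
    ),
    terms = c(
      has_attribute      = "sio:SIO_000008",
      has_value          = "sio:SIO_000300",
      has_proper_part    = "sio:SIO_000053",
      identifier         = "sio:SIO_000115",
      smiles_descriptor  = "sio:CHEMINF_000018",
      rdf_type           = "rdf:type",
      class_predicate    = "ont:lipidHasLiProClass",
      lm_class_predicate = "lmo:lipidHasLMClass"
    )
  )
}

.expand_curie <- function(curie, prefixes) {
  parts <- strsplit(curie, ":", fixed = TRUE)[[1]]
  paste0(prefixes[[parts[1]]], paste(parts[-1], collapse = ":"))
}

.tokenize_turtle <- function(text) {
  toks <- character(0)
  s <- strsplit(text, "")[[1]]
  i <- 1L
  n <- length(s)
  while (i <= n) {
    ch <- s[i]
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && s[i] != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i
      while (j <= n && s[j] != ">") j <- j + 1L
      if (j > n) stop("RDF syntax error: unterminated IRI")
      toks <- c(toks, paste(s[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == '"') {
      j <- i + 1L
      while (j <= n && !(s[j] == '"' && s[j - 1L] != "\\")) j <- j + 1L
      if (j > n) stop("RDF syntax error: unterminated literal")
      toks <- c(toks, paste(s[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch %in% c(".", ";", ",", "[", "]")) {
      toks <- c(toks, ch)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[[:space:]]$", s[j]) &&
             !(s[j] %in% c(";", ",", "[", "]", '"', "<")) &&
             !(s[j] == "." && (j == n || grepl("^[[:space:]]$|^$", s[j + 1L])))) {
        j <- j + 1L
      }
      toks <- c(toks, paste(s[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  toks
}

# Parse the supported Turtle subset into a triple data frame.
# Terms are returned as: <iri> expanded full IRIs wrapped in <>, _:bN blank
# ids, or bare literal strings (unquoted, unescaped).
.parse_turtle <- function(text) {
  toks <- .tokenize_turtle(text)
  prefixes <- character(0)
  triples <- list()
  blank_n <- 0L
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  err <- function(msg) stop(sprintf("RDF syntax error near token %d ('%s'): %s",
                                    pos, peek(), msg))

  resolve <- function(tok) {
    if (startsWith(tok, "<")) return(tok)
    if (startsWith(tok, '"')) {
      lit <- substr(tok, 2, nchar(tok) - 1L)
      return(gsub('\\\\"', '"', lit))
    }
    if (tok == "a") return("<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>")
    if (grepl(":", tok, fixed = TRUE)) {
      parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
      pfx <- parts[1]
      local <- paste(parts[-1], collapse = ":")
      ns <- prefixes[pfx]
      if (is.na(ns) && pfx == "sios") ns <- prefixes["sio"]  # listing misprint
      if (is.na(ns)) err(sprintf("undeclared prefix '%s'", pfx))
      return(paste0("<", unname(ns), local, ">"))
    }
    err(sprintf("unexpected term '%s'", tok))
  }

  emit <- function(s, p, o, is_literal) {
    triples[[length(triples) + 1L]] <<- list(s = s, p = p, o = o,
                                             literal = is_literal)
  }

  parse_object <- function() {
    if (peek() == "[") {
      take()
      blank_n <<- blank_n + 1L
      id <- sprintf("_:b%d", blank_n)
      if (peek() != "]") parse_predicate_list(id)
      if (take() != "]") err("expected ']'")
      list(term = id, literal = FALSE)
    } else {
      tok <- take()
      list(term = resolve(tok), literal = startsWith(tok, '"'))
    }
  }

  parse_predicate_list <- function(subject) {
    repeat {
      p <- resolve(take())
      repeat {
        o <- parse_object()
        emit(subject, p, o$term, o$literal)
        if (peek() == ",") { take(); next }
        break
      }
      if (peek() == ";") {
        take()
        if (peek() %in% c("]", ".")) break  # tolerate trailing ';'
        next
      }
      break
    }
  }

  while (pos <= length(toks)) {
    tok <- peek()
    if (tok %in% c("@prefix", "PREFIX")) {
      take()
      decl <- take()
      pfx <- sub(":$", "", decl)
      iri <- take()
      if (!startsWith(iri, "<")) err("expected IRI in @prefix")
      prefixes[pfx] <- substr(iri, 2, nchar(iri) - 1L)
      if (peek() == ".") take()
    } else if (tok == "[") {
      o <- parse_object()
      if (peek() != ".") parse_predicate_list(o$term)
      if (take() != ".") err("expected '.'")
    } else {
      subject <- resolve(take())
      parse_predicate_list(subject)
      if (take() != ".") err("expected '.'")
    }
  }

  if (length(triples) == 0L) {
    return(data.frame(s = character(0), p = character(0), o = character(0),
                      literal = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(
    s = vapply(triples, `[[`, character(1), "s"),
    p = vapply(triples, `[[`, character(1), "p"),
    o = vapply(triples, `[[`, character(1), "o"),
    literal = vapply(triples, `[[`, logical(1), "literal"),
    stringsAsFactors = FALSE
  )
}

.read_doc <- function(doc) {
  if (length(doc) == 1L && !grepl("\n", doc, fixed = TRUE) &&
      file.exists(doc)) {
    doc <- paste(readLines(doc, warn = FALSE), collapse = "\n")
  }
  paste(doc, collapse = "\n")
}

.term_iri <- function(name) {
  v <- leo_vocab()
  paste0("<", .expand_curie(v$terms[[name]], v$prefixes), ">")
}

#' Read molecules from a Turtle document
#'
#' Extracts one molecule record per subject carrying a SMILES descriptor:
#' a node typed `sio:CHEMINF_000018`, attached via `sio:SIO_000008`, with
#' its SMILES string under `sio:SIO_000300`.  Subjects without a SMILES
#' descriptor are ignored; a typed descriptor with no value is an error
#' naming the subject.
#'
#' @param doc Turtle text (character) or a file path.
#' @return A data frame with columns `uri` and `smiles`, in input order.
#' @export
read_molecule_rdf <- function(doc) {
  tr <- .parse_turtle(.read_doc(doc))
  type_p <- .term_iri("rdf_type")
  attr_p <- .term_iri("has_attribute")
  value_p <- .term_iri("has_value")
  smiles_t <- .term_iri("smiles_descriptor")

  descriptors <- tr$s[tr$p == type_p & tr$o == smiles_t]
  out_uri <- character(0)
  out_smiles <- character(0)
  for (k in which(tr$p == attr_p)) {
    d <- tr$o[k]
    if (!(d %in% descriptors)) next
    val <- tr$o[tr$s == d & tr$p == value_p & tr$literal]
    if (length(val) == 0L) {
      stop(sprintf("malformed record: SMILES descriptor of %s has no value",
                   tr$s[k]))
    }
    uri <- tr$s[k]
    uri <- sub("^<", "", sub(">$", "", uri))
    out_uri <- c(out_uri, uri)
    out_smiles <- c(out_smiles, val[1])
  }
  data.frame(uri = out_uri, smiles = out_smiles, stringsAsFactors = FALSE)
}

.prefix_block <- function(pfx_names) {
  v <- leo_vocab()
  pfx_names <- sort(pfx_names)
  vapply(pfx_names, function(p)
    sprintf("@prefix %s: <%s> .", p, v$prefixes[[p]]), character(1))
}

#' Write a functional-group annotation as Turtle
#'
#' Emits the molecule's SMILES descriptor (making the document
#' self-contained) and one `sio:SIO_000053` ('has proper part') blank node
#' per occurrence, typed with its functional-group class.  With
#' `entailed = TRUE` each blank node additionally carries rdf:type triples
#' for all asserted superclasses of its group class (so an Alcohol part is
#' also typed Hydroxy_Compound).
#'
#' @param profile An `fg_profile`.
#' @param entailed Also emit superclass types?  Requires `lib`.
#' @param lib A `pattern_library` (only needed when `entailed = TRUE`).
#' @param path Optional output file; when given, the document is written
#'   there.
#' @return The Turtle document as a single string (invisibly when `path`
#'   is given).
#' @export
write_annotation_rdf <- function(profile, entailed = FALSE, lib = NULL,
                                 path = NULL) {
  stopifnot(inherits(profile, "fg_profile"))
  if (entailed && is.null(lib)) {
    stop("'lib' is required for entailed superclass typing")
  }
  v <- leo_vocab()
  lines <- .prefix_block(c("lipro", "sio"))
  uri <- sprintf("<%s>", profile$molecule$uri)
  body <- character(0)
  if (!is.na(profile$molecule$smiles)) {
    body <- c(body,
              sprintf("%s %s [ a %s ; %s \"%s\" ]", uri,
                      v$terms[["has_attribute"]],
                      v$terms[["smiles_descriptor"]],
                      v$terms[["has_value"]],
                      gsub('"', '\\\\"', profile$molecule$smiles)))
  }
  occ <- profile$occurrences
  if (nrow(occ) > 0L) {
    key <- vapply(seq_len(nrow(occ)), function(i)
      paste(occ$group_class[i], occ$pattern_id[i],
            paste(occ$atoms[[i]], collapse = "-")), character(1))
    for (i in order(key, method = "radix")) {
      types <- occ$group_class[i]
      if (entailed) {
        sup <- setdiff(superclasses_of(lib, types), types)
        types <- c(types, sort(sup))
      }
      body <- c(body, sprintf("%s %s [ a %s ]", uri,
                              v$terms[["has_proper_part"]],
                              paste0("lipro:", types, collapse = ", ")))
    }
  }
  if (length(body) == 0L) body <- sprintf("%s a %s", uri, "sio:SIO_010004")
  doc <- paste(c(lines, "", paste0(body, " ."), ""), collapse = "\n")
  if (!is.null(path)) { writeLines(doc, path, sep = ""); return(invisible(doc)) }
  doc
}

#' Read functional-group part annotations from Turtle
#'
#' Recovers, per molecule subject, the multiset of functional-group classes
#' typed on its 'has proper part' blank nodes.  When `lib` is given and a
#' part node carries several types (entailed documents), only the most
#' specific type per node is kept.
#'
#' @param doc Turtle text or file path.
#' @param lib Optional `pattern_library` for entailed-type reduction.
#' @return A data frame with columns `uri` and `group_class`, one row per
#'   part occurrence.
#' @export
read_annotation_rdf <- function(doc, lib = NULL) {
  tr <- .parse_turtle(.read_doc(doc))
  part_p <- .term_iri("has_proper_part")
  type_p <- .term_iri("rdf_type")
  v <- leo_vocab()
  lipro_ns <- v$prefixes[["lipro"]]

  out_uri <- character(0)
  out_class <- character(0)
  for (k in which(tr$p == part_p)) {
    node <- tr$o[k]
    types <- tr$o[tr$s == node & tr$p == type_p]
    cls <- sub("^<", "", sub(">$", "", types))
    cls <- cls[startsWith(cls, lipro_ns)]
    cls <- substring(cls, nchar(lipro_ns) + 1L)
    if (length(cls) == 0L) next
    if (!is.null(lib) && length(cls) > 1L) {
      known <- intersect(cls, lib$classes$name)
      if (length(known)) {
        sup <- unique(unlist(lapply(known, function(cl)
          setdiff(superclasses_of(lib, cl), cl))))
        keep <- setdiff(known, sup)
        cls <- if (length(keep)) keep else known
      }
    }
    for (cl in cls) {
      out_uri <- c(out_uri, sub("^<", "", sub(">$", "", tr$s[k])))
      out_class <- c(out_class, cl)
    }
  }
  data.frame(uri = out_uri, group_class = out_class, stringsAsFactors = FALSE)
}

#' Write a classification result as Turtle
#'
#' One `ont:lipidHasLiProClass` triple per most-specific class; one
#' `lmo:lipidHasLMClass` triple per mapped LIPID MAPS class, each LM class
#' node carrying an identifier attribute (`sio:SIO_000115` blank node with
#' the id literal under `sio:SIO_000300`).
#'
#' @param result A `classification_result`.
#' @param path Optional output file.
#' @return The Turtle document as a single string.
#' @export
write_classification_rdf <- function(result, path = NULL) {
  stopifnot(inherits(result, "classification_result"))
  v <- leo_vocab()
  lines <- .prefix_block(c("lipro", "lmo", "ont", "sio"))
  uri <- sprintf("<%s>", result$uri)
  body <- character(0)
  for (nm in result$most_specific) {
    body <- c(body, sprintf("%s %s lipro:%s", uri,
                            v$terms[["class_predicate"]], nm))
  }
  ids <- sort(result$lm_classes$lm_id)
  for (id in ids) {
    body <- c(body, sprintf("%s %s lmo:%s", uri,
                            v$terms[["lm_class_predicate"]], id))
  }
  for (id in ids) {
    body <- c(body, sprintf("lmo:%s %s [ %s \"%s\" ]", id,
                            v$terms[["identifier"]],
                            v$terms[["has_value"]], id))
  }
  if (length(body) == 0L) body <- sprintf("%s a %s", uri, "sio:SIO_010004")
  doc <- paste(c(lines, "", paste0(body, " ."), ""), collapse = "\n")
  if (!is.null(path)) { writeLines(doc, path, sep = ""); return(invisible(doc)) }
  doc
}
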