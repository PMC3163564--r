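# Shared fixtures for the suite: the shipped library/ontology (loaded once),
# reference molecules, a small randomized profile/expression generator, and
# brute-force oracles.

.fixture_env <- new.env(parent = emptyenv())

lc_lib <- function() {
  if (is.null(.fixture_env$lib)) .fixture_env$lib <- load_pattern_library()
  .fixture_env$lib
}

lc_ont <- function() {
  if (is.null(.fixture_env$ont)) .fixture_env$ont <- load_ontology(lib = lc_lib())
  .fixture_env$ont
}

# the prostaglandin worked-example molecule (from the shipped example
# Turtle document)
pg_smiles <- function() {
  "CCCCC[C@H](O)/C=C/[C@H]1[C@H](O)C[C@H](O)[C@@H]1CC(=O)CCCCC(=O)O"
}

# synthetic epoxy-trienoic acid analog: 3 isolated alkenes, one epoxide,
# one carboxyl, no hydroxyl/hydroperoxide/peroxide
epoxy_trienoic_smiles <- function() {
  "CCCCC1OC1C=CCC=CCC=CCCCCCC(=O)O"
}

lc_corpus <- function(n = 50, seed = 7) {
  key <- sprintf("corpus_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_fixture_set(n, seed, lc_ont(), lc_lib())
  }
  .fixture_env[[key]]
}

lc_classify_corpus <- function(corpus) {
  lib <- lc_lib(); ont <- lc_ont()
  lapply(seq_len(nrow(corpus)), function(i)
    classify(annotate(list(uri = corpus$uri[i], smiles = corpus$smiles[i]),
                      lib), ont, lib))
}

lc_corpus_results <- function(n = 50, seed = 7) {
  key <- sprintf("results_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- lc_classify_corpus(lc_corpus(n, seed))
  }
  .fixture_env[[key]]
}

# exhaustive maximum-independent-set size over the overlap graph of a list
# of atom sets (for <= 20 or so sets)
brute_mis_size <- function(sets) {
  n <- length(sets)
  if (n == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1L) {
      for (a in seq_len(length(idx) - 1L)) {
        for (b in seq(a + 1L, length(idx))) {
          if (length(intersect(sets[[idx[a]]], sets[[idx[b]]])) > 0L) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(idx)
  }
  best
}

# randomized profile over the shipped library's non-abstract classes
random_profile <- function(lib, max_classes = 6, max_count = 5) {
  pool <- lib$classes$name
  k <- sample(0:max_classes, 1)
  if (k == 0L) {
    return(profile_from_counts(stats::setNames(integer(0), character(0)), lib))
  }
  cls <- sample(pool, min(k, length(pool)))
  counts <- stats::setNames(sample(seq_len(max_count), length(cls),
                                   replace = TRUE), cls)
  profile_from_counts(counts, lib)
}

# randomized class expression of depth <= 3 over the library's classes
random_expression <- function(lib) {
  pool <- lib$classes$name
  rand_filler <- function() {
    if (stats::runif(1) < 0.6) {
      lipidclassr:::ce_named(sample(pool, 1))
    } else {
      members <- lapply(sample(pool, sample(2:3, 1)), lipidclassr:::ce_named)
      lipidclassr:::ce_union(members)
    }
  }
  rand_term <- function() {
    kind <- sample(c("some", "min", "exactly"), 1)
    switch(kind,
      some = lipidclassr:::ce_some(rand_filler()),
      min = lipidclassr:::ce_min(sample(0:4, 1), rand_filler()),
      exactly = lipidclassr:::ce_exactly(sample(0:4, 1), rand_filler()))
  }
  nterms <- sample(1:3, 1)
  terms <- replicate(nterms, rand_term(), simplify = FALSE)
  if (nterms == 1L) terms[[1]] else lipidclassr:::ce_intersection(terms)
}

# evaluate both satisfaction routes, capturing errors, for equivalence checks
both_satisfy <- function(profile, expr, lib) {
  f <- function(fun) tryCatch(list(value = fun(profile, expr, lib)),
                              error = function(e) list(error = TRUE))
  list(main = f(satisfies), oracle = f(oracle_satisfies))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
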