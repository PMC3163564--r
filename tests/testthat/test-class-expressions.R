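# Class-expression grammar, hierarchy-aware counting, and closed-world
# satisfaction (with its brute-force oracle).

fa0305_text <- paste(
  "part exactly 1 Primary_Acyl_Chain",
  "and part some Carboxylic_Acid",
  "and part some (Alcohol or Hydroperoxide or Peroxide)",
  "and part exactly 3 Alkenyl_Group")

fa0308_text <- paste(
  "part exactly 1 Primary_Acyl_Chain",
  "and part some Epoxy",
  "and part some Carboxylic_Acid",
  "and part exactly 3 Alkenyl_Group")

test_that("parse_expression handles the published definition forms", {
  e <- parse_expression(fa0308_text)
  expect_s3_class(e, "class_expression")
  expect_equal(e$kind, "intersection")
  expect_length(e$members, 4L)
  expect_equal(e$members[[1]]$kind, "exactly")
  expect_equal(e$members[[1]]$n, 1L)
  expect_equal(e$members[[1]]$filler$name, "Primary_Acyl_Chain")

  u <- parse_expression("part some (Alcohol or Hydroperoxide or Peroxide)")
  expect_equal(u$kind, "some")
  expect_equal(u$filler$kind, "union")
  expect_length(u$filler$members, 3L)

  q <- parse_expression("part exactly 3 'Alkenyl_Group'")
  expect_equal(q$filler$name, "Alkenyl_Group")
})

test_that("grammar violations are syntax errors", {
  expect_error(parse_expression("part exactly Alkenyl_Group"),
               "non-negative integer")
  expect_error(parse_expression("part around 3 Alkenyl_Group"),
               "unknown restriction operator")
  expect_error(parse_expression(""), "empty")
  expect_error(parse_expression("part some (A or"), "filler")
})

test_that("expressions round-trip through the printer", {
  texts <- c(
    fa0305_text, fa0308_text,
    "part some Epoxy",
    "part min 2 (Alcohol or Peroxide)",
    "LC_Prostaglandin",
    "part exactly 0 Cyclopentane_Ring and part some Alcohol")
  for (txt in texts) {
    e <- parse_expression(txt)
    expect_identical(parse_expression(format_expression(e)), e, info = txt)
  }
})

test_that("count_instances sums over the subclass closure", {
  lib <- lc_lib()
  p <- profile_from_counts(c(Alcohol = 2), lib)
  ci <- count_instances(p, parse_expression("Hydroxy_Compound"), lib)
  expect_equal(ci$count, 2L)
  expect_true(ci$exact)

  empty <- profile_from_counts(stats::setNames(integer(0), character(0)), lib)
  expect_equal(count_instances(empty, parse_expression("Alcohol"), lib)$count, 0L)

  p2 <- profile_from_counts(c(Alcohol = 1, Hydroperoxide = 1), lib)
  u <- parse_expression("part some (Alcohol or Hydroperoxide or Peroxide)")
  expect_equal(count_instances(p2, u$filler, lib)$count, 2L)

  # ubiquitous classes make counts inexact
  p3 <- profile_from_counts(c(Propyl = 5), lib)
  ci3 <- count_instances(p3, parse_expression("Propyl"), lib)
  expect_equal(ci3$count, 1L)  # single witness
  expect_false(ci3$exact)
})

test_that("satisfaction reproduces the FA0305/FA0308 discrimination", {
  lib <- lc_lib()
  fa0305 <- parse_expression(fa0305_text)
  fa0308 <- parse_expression(fa0308_text)

  epoxy_profile <- profile_from_counts(
    c(Primary_Acyl_Chain = 1, Carboxylic_Acid = 1, Alkenyl_Group = 3,
      Epoxy = 1), lib)
  expect_true(satisfies(epoxy_profile, fa0308, lib))
  expect_false(satisfies(epoxy_profile, fa0305, lib))

  hydroxy_profile <- profile_from_counts(
    c(Primary_Acyl_Chain = 1, Carboxylic_Acid = 1, Alkenyl_Group = 3,
      Alcohol = 1), lib)
  expect_true(satisfies(hydroxy_profile, fa0305, lib))
  expect_false(satisfies(hydroxy_profile, fa0308, lib))

  # vacuous lower bound
  expect_true(satisfies(epoxy_profile, parse_expression("part min 0 Alcohol"),
                        lib))
})

test_that("exact cardinality over a ubiquitous class is rejected", {
  lib <- lc_lib()
  p <- profile_from_counts(c(Propyl = 1, Alcohol = 1), lib)
  bad <- parse_expression("part exactly 2 Propyl")
  expect_error(satisfies(p, bad, lib), "ubiquitous")
  expect_error(oracle_satisfies(p, bad, lib), "ubiquitous")
  # under some/min a ubiquitous witness is fine
  expect_true(satisfies(p, parse_expression("part some Propyl"), lib))
})

test_that("satisfies agrees with the brute-force oracle on random cases", {
  lib <- lc_lib()
  set.seed(20231105)
  n_cases <- 250L
  n_checked <- 0L
  for (k in seq_len(n_cases)) {
    p <- random_profile(lib)
    e <- random_expression(lib)
    r <- both_satisfy(p, e, lib)
    if (!is.null(r$main$error) || !is.null(r$oracle$error)) {
      expect_identical(is.null(r$main$error), is.null(r$oracle$error),
                       info = format_expression(e))
    } else {
      expect_identical(r$main$value, r$oracle$value,
                       info = format_expression(e))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("removing an intersection conjunct never unsatisfies", {
  lib <- lc_lib()
  set.seed(42)
  for (k in 1:40) {
    p <- random_profile(lib)
    e <- random_expression(lib)
    if (e$kind != "intersection" || length(e$members) < 2L) next
    full <- tryCatch(satisfies(p, e, lib), error = function(err) NA)
    if (!isTRUE(full)) next
    for (drop in seq_along(e$members)) {
      reduced <- e$members[-drop]
      re <- if (length(reduced) == 1L) reduced[[1]]
            else lipidclassr:::ce_intersection(reduced)
      expect_true(satisfies(p, re, lib), info = format_expression(e))
    }
  }
})

test_that("replacing a some/min filler by a superclass preserves truth", {
  lib <- lc_lib()
  # Alcohol -> Hydroxy_Compound is the shipped subclass axiom
  p <- profile_from_counts(c(Alcohol = 2), lib)
  expect_true(satisfies(p, parse_expression("part some Alcohol"), lib))
  expect_true(satisfies(p, parse_expression("part some Hydroxy_Compound"), lib))
  expect_true(satisfies(p, parse_expression("part min 2 Hydroxy_Compound"), lib))

  p2 <- profile_from_counts(c(Carboxylic_Acid = 1), lib)
  expect_true(satisfies(p2, parse_expression("part some Carboxylic_Acid"), lib))
  expect_true(satisfies(
    p2, parse_expression("part some Carboxylic_Acid_Derivative"), lib))
})

test_that("exact cardinalities are mutually exclusive", {
  lib <- lc_lib()
  set.seed(99)
  for (k in 1:25) {
    p <- random_profile(lib)
    exact_classes <- names(p$exact)[unlist(p$exact)]
    if (length(exact_classes) == 0L) next
    cl <- sample(exact_classes, 1)
    filler <- lipidclassr:::ce_named(cl)
    ci <- count_instances(p, filler, lib)
    if (!ci$exact) next  # a ubiquitous subclass makes 'exactly' undecidable
    hits <- vapply(0:12, function(n)
      satisfies(p, lipidclassr:::ce_exactly(n, filler), lib), logical(1))
    expect_equal(sum(hits), 1L)
    expect_true(hits[ci$count + 1L])
  }
})
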