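# Evaluation procedure: exact / partial / mismatch / dual outcomes,
# tabulation arithmetic, and the synthetic fixture generator.

mk_result <- function(uri, ms) {
  structure(list(uri = uri, satisfied = ms, most_specific = sort(ms),
                 lm_classes = data.frame(class = character(0),
                                         lm_id = character(0),
                                         category_code = character(0),
                                         category = character(0))),
            class = "classification_result")
}

test_that("compare_classification covers the outcome taxonomy", {
  ont <- lc_ont()
  # dual: correct prostaglandin plus the structurally indistinguishable
  # isoprostane sibling
  out <- compare_classification(
    mk_result("m", c("LC_Prostaglandin", "LC_Isoprostane")), "FA0301", ont)
  expect_equal(out$category, "exact")
  expect_true(out$dual)

  # generalization to an ancestor is a partial match
  out2 <- compare_classification(mk_result("m", "LC_Fatty_Acid"), "FA0305", ont)
  expect_equal(out2$category, "partial")
  expect_false(out2$dual)

  # the gold class alone: exact, no dual
  out3 <- compare_classification(
    mk_result("m", "LC_Epoxyeicosatrienoic_Acid"), "FA0308", ont)
  expect_equal(out3$category, "exact")
  expect_false(out3$dual)

  # a wrong terminal class alone: mismatch
  out4 <- compare_classification(
    mk_result("m", "LC_Leukotriene"), "FA0308", ont)
  expect_equal(out4$category, "mismatch")
  expect_false(out4$dual)

  # nothing predicted
  out5 <- compare_classification(mk_result("m", character(0)), "FA0308", ont)
  expect_equal(out5$category, "none")

  expect_error(compare_classification(mk_result("m", character(0)),
                                      "GP9999", ont), "not mapped")
})

test_that("tabulation arithmetic and conservation", {
  ont <- lc_ont()
  results <- c(
    lapply(1:9, function(i)
      mk_result(sprintf("u%d", i), "LC_Epoxyeicosatrienoic_Acid")),
    list(mk_result("u10", "LC_Fatty_Acid")))
  gold <- data.frame(uri = sprintf("u%d", 1:10),
                     asserted_lm = rep("FA0308", 10))
  tally <- tabulate_outcomes(results, gold, ont)
  expect_equal(tally$n, 10L)
  expect_equal(tally$pct_exact, 90)
  expect_equal(tally$pct_partial, 10)
  expect_equal(tally$pct_consistent, 100)
  expect_equal(sum(tally$counts), tally$n)

  single <- tabulate_outcomes(results[1], gold[1, , drop = FALSE], ont)
  expect_equal(single$n, 1L)
  expect_equal(single$pct_exact, 100)

  none <- tabulate_outcomes(list(mk_result("u1", character(0))),
                            data.frame(uri = "u1", asserted_lm = "FA0308"),
                            ont)
  expect_equal(none$pct_none, 100)
})

test_that("tally category counts sum to n under random seeds", {
  ont <- lc_ont()
  for (seed in c(3, 11, 29)) {
    corpus <- generate_fixture_set(8, seed, ont, lc_lib())
    results <- lc_classify_corpus(corpus)
    tally <- tabulate_outcomes(results, corpus, ont)
    expect_equal(sum(tally$counts), tally$n)
  }
})

test_that("the generator is deterministic and covers the terminal classes", {
  lib <- lc_lib(); ont <- lc_ont()
  a <- generate_fixture_set(12, 5, ont, lib)
  b <- generate_fixture_set(12, 5, ont, lib)
  expect_identical(a, b)
  c2 <- generate_fixture_set(12, 6, ont, lib)
  expect_false(identical(a$smiles, c2$smiles))

  # with n >= number of terminal classes every class gets a molecule, and
  # at least two distinct terminal classes appear even at n = 4
  small <- generate_fixture_set(4, 1, ont, lib)
  expect_gte(length(unique(small$asserted_lm)), 2L)
  mapped_terminals <- Filter(function(nm) !is.na(lm_mapping(ont, nm)),
                             terminal_classes(ont))
  full <- generate_fixture_set(length(mapped_terminals), 1, ont, lib)
  expect_setequal(unique(full$asserted_lm),
                  unique(vapply(mapped_terminals, function(nm)
                    lm_mapping(ont, nm), character(1))))
})

test_that("every generated molecule is classified consistently with its gold", {
  ont <- lc_ont()
  corpus <- lc_corpus()
  results <- lc_corpus_results()
  tally <- tabulate_outcomes(results, corpus, ont)
  expect_equal(tally$pct_consistent, 100)
  expect_gte(tally$counts[["exact"]], 1L)
})

test_that("the epoxide template reproduces the misannotation fingerprint", {
  lib <- lc_lib(); ont <- lc_ont()
  corpus <- lc_corpus()
  epox <- corpus[corpus$asserted_lm == "FA0308", ]
  expect_gte(nrow(epox), 1L)
  for (i in seq_len(nrow(epox))) {
    p <- annotate(list(uri = epox$uri[i], smiles = epox$smiles[i]), lib)
    expect_equal(p$counts[["Alkenyl_Group"]], 3L)
    expect_equal(p$counts[["Epoxy"]], 1L)
    expect_equal(p$counts[["Carboxylic_Acid"]], 1L)
    expect_false(any(c("Alcohol", "Hydroperoxide", "Peroxide") %in%
                       names(p$counts)))
  }
})

test_that("weakening the epoxy class definition destroys the FA0305/FA0308 discrimination", {
  # dropping the 'part some Epoxy' conjunct leaves a strictly weaker class:
  # epoxide fixtures still satisfy it (a conjunction's instance satisfies
  # any sub-conjunction), but hydroxy-trienoic fixtures now satisfy it too,
  # so gold-FA0305 molecules pick up an inconsistent terminal class
  lib <- lc_lib(); ont <- lc_ont()
  weak <- ont
  weak$classes$LC_Epoxyeicosatrienoic_Acid$definition <- parse_expression(
    paste("part exactly 1 Primary_Acyl_Chain",
          "and part some Carboxylic_Acid",
          "and part exactly 3 Alkenyl_Group"))
  corpus <- lc_corpus()
  hyd <- corpus[corpus$asserted_lm == "FA0305", ]
  expect_gte(nrow(hyd), 1L)
  for (i in seq_len(nrow(hyd))) {
    p <- annotate(list(uri = hyd$uri[i], smiles = hyd$smiles[i]), lib)
    res <- classify(p, weak, lib)
    out <- compare_classification(res, "FA0305", weak)
    expect_true("LC_Epoxyeicosatrienoic_Acid" %in% res$most_specific)
    expect_true(out$dual, info = hyd$uri[i])
  }
  # while under the intact ontology the same molecules are clean exacts
  for (i in seq_len(nrow(hyd))) {
    p <- annotate(list(uri = hyd$uri[i], smiles = hyd$smiles[i]), lib)
    out <- compare_classification(classify(p, ont, lib), "FA0305", ont)
    expect_equal(out$category, "exact")
    expect_false(out$dual)
  }
})

test_that("gold TSV and report TSV round-trip", {
  ont <- lc_ont()
  corpus <- lc_corpus(8, 3)
  gold_path <- tempfile(fileext = ".tsv")
  writeLines(sprintf("%s\t%s", corpus$uri, corpus$asserted_lm), gold_path)
  gold <- read_gold_tsv(gold_path)
  expect_identical(gold$uri, corpus$uri)
  expect_identical(gold$asserted_lm, corpus$asserted_lm)

  results <- lc_classify_corpus(corpus)
  tally <- tabulate_outcomes(results, gold, ont)
  rep_path <- tempfile(fileext = ".tsv")
  write_report_tsv(tally, rep_path)
  back <- utils::read.table(rep_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_equal(nrow(back), tally$n)
  expect_true(all(back$category %in% c("exact", "partial", "mismatch", "none")))
})
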