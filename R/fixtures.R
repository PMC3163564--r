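# Synthetic eicosanoid generator: C20-scaffold SMILES with controlled
# functional-group content and a known intended terminal class, standing in
# for a curated structure corpus in tests and examples.
#
# Templates (one per terminal ontology class):
#  * prostanoid (FA0301 / FA0311): cyclopentane ring flanked by an omega
#    chain (1 alkene, optional chain hydroxyl) and a carboxyl chain
#    (optional second alkene), 1-2 ring hydroxyls.  By construction these
#    satisfy both the prostaglandin and the isoprostane definitions, which
#    are structurally identical, so they classify dually.
#  * hydroxy/hydroperoxy-trienoic (FA0305): linear chain, exactly 3
#    isolated alkenes, one hydroxyl or hydroperoxide, carboxyl.
#  * epoxy-trienoic (FA0308): linear chain, exactly 3 alkenes, one
#    epoxide, carboxyl, no hydroxyl.
#  * leukotriene-like (FA0302): linear chain, exactly 4 alkenes, one
#    hydroxyl, carboxyl.
#
# Alkenes are separated by a methylene so that alkene occurrences never
# overlap; every template ends in at least two sp3 carbons before the
# carboxyl so that exactly one primary acyl chain is detected.

.fixture_templates <- function() {
  pad <- function(k) strrep("C", max(0L, k))
  list(
    FA0301 = function(draw) {
      ring_oh2 <- draw(2) == 1L
      chain_oh <- draw(2) == 1L
      second_db <- draw(2) == 1L
      left <- paste0(pad(4L + draw(2)), if (chain_oh) "C(O)" else "C", "C=C")
      ring <- paste0("C1C(O)C", if (ring_oh2) "C(O)" else "C", "C1")
      right <- paste0(if (second_db) "CC=C" else "C", pad(2L + draw(2)),
                      "CC(=O)O")
      paste0(left, ring, right)
    },
    FA0305 = function(draw) {
      oh <- if (draw(2) == 1L) "C(O)" else "C(OO)"
      paste0(pad(3L + draw(2)), oh, "C=CCC=CCC=C", pad(3L + draw(2)),
             "CC(=O)O")
    },
    FA0308 = function(draw) {
      paste0(pad(3L + draw(2)), "C1OC1", "C=CCC=CCC=C", pad(3L + draw(2)),
             "CC(=O)O")
    },
    FA0302 = function(draw) {
      paste0(pad(2L + draw(2)), "C(O)", "C=CCC=CCC=CCC=C", pad(2L + draw(2)),
             "CC(=O)O")
    }
  )
}

# which template serves which terminal class (isoprostanes share the
# prostanoid scaffold)
.template_for_class <- c(
  LC_Prostaglandin = "FA0301",
  LC_Isoprostane = "FA0301",
  LC_Hydroxyeicosatrienoic_Acid = "FA0305",
  LC_Epoxyeicosatrienoic_Acid = "FA0308",
  LC_Leukotriene = "FA0302"
)

#' Generate a synthetic eicosanoid fixture corpus
#'
#' Builds `n` SMILES from C20-style scaffold templates (linear or
#' cyclopentane-bearing) with controlled counts of alkenes, hydroxyls,
#' hydroperoxides, epoxides and one carboxylic acid, so that each
#' molecule's intended terminal class -- its gold assignment -- is known by
#' construction.  The first molecules cycle through every terminal class
#' of the ontology (so each receives at least one molecule whenever `n` is
#' at least the number of terminal classes); the rest draw templates at
#' random.  Deterministic for a fixed seed.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed.
#' @param ont A `lipid_ontology`; every terminal class must have a
#'   generator template.
#' @param lib A `pattern_library` (interface symmetry with the rest of the
#'   pipeline; the generator itself only needs the ontology).
#' @return A data frame with columns `uri`, `smiles`, `asserted_lm`.
#' @examples
#' lib <- load_pattern_library()
#' ont <- load_ontology(lib = lib)
#' generate_fixture_set(5, seed = 1, ont = ont, lib = lib)
#' @export
generate_fixture_set <- function(n, seed, ont, lib) {
  stopifnot(n >= 1L, inherits(ont, "lipid_ontology"))
  templates <- .fixture_templates()
  terms <- terminal_classes(ont)
  lm_of <- vapply(terms, function(nm) lm_mapping(ont, nm), character(1))
  terms <- terms[!is.na(lm_of)]
  missing <- terms[!(terms %in% names(.template_for_class))]
  if (length(missing)) {
    stop(sprintf("no generator template for terminal class '%s'", missing[1]))
  }

  rng <- .lcg(seed)
  draw <- function(k) 1L + rng() %% k

  uris <- sprintf("http://example.org/lipid/SYN%04d", seq_len(n))
  smiles <- character(n)
  gold <- character(n)
  for (i in seq_len(n)) {
    cls <- if (i <= length(terms)) terms[i]
           else terms[1L + rng() %% length(terms)]
    tpl <- .template_for_class[[cls]]
    smiles[i] <- templates[[tpl]](draw)
    gold[i] <- lm_mapping(ont, cls)
  }
  data.frame(uri = uris, smiles = smiles, asserted_lm = gold,
             stringsAsFactors = FALSE)
}

# small deterministic linear congruential generator so fixture generation
# never disturbs (or depends on) R's global RNG state
.lcg <- function(seed) {
  state <- (as.integer(seed) %% 2147483647L)
  if (state <= 0L) state <- state + 2147483646L
  function() {
    state <<- as.integer((as.double(state) * 16807) %% 2147483647)
    state
  }
}
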