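## ----include = FALSE----------------------------------------------------------
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")

## ----setup--------------------------------------------------------------------
library(cohortpe)

## ----lexicon------------------------------------------------------------------
lex <- as_lexicon(tibble::tibble(
  word          = c("bingo", "tango", "tangle", "tang", "tank"),
  transcription = c("b I N - g @U", "t a N - g @U", "t a N - g l=",
                    "t a N", "t a N k"),
  frequency     = c(210, 7, 69, 58, 60)))
conditional_syllable_probability(lex, "b I N", "g @U")
conditional_syllable_probability(lex, "t a N", "g @U")
syllable_entropy(lex, "t a N")

## ----simulation---------------------------------------------------------------
pl <- run_divergence_simulation(t_grid = NULL)
glance(pl$simulation)

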