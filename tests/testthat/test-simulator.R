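test_that("posterior update normalises and flags degenerate prefixes", {
  lex <- toy_lexicon()
  ev <- toy_evidence(lex)

  # empty prefix: posterior equals the normalised priors
  p0 <- posterior_update(lex, ev)
  expect_equal(p0$posterior, lex$frequency / sum(lex$frequency))
  expect_false(attr(p0, "degenerate"))

  p1 <- posterior_update(lex, ev, c("t", "a"))
  expect_equal(sum(p1$posterior), 1)
  expect_true(all(p1$posterior >= 0))
  # the /t a .../ words dominate under near-diagonal evidence
  expect_gt(sum(p1$posterior[p1$word %in% c("tango", "tangle", "tang", "tank")]),
            0.9)

  expect_error(posterior_update(lex[0, ], ev), class = "cohortpe_bad_lexicon")
  expect_error(posterior_update(lex, ev, c("zz")),
               class = "cohortpe_unknown_segment")
})

test_that("a zero-evidence prefix degenerates instead of erroring", {
  lex <- toy_lexicon()
  inv <- segment_inventory(lex)
  # deterministic evidence: identity rows leave pseudoword prefixes with
  # exactly zero likelihood everywhere
  ev <- structure(diag(length(inv)), dimnames = list(inv, inv),
                  class = "evidence_matrix", temperature = Inf)
  pd <- posterior_update(lex, ev, c("g", "a"))
  expect_true(attr(pd, "degenerate"))
  expect_equal(pd$posterior, rep(0, nrow(lex)))
  expect_error(segment_prediction(pd, lex),
               class = "cohortpe_degenerate_posterior")
  # documented fallback: prior-only prediction
  pred <- segment_prediction(pd, lex, prior_fallback = TRUE)
  expect_equal(sum(pred), 1)  # every toy word continues past two segments
})

test_that("segment predictions sum word posteriors by next segment", {
  lex <- toy_lexicon()
  ev <- toy_evidence(lex)
  heard <- c("t", "a", "N")
  post <- posterior_update(lex, ev, heard)
  pred <- segment_prediction(post, lex)
  expect_named(pred, segment_inventory(lex))
  expect_true(all(pred >= 0))
  # "tang" ends here and predicts nothing, so mass can drop below one
  expect_lt(sum(pred), 1)
  # bingo also predicts a boundary at position 4, with tiny posterior mass
  expect_equal(unname(pred["-"]),
               sum(post$posterior[post$word %in% c("tango", "tangle", "bingo")]))
  expect_equal(unname(pred["k"]), post$posterior[post$word == "tank"])
  expect_equal(sum(pred),
               1 - post$posterior[post$word == "tang"])
  # oracle agreement
  expect_equal(pred, oracle_prediction(lex, post$posterior, heard),
               tolerance = 1e-12)
})

test_that("sharpened and prediction-error representations obey their algebra", {
  pred <- stats::setNames(c(0.6, 0.3, 0, 0.1), letters[1:4])
  input <- stats::setNames(c(0.1, 0.7, 0.15, 0.05), letters[1:4])

  sh <- sharpened_signal(pred, input)
  expect_s3_class(sh, "model_repr")
  expect_identical(attr(sh, "kind"), "sharpened")
  expect_equal(sum(as.numeric(sh)), 1)
  expect_true(all(as.numeric(sh) >= 0))
  expect_equal(as.numeric(sh), unname(pred * input / sum(pred * input)))

  pe <- prediction_error(pred, input)
  expect_identical(attr(pe, "kind"), "prediction_error")
  expect_equal(as.numeric(pe), unname(input - pred))
  # the PE vector sums to (sum input - sum prediction)
  expect_equal(sum(as.numeric(pe)), sum(input) - sum(pred))

  # disjoint support: warned fallback to the raw input row
  pred0 <- stats::setNames(c(1, 0, 0, 0), letters[1:4])
  input0 <- stats::setNames(c(0, 0.5, 0.5, 0), letters[1:4])
  expect_warning(sh0 <- sharpened_signal(pred0, input0),
                 class = "cohortpe_no_support")
  expect_equal(as.numeric(sh0), unname(input0 / sum(input0)))
})

test_that("univariate readouts check kinds and match their formulas", {
  pred <- stats::setNames(c(0.5, 0.5, 0), letters[1:3])
  input <- stats::setNames(c(0.2, 0.3, 0.5), letters[1:3])
  sh <- sharpened_signal(pred, input)
  pe <- prediction_error(pred, input)

  expect_equal(univariate_pe(pe), sum(abs(input - pred)))
  v <- as.numeric(sh)
  expect_equal(univariate_sharpened(sh), mean(log(v + 1e-12)))
  vp <- v[v > 0]
  expect_equal(univariate_entropy_link(sh), -sum(vp * log(vp)))

  expect_error(univariate_pe(sh), class = "cohortpe_wrong_kind")
  expect_error(univariate_sharpened(pe), class = "cohortpe_wrong_kind")
  expect_error(univariate_entropy_link(pe), class = "cohortpe_wrong_kind")
})

test_that("divergence-point simulation of one item wires the pieces together", {
  s <- small_setup()
  item <- s$design[1, ]
  out <- simulate_item_at_dp(s$lexicon, s$evidence, item)
  inv <- segment_inventory(s$lexicon)
  heard <- strsplit(item$heard_segments, " ")[[1]]
  dp <- item$dp_index

  # input row is the evidence row of the segment actually heard at the DP
  expect_equal(out$input_row,
               stats::setNames(as.numeric(s$evidence[heard[dp], inv]), inv))
  # representations recombine prediction and input exactly
  expect_equal(as.numeric(out$prediction_error),
               unname(out$input_row - out$prediction))
  prod_v <- out$prediction * out$input_row
  expect_equal(as.numeric(out$sharpened), unname(prod_v / sum(prod_v)))
  # posterior is conditioned on the pre-DP prefix only
  expect_identical(attr(out$posterior, "heard"), heard[seq_len(dp - 1)])

  bad <- item
  bad$dp_index <- length(heard) + 5L
  expect_error(simulate_item_at_dp(s$lexicon, s$evidence, bad),
               class = "cohortpe_bad_item")
})

test_that("condition simulation validates its design", {
  s <- small_setup()
  expect_error(
    run_condition_simulation(s$lexicon, s$evidence,
                             dplyr::select(s$design, -"set_id")),
    class = "cohortpe_bad_design")
  expect_error(
    run_condition_simulation(s$lexicon, s$evidence, s$design[-1, ]),
    class = "cohortpe_bad_design")
  dd <- s$design
  dd$strength[1] <- "Middling"
  expect_error(run_condition_simulation(s$lexicon, s$evidence, dd),
               class = "cohortpe_bad_design")
})

test_that("condition simulation produces coherent tidy summaries", {
  s <- small_setup()
  sim <- run_condition_simulation(s$lexicon, s$evidence, s$design)
  expect_s3_class(sim, "dp_simulation")
  expect_equal(nrow(sim$items), nrow(s$design))
  expect_true(all(c("univariate_pe", "univariate_sharpened", "entropy_link")
                  %in% names(sim$items)))
  expect_false(anyNA(sim$items$univariate_pe))

  # pattern rows recombine per-item representations
  expect_equal(dim(sim$representations$sharpened),
               c(nrow(s$design), length(segment_inventory(s$lexicon))))
  expect_equal(unname(rowSums(sim$representations$sharpened)),
               rep(1, nrow(s$design)))

  # condition means recompute from the pair table
  cm <- sim$pairs |>
    dplyr::group_by(kind, condition) |>
    dplyr::summarise(m = mean(distance), .groups = "drop")
  expect_equal(sort(cm$m), sort(sim$condition_means$mean_distance))

  # crossover column matches its defining contrast
  co <- sim$crossover
  expect_equal(co$crossover,
               (co$`Strong+Mismatch` - co$`Weak+Mismatch`) -
                 (co$`Strong+Match` - co$`Weak+Match`))

  # masked reciprocal pairs never appear in the pair table
  mask <- sim$mask
  for (r in seq_len(nrow(sim$pairs))) {
    expect_false(mask[sim$pairs$item_a[r], sim$pairs$item_b[r]])
  }

  td <- tidy(sim)
  expect_true(tibble::is_tibble(td))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$temperature, default_temperature())
})

test_that("uncertainty sweep enforces the grid and reports per-T flags", {
  s <- small_setup()
  expect_error(uncertainty_sweep(s$lexicon, s$features, s$design,
                                 t_grid = c(0.5, 1)),
               class = "cohortpe_bad_temperature")
  expect_error(uncertainty_sweep(s$lexicon, s$features, s$design,
                                 t_grid = c(0.5, 1, 2)),
               class = "cohortpe_bad_temperature")
  sw <- uncertainty_sweep(s$lexicon, s$features, s$design,
                          t_grid = c(0.05, 0.5, 5))
  expect_s3_class(sw, "uncertainty_sweep")
  expect_equal(nrow(sw$flags), 3)
  expect_true(all(c("pe_crossover", "sharpened_crossover", "match_reversal")
                  %in% names(sw$flags)))
  expect_equal(nrow(glance(sw)), 1)
  # T -> 0 limit: uniform rows make Match and Mismatch inputs identical
  # within a pair, so distances are driven by predictions alone
  lowsim <- run_condition_simulation(
    s$lexicon,
    softmax_evidence(segment_distance_matrix(
      s$features, boundary = boundary_token(s$lexicon)), 1e-9),
    s$design)
  reprs <- lowsim$representations$prediction_error
  match_ids <- s$design$item_id[s$design$congruency == "Match"]
  mm_ids <- sub("$", ".pw", match_ids)
  for (k in seq_along(match_ids)) {
    # same Syl1 prefix, near-uniform input: PE rows of a word and its
    # cross-spliced pseudoword coincide
    expect_equal(reprs[match_ids[k], ], reprs[mm_ids[k], ], tolerance = 1e-6)
  }
})
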