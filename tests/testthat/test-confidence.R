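# Helpers to fabricate profiles/evidence with chosen observed values, so the
# rule logic is tested independently of the geometry/evidence code.
mk_profile <- function(mismatches = 0, bulges = data.frame(arm = character(0),
                                                           size = integer(0)),
                       overhangs = c(2, 2), pf = c(0.9, 0.9)) {
  structure(class = "duplex_profile", list(
    mismatches = mismatches, bulges = bulges,
    overhang_mature_3p = overhangs[1], overhang_star_3p = overhangs[2],
    paired_fraction_mature = pf[1], paired_fraction_star = pf[2]))
}

mk_evidence <- function(exact = c(100, 50), excision = 0.9, hom = c(0.9, 0.9),
                        libs = 3, dom = 0.6) {
  structure(class = "evidence_summary", list(
    arm_exact_reads_mature = exact[1], arm_exact_reads_star = exact[2],
    excision_fraction = excision, five_prime_homogeneity_mature = hom[1],
    five_prime_homogeneity_star = hom[2], libraries_detected = libs,
    dominance = dom))
}

mk_prec <- function(mfe_nt = -0.3, hits = 1) {
  precursor("t", strrep("A", 100), strrep(".", 100), mfe = mfe_nt * 100,
            n_genome_hits = hits)
}

eval_call <- function(profile = mk_profile(), evidence = mk_evidence(),
                      prec = mk_prec(), star_present = TRUE,
                      thresholds = mirna_thresholds(), require_r4 = FALSE) {
  classify(evaluate_rules(profile, evidence, prec, star_present, thresholds),
           require_r4)
}

test_that("printed boundary semantics are applied exactly", {
  # "four or fewer mismatches": 4 passes, 5 fails
  expect_true(eval_call(mk_profile(mismatches = 4))$report$r2$pass)
  expect_false(eval_call(mk_profile(mismatches = 5))$report$r2$pass)
  # "At least 10 reads": 10 passes, 9 fails (either arm)
  expect_true(eval_call(evidence = mk_evidence(exact = c(10, 10)))$report$r5$pass)
  expect_false(eval_call(evidence = mk_evidence(exact = c(9, 200)))$report$r5$pass)
  # "at least 50% ... same 5' end": 0.50 passes, 0.49 fails
  expect_true(eval_call(evidence = mk_evidence(hom = c(0.5, 0.8)))$report$r6$pass)
  expect_false(eval_call(evidence = mk_evidence(hom = c(0.49, 0.8)))$report$r6$pass)
  # "more than 75%": 0.75 exactly fails, 0.751 passes
  expect_false(eval_call(evidence = mk_evidence(excision = 0.75))$report$r4$pass)
  expect_true(eval_call(evidence = mk_evidence(excision = 0.751))$report$r4$pass)
  # "<-0.2 kcal/mol/nt": -0.2 exactly fails, -0.21 passes
  expect_false(eval_call(prec = mk_prec(-0.2))$report$r7$pass)
  expect_true(eval_call(prec = mk_prec(-0.21))$report$r7$pass)
  # bulges: one 1-nt bulge passes, a 2-nt bulge fails ("less than two bases"),
  # two bulges fail
  b1 <- data.frame(arm = "mature", size = 1L)
  b2 <- data.frame(arm = "mature", size = 2L)
  b11 <- data.frame(arm = c("mature", "star"), size = c(1L, 1L))
  expect_true(eval_call(mk_profile(bulges = b1))$report$r3$pass)
  expect_false(eval_call(mk_profile(bulges = b2))$report$r3$pass)
  expect_false(eval_call(mk_profile(bulges = b11))$report$r3$pass)
  # the 2-nt boundary is configurable
  expect_true(eval_call(mk_profile(bulges = b2),
                        thresholds = mirna_thresholds(max_bulge_size = 3))$report$r3$pass)
})

test_that("rule 1 falls back to multi-library detection without a star", {
  call <- eval_call(evidence = mk_evidence(exact = c(200, 0), libs = 9),
                    star_present = FALSE)
  expect_true(call$report$r1$pass)
  expect_false(eval_call(evidence = mk_evidence(exact = c(200, 0), libs = 1),
                         star_present = FALSE)$report$r1$pass)
})

test_that("classify implements the HC/VHC/rescue logic", {
  # r1-r4 pass, r5 fails -> high confidence, not very high
  call <- eval_call(evidence = mk_evidence(exact = c(200, 3)))
  expect_equal(call$category, "high_confidence")
  # all seven -> very high confidence
  expect_equal(eval_call()$category, "very_high_confidence")
  # one structural violation + precise excision -> rescued high confidence
  call <- eval_call(mk_profile(mismatches = 5), prec = mk_prec(-0.15))
  expect_equal(call$category, "high_confidence")
  expect_true(call$rescue_applied)
  # two structural violations are beyond rescue
  call <- eval_call(mk_profile(mismatches = 5,
                               bulges = data.frame(arm = "star", size = 3L)))
  expect_equal(call$category, "rejected")
  # structural pass + poor excision -> HC with low-excision warning ...
  call <- eval_call(evidence = mk_evidence(excision = 0.5, exact = c(200, 3)))
  expect_equal(call$category, "high_confidence")
  expect_true(call$low_excision)
  # ... unless rule 4 is made mandatory
  call <- eval_call(evidence = mk_evidence(excision = 0.5), require_r4 = TRUE)
  expect_equal(call$category, "rejected")
  # genome multi-hit filter rejects outright
  call <- eval_call(prec = mk_prec(-0.3, hits = 20))
  expect_equal(call$category, "rejected")
})

test_that("degenerate evidence fails rules instead of erroring", {
  ev <- mk_evidence(hom = c(NA, NA), excision = NA)
  rep <- evaluate_rules(mk_profile(), ev, mk_prec(), TRUE)
  expect_false(rep$r4$pass)
  expect_false(rep$r6$pass)
  expect_s3_class(classify(rep), "confidence_call")
})

test_that("thresholds validate their inputs", {
  expect_error(mirna_thresholds(min_excision = 1.5), class = "parameter_error")
  expect_error(mirna_thresholds(max_mismatches = NA), class = "parameter_error")
})

test_that("relaxing/tightening a threshold moves calls monotonically", {
  # spot check at the rule level (the full 11-threshold suite runs in the
  # acceptance tests)
  base <- eval_call(mk_profile(mismatches = 4))
  relaxed <- eval_call(mk_profile(mismatches = 4),
                       thresholds = mirna_thresholds(max_mismatches = 6))
  tightened <- eval_call(mk_profile(mismatches = 4),
                         thresholds = mirna_thresholds(max_mismatches = 3))
  expect_gte(category_rank(relaxed$category), category_rank(base$category))
  expect_lte(category_rank(tightened$category), category_rank(base$category))
})
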