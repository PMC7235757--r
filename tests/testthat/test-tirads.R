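# The five classifiers: published rule examples, hand-summed ACR scores,
# suspicion-count oracle, and the ordinal/monotonicity properties.

test_that("EU-TIRADS assigns the published pattern categories", {
  expect_equal(classify_eu(make_nodule(echogenicity = "isoechoic")), "3")
  expect_equal(classify_eu(make_nodule(echogenicity = "hyperechoic")), "3")
  expect_equal(classify_eu(make_nodule(echogenicity = "mild_hypoechoic")), "4")
  expect_equal(classify_eu(make_nodule(composition = "spongiform")), "2")
  expect_equal(classify_eu(make_nodule(foci_microcalcification = TRUE)), "5")
  expect_equal(classify_eu(make_nodule(echogenicity = "marked_hypoechoic")), "5")
  expect_equal(classify_eu(make_nodule(margins = "irregular")), "5")
  expect_equal(classify_eu(make_nodule(taller_than_wide = TRUE)), "5")
})

test_that("EU category 5 is equivalent to >=1 suspicious feature for solid/mixed", {
  cohort <- random_cohort(400, seed = 21)
  cohort <- cohort[cohort$composition %in% c("solid", "mixed"), ]
  suspicious <- cohort$taller_than_wide |
    cohort$margins %in% c("irregular", "extrathyroidal_extension") |
    cohort$foci_microcalcification |
    cohort$echogenicity == "marked_hypoechoic"
  expect_equal(classify_eu(cohort) == "5", suspicious)
})

test_that("an anechoic solid nodule is rejected as contradictory", {
  bad <- make_nodule(composition = "solid", echogenicity = "anechoic")
  expect_error(classify_eu(bad), "anechoic solid")
})

test_that("ACR scores match hand-computed point sums", {
  expect_equal(score_acr(make_nodule(echogenicity = "mild_hypoechoic"))$total,
               2 + 2 + 0 + 0 + 0)
  expect_equal(score_acr(make_nodule(composition = "spongiform"))$total,
               0 + 1 + 0 + 0 + 0)
  stacked <- make_nodule(echogenicity = "marked_hypoechoic",
                         taller_than_wide = TRUE, margins = "irregular",
                         foci_microcalcification = TRUE)
  expect_equal(score_acr(stacked)$total, 2 + 3 + 3 + 2 + 3)
  expect_equal(score_acr(stacked)$total,
               sum(score_acr(stacked)[1, 1:5]))  # total = component sum
  # foci points sum over all co-occurring foci
  multi <- make_nodule(foci_microcalcification = TRUE,
                       foci_macrocalcification = TRUE,
                       foci_rim_calcification = TRUE)
  expect_equal(score_acr(multi)$points_foci, 3 + 1 + 2)
})

test_that("ACR score bands map to the published categories", {
  # totals 0, 2, 3, 5, 7 via constructed records
  cystic0 <- make_nodule(composition = "cystic", echogenicity = "anechoic")
  expect_equal(score_acr(cystic0)$total, 0)
  expect_equal(classify_acr(cystic0), "1")
  mixed2 <- make_nodule(composition = "mixed")        # 1 + 1
  expect_equal(score_acr(mixed2)$total, 2)
  expect_equal(classify_acr(mixed2), "2")
  solid3 <- make_nodule()                              # 2 + 1
  expect_equal(classify_acr(solid3), "3")
  solid5 <- make_nodule(echogenicity = "mild_hypoechoic",
                        foci_macrocalcification = TRUE)  # 2+2+1
  expect_equal(score_acr(solid5)$total, 5)
  expect_equal(classify_acr(solid5), "4")
  solid7 <- make_nodule(echogenicity = "mild_hypoechoic",
                        foci_microcalcification = TRUE)  # 2+2+3
  expect_equal(score_acr(solid7)$total, 7)
  expect_equal(classify_acr(solid7), "5")
})

test_that("adding a positive-point feature never lowers the ACR category", {
  cohort <- random_cohort(300, seed = 22)
  base_rank <- category_rank(classify_acr(cohort))
  bumped <- cohort
  bumped$foci_microcalcification <- TRUE
  expect_true(all(category_rank(classify_acr(bumped)) >= base_rank))
  bumped2 <- cohort
  bumped2$taller_than_wide <- TRUE
  expect_true(all(category_rank(classify_acr(bumped2)) >= base_rank))
})

test_that("Horvath patterns match the published examples, highest risk first", {
  expect_equal(classify_horvath(make_nodule(background_hashimoto = TRUE)),
               "3", ignore_attr = TRUE)
  expect_equal(classify_horvath(make_nodule(composition = "mixed",
                                            colloid_pattern = TRUE)),
               "2", ignore_attr = TRUE)
  p4b <- make_nodule(echogenicity = "mild_hypoechoic", margins = "irregular",
                     vasc_2d = "penetrating", foci_microcalcification = TRUE)
  expect_equal(classify_horvath(p4b), "4B", ignore_attr = TRUE)
  p5 <- make_nodule(echogenicity = "isoechoic", capsule_2d = "nonencapsulated",
                    foci_microcalcification = TRUE, vasc_2d = "hypervascular")
  expect_equal(classify_horvath(p5), "5", ignore_attr = TRUE)
  # pattern precedence: a record matching both 5 and lower tiers gets 5
  p5_hashi <- make_nodule(echogenicity = "isoechoic",
                          capsule_2d = "nonencapsulated",
                          foci_microcalcification = TRUE,
                          vasc_2d = "hypervascular",
                          background_hashimoto = TRUE)
  expect_equal(classify_horvath(p5_hashi), "5", ignore_attr = TRUE)
})

test_that("unmatched solid nodules fall back to Horvath 4A and are counted", {
  plain <- make_nodule()   # solid isoechoic, no pattern applies
  out <- classify_horvath(plain)
  expect_equal(out, "4A", ignore_attr = TRUE)
  expect_equal(attr(out, "n_fallback"), 1L)
})

test_that("suspicion counts match the published feature list", {
  quiet <- make_nodule(strain_ratio = 2)
  expect_equal(count_suspicion(quiet)$count, 0L)
  three <- make_nodule(taller_than_wide = TRUE, foci_microcalcification = TRUE,
                       strain_ratio = 5)
  expect_equal(count_suspicion(three, include_4d = FALSE)$count, 3L)
  four <- make_nodule(taller_than_wide = TRUE, foci_microcalcification = TRUE,
                      strain_ratio = 5, d3_capsule_altered = TRUE)
  expect_equal(count_suspicion(four, include_4d = TRUE)$count, 4L)
  expect_equal(count_suspicion(four, include_4d = FALSE)$count, 3L)
})

test_that("a missing strain ratio counts stiffness as absent, with warning", {
  gap <- make_nodule(strain_ratio = NA_real_, taller_than_wide = TRUE)
  expect_warning(out <- count_suspicion(gap), "strain ratio unavailable")
  expect_equal(out$count, 1L)
  expect_false(out$stiff_elastography)
})

test_that("suspicion count agrees with a brute-force feature re-count", {
  cohort <- random_cohort(500, seed = 23)
  for (with4d in c(FALSE, TRUE)) {
    got <- count_suspicion(cohort, include_4d = with4d)
    brute <- vapply(seq_len(nrow(cohort)), function(i) {
      r <- cohort[i, ]
      sum(r$taller_than_wide,
          r$margins %in% c("irregular", "extrathyroidal_extension"),
          r$echogenicity == "marked_hypoechoic",
          r$foci_microcalcification,
          r$strain_ratio > 4,
          with4d && (r$d3_capsule_altered || r$d3_intranodular_increased))
    }, double(1))
    expect_equal(got$count, as.integer(brute))
    expect_equal(got$count, as.integer(rowSums(got[setdiff(names(got), "count")])))
  }
})

test_that("French TI-RADS assigns the published pattern categories", {
  expect_equal(classify_french(make_nodule(suspicious_lymph_nodes = TRUE)), "5")
  two <- make_nodule(margins = "irregular", strain_ratio = 4.5)
  expect_equal(classify_french(two), "4B")
  expect_equal(classify_french(make_nodule(echogenicity = "mild_hypoechoic")),
               "4A")
  expect_equal(classify_french(make_nodule()), "3")
  expect_equal(classify_french(make_nodule(composition = "spongiform")), "2")
  expect_equal(classify_french(make_nodule(composition = "cystic",
                                           echogenicity = "anechoic")), "2")
  three <- make_nodule(taller_than_wide = TRUE, foci_microcalcification = TRUE,
                       strain_ratio = 5)
  expect_equal(classify_french(three), "5")
})

test_that("isolated macrocalcification is French category 2, but only isolated", {
  iso_macro <- make_nodule(foci_macrocalcification = TRUE)
  expect_equal(classify_french(iso_macro), "2")
  with_micro <- make_nodule(foci_macrocalcification = TRUE,
                            foci_microcalcification = TRUE)
  expect_equal(classify_french(with_micro), "4B")  # micro = 1 suspicion feature
  with_feature <- make_nodule(foci_macrocalcification = TRUE,
                              taller_than_wide = TRUE)
  expect_equal(classify_french(with_feature), "4B")
})

test_that("blurred margins are not a French suspicion feature", {
  blurred <- make_nodule(margins = "blurred_ill_defined")
  expect_equal(count_suspicion(blurred)$count, 0L)
  expect_equal(classify_french(blurred), "3")
})

test_that("the 4D variant never downgrades and reduces to French when 4D-negative", {
  cohort <- random_cohort(2000, seed = 24)
  base <- classify_french(cohort, include_4d = FALSE)
  plus <- classify_french(cohort, include_4d = TRUE)
  expect_true(all(category_rank(plus) >= category_rank(base)))
  neg <- !doppler4d_positive(cohort)
  expect_equal(plus[neg], base[neg])
})

test_that("every valid record receives exactly one category on each system's scale", {
  cohort <- random_cohort(1000, seed = 25)
  for (system in tirads_systems()) {
    label <- tirads_classify(cohort, system)
    expect_equal(length(label), nrow(cohort))
    expect_true(all(label %in% system_scale(system)))
    expect_false(anyNA(label))
  }
})

test_that("binary calls use each system's operating threshold", {
  expect_false(binary_call("4A", "french"))
  expect_true(binary_call("4B", "french"))
  expect_true(binary_call("4", "eu"))
  expect_false(binary_call("3", "eu"))
  for (system in tirads_systems()) expect_false(binary_call("2", system))
  # threshold override
  expect_true(binary_call("4A", "french", threshold = "4A"))
})
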