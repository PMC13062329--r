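dict <- load_drug_dictionary()

test_that("the shipped dictionary covers the ten target ICIs", {
  targets <- dict[dict$is_target_ici, ]
  expect_setequal(unique(targets$ingredient), target_ici_ingredients())
  expect_setequal(unique(targets$ici_class), c("PD1", "PDL1", "CTLA4"))
})

test_that("names normalize through canonicalization and exact lookup", {
  expect_equal(normalize_drug_name("Keytruda", dict), "PEMBROLIZUMAB")
  expect_equal(normalize_drug_name("  nivolumab 240 MG ", dict), "NIVOLUMAB")
  expect_equal(normalize_drug_name("opdivo 3 MG/ML infusion", dict),
               "NIVOLUMAB")
  expect_true(is.na(normalize_drug_name("VITAMIN B12", dict)))
  # idempotent on its own outputs
  out <- normalize_drug_name(c("Keytruda", "TECENTRIQ"), dict)
  expect_equal(normalize_drug_name(out, dict), out)
})

test_that("exposure uses suspect roles only; partners are kept", {
  drugs <- tibble::tibble(
    primaryid = c("1", "1", "2", "2", "3"),
    drug_seq = c("1", "2", "1", "2", "1"),
    role_cod = c("PS", "C", "PS", "SS", "C"),
    drugname = c("Keytruda", "Levothyroxine", "Opdivo", "Yervoy",
                 "nivolumab")
  )
  prof <- exposure_profiles(drugs, dict)
  p1 <- prof[prof$primaryid == "1", ]
  expect_equal(p1$target_icis[[1]], "PEMBROLIZUMAB")
  expect_equal(p1$concomitant[[1]], "LEVOTHYROXINE")
  expect_equal(p1$co_suspect[[1]], character(0))

  p2 <- prof[prof$primaryid == "2", ]
  expect_setequal(p2$target_icis[[1]], c("NIVOLUMAB", "IPILIMUMAB"))
  expect_setequal(p2$target_classes[[1]], c("PD1", "CTLA4"))

  # a concomitant ICI does not qualify as exposure
  p3 <- prof[prof$primaryid == "3", ]
  expect_equal(p3$n_target, 0L)
  expect_equal(p3$concomitant[[1]], "NIVOLUMAB")
})

test_that("unnormalizable names survive with a RAW prefix", {
  drugs <- tibble::tibble(primaryid = "1", drug_seq = "1", role_cod = "SS",
                          drugname = "mystery compound 12")
  prof <- exposure_profiles(drugs, dict)
  expect_equal(prof$co_suspect[[1]], "RAW:MYSTERY COMPOUND")
  expect_equal(prof$unnormalized, 1L)
})

test_that("profiles are invariant to drug-record order", {
  drugs <- tibble::tibble(
    primaryid = rep("9", 4),
    drug_seq = as.character(1:4),
    role_cod = c("PS", "SS", "C", "C"),
    drugname = c("TECENTRIQ", "paclitaxel", "PREDNISONE", "Synthroid")
  )
  a <- exposure_profiles(drugs, dict)
  b <- exposure_profiles(drugs[sample(4), ], dict)
  expect_equal(a$target_icis, b$target_icis)
  expect_equal(a$co_suspect, b$co_suspect)
  expect_equal(a$concomitant, b$concomitant)
})

test_that("monotherapy means one ICI and no other suspect", {
  prof <- tibble::tibble(
    n_target = c(1L, 2L, 1L),
    n_co_suspect = c(0L, 0L, 1L)
  )
  expect_equal(is_monotherapy(prof), c(TRUE, FALSE, FALSE))
  expect_error(is_monotherapy(tibble::tibble(n_target = 0L,
                                             n_co_suspect = 0L)),
               "undefined")
})
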