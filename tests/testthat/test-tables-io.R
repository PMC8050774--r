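test_that("evidence parsing honours the dialect and the missing-value contract", {
  f <- write_tmp(c(
    "Sequence\tCharge\tIntensity H\tIntensity L\tProtein group IDs\tRaw file",
    "PEPTIDEK\t2\t100.5\t200\tP001\trun_b1t1",
    "AAAK\t3\t\t50\tP002\trun_b1t1",
    "GGGGK\t2\t1e6\t\tP003\trun_b1t1"
  ))
  ev <- read_evidence(f)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$intensity_heavy, c(100.5, NA, 1e6))
  expect_equal(ev$intensity_light, c(200, 50, NA))
  expect_true(is.na(ev$intensity_heavy[2]))   # absent, never 0
  expect_equal(ev$peptide_sequence[1], "PEPTIDEK")

  # missing mandatory column names the column
  f2 <- write_tmp(c("Charge\tIntensity H\tIntensity L\tProtein group IDs",
                    "2\t1\t1\tP001"))
  expect_error(read_evidence(f2), "Sequence")

  # unparsable numeric reports the file line
  f3 <- write_tmp(c(
    "Sequence\tCharge\tIntensity H\tIntensity L\tProtein group IDs",
    "AAAK\t2\t10\t20\tP001",
    "CCCK\t2\tnot_a_number\t20\tP002"
  ))
  expect_error(read_evidence(f3), "line 3")

  # both channels absent is a contract violation
  f4 <- write_tmp(c(
    "Sequence\tCharge\tIntensity H\tIntensity L\tProtein group IDs",
    "AAAK\t2\t\t\tP001"
  ))
  expect_error(read_evidence(f4), "both channel intensities absent")
})

test_that("protein-groups flags use the '+' dialect and members split in order", {
  f <- write_tmp(c(
    paste("Protein group IDs", "Protein IDs", "Ratio H/L normalized",
          "Intensity H", "Intensity L", "Reverse", "Potential contaminant",
          "Only identified by site", sep = "\t"),
    "G1\tA;B\t1.5\t10\t20\t+\t\t",
    "G2\tC\t0.5\t5\t5\t\t+\t+"
  ))
  pg <- read_protein_groups(f)
  expect_equal(pg$flag_reverse, c(TRUE, FALSE))
  expect_equal(pg$flag_contaminant, c(FALSE, TRUE))
  expect_equal(pg$flag_only_by_site, c(FALSE, TRUE))
  expect_equal(pg$member_protein_ids[[1]], c("A", "B"))

  # header-only file gives an empty table
  f2 <- write_tmp(paste("Protein group IDs", "Protein IDs", "Reverse",
                        sep = "\t"))
  expect_equal(nrow(read_protein_groups(f2)), 0)
})

test_that("site tables validate residues and localization probabilities", {
  f <- write_tmp(c(
    paste("Protein group IDs", "Position", "Amino acid", "Localization prob",
          "Ratio H/L normalized b1t1", "Ratio H/L normalized b2t1", sep = "\t"),
    "P1\t10\tS\t0.99\t2.0\t",
    "P2\t4\tY\t0.5\t0.5\t1.0"
  ))
  s <- read_sites(f)
  expect_equal(attr(s, "ratio_labels"), c("b1t1", "b2t1"))
  expect_equal(s$`ratio_hl.b1t1`, c(2, 0.5))
  expect_true(is.na(s$`ratio_hl.b2t1`[1]))

  f2 <- write_tmp(c(
    "Protein group IDs\tPosition\tAmino acid\tLocalization prob",
    "P1\t10\tK\t0.9"
  ))
  expect_error(read_sites(f2), "not one of S/T/Y")
  f3 <- write_tmp(c(
    "Protein group IDs\tPosition\tAmino acid\tLocalization prob",
    "P1\t10\tS\t1.4"
  ))
  expect_error(read_sites(f3), "outside")
})

test_that("GMT parsing extracts members and rejects degenerate lines", {
  f <- write_tmp(c("SETX\tdesc\tG1\tG2", "SETY\tother\tG3"))
  sets <- read_gmt(f)
  expect_named(sets, c("SETX", "SETY"))
  expect_setequal(sets$SETX$members, c("G1", "G2"))
  expect_equal(sets$SETX$description, "desc")

  expect_error(read_gmt(write_tmp("EMPTY\tdesc")), "no members")
  expect_error(read_gmt(write_tmp(c("S\td\tG1", "S\td\tG2"))), "duplicated")
})

test_that("annotation maps each protein to at most one category", {
  f <- write_tmp(c("Protein ID\tCategory\tMitochondrial",
                   "P1\tOXPHOS\t+", "P2\tRibosome\t"))
  an <- read_annotation(f)
  expect_equal(an$is_mitochondrial, c(TRUE, FALSE))
  expect_equal(an$functional_category, c("OXPHOS", "Ribosome"))

  f2 <- write_tmp(c("Protein ID\tCategory", "P1\tA", "P1\tB"))
  expect_error(read_annotation(f2), "more than one category")
})

test_that("write-then-read round-trips are lossless on randomized fixtures", {
  set.seed(101)
  for (i in 1:30) {
    d <- tempfile()
    dir.create(d)

    ev <- random_evidence(sample(5:25, 1))
    write_evidence(ev, file.path(d, "ev.txt"))
    ev2 <- read_evidence(file.path(d, "ev.txt"))
    expect_equal(ev2, ev, tolerance = 1e-12)
    # count of absent cells preserved
    expect_identical(sum(is.na(ev2$intensity_heavy)), sum(is.na(ev$intensity_heavy)))
    expect_identical(sum(is.na(ev2$intensity_light)), sum(is.na(ev$intensity_light)))

    pg <- random_protein_groups(sample(3:12, 1))
    write_protein_groups(pg, file.path(d, "pg.txt"))
    pg2 <- read_protein_groups(file.path(d, "pg.txt"))
    expect_equal(pg2[names(pg)], pg, tolerance = 1e-12)

    st <- random_sites(sample(3:12, 1))
    st$localization_prob <- round(runif(nrow(st), 0.1, 0.99), 6)
    write_sites(st, file.path(d, "st.txt"))
    st2 <- read_sites(file.path(d, "st.txt"))
    expect_equal(st2[names(st)], st, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(attr(st2, "ratio_labels"), attr(st, "ratio_labels"))

    sets <- lapply(sprintf("SET%d", 1:sample(2:5, 1)), function(id)
      list(set_id = id, description = paste("d", id),
           members = sample(sprintf("P%02d", 1:30), sample(2:8, 1))))
    names(sets) <- vapply(sets, `[[`, "", "set_id")
    write_gmt(sets, file.path(d, "s.gmt"))
    expect_identical(read_gmt(file.path(d, "s.gmt")), sets)

    an <- data.frame(protein_id = sprintf("P%02d", sample(1:50, 8)),
                     functional_category = sample(LETTERS[1:3], 8, TRUE),
                     is_mitochondrial = runif(8) < 0.5,
                     stringsAsFactors = FALSE)
    write_annotation(an, file.path(d, "an.txt"))
    expect_equal(read_annotation(file.path(d, "an.txt")), an)
    unlink(d, recursive = TRUE)
  }
})
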