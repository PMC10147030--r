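test_that("default scales encode the rubric bands with the stated inclusivity", {
  sc <- default_scales()
  expect_named(sc, rubric_attributes())

  # printed boundary semantics: plain ends closed, ">"-prefixed ends open
  expect_identical(score_value(sc$rooting_pct, 72), 5L)
  expect_identical(score_value(sc$rooting_pct, 70), 4L)
  expect_identical(score_value(sc$rooting_pct, 5), 1L)
  expect_identical(score_value(sc$rooting_pct, 4.999), 0L)
  expect_identical(score_value(sc$tpc_mgGAE_100g, 20), 1L)
  expect_identical(score_value(sc$tpc_mgGAE_100g, 19.99), 0L)
  expect_identical(score_value(sc$tpc_mgGAE_100g, 250), 5L)  # clamp above 200
  expect_identical(score_value(sc$tree_height_18m_m, 0), 0L) # failed to grow
  expect_identical(score_value(sc$tree_height_18m_m, 2.01), 5L)
  expect_identical(score_value(sc$growth_rate_pct, 20), 4L)
  expect_identical(score_value(sc$growth_rate_pct, 20.5), 5L)

  # molecular authentication admits only 0 / 5
  expect_identical(score_value(sc$molecular_auth, TRUE), 5L)
  expect_identical(score_value(sc$molecular_auth, FALSE), 0L)

  # fruit onset: earlier seasons score higher
  onsets <- vapply(c(1, 2, 3, 4, 5, 6, 9), function(s)
    score_value(sc$fruit_onset, s), integer(1))
  expect_identical(onsets, c(5L, 5L, 4L, 3L, 2L, 1L, 1L))
})

test_that("missing values score 0 and wrong types are rejected", {
  sc <- default_scales()
  for (id in rubric_attributes())
    expect_identical(score_value(sc[[id]], NA), 0L)
  expect_identical(score_value(sc$rooting_pct, NULL), 0L)
  expect_error(score_value(sc$rooting_pct, -1), class = "nupeval_validation_error")
  expect_error(score_value(sc$rooting_pct, TRUE), class = "nupeval_type_error")
  expect_error(score_value(sc$molecular_auth, 1), class = "nupeval_type_error")
  expect_error(score_value(sc$fruit_onset, 2.5), class = "nupeval_validation_error")
})

test_that("numeric scales partition their domain and are monotone", {
  sc <- default_scales()
  edges <- list(rooting_pct = c(5, 20, 30, 50, 70),
                antioxidant_aa_pct = c(5, 20, 40, 65, 85),
                tpc_mgGAE_100g = c(20, 50, 80, 100, 150, 200),
                tree_height_18m_m = c(0.5, 1, 1.5, 2),
                growth_rate_pct = c(5, 10, 15, 20))
  for (id in names(edges)) {
    e <- edges[[id]]
    grid <- sort(unique(c(seq(0, max(e) * 1.3, length.out = 400),
                          e, e - 1e-9, e + 1e-9)))
    scores <- vapply(grid, function(v) score_value(sc[[id]], v), integer(1))
    # exactly one band per value (no error raised) and monotone in the raw value
    expect_true(all(diff(scores) >= 0), info = id)
    expect_true(all(scores >= 0 & scores <= 5), info = id)
  }
})

test_that("species scoring averages genotypes, takes earliest onset, all-distinct molecular", {
  g1 <- genotype_measurements("GR-1-BBGK-19,191", rooting_pct = 60,
                              aa_rsa_pct = 90, tpc = 120, height_18m = 2.4,
                              growth_rate_6_18 = 25, fruit_onset_season = 3,
                              genetically_distinct = TRUE)
  g2 <- genotype_measurements("GR-1-BBGK-19,635", rooting_pct = 80,
                              aa_rsa_pct = 86, height_18m = 2.2,
                              growth_rate_6_18 = 35, fruit_onset_season = 2,
                              genetically_distinct = NA)
  card <- score_species(species_profile("Rosa canina", list(g1, g2)))
  # rooting mean 70 lies in (50, 70] -> 4; aa mean 88 -> 5; tpc only g1 -> 120 -> 4
  expect_identical(unname(card$scores), c(5L, 4L, 5L, 4L, 5L, 5L, 5L))
  expect_identical(card$total, 33L)
  expect_equal(card$percentage, 94.3)

  # one non-distinct genotype pulls molecular authentication to 0
  g3 <- genotype_measurements("x", genetically_distinct = FALSE)
  card2 <- score_species(species_profile("sp", list(g1, g3)))
  expect_identical(card2$scores[["molecular_auth"]], 0L)

  # empty measurements throughout score 0 everywhere
  card3 <- score_species(species_profile("sp", list(genotype_measurements("y"))))
  expect_identical(card3$total, 0L)
  expect_equal(card3$percentage, 0)
})

test_that("percentage of maximum inverts back to the total for every possible total", {
  for (t in 0:35) {
    p <- potential_percentage(t)
    expect_identical(round(p * 35 / 100), as.numeric(t))
  }
  expect_error(potential_percentage(36), class = "nupeval_validation_error")
  expect_error(potential_percentage(-1), class = "nupeval_validation_error")
})

test_that("species comparison sorts by percentage with alphabetical ties", {
  mk <- function(name, base) {
    fives <- base %/% 5L; rem <- base %% 5L
    scores <- c(rep(5L, fives), rem, rep(0L, 7L))[1:7]
    names(scores) <- rubric_attributes()
    nupeval:::new_multifaceted_scorecard(name, scores)
  }
  cards <- list(mk("Cornus mas", 33), mk("Amelanchier ovalis", 35),
                mk("Rosa canina", 34))
  tab <- compare_species(cards)
  expect_identical(tab$species,
                   c("Amelanchier ovalis", "Rosa canina", "Cornus mas"))
  expect_true(all(diff(tab$percentage) <= 0))

  tie <- compare_species(list(mk("b species", 30), mk("a species", 30)))
  expect_identical(tie$species, c("a species", "b species"))

  single <- compare_species(list(mk("solo", 20)))
  expect_identical(nrow(single), 1L)
  expect_error(compare_species(list(mk("dup", 30), mk("dup", 28))),
               class = "nupeval_validation_error")
})

test_that("genotype measurement validation enforces domains and trims accessions", {
  expect_error(genotype_measurements("a", rooting_pct = 105),
               class = "nupeval_validation_error")
  expect_error(genotype_measurements("a", tpc = -2),
               class = "nupeval_validation_error")
  expect_error(genotype_measurements(""), class = "nupeval_validation_error")
  g <- genotype_measurements("  GR-1-BBGK-19,191 ", growth_rate_6_18 = 150)
  expect_identical(g$accession, "GR-1-BBGK-19,191")
  expect_identical(g$growth_rate_6_18, 150)
  expect_error(species_profile("sp", list()), class = "nupeval_validation_error")
})
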