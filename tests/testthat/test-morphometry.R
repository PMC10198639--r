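# Normalized landmark distances, landmark assignment, occurrence
# frequencies, and the species-effect test with post hoc contrasts.

test_that("normalized distance obeys its arithmetic contracts", {
  expect_equal(normalizedDistance(5, 5, 100), 0)
  expect_equal(normalizedDistance(17.5 + 2, 2, 175), 0.1)
  # antisymmetry and rigid-shift invariance
  expect_equal(normalizedDistance(3, 8, 60),
               -normalizedDistance(8, 3, 60))
  expect_equal(normalizedDistance(3 + 11, 8 + 11, 60),
               normalizedDistance(3, 8, 60))
  # missing feature Y propagates, invalid extent errors
  expect_true(is.na(normalizedDistance(NA, 5, 60)))
  expect_error(normalizedDistance(1, 2, 0), "apExtent")
})

test_that("landmark assignment recovers the generating anchor", {
  # candidates 10 mm apart, jitter SD 1 mm (1/10 of the spacing)
  lms <- new("LandmarkSet",
             table = data.frame(species = "macaque",
                                landmark = c("anterior_commissure",
                                             "optic_chiasma_rostral"),
                                y = c(0, 10)),
             apExtent = c(macaque = 60))
  hits <- vapply(seq_len(500), function(s) {
    set.seed(s)
    rec <- data.frame(species = "macaque",
                      caudal_y = rnorm(20, mean = 0, sd = 1))
    assignLandmark(rec, lms)$landmark == "anterior_commissure"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("assignment handles single records, ties and missing data", {
  lms <- new("LandmarkSet",
             table = data.frame(species = "macaque",
                                landmark = c("anterior_commissure",
                                             "optic_chiasma_rostral"),
                                y = c(0, 10)),
             apExtent = c(macaque = 60))
  one <- data.frame(species = "macaque", caudal_y = 10)
  a <- assignLandmark(one, lms)
  expect_identical(a$landmark, "optic_chiasma_rostral")
  expect_equal(a$medians$median[a$medians$landmark == a$landmark], 0)
  expect_false(a$tie)
  # exactly midway -> tie, resolved to the more caudal landmark
  mid <- data.frame(species = "macaque", caudal_y = 5)
  am <- assignLandmark(mid, lms)
  expect_true(am$tie)
  expect_identical(am$landmark, "anterior_commissure")
  expect_error(assignLandmark(data.frame(species = "macaque",
                                         caudal_y = NA_real_), lms),
               "missing")
})

test_that("occurrence frequencies equal brute-force proportions", {
  rec <- data.frame(
    species = rep(c("a", "b"), each = 4),
    feature = "s1", type = "sulcus",
    present = c(TRUE, TRUE, TRUE, FALSE, rep(TRUE, 4)))
  fr <- occurrenceFrequency(rec)
  expect_equal(fr$percent[fr$species == "a"], 75)
  expect_equal(fr$percent[fr$species == "b"], 100)
  expect_equal(fr$n, c(4L, 4L))
  # simulated table against an independent tally
  preset <- studyPreset()
  tab <- simulateSulcalTables(preset$species, preset$landmarks, seed = 8L)
  fr2 <- occurrenceFrequency(tab)
  for (r in sample(nrow(fr2), 5)) {
    sel <- tab$species == fr2$species[r] & tab$feature == fr2$feature[r]
    expect_equal(fr2$percent[r], 100 * sum(tab$present[sel]) / sum(sel))
  }
  # empty input -> empty table, not zeros
  expect_identical(nrow(occurrenceFrequency(rec[0, ])), 0L)
})

test_that("species test reports numerator df = n_species - 1", {
  cfgs <- nullSpeciesConfigs(p = 0.5, nSubjects = 15L)
  rec <- simulateSulcalTables(cfgs, studyPreset()$landmarks, seed = 1L)
  res <- suppressMessages(speciesEffectTest(rec))
  expect_identical(res@numDf, 3L)
  expect_identical(res@denDf, "n/a")
  expect_true(res@pValue >= 0 && res@pValue <= 1)
  # two species only -> df 1
  rec2 <- rec[rec$species %in% c("human", "macaque"), ]
  expect_identical(suppressMessages(speciesEffectTest(rec2))@numDf, 1L)
})

test_that("a total presence split yields an overwhelming species effect", {
  rec <- data.frame(
    species = rep(c("human", "macaque"), each = 160),
    subject = rep(sprintf("s%03d", 1:160), each = 2),
    present = rep(c(TRUE, FALSE), each = 160))
  expect_warning(res <- speciesEffectTest(rec), "separation")
  expect_lt(res@pValue, 1e-6)
  expect_match(res@method, "Firth")
})

test_that("the mixed model is used when subject effects are real", {
  # strong per-subject random intercepts induce nonzero RE variance
  set.seed(42)
  species <- rep(c("human", "chimpanzee", "baboon", "macaque"), each = 60)
  subject <- paste0(species, rep(1:30, each = 2))
  re <- rnorm(120, sd = 2.5)[match(subject, unique(subject))]
  p <- stats::plogis(0.3 + re)
  rec <- data.frame(species = species, subject = subject,
                    present = stats::rbinom(240, 1, p) == 1)
  res <- speciesEffectTest(rec)
  expect_match(res@method, "GLMM")
  expect_identical(res@numDf, 3L)
})

test_that("the logistic fallback is taken when the RE variance is zero", {
  # one present and one absent hemisphere per subject: within-subject
  # disagreement is maximal, so the RE variance is estimated at its 0 bound
  rec <- expand.grid(hemisphere = c("L", "R"), subj = 1:25,
                     species = c("human", "chimpanzee", "baboon", "macaque"),
                     stringsAsFactors = FALSE)
  rec$subject <- paste0(rec$species, rec$subj)
  rec$present <- rec$hemisphere == "L"
  # perturb a few records so the outcome is not a deterministic function
  rec$present[c(1, 4, 53, 102, 151)] <- !rec$present[c(1, 4, 53, 102, 151)]
  expect_message(res <- speciesEffectTest(rec), "variance estimated at 0")
  expect_match(res@method, "logistic regression")
  # matches a direct glm likelihood-ratio test
  rec$present <- as.integer(rec$present)
  full <- glm(present ~ species, binomial(), rec)
  null <- glm(present ~ 1, binomial(), rec)
  expect_equal(res@statistic, null$deviance - full$deviance,
               tolerance = 1e-10)
  expect_equal(res@pValue,
               pchisq(res@statistic, 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("post hoc contrasts cover all pairs with monotone adjustment", {
  cfgs <- nullSpeciesConfigs(p = 0.4, nSubjects = 20L)
  rec <- simulateSulcalTables(cfgs, studyPreset()$landmarks, seed = 4L)
  ph <- suppressMessages(pairwisePosthoc(rec))
  expect_identical(nrow(ph), 6L)  # C(4,2)
  expect_true(all(ph$pAdjusted >= ph$p - 1e-15))
  # a species with no data yields missing rows
  rec3 <- rec[rec$species != "baboon", ]
  ph3 <- suppressMessages(
    pairwisePosthoc(rec3, species = c("human", "chimpanzee", "baboon",
                                      "macaque")))
  expect_identical(nrow(ph3), 6L)
  expect_true(all(is.na(ph3$p[ph3$species1 == "baboon" |
                                ph3$species2 == "baboon"])))
  expect_true(all(!is.na(ph3$p[ph3$species1 != "baboon" &
                                 ph3$species2 != "baboon"])))
})

test_that("the Firth fit matches ordinary ML away from separation", {
  # with a well-behaved design, bias reduction barely moves the estimates
  set.seed(11)
  x <- rep(c(0, 1), each = 100)
  y <- rbinom(200, 1, stats::plogis(-0.5 + 1 * x))
  X <- cbind(1, x)
  firth <- sulcparc:::.firthLogit(X, y)
  ml <- glm(y ~ x, family = binomial())
  expect_equal(unname(firth$coef), unname(coef(ml)), tolerance = 0.05)
  # and stays finite under complete separation
  ysep <- rep(c(0, 1), each = 100)
  fs <- sulcparc:::.firthLogit(X, ysep)
  expect_true(all(is.finite(fs$coef)))
  expect_lt(max(abs(fs$coef)), 20)
})
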