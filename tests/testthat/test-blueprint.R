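# Blueprint assembly, validation, counting, subsetting, truncation.

# a feasible hand-built assignment: 2 targets, disjoint foils
handAssignment <- function(nTargets = 2) {
  targets <- sprintf("t%d", seq_len(nTargets))
  rows <- list()
  f <- 0
  for (tg in targets) {
    for (slot in list(c("test", "high"), c("test", "medium"), c("test", "low"),
                      c("learning", "medium"))) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, role = slot[1], similarity = slot[2],
        foil1 = sprintf("f%02d", f + 1), foil2 = sprintf("f%02d", f + 2),
        size = 1, deviation = 0.01, stringsAsFactors = FALSE)
      f <- f + 2
    }
  }
  new("TripletAssignment", targets = targets,
      assignments = do.call(rbind, rows), config = list())
}

test_that("each target accrues exactly 5 distinct learning sentences", {
  asg <- handAssignment(8)
  bp <- assembleBlueprint(asg, seed = 3)
  lt <- learningTrials(bp)
  for (tg in targetIds(asg)) {
    fam <- lt$familiarization[lt$familiarization$speaker == tg, ]
    imm <- lt$immediate[lt$immediate$target == tg, ]
    sentences <- unique(c(fam$sentence_1, fam$sentence_2, fam$sentence_3,
                          imm$sentence))
    expect_length(sentences, 5L)
  }
  # familiarization sentences identical across speakers and cycles
  expect_length(unique(c(lt$familiarization$sentence_1,
                         lt$familiarization$sentence_2,
                         lt$familiarization$sentence_3)), 3L)
  # cycle-2 immediate trials use new sentences
  imm <- lt$immediate
  expect_length(intersect(imm$sentence[imm$cycle == 1], imm$sentence[imm$cycle == 2]), 0L)
})

test_that("the full design yields 72 test trials with balanced positions", {
  bp <- assembleBlueprint(handAssignment(8), seed = 1)
  tt <- testTrials(bp)
  expect_equal(nrow(tt), 72L)
  cnt <- table(tt$target_position)
  expect_true(all(abs(cnt - 24) <= 1))
  # full factorial per target
  for (tg in unique(tt$target)) {
    cells <- table(tt$similarity[tt$target == tg], tt$duration[tt$target == tg])
    expect_true(all(cells == 1))
  }
})

test_that("assembly is deterministic given the seed", {
  asg <- handAssignment(4)
  b1 <- assembleBlueprint(asg, seed = 11)
  b2 <- assembleBlueprint(asg, seed = 11)
  b3 <- assembleBlueprint(asg, seed = 12)
  expect_identical(b1@test, b2@test)
  expect_identical(b1@familiarization, b2@familiarization)
  expect_identical(b1@repetition, b2@repetition)
  expect_false(identical(b1@test, b3@test))
})

test_that("sentence pool exhaustion raises assembly errors", {
  asg <- handAssignment(1)
  expect_error(assembleLearningPhase(asg, sprintf("s%d", 1:4)), "exhausted")
  # learning fits but testing needs 3 more unused sentences
  expect_error(assembleBlueprint(asg, sentencePool = sprintf("s%d", 1:6)),
               "exhausted")
})

test_that("assembled blueprints pass the independent validator across seeds", {
  asg <- handAssignment(8)
  for (s in 1:100) {
    bp <- assembleBlueprint(asg, seed = s)
    expect_equal(nrow(validateBlueprint(bp)), 0L)
  }
})

test_that("the validator reports injected faults precisely", {
  bp <- assembleBlueprint(handAssignment(8), seed = 2)
  # swap one test sentence to a learning sentence
  broken <- bp
  broken@test$sentence[5] <- broken@familiarization$sentence_1[1]
  v <- validateBlueprint(broken)
  expect_true("sentence_reuse" %in% v$constraint)
  expect_equal(sum(v$constraint == "sentence_reuse"), 1L)
  # insert a learning-phase foil into a test trial
  broken2 <- bp
  broken2@test$foil1[1] <- broken2@immediate$foil1[1]
  expect_true("foil_novelty" %in% validateBlueprint(broken2)$constraint)
  # unbalance positions
  broken3 <- bp
  broken3@test$target_position <- rep(1L, nrow(broken3@test))
  expect_true("position_balance" %in% validateBlueprint(broken3)$constraint)
})

test_that("stimulus counting reproduces the canonical design sizes", {
  bp <- assembleBlueprint(handAssignment(8), seed = 1)
  cs <- countStimuli(bp)
  expect_equal(cs$learning, 72L)   # 8 x 5 target + 16 x 2 foil sentences
  expect_equal(cs$testing, 216L)   # 72 target + 144 foil presentations
  expect_equal(cs$total, 288L)
  expect_equal(cs$detail$learning_targets, 40L)
  expect_equal(cs$detail$learning_foils, 32L)
  expect_equal(cs$practice, 18L)
})

test_that("subsetting to 26 items yields the validation-size design", {
  bp <- assembleBlueprint(handAssignment(8), seed = 1)
  ids <- withr::with_seed(5, sample(testTrials(bp)$item_id, 26))
  sub <- subsetBlueprint(bp, ids)
  expect_equal(nrow(testTrials(sub)), 26L)
  cs <- countStimuli(sub)
  expect_equal(cs$testing, 78L)
  expect_equal(cs$total, 150L)
  # original fixed order preserved
  expect_equal(testTrials(sub)$order, sort(testTrials(sub)$order))
  # retain all = identity; retain none flags; unknown id errors
  expect_identical(subsetBlueprint(bp, testTrials(bp)$item_id), bp)
  none <- subsetBlueprint(bp, character())
  expect_true("no_test_trials" %in% validateBlueprint(none)$constraint)
  expect_error(subsetBlueprint(bp, "nonexistent_item"), "unknown")
})

test_that("no sentence is shared between learning and testing phases", {
  for (s in c(4, 44)) {
    bp <- assembleBlueprint(handAssignment(8), seed = s)
    lt <- learningTrials(bp)
    learnSent <- c(lt$familiarization$sentence_1, lt$familiarization$sentence_2,
                   lt$familiarization$sentence_3, lt$immediate$sentence)
    expect_length(intersect(learnSent, testTrials(bp)$sentence), 0L)
    expect_lte(length(unique(c(learnSent, testTrials(bp)$sentence))),
               length(bp@sentencePool))
  }
})

test_that("stimulus truncation cuts from onset with an offset ramp", {
  wav <- sin(2 * pi * 100 * seq(0, 1, by = 1 / 48000))
  expect_identical(truncateStimulus(wav, 48000, "full"), wav)
  seg <- truncateStimulus(wav, 48000, "250")
  expect_length(seg, 12000L)
  # ramp drives the tail to (near) zero; hard cut does not
  expect_lt(abs(seg[12000]), 1e-6)
  hard <- truncateStimulus(wav, 48000, "250", rampMs = 0)
  expect_identical(hard, wav[1:12000])
  expect_error(truncateStimulus(wav[1:24000], 48000, "750"), "remain")
  expect_error(truncateStimulus(wav, 48000, "250", onset = length(wav) + 5),
               "onset")
})

test_that("blueprints survive a JSON round trip", {
  bp <- assembleBlueprint(handAssignment(2), seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  writeBlueprintJSON(bp, path)
  bp2 <- readBlueprintJSON(path)
  expect_equal(testTrials(bp2), testTrials(bp))
  expect_equal(bp2@seed, bp@seed)
  expect_equal(nrow(validateBlueprint(bp2)), 0L)
})
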