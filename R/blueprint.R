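# Three-phase test structure: a learning phase of alternating
# familiarization and immediate 3AFC recognition trials over two cycles, a
# passive repetition playlist, and the 3AFC testing phase crossing acoustic
# similarity (high/medium/low) with presentation duration (250 ms, 750 ms,
# full). Sentence assignment is uniform random without replacement under
# the constraints, seeded; sentences never repeat between the learning and
# testing phase, test-phase foils never occurred during learning, and
# target positions are balanced to within +-1 of uniform per phase.

withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# target positions for n 3AFC trials, counts within +-1 of n/3
balancedPositions <- function(n) {
  base <- n %/% 3L
  counts <- rep(base, 3L)
  r <- n - 3L * base
  if (r > 0) {
    extra <- sample(1:3, r)
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(1:3, counts))
}

#' Assemble the learning phase and repetition playlist
#'
#' Two learning-test cycles: on each familiarization trial a target speaker
#' utters three sentences (the same three sentences for every speaker, in
#' both cycles), immediately followed by a 3AFC immediate recognition trial
#' on the target's medium-similarity learning triplet with a previously
#' unheard sentence; cycle 2 uses new sentences on immediate trials. Each
#' target thus accrues five distinct sentences. The repetition playlist
#' draws, per target, one familiarization and one immediate-trial sentence.
#'
#' @param assignment a [TripletAssignment-class].
#' @param sentencePool character vector of available sentence ids.
#' @param seed integer seed; the assembly is deterministic given it.
#' @return list with `familiarization`, `immediate`, `repetition`
#'   data.frames and `usedSentences`.
#' @export
assembleLearningPhase <- function(assignment, sentencePool, seed = 1L) {
  targets <- targetIds(assignment)
  nT <- length(targets)
  need <- 3L + 2L * nT
  if (length(sentencePool) < need)
    stop(sprintf("sentence pool exhausted: learning phase needs %d sentences, pool has %d",
                 need, length(sentencePool)))
  asg <- assignments(assignment)
  learn <- asg[asg$role == "learning", ]
  withLocalSeed(seed, {
    famSentences <- sample(sentencePool, 3L)
    rest <- setdiff(sentencePool, famSentences)
    immSentences <- matrix(sample(rest, 2L * nT), nrow = nT, ncol = 2L,
                           dimnames = list(targets, NULL))
    fam <- imm <- list()
    pos <- balancedPositions(2L * nT)  # balance across the whole phase
    for (cycle in 1:2) {
      ordT <- sample(targets)
      for (k in seq_len(nT)) {
        tg <- ordT[k]
        lt <- learn[learn$target == tg, ]
        fam[[length(fam) + 1L]] <- data.frame(
          cycle = cycle, order = k, speaker = tg,
          sentence_1 = famSentences[1], sentence_2 = famSentences[2],
          sentence_3 = famSentences[3], stringsAsFactors = FALSE)
        imm[[length(imm) + 1L]] <- data.frame(
          cycle = cycle, order = k, target = tg,
          foil1 = lt$foil1, foil2 = lt$foil2,
          target_position = pos[(cycle - 1L) * nT + k],
          sentence = immSentences[tg, cycle],
          similarity = "medium", duration = "full",
          stringsAsFactors = FALSE)
      }
    }
    repOrd <- sample(targets)
    rep_ <- list()
    for (k in seq_along(repOrd)) {
      tg <- repOrd[k]
      rep_[[length(rep_) + 1L]] <- data.frame(
        order = 2L * k - 1L, speaker = tg,
        sentence = sample(famSentences, 1L), source = "familiarization",
        stringsAsFactors = FALSE)
      rep_[[length(rep_) + 1L]] <- data.frame(
        order = 2L * k, speaker = tg,
        sentence = immSentences[tg, sample.int(2L, 1L)], source = "immediate",
        stringsAsFactors = FALSE)
    }
    list(familiarization = do.call(rbind, fam),
         immediate = do.call(rbind, imm),
         repetition = do.call(rbind, rep_),
         usedSentences = c(famSentences, as.vector(immSentences)))
  })
}

#' Assemble the testing phase
#'
#' Per target, the full factorial crossing of acoustic similarity (high,
#' medium, low; one assigned test triplet per level) and presentation
#' duration (250 ms, 750 ms, full). Each (target, similarity) pair gets one
#' sentence never used in the learning phase and not used by any other test
#' trial; the triplet is then presented at all three durations with that
#' sentence. Trials are randomized once into a fixed order with balanced
#' target positions.
#'
#' @param assignment a [TripletAssignment-class].
#' @param sentencePool character vector of sentence ids.
#' @param usedSentences sentences already consumed by the learning phase.
#' @param durations duration levels (default `c("250", "750", "full")`,
#'   ms or "full").
#' @param seed integer seed.
#' @return data.frame of test trials.
#' @export
assembleTestPhase <- function(assignment, sentencePool, usedSentences,
                              durations = c("250", "750", "full"),
                              seed = 1L) {
  targets <- targetIds(assignment)
  asg <- assignments(assignment)
  test <- asg[asg$role == "test", ]
  avail <- setdiff(sentencePool, usedSentences)
  needed <- nrow(test)
  if (length(avail) < needed)
    stop(sprintf("sentence pool exhausted: testing phase needs %d unused sentences, %d available",
                 needed, length(avail)))
  withLocalSeed(seed + 1L, {
    test$sentence <- sample(avail, needed)
    rows <- list()
    for (k in seq_len(nrow(test))) {
      for (d in durations) {
        rows[[length(rows) + 1L]] <- data.frame(
          item_id = sprintf("%s_%s_%s", test$target[k], test$similarity[k], d),
          target = test$target[k], foil1 = test$foil1[k], foil2 = test$foil2[k],
          similarity = as.character(test$similarity[k]), duration = d,
          sentence = test$sentence[k], stringsAsFactors = FALSE)
      }
    }
    trials <- do.call(rbind, rows)
    ord <- sample.int(nrow(trials))
    trials <- trials[ord, , drop = FALSE]
    trials$target_position <- balancedPositions(nrow(trials))
    trials$order <- seq_len(nrow(trials))
    rownames(trials) <- NULL
    trials[, c("item_id", "order", "target", "foil1", "foil2",
               "target_position", "sentence", "similarity", "duration")]
  })
}

#' Assemble a complete three-phase blueprint
#'
#' Runs [assembleLearningPhase()] and [assembleTestPhase()] and wraps the
#' result, together with practice/dummy-trial and break metadata (12
#' practice/dummy slots before learning, 6 before testing; these are
#' presentation metadata only and excluded from analyses), into a
#' [TestBlueprint-class]. Byte-identical output for identical inputs and
#' seed.
#'
#' @param assignment a [TripletAssignment-class].
#' @param sentencePool character vector of sentence ids (default 50 ids,
#'   matching the pseudo-sentence repertoire size the design assumes).
#' @param seed integer seed.
#' @param durations test-phase duration levels.
#' @return a [TestBlueprint-class].
#' @export
assembleBlueprint <- function(assignment,
                              sentencePool = sprintf("s%02d", 1:50),
                              seed = 1L,
                              durations = c("250", "750", "full")) {
  lp <- assembleLearningPhase(assignment, sentencePool, seed)
  tp <- assembleTestPhase(assignment, sentencePool, lp$usedSentences,
                          durations, seed)
  new("TestBlueprint",
      familiarization = lp$familiarization,
      immediate = lp$immediate,
      repetition = lp$repetition,
      test = tp,
      sentencePool = sentencePool,
      practice = list(before_learning = 12L, before_testing = 6L,
                      breaks = "2-min fixed breaks between repetition and testing and after every 18 test trials, beep-signalled"),
      seed = as.integer(seed),
      config = list(durations = durations, response_window_ms = 4000,
                    factorial = TRUE))
}

learningSpeakerSentences <- function(blueprint) {
  fam <- blueprint@familiarization
  imm <- blueprint@immediate
  pairs <- rbind(
    data.frame(speaker = rep(fam$speaker, 3L),
               sentence = c(fam$sentence_1, fam$sentence_2, fam$sentence_3),
               stringsAsFactors = FALSE),
    data.frame(speaker = c(imm$target, imm$foil1, imm$foil2),
               sentence = rep(imm$sentence, 3L), stringsAsFactors = FALSE))
  unique(pairs)
}

#' Validate a blueprint against all structural constraints
#'
#' An independent checker (separate from the assemblers) for every
#' blueprint invariant: sentence novelty between learning and testing,
#' test-phase foil novelty, five distinct learning sentences per target,
#' familiarization-sentence identity across speakers, target-position
#' balance, factorial completeness (for full designs), and immediate-trial
#' structure. Content problems are reported, never raised.
#'
#' @param blueprint a [TestBlueprint-class].
#' @return data.frame of violations (`constraint`, `detail`); zero rows if
#'   and only if the blueprint is valid.
#' @export
validateBlueprint <- function(blueprint) {
  v <- list()
  bad <- function(constraint, detail)
    v[[length(v) + 1L]] <<- data.frame(constraint = constraint, detail = detail,
                                       stringsAsFactors = FALSE)
  fam <- blueprint@familiarization
  imm <- blueprint@immediate
  test <- blueprint@test

  learnSent <- unique(c(fam$sentence_1, fam$sentence_2, fam$sentence_3, imm$sentence))
  reused <- intersect(learnSent, unique(test$sentence))
  for (s in reused) bad("sentence_reuse",
    sprintf("sentence %s appears in both learning and testing phase", s))

  learnSpeakers <- unique(c(fam$speaker, imm$target, imm$foil1, imm$foil2))
  testFoils <- unique(c(test$foil1, test$foil2))
  for (f in intersect(testFoils, learnSpeakers))
    bad("foil_novelty", sprintf("test-phase foil %s occurred in the learning phase", f))

  for (tg in unique(fam$speaker)) {
    s <- unique(c(fam$sentence_1[fam$speaker == tg], fam$sentence_2[fam$speaker == tg],
                  fam$sentence_3[fam$speaker == tg], imm$sentence[imm$target == tg]))
    if (length(s) != 5L)
      bad("learning_sentences",
          sprintf("target %s has %d distinct learning sentences (expected 5)", tg, length(s)))
  }

  for (cycle in unique(fam$cycle)) {
    fc <- fam[fam$cycle == cycle, ]
    sets <- apply(fc[, c("sentence_1", "sentence_2", "sentence_3")], 1L,
                  function(r) paste(sort(r), collapse = "|"))
    if (length(unique(sets)) > 1L)
      bad("familiarization_identity",
          sprintf("cycle %d familiarization sentence sets differ across speakers", cycle))
    if (any(apply(fc[, c("sentence_1", "sentence_2", "sentence_3")], 1L,
                  function(r) length(unique(r))) != 3L))
      bad("familiarization_distinct",
          sprintf("cycle %d has a familiarization trial without 3 distinct sentences", cycle))
  }

  # position balance is a property of the assembled design; an item subset
  # inherits its trials unchanged, so the test phase is only checked when
  # the blueprint still claims the full factorial design
  phases <- list(immediate = imm)
  if (isTRUE(blueprint@config$factorial)) phases$test <- test
  for (ph in names(phases)) {
    df <- phases[[ph]]
    if (!nrow(df)) next
    cnt <- tabulate(df$target_position, 3L)
    if (diff(range(cnt)) > 1L)
      bad("position_balance",
          sprintf("%s-phase target positions %s are not within +-1 of uniform",
                  ph, paste(cnt, collapse = "/")))
  }

  if (nrow(imm)) {
    if (!all(imm$similarity == "medium"))
      bad("immediate_similarity", "immediate trials must use medium-similarity triplets")
    if (!all(imm$duration == "full"))
      bad("immediate_duration", "immediate trials must be presented full-length")
  }

  if (!nrow(test)) {
    bad("no_test_trials", "blueprint has no test trials")
  } else if (isTRUE(blueprint@config$factorial)) {
    durs <- blueprint@config$durations
    for (tg in unique(test$target)) {
      cells <- table(test$similarity[test$target == tg], test$duration[test$target == tg])
      if (!all(dim(cells) == c(3L, length(durs))) || !all(cells == 1L))
        bad("factor_crossing",
            sprintf("target %s does not cover the full similarity x duration factorial once", tg))
    }
  }

  for (df in list(imm, test)) {
    if (!nrow(df)) next
    trio <- cbind(df$target, df$foil1, df$foil2)
    if (any(apply(trio, 1L, function(r) length(unique(r))) != 3L))
      bad("trial_members", "a 3AFC trial must contain three distinct speakers")
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(constraint = character(), detail = character(),
               stringsAsFactors = FALSE)
}

#' Count stimulus presentations per phase
#'
#' Counts every distinct (speaker, sentence, duration) presentation.
#' Familiarization sentences recur in cycle 2 but count once; learning
#' foils utter a different sentence per cycle and count per sentence; each
#' test trial contributes three presentations (target and both foils at the
#' trial's duration). Practice/dummy slots are reported separately and are
#' not experimental stimuli.
#'
#' @param blueprint a [TestBlueprint-class].
#' @return list with `learning`, `testing`, `total` (experimental
#'   stimuli), `practice`, and a `detail` breakdown.
#' @export
countStimuli <- function(blueprint) {
  lp <- learningSpeakerSentences(blueprint)
  test <- blueprint@test
  testStim <- if (nrow(test)) {
    unique(rbind(
      data.frame(speaker = test$target, sentence = test$sentence,
                 duration = test$duration, stringsAsFactors = FALSE),
      data.frame(speaker = test$foil1, sentence = test$sentence,
                 duration = test$duration, stringsAsFactors = FALSE),
      data.frame(speaker = test$foil2, sentence = test$sentence,
                 duration = test$duration, stringsAsFactors = FALSE)))
  } else data.frame()
  nl <- nrow(lp); nt <- nrow(testStim)
  targets <- unique(blueprint@familiarization$speaker)
  list(learning = nl, testing = nt, total = nl + nt,
       practice = sum(unlist(blueprint@practice[c("before_learning", "before_testing")])),
       detail = list(
         learning_targets = nrow(lp[lp$speaker %in% targets, , drop = FALSE]),
         learning_foils = nrow(lp[!lp$speaker %in% targets, , drop = FALSE]),
         testing_targets = if (nt) nrow(testStim[testStim$speaker %in% targets, , drop = FALSE]) else 0L,
         testing_foils = if (nt) nrow(testStim[!testStim$speaker %in% targets, , drop = FALSE]) else 0L,
         test_trials = nrow(test)))
}

#' Reduce a blueprint to a retained item subset
#'
#' Filters the testing phase to the given item ids, preserving the original
#' fixed randomized order; learning and repetition phases are untouched.
#' Proper subsets no longer cover the full factorial, which the validator
#' is told about via the config.
#'
#' @param blueprint a [TestBlueprint-class].
#' @param itemIds test-trial item ids to retain.
#' @return the reduced [TestBlueprint-class].
#' @export
subsetBlueprint <- function(blueprint, itemIds) {
  unknown <- setdiff(itemIds, blueprint@test$item_id)
  if (length(unknown))
    stop("unknown item ids: ", paste(unknown, collapse = ", "))
  keep <- blueprint@test$item_id %in% itemIds
  if (all(keep)) return(blueprint)
  blueprint@test <- blueprint@test[keep, , drop = FALSE]
  rownames(blueprint@test) <- NULL
  blueprint@config$factorial <- FALSE
  blueprint
}

#' Truncate a stimulus waveform from voice onset
#'
#' Extracts a 250 ms or 750 ms segment starting at the voice onset sample,
#' applying a short raised-cosine offset ramp (default 10 ms) so the cut
#' does not click; `"full"` returns the waveform unchanged. Set
#' `rampMs = 0` for a hard cut.
#'
#' @param waveform numeric vector of samples.
#' @param rate sampling rate in Hz.
#' @param duration `"250"`, `"750"` (ms) or `"full"`; numeric ms also
#'   accepted.
#' @param onset voice onset as a sample index (default 1).
#' @param rampMs offset ramp length in ms (default 10).
#' @return the truncated waveform.
#' @export
truncateStimulus <- function(waveform, rate, duration, onset = 1L, rampMs = 10) {
  if (identical(duration, "full")) return(waveform)
  ms <- as.numeric(duration)
  if (!is.finite(ms) || ms <= 0) stop("duration must be 'full' or a positive number of ms")
  if (onset < 1L || onset > length(waveform)) stop("onset outside the waveform")
  n <- round(ms / 1000 * rate)
  if (onset + n - 1L > length(waveform))
    stop(sprintf("requested %g ms from onset but only %.0f ms remain",
                 ms, (length(waveform) - onset + 1) / rate * 1000))
  seg <- waveform[onset:(onset + n - 1L)]
  nr <- min(n, round(rampMs / 1000 * rate))
  if (nr > 0) {
    ramp <- 0.5 * (1 + cos(pi * seq_len(nr) / nr))
    seg[(n - nr + 1L):n] <- seg[(n - nr + 1L):n] * ramp
  }
  seg
}
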