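# Respondent scoring: omission handling (trials with RT >= 4000 ms are
# errors of omission and removed before computing proportion correct, the
# boundary being inclusive), comparison against the 3AFC chance level of
# 1/3, and norm-referenced screening where scores at least 2 SDs below or
# above the norm mean flag potential phonagnosia or super-recognition.
# Flags are screening signals: clinical conclusions require comprehensive
# follow-up testing.

#' Score a response matrix
#'
#' Removes omission trials (response time at or above `rtCutoff`, or
#' missing correctness) person-wise, then computes sum scores and
#' proportion correct over the scored trials. Under the Rasch model the
#' sum score is a sufficient statistic for ability, so both the raw score
#' and the proportion are reported; EAP abilities from [eapAbilities()]
#' are the recommended metric scale. When norms are supplied, each person
#' is flagged via [flagExtremes()].
#'
#' @param responses a [ResponseMatrix-class] (or correctness matrix;
#'   omissions then must already be NA).
#' @param rtCutoff omission cutoff in ms, inclusive (default 4000).
#' @param norms optional norm row: list/data.frame with `mean` and `sd`
#'   (e.g. one row of [defaultNorms()]).
#' @return a [ScoreReport-class].
#' @export
scoreResponses <- function(responses, rtCutoff = 4000, norms = NULL) {
  X <- asCorrectness(responses)
  RT <- if (is(responses, "ResponseMatrix")) responseTimes(responses) else NULL
  scored <- !is.na(X)
  if (!is.null(RT)) scored <- scored & (RT < rtCutoff)
  Xs <- X
  Xs[!scored] <- NA_integer_
  nTrials <- ncol(X)
  nScored <- rowSums(scored)
  if (any(nScored == 0))
    warning("persons with zero scored trials have undefined proportions: ",
            paste(rownames(X)[nScored == 0], collapse = ", "))
  sums <- rowSums(Xs, na.rm = TRUE)
  prop <- ifelse(nScored > 0, sums / nScored, NA_real_)
  persons <- data.frame(
    person = rownames(X),
    n_trials = nTrials,
    n_scored = nScored,
    n_omitted = nTrials - nScored,
    omission_rate = (nTrials - nScored) / nTrials,
    sum_correct = sums,
    proportion_correct = prop,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(norms)) {
    persons$flag <- vapply(persons$proportion_correct, function(s)
      if (is.na(s)) NA_character_ else flagExtremes(s, norms$mean, norms$sd),
      character(1))
  }
  cohort <- list(n = nrow(X),
                 mean = mean(prop, na.rm = TRUE),
                 sd = sd(prop, na.rm = TRUE),
                 range = range(prop, na.rm = TRUE),
                 omission_rate = sum(persons$n_omitted) / sum(persons$n_trials))
  gr <- if (is(responses, "ResponseMatrix")) personGroups(responses) else NULL
  if (!is.null(gr)) {
    cohort$groups <- lapply(setNames(names(gr), names(gr)), function(gv)
      vapply(split(prop, gr[[gv]]), function(x)
        c(n = sum(!is.na(x)), mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE)),
        numeric(3)))
  }
  new("ScoreReport", persons = persons, cohort = cohort, rtCutoff = rtCutoff)
}

#' One-sample t test of scores against chance
#'
#' Compares mean accuracy against the chance constant (1/3 for 3AFC). The
#' degenerate all-at-chance case (zero variance, mean exactly at chance)
#' returns t = 0; zero variance away from chance is an error.
#'
#' @param scores numeric vector of per-person proportions correct.
#' @param chance chance level (default 1/3).
#' @param alternative "greater" (default; is performance above chance?),
#'   "two.sided", or "less".
#' @return list with `t`, `df`, `p`, `mean`, `se`.
#' @export
tVsChance <- function(scores, chance = 1 / 3,
                      alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scores")
  m <- mean(scores); s <- sd(scores)
  if (s == 0) {
    if (m == chance) {
      tt <- 0
    } else stop("scores have zero variance away from chance; t undefined")
  } else tt <- (m - chance) / (s / sqrt(n))
  df <- n - 1L
  p <- switch(alternative,
              greater = pt(tt, df, lower.tail = FALSE),
              less = pt(tt, df),
              two.sided = 2 * pt(-abs(tt), df))
  list(t = tt, df = df, p = p, mean = m, se = s / sqrt(n))
}

#' Flag extreme scores against norms
#'
#' Scores at least 2 SDs below the norm mean flag potential phonagnosia;
#' at least 2 SDs above, potential super-recognition; boundaries are
#' inclusive ("at least"). Flags are screening signals only.
#'
#' @param score proportion correct.
#' @param mean,sd norm mean and SD.
#' @param nSD number of SDs defining "extreme" (default 2).
#' @return one of "potential_phonagnosia", "typical",
#'   "potential_super_recognizer".
#' @export
flagExtremes <- function(score, mean, sd, nSD = 2) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  if (score <= mean - nSD * sd) "potential_phonagnosia"
  else if (score >= mean + nSD * sd) "potential_super_recognizer"
  else "typical"
}

#' Packaged norm table
#'
#' Descriptive norms (proportion correct) for the published validation
#' cohort of the 22-item voice learning and memory test this toolkit
#' models: overall, by gender, and by age band. The age bands are printed
#' with a shared 31-year boundary; [normLookup()] assigns age 31 to the
#' younger band.
#'
#' @return data.frame with `group`, `level`, `mean`, `sd`, `range_lo`,
#'   `range_hi`, `n`.
#' @export
defaultNorms <- function() {
  data.frame(
    group = c("overall", "gender", "gender", "age", "age", "age"),
    level = c("overall", "female", "male", "18-31", "31-45", "46-74"),
    mean = c(0.51, 0.54, 0.50, 0.48, 0.51, 0.57),
    sd = c(0.18, 0.17, 0.18, 0.17, 0.17, 0.17),
    range_lo = c(0.05, 0.11, 0.05, 0.05, 0.13, 0.12),
    range_hi = c(0.95, 0.91, 0.95, 0.91, 0.91, 0.95),
    n = c(454L, 156L, 296L, 163L, 186L, 105L),
    stringsAsFactors = FALSE)
}

#' Look up norm rows for a respondent
#'
#' Returns the overall row plus the matching gender and age-band rows. Age
#' 31 goes to the younger band (documented resolution of the table's
#' shared band boundary); ages above the supported range fall back to the
#' nearest band with a warning; ages below 18 are unsupported.
#'
#' @param age age in years (>= 18).
#' @param gender "female" or "male" (optional; NULL skips the gender row).
#' @param norms a norm table shaped like [defaultNorms()].
#' @return data.frame of matching norm rows.
#' @export
normLookup <- function(age, gender = NULL, norms = defaultNorms()) {
  if (!is.finite(age) || age < 18)
    stop("norms cover ages 18 and above only")
  band <- if (age <= 31) "18-31" else if (age <= 45) "31-45" else "46-74"
  if (age > 74)
    warning("age above the normed range (18-74); using the nearest band")
  rows <- norms[norms$group == "overall" |
                (norms$group == "age" & norms$level == band), , drop = FALSE]
  if (!is.null(gender)) {
    g <- norms[norms$group == "gender" & norms$level == gender, , drop = FALSE]
    if (!nrow(g)) stop("no gender norm row for: ", gender)
    rows <- rbind(rows, g)
  }
  rownames(rows) <- NULL
  rows
}

#' Score an auditory digit-span test
#'
#' Sequences start at length 4 with six trials per length; the length
#' increases once at least five of the six trials are correct, and the
#' test aborts otherwise (so fewer than six trials are tolerated only at
#' the final, aborted length). The span score is the largest length L such
#' that every length from 4 through L has at least five correct trials.
#' Failing at length 4 returns the below-floor sentinel 3.
#'
#' @param trials data.frame with `sequence_length` and `correct` (0/1),
#'   one row per trial, for one participant.
#' @param floorLength first sequence length (default 4).
#' @param trialsPerLength trials per length (default 6).
#' @param passCriterion correct trials needed to pass a length (default 5).
#' @return integer span score (`floorLength - 1` as below-floor sentinel).
#' @export
digitSpanScore <- function(trials, floorLength = 4L, trialsPerLength = 6L,
                           passCriterion = 5L) {
  lens <- sort(unique(trials$sequence_length))
  if (!length(lens) || lens[1] != floorLength)
    stop(sprintf("trial log must start at sequence length %d", floorLength))
  if (!all(diff(lens) == 1L))
    stop("sequence lengths must be contiguous")
  counts <- table(factor(trials$sequence_length, levels = lens))
  if (any(counts[-length(counts)] != trialsPerLength))
    stop(sprintf("every non-final length needs exactly %d trials", trialsPerLength))
  if (counts[length(counts)] > trialsPerLength)
    stop(sprintf("more than %d trials at a single length", trialsPerLength))
  score <- floorLength - 1L
  for (L in lens) {
    nCorrect <- sum(trials$correct[trials$sequence_length == L])
    if (nCorrect >= passCriterion) score <- L else break
  }
  as.integer(score)
}
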