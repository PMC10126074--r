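# Plain-format interchange: CSV for tabular data, JSON (via jsonlite) for
# structured artifacts, with seeds and configuration carried along for
# reproducibility.

#' Read a long-format response log
#'
#' One row per (person, item) response. Recognized columns: `person_id`,
#' `item_id`, `correct` (0/1, empty for no response), optional `rt_ms`,
#' optional `response_position`; any further columns are treated as
#' per-person group labels (they must be constant within person).
#'
#' @param path CSV file.
#' @return a [ResponseMatrix-class].
#' @export
readResponsesLong <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "item_id", "correct")
  if (!all(need %in% names(df)))
    stop("long response CSV needs columns: ", paste(need, collapse = ", "))
  persons <- unique(df$person_id); items <- unique(df$item_id)
  X <- matrix(NA_integer_, length(persons), length(items),
              dimnames = list(persons, items))
  X[cbind(match(df$person_id, persons), match(df$item_id, items))] <-
    as.integer(df$correct)
  RT <- matrix(NA_real_, length(persons), length(items),
               dimnames = dimnames(X))
  if ("rt_ms" %in% names(df))
    RT[cbind(match(df$person_id, persons), match(df$item_id, items))] <- df$rt_ms
  groupCols <- setdiff(names(df), c(need, "rt_ms", "response_position"))
  gdf <- data.frame(row.names = persons)
  for (gc in groupCols) {
    vals <- tapply(df[[gc]], df$person_id, function(v) {
      u <- unique(v)
      if (length(u) > 1L) stop("group column '", gc, "' varies within a person")
      u
    })
    gdf[[gc]] <- as.character(vals[persons])
  }
  new("ResponseMatrix", correctness = X,
      rt = if ("rt_ms" %in% names(df)) RT else matrix(numeric(), 0, 0),
      groups = gdf)
}

#' Read a wide-format response matrix
#'
#' First column `person_id`, remaining columns one per item (0/1/empty).
#'
#' @param path CSV file.
#' @return a [ResponseMatrix-class] (without RTs or groups).
#' @export
readResponsesWide <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "person_id") stop("first column must be person_id")
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "integer"
  rownames(X) <- df$person_id
  new("ResponseMatrix", correctness = X, rt = matrix(numeric(), 0, 0),
      groups = data.frame(row.names = df$person_id))
}

#' Serialize a blueprint to JSON
#'
#' Phases, trials, the sentence pool, practice/break metadata, the seed
#' and the assembly configuration, so a blueprint can be reproduced and
#' audited.
#'
#' @param blueprint a [TestBlueprint-class].
#' @param path output file.
#' @export
writeBlueprintJSON <- function(blueprint, path) {
  jsonlite::write_json(list(
    familiarization = blueprint@familiarization,
    immediate = blueprint@immediate,
    repetition = blueprint@repetition,
    test = blueprint@test,
    sentence_pool = blueprint@sentencePool,
    practice = blueprint@practice,
    seed = blueprint@seed,
    config = blueprint@config
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a blueprint back from JSON
#'
#' @param path file written by [writeBlueprintJSON()].
#' @return a [TestBlueprint-class].
#' @export
readBlueprintJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TestBlueprint",
      familiarization = as.data.frame(x$familiarization),
      immediate = as.data.frame(x$immediate),
      repetition = as.data.frame(x$repetition),
      test = as.data.frame(x$test),
      sentencePool = x$sentence_pool,
      practice = x$practice,
      seed = as.integer(x$seed),
      config = x$config)
}

#' Serialize a fitted IRT model to JSON
#'
#' @param fit an [IRTFit-class].
#' @param path output file.
#' @export
writeFitJSON <- function(fit, path) {
  jsonlite::write_json(list(
    model = fit@model,
    items = itemParams(fit),
    prior = priorParams(fit),
    loglik = fit@loglik, npar = fit@npar,
    AIC = fit@AIC, BIC = fit@BIC,
    n_persons = fit@nPersons, n_items = fit@nItems,
    convergence = fit@convergence,
    quadrature = fit@quad
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-item parameters as CSV
#'
#' @param fit an [IRTFit-class].
#' @param path output file.
#' @export
writeItemTable <- function(fit, path) {
  write.csv(itemParams(fit), path, row.names = FALSE)
  invisible(path)
}

#' Write EAP abilities as CSV
#'
#' @param abilities data.frame from [eapAbilities()].
#' @param path output file.
#' @export
writeAbilities <- function(abilities, path) {
  write.csv(abilities, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a triplet assignment to JSON
#'
#' @param assignment a [TripletAssignment-class].
#' @param path output file.
#' @export
writeAssignmentJSON <- function(assignment, path) {
  jsonlite::write_json(list(
    targets = targetIds(assignment),
    assignments = assignments(assignment),
    config = assignment@config
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
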