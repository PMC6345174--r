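#' Default phrasebook for the corpus simulator
#'
#' Twelve diagnosis groups, each with a handful of terse ED-style complaint
#' templates and positive selection weights. Templates for the
#' pregnancy-related group carry the `"preg"` token (subject to the default
#' gender-exclusivity rule); the injury group carries the `"fall"` token
#' (subject to the default age association rule). All templates are at most
#' 16 words so that name injection can never push a complaint past the
#' 18-word filter.
#'
#' @return named list (by diagnosis code as character) of data frames with
#'   columns `template`, `weight`.
#' @export
defaultPhrasebook <- function() {
  pb <- list(
    "0" = c("chest pain", "chest pain x 2 days", "pt complains of chest pain",
            "chest tightness and pressure", "substernal chest pain radiating to left arm"),
    "1" = c("abd pain", "abdominal pain x 3 days", "pt complains of stomach pain",
            "nausea vomiting and abd pain", "epigastric pain since this morning"),
    "2" = c("fall at home", "s p fall from standing", "pt found on floor after fall",
            "fall with head injury", "twisted ankle playing sports",
            "injury to right hand", "laceration to left leg"),
    "3" = c("od", "overdose", "od narcan given by ems",
            "found unresponsive possible overdose", "intentional overdose of pills",
            "possible od of pills"),
    "4" = c("preg with abd cramping", "preg vaginal spotting", "pelvic pain",
            "lower pelvic pain x 1 week", "pelvic cramping since yesterday"),
    "5" = c("shortness of breath", "sob and wheezing", "asthma attack",
            "difficulty breathing x 1 day", "cough and wheezing"),
    "6" = c("elevated bp", "high blood pressure", "elevated blood pressure no travel",
            "headache with elevated bp"),
    "7" = c("etoh", "etoh consumption", "found on street intoxicated",
            "pt admits to drinking alcohol"),
    "8" = c("mvc", "mva", "pt was rear ended", "pt was in a car accident",
            "neck pain after mvc"),
    "9" = c("anxiety attack", "pt feeling depressed", "suicidal ideation",
            "hearing voices"),
    "10" = c("fever and chills", "fever x 2 days", "sore throat and fever",
             "body aches and fever"),
    "11" = c("lower back pain", "back pain m545", "low back pain x 1 week",
             "back pain radiating down leg"))
  out <- lapply(pb, function(tt) data.frame(template = tt, weight = 1,
                                            stringsAsFactors = FALSE))
  # the preg templates are a small share of the pregnancy group so that about
  # 1% of female records carry the token overall
  out[["4"]]$weight[1:2] <- 0.2
  out
}

#' Default simulator schema
#'
#' A desk-scale visit schema: 5 age groups, 2 genders, 12 multi-valued
#' diagnosis codes, 2 hospitals (21 binary dimensions).
#'
#' @return a [RecordSchema-class].
#' @export
simSchema <- function() {
  buildSchema(c("age_group", "gender", "diagnosis", "hospital"),
              c(5L, 2L, 12L, 2L),
              multiValued = c(FALSE, FALSE, TRUE, FALSE),
              missingAllowed = c(FALSE, FALSE, TRUE, TRUE))
}

#' Configure the synthetic-corpus simulator
#'
#' The simulator emulates the structural features of an ED chief-complaint
#' feed that the downstream pipeline depends on: short template-driven
#' complaints keyed to the diagnosis, tokens that are absolutely exclusive
#' to one stratum of a demographic variable (a pregnancy token for
#' female-coded records), tokens whose selection odds are tilted in one
#' stratum (falls in the oldest age group), rare planted name tokens, and
#' low-frequency misspelling noise.
#'
#' Exclusivity rules zero the selection weight of every template containing
#' the token outside the allowed codes, so the exclusion holds with
#' probability 1. Association rules multiply the joint
#' (diagnosis, template) selection weight of templates containing the token
#' by the odds factor inside the stratum, so the planted complaint-level
#' odds ratio equals the configured factor in expectation.
#'
#' @param nPairs number of record-sentence pairs.
#' @param schema a [RecordSchema-class]; default [simSchema()].
#' @param phrasebook named list of template frames keyed by diagnosis code;
#'   default [defaultPhrasebook()].
#' @param exclusivityRules list of `list(token, variable, allowed)` rules.
#' @param associationRules list of `list(token, variable, code, odds)` rules.
#' @param nameTokens character vector of name tokens to plant.
#' @param nameCounts integer vector of target occurrence counts (parallel to
#'   `nameTokens`).
#' @param noiseRate per-token probability of character-swap corruption.
#' @param missingRates named numeric vector of per-variable missingness
#'   probabilities.
#' @param ageWeights,genderWeights sampling weights for the demographic
#'   variables.
#' @param secondaryDiagnosisRate probability that a record carries a second,
#'   random diagnosis code.
#' @param seed master seed.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(nPairs = 50000L,
                             schema = simSchema(),
                             phrasebook = defaultPhrasebook(),
                             exclusivityRules = list(
                               list(token = "preg", variable = "gender",
                                    allowed = 0L)),
                             associationRules = list(
                               list(token = "fall", variable = "age_group",
                                    code = 4L, odds = 8)),
                             nameTokens = c("smith", "johnson", "williams",
                               "brown", "jones", "garcia", "miller", "davis",
                               "rodriguez", "martinez", "hernandez", "lopez",
                               "gonzalez", "wilson", "anderson", "thomas",
                               "taylor", "moore", "jackson", "martin"),
                             nameCounts = round(seq(10, 30,
                               length.out = length(nameTokens))),
                             noiseRate = 0.005,
                             missingRates = c(diagnosis = 0.15,
                                              hospital = 0.02),
                             ageWeights = c(0.22, 0.22, 0.20, 0.18, 0.18),
                             genderWeights = c(0.5, 0.5),
                             secondaryDiagnosisRate = 0.2,
                             seed = 11L) {
  if (length(phrasebook) == 0L) stopf("phrasebook must be nonempty")
  for (d in names(phrasebook)) {
    tf <- phrasebook[[d]]
    if (any(tf$weight <= 0)) stopf("phrasebook weights must be positive")
    if (any(lengths(tokenizeText(tf$template)) > 18L))
      stopf("phrasebook template longer than 18 words (diagnosis %s)", d)
  }
  if (length(nameCounts) != length(nameTokens))
    stopf("nameTokens and nameCounts differ in length")
  if (noiseRate < 0 || noiseRate > 1) stopf("noiseRate must lie in [0, 1]")
  structure(list(nPairs = as.integer(nPairs), schema = schema,
                 phrasebook = phrasebook,
                 exclusivityRules = exclusivityRules,
                 associationRules = associationRules,
                 nameTokens = nameTokens,
                 nameCounts = as.integer(nameCounts),
                 noiseRate = noiseRate, missingRates = missingRates,
                 ageWeights = ageWeights, genderWeights = genderWeights,
                 secondaryDiagnosisRate = secondaryDiagnosisRate,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# flat (diagnosis, template) table with within-diagnosis-normalised joint
# weights; diagnosis marginal uniform over phrasebook entries
jointTemplateTable <- function(phrasebook) {
  dg <- rep(names(phrasebook), vapply(phrasebook, nrow, 1L))
  tpl <- unlist(lapply(phrasebook, function(x) x$template), use.names = FALSE)
  w <- unlist(lapply(phrasebook, function(x) x$weight / sum(x$weight)),
              use.names = FALSE) / length(phrasebook)
  data.frame(diagnosis = as.integer(dg), template = tpl, weight = w,
             stringsAsFactors = FALSE)
}

templateHasToken <- function(templates, token) {
  vapply(tokenizeText(templates), function(tt) token %in% tt, logical(1))
}

# swap two adjacent characters (deterministic position given RNG state)
corruptToken <- function(tok) {
  n <- nchar(tok)
  if (n < 2L) return(paste0(tok, tok))
  p <- sample.int(n - 1L, 1L)
  paste0(substr(tok, 1L, p - 1L), substr(tok, p + 1L, p + 1L),
         substr(tok, p, p), substr(tok, p + 2L, n))
}

#' Generate a synthetic record-sentence corpus with planted structure
#'
#' Samples discrete visit variables per record, then a
#' (diagnosis, template) pair from the phrasebook under the configured
#' exclusivity and association rules, applies misspelling noise, and plants
#' the name tokens. The returned `truth` is recounted from the emitted
#' corpus, so every planted quantity can be checked downstream.
#'
#' @param config a [simulationConfig()].
#' @return list with `records` (a record frame with a `complaint` column)
#'   and `truth` (planted-structure recounts: exclusivity contingency
#'   tables, realized association ratios, name counts, corrupted-token
#'   inventory).
#' @export
generatePairs <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  n <- config$nPairs
  schema <- config$schema
  nDiag <- schema@variables$cardinality[schema@variables$name == "diagnosis"]

  age <- sample.int(length(config$ageWeights), n, TRUE,
                    prob = config$ageWeights) - 1L
  gender <- sample.int(length(config$genderWeights), n, TRUE,
                       prob = config$genderWeights) - 1L
  nHosp <- schema@variables$cardinality[schema@variables$name == "hospital"]
  hospital <- sample.int(nHosp, n, TRUE) - 1L

  joint <- jointTemplateTable(config$phrasebook)
  # per-stratum weight vectors: strata defined by the variables the rules
  # reference (here gender x age); build a key per record
  ruleVars <- unique(c(
    vapply(config$exclusivityRules, `[[`, "", "variable"),
    vapply(config$associationRules, `[[`, "", "variable")))
  varValues <- list(age_group = age, gender = gender, hospital = hospital)
  strata <- if (length(ruleVars))
    do.call(interaction, c(unname(varValues[ruleVars]), drop = TRUE))
  else factor(rep(1L, n))

  templateIdx <- integer(n)
  for (lev in levels(strata)) {
    inStratum <- which(strata == lev)
    if (!length(inStratum)) next
    w <- joint$weight
    ex <- inStratum[1L]  # representative record of the stratum
    for (r in config$exclusivityRules) {
      if (!varValues[[r$variable]][ex] %in% r$allowed)
        w[templateHasToken(joint$template, r$token)] <- 0
    }
    for (r in config$associationRules) {
      if (varValues[[r$variable]][ex] == r$code)
        w[templateHasToken(joint$template, r$token)] <-
          w[templateHasToken(joint$template, r$token)] * r$odds
    }
    if (sum(w) <= 0)
      stopf("unsatisfiable rule set: no template available in stratum %s", lev)
    templateIdx[inStratum] <- sample.int(nrow(joint), length(inStratum),
                                         TRUE, prob = w)
  }
  diagnosis <- joint$diagnosis[templateIdx]
  complaint <- joint$template[templateIdx]

  # secondary diagnosis codes
  second <- stats::runif(n) < config$secondaryDiagnosisRate
  extra <- (diagnosis[second] +
            sample.int(nDiag - 1L, sum(second), TRUE)) %% nDiag
  diagStr <- as.character(diagnosis)
  diagStr[second] <- paste(diagnosis[second], extra, sep = ";")

  # missingness
  miss <- config$missingRates
  if (!is.na(miss["diagnosis"]) && miss["diagnosis"] > 0)
    diagStr[stats::runif(n) < miss["diagnosis"]] <- NA_character_
  hospital <- as.integer(hospital)
  if (!is.na(miss["hospital"]) && miss["hospital"] > 0)
    hospital[stats::runif(n) < miss["hospital"]] <- NA_integer_

  # misspelling noise
  corrupted <- character(0)
  if (config$noiseRate > 0) {
    toks <- tokenizeText(complaint)
    lens <- lengths(toks)
    flat <- unlist(toks, use.names = FALSE)
    hit <- which(stats::runif(length(flat)) < config$noiseRate)
    if (length(hit)) {
      flat[hit] <- vapply(flat[hit], corruptToken, "")
      corrupted <- unique(flat[hit])
      complaint <- vapply(split(flat, rep.int(seq_len(n), lens)),
                          paste, "", collapse = " ")
      complaint <- unname(complaint[order(as.integer(names(complaint)))])
    }
  }

  records <- data.frame(age_group = age, gender = gender,
                        diagnosis = diagStr, hospital = hospital,
                        complaint = complaint, stringsAsFactors = FALSE)
  records <- injectNames(records, config$nameTokens, config$nameCounts,
                         seed = deriveSeed(config$seed, "names"))

  truth <- recountTruth(records, config, corrupted)
  list(records = records, truth = truth)
}

#' Plant name tokens into complaints
#'
#' Each name is appended (as `"dr <name>"`, so all names share a cue
#' context) to its target number of randomly chosen complaints. Only
#' complaints short enough to stay within 18 words are eligible, and no
#' complaint receives two names, so target counts are met exactly.
#'
#' @param records a record frame with a `complaint` column.
#' @param nameTokens character vector of names.
#' @param nameCounts integer target occurrence counts.
#' @param seed RNG seed.
#' @return the record frame with modified complaints.
#' @export
injectNames <- function(records, nameTokens, nameCounts, seed = 1L) {
  if (length(nameTokens) == 0L) return(records)
  if (length(nameCounts) != length(nameTokens))
    stopf("nameTokens and nameCounts differ in length")
  nameCounts <- as.integer(nameCounts)
  if (any(nameCounts < 1L)) {
    warnf("name target count below 1; inserting once")
    nameCounts[nameCounts < 1L] <- 1L
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  lens <- lengths(tokenizeText(records$complaint))
  eligible <- which(lens <= 16L)
  need <- sum(nameCounts)
  if (need > length(eligible))
    stopf("corpus too small to plant %d name occurrences", need)
  slots <- sample(eligible, need)
  at <- split(slots, factor(rep.int(seq_along(nameTokens), nameCounts),
                            levels = seq_along(nameTokens)))
  for (k in seq_along(nameTokens)) {
    idx <- at[[k]]
    records$complaint[idx] <- paste(records$complaint[idx], "dr",
                                    nameTokens[k])
  }
  records
}

# recount every planted quantity from the emitted corpus
recountTruth <- function(records, config, corrupted) {
  toks <- tokenizeText(records$complaint)
  hasTok <- function(token) vapply(toks, function(tt) token %in% tt, logical(1))

  exclusivity <- do.call(rbind, lapply(config$exclusivityRules, function(r) {
    inAllowed <- records[[r$variable]] %in% r$allowed
    h <- hasTok(r$token)
    data.frame(token = r$token, variable = r$variable,
               allowed = paste(r$allowed, collapse = ";"),
               allowedWith = sum(h & inAllowed),
               allowedTotal = sum(inAllowed),
               disallowedWith = sum(h & !inAllowed),
               disallowedTotal = sum(!inAllowed),
               stringsAsFactors = FALSE)
  }))

  association <- do.call(rbind, lapply(config$associationRules, function(r) {
    exposed <- records[[r$variable]] == r$code
    h <- hasTok(r$token)
    tab <- contingencyTable(sum(h & exposed), sum(exposed),
                            sum(h & !exposed), sum(!exposed))
    rr <- ratios(tab)
    data.frame(token = r$token, variable = r$variable, code = r$code,
               configuredOdds = r$odds,
               exposedWith = tab$exposedWith, exposedTotal = tab$exposedTotal,
               unexposedWith = tab$unexposedWith,
               unexposedTotal = tab$unexposedTotal,
               riskRatio = rr$riskRatio, oddsRatio = rr$oddsRatio,
               stringsAsFactors = FALSE)
  }))

  nameCountsTok <- vapply(config$nameTokens, function(nm)
    sum(vapply(toks, function(tt) sum(tt == nm), 0L)), 0L)
  nameComplaints <- vapply(config$nameTokens, function(nm) sum(hasTok(nm)), 0L)
  names <- data.frame(name = config$nameTokens,
                      tokenCount = as.integer(nameCountsTok),
                      complaintCount = as.integer(nameComplaints),
                      stringsAsFactors = FALSE)
  anyName <- if (length(config$nameTokens))
    sum(vapply(toks, function(tt) any(tt %in% config$nameTokens), logical(1)))
  else 0L

  list(exclusivity = exclusivity, association = association,
       names = names, complaintsWithAnyName = as.integer(anyName),
       corruptedTokens = corrupted)
}
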