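# FACS (Facial Action Coding System) emotion rules and dataset statistics.
#
# Each emotion is defined by a conjunction of clauses; a clause is satisfied
# by any one of its action units (the "AU4 + (AU6/AU7)" notation: "+" joins
# clauses, "/" lists within-clause alternatives). Neutral is the absence of
# any action unit.

#' Action-unit vocabulary
#'
#' The closed set of FACS action units used by the emotion rules: brow
#' movements (AU1/2/4), lid and cheek action (AU5/6/7/43), nose and upper-lip
#' raising (AU9/10), mouth action (AU12/15/23/24/26/28) and head lowering
#' (AU54).
#'
#' @return Character vector of AU codes.
#' @export
au_vocabulary <- function() {
  c("AU1", "AU2", "AU4", "AU5", "AU6", "AU7", "AU9", "AU10", "AU12",
    "AU15", "AU23", "AU24", "AU26", "AU28", "AU43", "AU54")
}

#' Built-in FACS emotion rules
#'
#' Returns the rule set in decision-priority order (clinically most alarming
#' first, so a set satisfying several rules resolves to the most urgent
#' label): painful, strained, tired, surprised, angry, sad, happy, neutral.
#'
#' @param file optional JSON file of `{emotion: [[AU, ...], ...]}` overriding
#'   the built-in table; clause order in the file defines priority.
#' @return Named list; each element is a list of clauses (character vectors
#'   of alternative AUs). Neutral has zero clauses.
#' @export
facs_rules <- function(file = NULL) {
  if (!is.null(file)) {
    raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
    rules <- lapply(raw, function(cl) lapply(cl, function(x)
      as.character(unlist(x))))
    names(rules) <- names(raw)
  } else {
    rules <- list(
      painful   = list("AU4", c("AU6", "AU7"), c("AU9", "AU10"), "AU43"),
      strained  = list("AU4", "AU6", c("AU23", "AU24", "AU28")),
      tired     = list("AU43", "AU54"),
      surprised = list("AU1", "AU2", "AU5", "AU26"),
      angry     = list("AU4", "AU5", "AU7", "AU23"),
      sad       = list("AU1", "AU4", "AU15"),
      happy     = list("AU6", "AU12"),
      neutral   = list()
    )
  }
  bad <- setdiff(unlist(rules), au_vocabulary())
  if (length(bad))
    stop("rule table references unknown action units: ",
         paste(bad, collapse = ", "))
  rules
}

#' Map a set of action units to an emotion label
#'
#' Returns the highest-priority emotion whose every clause is satisfied by
#' the set. The empty set is neutral; a non-empty set matching no rule maps
#' to neutral with a warning (annotator AU sets are noisy).
#'
#' @param au_set character vector of AU codes (possibly empty).
#' @param rules rule table from [facs_rules()].
#' @return Emotion name (character scalar).
#' @examples
#' aus_to_emotion(c("AU6", "AU12"))   # "happy"
#' aus_to_emotion(character())        # "neutral"
#' @export
aus_to_emotion <- function(au_set, rules = facs_rules()) {
  au_set <- unique(as.character(au_set))
  unknown <- setdiff(au_set, au_vocabulary())
  if (length(unknown))
    stop("unknown action unit code: ", paste(unknown, collapse = ", "))
  if (length(au_set) == 0) return("neutral")
  for (emo in names(rules)) {
    clauses <- rules[[emo]]
    if (length(clauses) == 0) next   # neutral never matches a non-empty set
    ok <- all(vapply(clauses, function(cl) any(cl %in% au_set), logical(1)))
    if (ok) return(emo)
  }
  warning("AU set {", paste(au_set, collapse = ", "),
          "} matches no rule; labeling as neutral")
  "neutral"
}

#' Emotion vocabularies
#'
#' `private8` is the stroke-rehabilitation vocabulary (four basic emotions
#' assessing concentration plus four special emotions assessing training
#' intensity); `rafdb7` and `ferplus8` are the public-dataset vocabularies.
#'
#' @param name one of `"private8"`, `"rafdb7"`, `"ferplus8"`.
#' @return Character vector of class names; the integer index of a label is
#'   its position in this vector.
#' @export
emotion_vocabulary <- function(name = c("private8", "rafdb7", "ferplus8")) {
  name <- match.arg(name)
  switch(name,
    private8 = c("happy", "sad", "surprised", "angry", "neutral",
                 "painful", "strained", "tired"),
    rafdb7   = c("surprised", "fearful", "disgusted", "happy", "sad",
                 "angry", "neutral"),
    ferplus8 = c("surprised", "fearful", "disgusted", "happy", "sad",
                 "angry", "neutral", "contempt"))
}

#' Class counts, proportions and min/max imbalance ratio
#'
#' @param x manifest data frame (uses its `label` column) or a character
#'   vector of labels.
#' @param vocab class vocabulary; defaults to the sorted unique labels.
#' @return List with `counts` (named integer), `proportions` (summing to 1),
#'   `ratio` (smallest count / largest count, rounded to 4 decimals) and `n`.
#' @export
dataset_stats <- function(x, vocab = NULL) {
  labels <- if (is.data.frame(x)) x$label else as.character(x)
  if (length(labels) == 0) stop("empty manifest: no labels to summarize")
  if (is.null(vocab)) vocab <- sort(unique(labels))
  bad <- setdiff(labels, vocab)
  if (length(bad))
    stop("labels outside the vocabulary: ",
         paste(unique(bad), collapse = ", "))
  counts <- table(factor(labels, levels = vocab))
  counts <- stats::setNames(as.integer(counts), vocab)
  list(counts = counts,
       proportions = counts / sum(counts),
       ratio = round(min(counts) / max(counts), 4),
       n = sum(counts))
}
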