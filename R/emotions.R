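# Emotion vocabulary and the 7-way class regrouping.
#
# The label space has 18 emotion names: the 6 basic categories plus 12
# compound categories formed by a modifier (the first, weaker source) and a
# head (the second, dominant source), e.g. "sadly fearful" = sadness + fear.
# For recognition they are regrouped into 7 classes: Pos, Neg, Sur for the
# basic emotions and PS, NS, PN, NN for the compounds.

basic_emotion_names <- function() {
  c("happiness", "sadness", "fear", "anger", "disgust", "surprise")
}

compound_emotion_names <- function() {
  c("happily surprised", "happily disgusted",
    "sadly fearful", "sadly angry", "sadly surprised", "sadly disgusted",
    "fearfully angry", "fearfully surprised", "fearfully disgusted",
    "angrily surprised", "angrily disgusted", "disgustedly surprised")
}

#' The 18-emotion vocabulary
#'
#' @return Character vector of the 6 basic and 12 compound emotion names.
#' @export
emotion_names <- function() c(basic_emotion_names(), compound_emotion_names())

#' The 7 recognition classes
#'
#' @return Character vector `c("Pos","Neg","Sur","PS","NS","PN","NN")`.
#' @export
class_names <- function() c("Pos", "Neg", "Sur", "PS", "NS", "PN", "NN")

# modifier adverb -> basic emotion, for parsing compound names
.modifier_map <- c(
  happily = "happiness", sadly = "sadness", fearfully = "fear",
  angrily = "anger", disgustedly = "disgust"
)

# head adjective -> basic emotion
.head_map <- c(
  surprised = "surprise", disgusted = "disgust", fearful = "fear",
  angry = "anger"
)

.class_map <- local({
  m <- c(
    happiness = "Pos",
    sadness = "Neg", fear = "Neg", anger = "Neg", disgust = "Neg",
    surprise = "Sur",
    "happily surprised" = "PS",
    "happily disgusted" = "PN",
    "sadly surprised" = "NS", "fearfully surprised" = "NS",
    "angrily surprised" = "NS", "disgustedly surprised" = "NS",
    "sadly fearful" = "NN", "sadly angry" = "NN", "sadly disgusted" = "NN",
    "fearfully angry" = "NN", "fearfully disgusted" = "NN",
    "angrily disgusted" = "NN"
  )
  m
})

#' Map an emotion name to its recognition class
#'
#' Basic emotions map to `Pos` (happiness), `Neg` (sadness, fear, anger,
#' disgust) or `Sur` (surprise). Compounds map to `PS` (happily surprised),
#' `PN` (happily disgusted), `NS` (the four `* surprised` compounds other
#' than happily surprised) and `NN` (the remaining six negative-negative
#' compounds).
#'
#' @param emotion character vector of emotion names (see [emotion_names()]).
#' @return Character vector of class labels, same length as `emotion`.
#' @examples
#' class_of(c("disgust", "happily surprised", "sadly angry"))
#' @export
class_of <- function(emotion) {
  emotion <- tolower(as.character(emotion))
  bad <- setdiff(unique(emotion), names(.class_map))
  if (length(bad) > 0) {
    abort(paste0("unknown emotion name(s): ", paste(bad, collapse = ", ")))
  }
  unname(.class_map[emotion])
}

#' Split a compound emotion name into its two source emotions
#'
#' @param emotion a single compound emotion name, e.g. `"sadly fearful"`.
#' @return Named character vector `c(modifier = ..., head = ...)` of basic
#'   emotion names; the head is the dominant source.
#' @examples
#' compound_sources("sadly fearful")
#' @export
compound_sources <- function(emotion) {
  emotion <- tolower(emotion)
  if (!emotion %in% compound_emotion_names()) {
    abort(paste0("'", emotion, "' is not a compound emotion name"))
  }
  parts <- strsplit(emotion, " ", fixed = TRUE)[[1]]
  c(modifier = unname(.modifier_map[parts[1]]),
    head = unname(.head_map[parts[2]]))
}

is_basic_emotion <- function(emotion) tolower(emotion) %in% basic_emotion_names()
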