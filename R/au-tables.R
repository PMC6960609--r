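# FACS action-unit profiles of the 6 basic and 12 compound emotions.
#
# Two tables ship with the package as a CSV resource
# (extdata/au_tables.csv):
#   * "micro": the prototypical AUs observed in spontaneous basic
#     micro-expressions (6 emotions, no secondary AUs);
#   * "macro": the prototypical-plus-secondary AU profiles of all 18
#     emotions, where each secondary AU carries the proportion of people
#     observed to use it when expressing that emotion.

.au_cache <- new.env(parent = emptyenv())

load_au_csv <- function() {
  if (is.null(.au_cache$df)) {
    f <- system.file("extdata", "au_tables.csv", package = "cmer")
    .au_cache$df <- read.csv(f, stringsAsFactors = FALSE)
  }
  .au_cache$df
}

profile_from_rows <- function(rows, emotion) {
  proto <- sort(rows$au[rows$role == "prototypical"])
  sec_rows <- rows[rows$role == "secondary", , drop = FALSE]
  secondary <- setNames(sec_rows$proportion, sec_rows$au)
  structure(list(emotion = emotion, prototypical = as.integer(proto),
                 secondary = secondary),
            class = "emotion_au_profile")
}

#' @export
print.emotion_au_profile <- function(x, ...) {
  cat(sprintf("<AU profile> %s\n  prototypical: %s\n", x$emotion,
              paste(x$prototypical, collapse = ", ")))
  if (length(x$secondary) > 0) {
    cat("  secondary:   ",
        paste(sprintf("%s (%d%%)", names(x$secondary),
                      round(100 * x$secondary)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Action-unit tables
#'
#' `basic_au_table()` returns the prototypical AU sets of the 6 basic
#' micro-expressions (happiness 6+12; sadness 1+4+15; fear 1+4+20; anger
#' 4+7+43; disgust 4+7+9+25+26; surprise 1+2+5). `compound_au_table()`
#' returns all 18 profiles of the compound-emotion taxonomy, each with its
#' prototypical AUs and the secondary AUs annotated with usage proportions
#' in (0, 1].
#'
#' @return Named list of `emotion_au_profile` objects (fields `emotion`,
#'   `prototypical` integer vector, `secondary` named numeric vector of
#'   proportions).
#' @examples
#' basic_au_table()$surprise$prototypical   # 1 2 5
#' compound_au_table()$fear$secondary[["5"]] # 0.63
#' @export
basic_au_table <- function() {
  df <- load_au_csv()
  df <- df[df$table == "micro", , drop = FALSE]
  ems <- basic_emotion_names()
  setNames(lapply(ems, function(e)
    profile_from_rows(df[df$emotion == e, , drop = FALSE], e)), ems)
}

#' @rdname basic_au_table
#' @export
compound_au_table <- function() {
  df <- load_au_csv()
  df <- df[df$table == "macro", , drop = FALSE]
  ems <- emotion_names()
  setNames(lapply(ems, function(e)
    profile_from_rows(df[df$emotion == e, , drop = FALSE], e)), ems)
}

#' Per-database sample counts of the source micro-expression corpora
#'
#' Two small reference tables used for bookkeeping and consistency checks:
#' `compound_db_counts()` holds, for each of the 18 emotions, the number of
#' usable samples contributed by each of the four FACS-coded source
#' databases to the compound database; `basic_db_counts()` holds the
#' negative/positive/surprise sample counts of the five basic-expression
#' source databases.
#'
#' @return A tibble (see Details).
#' @export
compound_db_counts <- function() {
  f <- system.file("extdata", "compound_db_counts.csv", package = "cmer")
  as_tibble(read.csv(f, stringsAsFactors = FALSE))
}

#' @rdname compound_db_counts
#' @export
basic_db_counts <- function() {
  f <- system.file("extdata", "basic_db_counts.csv", package = "cmer")
  as_tibble(read.csv(f, stringsAsFactors = FALSE))
}

#' Aggregate per-database counts into the 7 recognition classes
#'
#' Sums the per-database counts of [compound_db_counts()] over databases and
#' emotions within each class, giving the total sample count of each of the
#' 7 classes in the compound database.
#'
#' @return Named integer vector over [class_names()].
#' @export
cmed_class_totals <- function() {
  df <- compound_db_counts()
  stopifnot(all(df$class == class_of(df$emotion)))
  per_emotion <- rowSums(df[, c("CASME1", "CASME2", "CASME_SQ2", "SAMM")])
  tot <- tapply(per_emotion, df$class, sum)
  setNames(as.integer(tot[class_names()]), class_names())
}

#' Pooled 3-class sample counts of the basic databases
#'
#' @return Named integer vector `c(Neg = ..., Pos = ..., Sur = ...)`:
#'   column sums of [basic_db_counts()] over the five source databases.
#' @export
basic_class_totals <- function() {
  df <- basic_db_counts()
  c(Neg = sum(df$negative), Pos = sum(df$positive), Sur = sum(df$surprise))
}
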