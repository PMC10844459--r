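# Number-word parsing and scoring for the counting tasks (forward 1-20,
# backward 50-30 by threes).

# English number lexicon: units, teens, tens. Covers 0-99, which spans both
# counting tasks with room for participant errors.
.numberWords <- local({
  units <- c(zero = 0, one = 1, two = 2, three = 3, four = 4, five = 5,
             six = 6, seven = 7, eight = 8, nine = 9)
  teens <- c(ten = 10, eleven = 11, twelve = 12, thirteen = 13, fourteen = 14,
             fifteen = 15, sixteen = 16, seventeen = 17, eighteen = 18,
             nineteen = 19)
  tens <- c(twenty = 20, thirty = 30, forty = 40, fifty = 50, sixty = 60,
            seventy = 70, eighty = 80, ninety = 90)
  c(units, teens, tens)
})
.tensWords <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy",
                "eighty", "ninety")
.unitWords <- c("one", "two", "three", "four", "five", "six", "seven",
                "eight", "nine")

#' Render an integer as English number words
#'
#' Inverse of the parser's lexicon for 0-99 (`47` becomes `"forty seven"`).
#' Used by the synthetic counting-transcript generator.
#'
#' @param n integer vector in 0-99.
#' @return character vector, one (possibly two-word) rendering per value.
#' @export
numberToWords <- function(n) {
  stopifnot(all(n >= 0 & n <= 99))
  vapply(as.integer(n), function(v) {
    lex <- .numberWords
    if (v <= 20 || v %% 10 == 0) return(names(lex)[match(v, lex)])
    tens <- (v %/% 10) * 10
    paste(names(lex)[match(tens, lex)], names(lex)[match(v %% 10, lex)])
  }, character(1))
}

#' Parse spoken numbers from a timed transcript
#'
#' Maps number words (including two-word compounds such as "forty seven" and
#' digit strings such as "47") to integers, preserving order and token time
#' spans; non-number words (leading chatter included) are dropped. A tens
#' word (twenty...ninety) immediately followed by a unit word joins into one
#' compound value spanning both tokens.
#'
#' @param transcript a [TimedTranscript-class].
#' @return list with `values` (integer vector) and `spans` (two-column
#'   matrix of start/end seconds, one row per value).
#' @examples
#' tr <- TimedTranscript(c("okay", "fifty", "forty", "seven"),
#'                       c(0, 1, 2, 2.5), c(0.5, 1.5, 2.4, 3))
#' parseNumbers(tr)$values  # 50 47
#' @export
parseNumbers <- function(transcript) {
  stopifnot(is(transcript, "TimedTranscript"))
  tok <- transcript@text
  start <- transcript@start
  end <- transcript@end
  values <- integer(0)
  spans <- matrix(numeric(0), ncol = 2)
  i <- 1L
  while (i <= length(tok)) {
    w <- tok[i]
    if (grepl("^[0-9]+$", w)) {                       # digit string
      values <- c(values, as.integer(w))
      spans <- rbind(spans, c(start[i], end[i]))
    } else if (w %in% names(.numberWords)) {
      v <- .numberWords[[w]]
      s <- start[i]; e <- end[i]
      if (w %in% .tensWords && i < length(tok) && tok[i + 1L] %in% .unitWords) {
        v <- v + .numberWords[[tok[i + 1L]]]
        e <- end[i + 1L]
        i <- i + 1L
      }
      values <- c(values, v)
      spans <- rbind(spans, c(s, e))
    }
    i <- i + 1L
  }
  if (!length(values)) stop("no number words found in transcript")
  colnames(spans) <- c("start", "end")
  list(values = values, spans = spans)
}

#' Score a counting sequence
#'
#' Scores each spoken value for the forward (1 to 20 by +1) or backward (50
#' to 30 by -3) task. Under the default chain rule — participants were
#' instructed to keep counting even after a mistake — the first value is
#' correct iff it equals the task start, and each later value is correct iff
#' it equals the previously *spoken* value plus the step, so a single slip
#' is penalized once rather than cascading. `rule = "canonical"` instead
#' compares position-wise against the ideal sequence.
#'
#' @param values integer vector of spoken values (from [parseNumbers()]).
#' @param task `"forward_1_20"` or `"backward_50_30_by3"`.
#' @param rule `"chain"` (default) or `"canonical"`.
#' @return list with `correct_counts`, `incorrect_counts`,
#'   `correct_counts_ratio`, and logical `is_correct` per value.
#' @examples
#' scoreCounting(c(50, 47, 45, 42), "backward_50_30_by3")  # 3 correct, 1 not
#' @export
scoreCounting <- function(values, task = c("forward_1_20", "backward_50_30_by3"),
                          rule = c("chain", "canonical")) {
  task <- match.arg(task)
  rule <- match.arg(rule)
  stopifnot(length(values) >= 1)
  startVal <- if (task == "forward_1_20") 1L else 50L
  step <- if (task == "forward_1_20") 1L else -3L
  n <- length(values)
  if (rule == "chain") {
    expected <- c(startVal, values[-n] + step)
  } else {
    expected <- startVal + step * (seq_len(n) - 1L)
  }
  ok <- values == expected
  list(correct_counts = sum(ok),
       incorrect_counts = sum(!ok),
       correct_counts_ratio = mean(ok),
       is_correct = ok)
}

#' Counting-task features
#'
#' Parses the numbers spoken in a counting transcript, scores them, and
#' computes the timing features over the number tokens only (leading chatter
#' and other non-number words never contribute). Articulatory rate uses
#' voiced time, as in the passage task; counts per second uses total signal
#' time.
#'
#' @param transcript a [TimedTranscript-class].
#' @param task task label, see [scoreCounting()].
#' @param minPause pause threshold (s) passed to [segmentFromTranscript()].
#' @param rule scoring rule, see [scoreCounting()].
#' @return named list: the counting scores, `counts_per_second`, and the
#'   timing features of [timingFeatures()].
#' @export
countingFeatures <- function(transcript, task = c("forward_1_20",
                                                  "backward_50_30_by3"),
                             minPause = 0.10, rule = c("chain", "canonical")) {
  task <- match.arg(task)
  rule <- match.arg(rule)
  parsed <- parseNumbers(transcript)
  score <- scoreCounting(parsed$values, task, rule)
  numTr <- new("TimedTranscript",
               text = as.character(parsed$values),
               start = parsed$spans[, 1], end = parsed$spans[, 2],
               sourceTag = transcript@sourceTag)
  seg <- segmentFromTranscript(numTr, minPause = minPause)
  timing <- timingFeatures(seg, wordCount = length(parsed$values))
  c(score[c("correct_counts", "incorrect_counts", "correct_counts_ratio")],
    list(counts_per_second =
           length(parsed$values) / timing$total_signal_time_s),
    timing)
}
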