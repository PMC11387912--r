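#' Score a usability/motivation questionnaire
#'
#' Implements the instruments' standard scoring rules:
#'
#' * **SUS** (System Usability Scale): 10 items on 1-5. Odd items score
#'   `score - 1`, even items `5 - score`; the sum is multiplied by 2.5,
#'   giving 0-100.
#' * **IMI** (Intrinsic Motivation Inventory): items on 1-7 grouped into
#'   named subscales (e.g. interest/enjoyment, effort, pressure,
#'   usefulness); each subscale scores as the mean of its items after
#'   reverse-coding (`8 - score`) the items named in `reverse_items`.
#' * **MARS** (Mobile Application Rating Scale): items on 1-5 grouped into
#'   subscales (engagement, functionality, aesthetics, ...); subscale
#'   means, reverse-coding (`6 - score`) via `reverse_items`.
#'
#' @param instrument `"SUS"`, `"IMI"` or `"MARS"`.
#' @param responses For SUS: a numeric vector of 10 item scores (item order
#'   1..10) or a data frame with columns `item`, `score`. For IMI/MARS: a
#'   data frame with columns `subscale`, `item`, `score`.
#' @param reverse_items Character/integer vector naming reverse-coded items
#'   (IMI/MARS only; the administered item variants decide the key).
#' @return SUS: a single number in \[0, 100\]. IMI/MARS: named numeric
#'   vector of subscale means.
#' @section Errors: `handrehab_incomplete_response` for missing items or
#'   out-of-range scores.
#' @export
#' @examples
#' score_questionnaire("SUS", c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1))  # 100
score_questionnaire <- function(instrument = c("SUS", "IMI", "MARS"),
                                responses, reverse_items = character(0)) {
  instrument <- match.arg(instrument)
  if (instrument == "SUS") {
    if (is.data.frame(responses)) {
      if (!all(c("item", "score") %in% names(responses)))
        hr_stop("SUS responses need columns item, score",
                "handrehab_incomplete_response")
      responses <- responses$score[order(responses$item)]
    }
    if (length(responses) != 10L || anyNA(responses))
      hr_stop("SUS requires complete scores for all 10 items",
              "handrehab_incomplete_response")
    if (any(responses < 1 | responses > 5))
      hr_stop("SUS item scores must lie on the 1-5 scale",
              "handrehab_incomplete_response")
    odd <- seq(1, 9, by = 2)
    even <- seq(2, 10, by = 2)
    return(2.5 * (sum(responses[odd] - 1) + sum(5 - responses[even])))
  }
  top <- if (instrument == "IMI") 7 else 5
  if (!is.data.frame(responses) ||
      !all(c("subscale", "item", "score") %in% names(responses)))
    hr_stop(sprintf("%s responses need columns subscale, item, score",
                    instrument), "handrehab_incomplete_response")
  if (anyNA(responses$score))
    hr_stop("missing item scores", "handrehab_incomplete_response")
  if (any(responses$score < 1 | responses$score > top))
    hr_stop(sprintf("%s item scores must lie on the 1-%d scale", instrument,
                    top), "handrehab_incomplete_response")
  sc <- responses$score
  rev <- responses$item %in% reverse_items
  sc[rev] <- (top + 1) - sc[rev]
  out <- tapply(sc, responses$subscale, mean)
  setNames(as.numeric(out), names(out))
}
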