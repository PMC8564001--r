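#' Counterbalancing design for the IMPL novel-verb trials
#'
#' Returns the 8-sequence x 2-trial counterbalancing scheme of the
#' intermodal preferential looking task: which novel verb (gorp/tam) and
#' agent (boy/girl) each trial uses, which of the four novel causal
#' actions (A-D) serves as target and distracter, the target side, the
#' side from which the agent approaches, and whether the target or the
#' distracter video is presented first. Across the 16 rows each action
#' occurs equally often (4 times) as target and as distracter, and the
#' target appears on the left in 8 rows.
#'
#' @return a data.frame with one row per (sequence, trial): columns
#'   `sequence_id`, `trial`, `verb`, `agent`, `target_action`,
#'   `distracter_action`, `target_side`, `approach_side`, `first_video`,
#'   and `item` (the unique trial-type index 1..16).
#' @examples
#' d <- impl_design()
#' subset(d, sequence_id == 1 & trial == 1)
#' table(d$target_action)
#' @export
impl_design <- function() {
  d <- data.frame(
    sequence_id = rep(1:8, each = 2),
    trial = rep(1:2, times = 8),
    verb = c("gorp", "tam", "gorp", "tam", "gorp", "tam", "gorp", "tam",
             "tam", "gorp", "tam", "gorp", "tam", "gorp", "tam", "gorp"),
    agent = c("boy", "girl", "boy", "girl", "girl", "boy", "girl", "boy",
              "girl", "boy", "girl", "boy", "boy", "girl", "boy", "girl"),
    target_action = c("D", "A", "C", "B", "B", "C", "A", "D",
                      "D", "A", "C", "B", "B", "C", "A", "D"),
    distracter_action = c("C", "B", "A", "D", "A", "D", "C", "B",
                          "B", "C", "D", "A", "D", "A", "B", "C"),
    target_side = c("right", "left", "left", "right", "right", "left",
                    "left", "right", "right", "left", "left", "right",
                    "right", "left", "left", "right"),
    approach_side = rep(c("left", "right"), each = 8),
    first_video = c("target", "distracter", "distracter", "target",
                    "distracter", "target", "target", "distracter",
                    "target", "distracter", "distracter", "target",
                    "distracter", "target", "target", "distracter"),
    stringsAsFactors = FALSE
  )
  d$item <- (d$sequence_id - 1L) * 2L + d$trial
  stopifnot(all(d$target_action != d$distracter_action))
  d
}
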