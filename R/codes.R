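#' Behavior codes tracked by the coding schema
#'
#' The schema distinguishes four ordered symbolic-play levels
#' (`SYMB1` single-object play, `SYMB2` single-object sequences,
#' `SYMB3` multi-object play, `SYMB4` multi-object sequences), two verbal
#' levels (`VERB1` babbling, `VERB2` single-word utterances) and two
#' count-valued social-bid channels (`SOC_INFANT` infant requests,
#' `SOC_MOTHER` maternal responses). Locomotor status is not a counted
#' behavior; see [locomotor_stages()].
#'
#' @return Character vector of the eight behavior codes, in schema order.
#' @seealso [locomotor_stages()], [anchor_wiring()]
#' @export
#' @examples
#' behavior_codes()
behavior_codes <- function() {
  c("SYMB1", "SYMB2", "SYMB3", "SYMB4",
    "VERB1", "VERB2", "SOC_INFANT", "SOC_MOTHER")
}

#' Locomotor stages recorded as session-level flags
#'
#' Locomotor status (pre-sitting, independent sitting, crawling, walking)
#' is marked at each visit as an attained/not-attained flag, monotone in
#' age once a stage is reached.
#'
#' @return Character vector of the four stages in developmental order.
#' @export
#' @examples
#' locomotor_stages()
locomotor_stages <- function() {
  c("PRE_SITTING", "SITTING", "CRAWLING", "WALKING")
}

#' Milestone anchor wiring for dips and event-aligned contrasts
#'
#' Each behavior whose frequency dips around a later milestone is paired
#' with that milestone (its "anchor"): single-object sequences (`SYMB2`)
#' with the onset of single-word utterances, multi-object play (`SYMB3`)
#' with the onset of multi-object sequences, and single-word utterances
#' plus both social-bid channels with the onset of walking.
#'
#' @return Named character vector: names are dipped behavior codes, values
#'   the anchor milestone (a behavior code or locomotor stage).
#' @export
#' @examples
#' anchor_wiring()
anchor_wiring <- function() {
  c(SYMB2 = "VERB2", SYMB3 = "SYMB4", VERB2 = "WALKING",
    SOC_INFANT = "WALKING", SOC_MOTHER = "WALKING")
}

# All milestone labels (behavior codes + locomotor stages)
all_milestones <- function() c(behavior_codes(), locomotor_stages())

is_stage <- function(x) x %in% locomotor_stages()
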