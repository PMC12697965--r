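#' Reward structure of the three-armed bandit
#'
#' The task is a three-armed bandit in which each option pays a unit reward
#' with a fixed hidden probability.  The canonical structure used throughout
#' the experiment assigns probabilities 0.25, 0.50 and 0.75 to options 0, 1
#' and 2.  Option ids are 0-based; the mapping to on-screen stimuli is
#' randomised in the real task and irrelevant to the computations, so it is
#' not modelled.
#'
#' @param probs Numeric vector of length 3 with per-option reward
#'   probabilities in `[0, 1]`.
#' @return An object of class `reward_structure`.
#' @examples
#' rs <- reward_structure()
#' best_option(rs)
#' @export
reward_structure <- function(probs = c(0.25, 0.50, 0.75)) {
  probs <- as.numeric(probs)
  if (length(probs) != 3L) {
    stop("a reward structure has exactly 3 options, got ", length(probs))
  }
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("reward probabilities must lie in [0, 1]")
  }
  structure(list(probs = probs), class = "reward_structure")
}

#' @rdname reward_structure
#' @param structure A `reward_structure`.
#' @return `best_option()`: the 0-based id of the option with the highest
#'   reward probability (ties broken by the lowest index).
#' @export
best_option <- function(structure) {
  which.max(structure$probs) - 1L
}

#' @export
print.reward_structure <- function(x, ...) {
  cat("<reward_structure> p(reward) =", paste(x$probs, collapse = "/"),
      " best option:", best_option(x), "\n")
  invisible(x)
}

check_option <- function(option) {
  if (!all(option %in% 0:2)) {
    bad <- option[!option %in% 0:2]
    stop("invalid option id: ", paste(unique(bad), collapse = ", "),
         " (options are 0, 1, 2)")
  }
  as.integer(option)
}

#' Draw a Bernoulli reward for an option
#'
#' @param option 0-based option id (may be a vector).
#' @param structure A [reward_structure()].
#' @return Integer 0/1 reward draw(s).
#' @export
sample_reward <- function(option, structure = reward_structure()) {
  option <- check_option(option)
  as.integer(stats::runif(length(option)) < structure$probs[option + 1L])
}

#' Proportion of correct choices
#'
#' The fraction of choices that picked the option with the highest reward
#' probability; chance level for three options is 1/3.
#'
#' @param choices Integer vector of 0-based option ids.
#' @param structure A [reward_structure()].
#' @return A fraction in `[0, 1]`.
#' @export
proportion_correct <- function(choices, structure = reward_structure()) {
  choices <- choices[!is.na(choices)]
  if (length(choices) == 0L) stop("empty choice sequence")
  choices <- check_option(choices)
  mean(choices == best_option(structure))
}

# Canonical column set of the tidy trial-level study table.  One CSV holds
# every phase; `phase` distinguishes them.  `participant_reward` carries the
# participant's own outcome in the practice individual-learning phase (the
# only phase where it is shown), `partner_side` records which side of the
# selection screen the observed partner later occupied.
study_columns <- c(
  "participant_id", "block_id", "phase", "trial_index", "partner_noise",
  "partner_side", "partner_choice", "partner_reward",
  "participant_choice", "participant_reward", "selected_partner"
)

study_phases <- c("practice_individual", "practice_observational",
                  "passive_1", "passive_2", "observational")

#' Validate a tidy study dataset
#'
#' Checks the trial-level table against the schema: known phases, option ids
#' in 0..2, binary rewards, passive-phase rows without participant choices,
#' and consistency between the selected partner and the observational-phase
#' partner condition.
#'
#' @param study A data frame in the study schema (see [read_study()]).
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_study <- function(study) {
  study <- tibble::as_tibble(study)
  missing <- setdiff(study_columns, names(study))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(study) == 0L) stop("no records")

  bad_row <- function(test, what) {
    idx <- which(test)
    if (length(idx) > 0L) {
      stop(sprintf("row %d: invalid value in column '%s'", idx[1L], what))
    }
  }
  bad_row(!study$phase %in% study_phases, "phase")
  bad_row(!is.na(study$partner_choice) & !study$partner_choice %in% 0:2,
          "partner_choice")
  bad_row(!is.na(study$participant_choice) &
            !study$participant_choice %in% 0:2, "participant_choice")
  bad_row(!is.na(study$partner_reward) & !study$partner_reward %in% 0:1,
          "partner_reward")
  bad_row(!is.na(study$participant_reward) &
            !study$participant_reward %in% 0:1, "participant_reward")
  bad_row(!is.na(study$partner_noise) &
            !study$partner_noise %in% c("high", "low"), "partner_noise")
  bad_row(!is.na(study$selected_partner) &
            !study$selected_partner %in% c("high", "low"), "selected_partner")
  passive <- study$phase %in% c("passive_1", "passive_2")
  bad_row(passive & !is.na(study$participant_choice), "participant_choice")

  obs <- study[study$phase == "observational", ]
  if (nrow(obs) > 0L) {
    mismatch <- !is.na(obs$selected_partner) & !is.na(obs$partner_noise) &
      obs$selected_partner != obs$partner_noise
    if (any(mismatch)) {
      stop("selected_partner disagrees with the observational-phase ",
           "partner condition for block ",
           obs$block_id[which(mismatch)[1L]])
    }
  }
  invisible(study)
}

#' Read and write tidy study datasets
#'
#' The whole experiment lives in one UTF-8 CSV with a header row: practice
#' phases, the two passive-observation sequences per block, and the
#' observational-learning trials, distinguished by the `phase` column.
#' `read_study()` validates on the way in; the pair is a round-trip
#' identity on valid datasets.
#'
#' @param path Path to a CSV file.
#' @return `read_study()`: a validated tibble in the study schema.
#' @export
read_study <- function(path) {
  study <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(phase = "character"))
  if (nrow(study) == 0L) stop("no records in ", path)
  for (col in c("partner_noise", "partner_side", "selected_partner")) {
    if (col %in% names(study)) study[[col]] <- as.character(study[[col]])
  }
  validate_study(study)
  tibble::as_tibble(study)[, study_columns]
}

#' @rdname read_study
#' @param study A study table in the schema.
#' @export
write_study <- function(study, path) {
  study <- validate_study(study)
  utils::write.csv(as.data.frame(study)[, study_columns], path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Block-level partner selections
#'
#' One row per participant and block with the partner conditions shown on
#' each side of the selection screen, the presentation order, and the
#' selection outcome.
#'
#' @param study A validated study table.
#' @return A tibble with columns `participant_id`, `block_id`,
#'   `left_noise`, `right_noise`, `left_first` (logical: was the left-hand
#'   partner observed in the first passive sequence), `selected_partner`,
#'   and `chose_left`.
#' @export
study_selections <- function(study) {
  passive <- study[study$phase %in% c("passive_1", "passive_2") &
                     study$trial_index == 0L, ]
  obs <- study[study$phase == "observational" & study$trial_index == 0L, ]
  sel <- merge(
    stats::aggregate(cbind(n = trial_index) ~ participant_id + block_id,
                     data = obs, FUN = length)[, c("participant_id", "block_id")],
    as.data.frame(obs[, c("participant_id", "block_id", "selected_partner")]),
    by = c("participant_id", "block_id")
  )
  pass <- as.data.frame(passive[, c("participant_id", "block_id", "phase",
                                    "partner_noise", "partner_side")])
  left <- pass[pass$partner_side == "left", ]
  right <- pass[pass$partner_side == "right", ]
  out <- merge(merge(
    stats::setNames(left[, c("participant_id", "block_id", "partner_noise",
                             "phase")],
                    c("participant_id", "block_id", "left_noise", "left_phase")),
    stats::setNames(right[, c("participant_id", "block_id", "partner_noise")],
                    c("participant_id", "block_id", "right_noise")),
    by = c("participant_id", "block_id")), sel,
    by = c("participant_id", "block_id"))
  out$left_first <- out$left_phase == "passive_1"
  out$chose_left <- out$selected_partner == out$left_noise
  out$left_phase <- NULL
  out <- out[order(out$participant_id, out$block_id), ]
  tibble::as_tibble(out)
}

#' Per-participant preference for the high-noise partner
#'
#' The proportion of blocks in which the participant selected the
#' high-noise partner; with four blocks this takes values in
#' \{0, 0.25, 0.5, 0.75, 1\}.
#'
#' @param study A validated study table.
#' @return A tibble with `participant_id` and `pref_high`.
#' @export
high_noise_preference <- function(study) {
  sel <- study_selections(study)
  agg <- stats::aggregate(list(pref_high = sel$selected_partner == "high"),
                          by = list(participant_id = sel$participant_id),
                          FUN = mean)
  tibble::as_tibble(agg)
}
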