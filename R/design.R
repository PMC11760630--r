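# Experiment-plan generation for the dual-stream auditory spatial n-back
# task: 2 SNR x 2 memory-load x 2 predictability conditions, each repeated
# twice (16 blocks), 120 target/distractor pairs per block at a 2-s
# onset-to-onset interval.

#' Split the numbers 1-8 into two disjoint groups of four
#'
#' One group serves as targets and the other as distractors in a block; the
#' roles swap between the two repeats of a condition.
#'
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return list with sorted integer vectors `group_a` and `group_b`.
#' @export
split_number_groups <- function(seed = NULL) {
  with_seed_maybe(seed, {
    a <- sort(sample(1:8, 4))
    list(group_a = a, group_b = setdiff(1:8, a))
  })
}

#' Generate a target stream with an exact n-back event rate
#'
#' Scoreable positions are those with at least `n` predecessors. Exactly
#' `round(nback_rate * (n_trials - n))` scoreable positions are n-back
#' matches (the item repeats the item `n` back); every other scoreable
#' position is guaranteed *not* to match at lag `n`. At the default block
#' length of 120 this yields 24 events, i.e. 20% of the presented numbers.
#'
#' @param numbers integer vector of 4 distinct item identities.
#' @param n n-back level (1 or 2).
#' @param n_trials number of trials in the block.
#' @param nback_rate fraction of scoreable positions that are matches.
#' @param seed optional integer seed.
#' @return tibble with columns `number` and `is_nback`.
#' @export
generate_target_sequence <- function(numbers, n, n_trials = 120,
                                     nback_rate = 0.2, seed = NULL) {
  stopifnot(length(numbers) == 4, !anyDuplicated(numbers), n %in% 1:2)
  scoreable <- n_trials - n
  if (scoreable < 0) stop("n_trials must be at least n")
  n_events <- round(nback_rate * scoreable)
  if (nback_rate < 0 || nback_rate > 1 || n_events > scoreable)
    stop("infeasible n-back rate: ", nback_rate)
  with_seed_maybe(seed, {
    flagged <- logical(n_trials)
    if (n_events > 0)
      flagged[sample(seq.int(n + 1L, n_trials), n_events)] <- TRUE
    seqn <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      if (i <= n) {
        seqn[i] <- sample(numbers, 1L)
      } else if (flagged[i]) {
        seqn[i] <- seqn[i - n]
      } else {
        seqn[i] <- sample(setdiff(numbers, seqn[i - n]), 1L)
      }
    }
    tibble::tibble(number = seqn, is_nback = flagged)
  })
}

#' Generate a predictable distractor stream
#'
#' The four-number `pattern` repeats cyclically over the block, so every
#' observed transition has probability 1.
#'
#' @param pattern ordered vector of 4 distinct numbers.
#' @param n_trials sequence length.
#' @return integer vector of length `n_trials`.
#' @export
generate_predictable_distractors <- function(pattern, n_trials) {
  if (length(pattern) != 4 || anyDuplicated(pattern))
    stop("pattern must contain 4 distinct numbers")
  pattern[((seq_len(n_trials) - 1L) %% 4L) + 1L]
}

#' Generate an unpredictable distractor stream
#'
#' Each item is drawn uniformly from the block's four distractor numbers
#' under the constraint that it differs from the previous and the
#' penultimate item. The second item therefore has three admissible
#' alternatives (probability 1/3 each) and every later item two
#' (probability 1/2 each).
#'
#' @param numbers integer vector of 4 distinct numbers.
#' @param n_trials sequence length.
#' @param seed optional integer seed.
#' @return integer vector of length `n_trials`.
#' @export
generate_unpredictable_distractors <- function(numbers, n_trials, seed = NULL) {
  stopifnot(length(numbers) == 4, !anyDuplicated(numbers))
  with_seed_maybe(seed, {
    seqn <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      excl <- seqn[seq.int(max(1L, i - 2L), max(1L, i - 1L))]
      admissible <- if (i == 1L) numbers else setdiff(numbers, excl)
      seqn[i] <- admissible[sample.int(length(admissible), 1L)]
    }
    seqn
  })
}

#' Empirical lag-1 transition frequencies of one or more sequences
#'
#' Validator for the designed transition-probability structure: frequencies
#' are conditional on the previous item and sum to 1 within each
#' conditioning context.
#'
#' @param sequences a single integer vector or a list of them.
#' @param min_position first position (>= 2) from which transitions are
#'   pooled; use 3 to restrict to positions where both constraint lags
#'   apply.
#' @return tibble with columns `from`, `to`, `n`, `freq`.
#' @export
empirical_transition_stats <- function(sequences, min_position = 2) {
  if (!is.list(sequences)) sequences <- list(sequences)
  stopifnot(min_position >= 2, all(lengths(sequences) >= min_position))
  pairs <- dplyr::bind_rows(lapply(sequences, function(s) {
    idx <- seq.int(min_position, length(s))
    tibble::tibble(from = s[idx - 1L], to = s[idx])
  }))
  out <- dplyr::count(pairs, .data$from, .data$to, name = "n")
  dplyr::mutate(dplyr::group_by(out, .data$from),
                freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Frequency with which a designated admissible alternative is chosen
#'
#' For unpredictable sequences, estimates the conditional probability that
#' the generator picks one specific admissible number: at positions >= 3
#' there are two admissible alternatives (expected frequency 0.5); at
#' position 2 there are three (expected frequency 1/3). The designated
#' alternative is the numerically smallest admissible one, a fixed choice
#' that makes the estimator well defined.
#'
#' @param sequences list of integer sequences over the same 4-number set.
#' @param numbers the 4-number alphabet of the sequences.
#' @param position `"late"` (positions 3..end, pooled) or `"second"`.
#' @return named list with `freq` (empirical frequency), `n_choices`
#'   (number of pooled decisions) and `expected` (design probability).
#' @export
admissible_choice_freq <- function(sequences, numbers,
                                   position = c("late", "second")) {
  position <- match.arg(position)
  if (!is.list(sequences)) sequences <- list(sequences)
  hits <- 0L
  total <- 0L
  for (s in sequences) {
    if (position == "second") {
      admissible <- setdiff(numbers, s[1])
      hits <- hits + as.integer(s[2] == min(admissible))
      total <- total + 1L
    } else {
      for (i in seq.int(3L, length(s))) {
        admissible <- setdiff(numbers, c(s[i - 1L], s[i - 2L]))
        hits <- hits + as.integer(s[i] == min(admissible))
        total <- total + 1L
      }
    }
  }
  list(freq = hits / total, n_choices = total,
       expected = if (position == "second") 1 / 3 else 0.5)
}

condition_grid <- function() {
  tidyr::expand_grid(
    snr_db = c(0, -10),
    memory_load = c(1L, 2L),
    predictability = c("predictable", "unpredictable")
  )
}

#' Build the full 16-block experiment plan
#'
#' Eight condition combinations (2 SNR x 2 memory load x 2 predictability),
#' each run twice with the target/distractor number-group roles and the
#' attended side swapped between repeats, in seeded random block order.
#' Every block holds `n_trials` simultaneous target/distractor pairs with a
#' 2-s onset-to-onset interval.
#'
#' @param seed integer master seed.
#' @param n_trials pairs per block (study value 120).
#' @param nback_rate fraction of scoreable target positions that are n-back
#'   events (study value 0.2).
#' @return object of class `experiment_plan`: list with `seed`, `groups`,
#'   `blocks` (one row per block) and `trials` (one row per pair).
#' @export
build_experiment <- function(seed, n_trials = 120, nback_rate = 0.2) {
  withr::with_seed(as.integer(seed), {
    groups <- split_number_groups()
    cells <- condition_grid()
    # repeat 1 uses group_a targets; repeat 2 swaps roles and side
    side1 <- sample(c("left", "right"), nrow(cells), replace = TRUE)
    blocks <- dplyr::bind_rows(
      dplyr::mutate(cells, repetition = 1L, attend_side = side1,
                    targets = list(groups$group_a),
                    distractors = list(groups$group_b)),
      dplyr::mutate(cells, repetition = 2L,
                    attend_side = ifelse(side1 == "left", "right", "left"),
                    targets = list(groups$group_b),
                    distractors = list(groups$group_a))
    )
    blocks <- blocks[sample.int(nrow(blocks)), ]
    blocks$block <- seq_len(nrow(blocks))
    blocks$distractor_pattern <- lapply(seq_len(nrow(blocks)), function(i) {
      if (blocks$predictability[i] == "predictable")
        sample(blocks$distractors[[i]]) else NULL
    })

    trials <- lapply(seq_len(nrow(blocks)), function(i) {
      b <- blocks[i, ]
      tgt <- generate_target_sequence(b$targets[[1]], b$memory_load,
                                      n_trials, nback_rate)
      dis <- if (b$predictability == "predictable") {
        generate_predictable_distractors(b$distractor_pattern[[1]], n_trials)
      } else {
        generate_unpredictable_distractors(b$distractors[[1]], n_trials)
      }
      tibble::tibble(
        block = b$block, trial = seq_len(n_trials),
        snr_db = b$snr_db, memory_load = b$memory_load,
        predictability = b$predictability, attend_side = b$attend_side,
        target = tgt$number, distractor = dis, is_nback = tgt$is_nback,
        onset_s = (seq_len(n_trials) - 1) * 2.0
      )
    })
    out <- list(
      seed = as.integer(seed), n_trials = n_trials, nback_rate = nback_rate,
      groups = groups,
      blocks = blocks[, c("block", "snr_db", "memory_load", "predictability",
                          "repetition", "attend_side", "targets",
                          "distractors", "distractor_pattern")],
      trials = dplyr::bind_rows(trials)
    )
    class(out) <- "experiment_plan"
    out
  })
}

#' Validate the invariants of an experiment plan
#'
#' Checks block/condition census, target-distractor disjointness, n-back
#' flags and sequence constraints; stops at the first violation.
#'
#' @param plan an `experiment_plan`.
#' @return invisibly `TRUE` if all invariants hold.
#' @export
validate_experiment_plan <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  b <- plan$blocks
  if (nrow(b) != 16) stop("expected 16 blocks")
  census <- dplyr::count(b, .data$snr_db, .data$memory_load,
                         .data$predictability)
  if (nrow(census) != 8 || any(census$n != 2))
    stop("each condition combination must occur exactly twice")
  if (sum(b$attend_side == "left") != 8)
    stop("attend-left must hold in exactly 8 blocks")
  for (i in seq_len(nrow(b))) {
    if (length(intersect(b$targets[[i]], b$distractors[[i]])) > 0)
      stop("target and distractor numbers overlap in block ", b$block[i])
    if (b$predictability[i] == "predictable" &&
        !setequal(b$distractor_pattern[[i]], b$distractors[[i]]))
      stop("distractor pattern is not a permutation of the distractor set")
  }
  tr <- plan$trials
  if (nrow(tr) != 16 * plan$n_trials) stop("wrong total trial-pair count")
  for (blk in split(tr, tr$block)) {
    n <- blk$memory_load[1]
    lagged <- c(rep(NA, n), head(blk$target, -n))
    scoreable <- blk$trial > n
    if (any(blk$is_nback[!scoreable]))
      stop("n-back flag on a non-scoreable trial")
    if (!all(blk$target[blk$is_nback] == lagged[blk$is_nback]))
      stop("flagged trial does not match at lag n")
    if (any(blk$target[scoreable & !blk$is_nback] ==
            lagged[scoreable & !blk$is_nback]))
      stop("unflagged lag-n match found")
    n_events <- round(plan$nback_rate * (plan$n_trials - n))
    if (sum(blk$is_nback) != n_events)
      stop("wrong n-back event count in block ", blk$block[1])
    d <- blk$distractor
    if (blk$predictability[1] == "unpredictable") {
      if (d[2] == d[1]) stop("second distractor repeats the first")
      i <- seq.int(3L, length(d))
      if (any(d[i] == d[i - 1L] | d[i] == d[i - 2L]))
        stop("unpredictable distractor repeats within lag 2")
    } else {
      if (any(d != rep_len(d[1:4], length(d))))
        stop("predictable distractors are not cyclic with period 4")
    }
  }
  invisible(TRUE)
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat("<experiment_plan> seed", x$seed, "-", nrow(x$blocks), "blocks x",
      x$n_trials, "pairs =", nrow(x$trials), "trial pairs\n")
  invisible(x)
}

#' Write an experiment plan to disk
#'
#' Serialises the design as JSON plus a TSV trial table.
#'
#' @param plan an `experiment_plan`.
#' @param dir output directory (created if needed).
#' @return invisibly the paths written.
#' @export
write_experiment_plan <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design_path <- file.path(dir, "design.json")
  trials_path <- file.path(dir, "trials.tsv")
  blocks <- plan$blocks
  blocks$targets <- vapply(blocks$targets, paste, "", collapse = ",")
  blocks$distractors <- vapply(blocks$distractors, paste, "", collapse = ",")
  blocks$distractor_pattern <- vapply(
    blocks$distractor_pattern,
    function(p) if (is.null(p)) "" else paste(p, collapse = ","), "")
  jsonlite::write_json(
    list(seed = plan$seed, n_trials = plan$n_trials,
         nback_rate = plan$nback_rate, groups = plan$groups, blocks = blocks),
    design_path, auto_unbox = TRUE, digits = NA)
  utils::write.table(plan$trials, trials_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(design_path, trials_path))
}
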