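## Block-design sequencing for the three experiment protocols, and
## BIDS-style events tables.

#' Randomise block order under the no-adjacent-repeat constraint
#'
#' Conditions are permuted independently within each epoch and the epochs
#' concatenated; a condition may never occupy two successive blocks, so
#' each epoch's permutation is redrawn until its first element differs
#' from the previous epoch's last (within an epoch a permutation has no
#' repeats by construction).
#'
#' @param conditions Character vector of condition labels.
#' @param epochs Number of epochs (each condition appears once per epoch).
#' @param seed Optional seed.
#' @return Character vector of length `length(conditions) * epochs`.
#' @export
randomize_block_order <- function(conditions, epochs = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conditions <- as.character(conditions)
  if (length(conditions) < 2 && epochs > 1)
    stop("adjacency constraint unsatisfiable with a single condition")
  out <- character(0)
  for (e in seq_len(epochs)) {
    repeat {
      perm <- sample(conditions)
      if (!length(out) || perm[1] != out[length(out)]) break
    }
    out <- c(out, perm)
  }
  out
}

#' Insert a one-back repetition into a block's image sequence
#'
#' One image is chosen uniformly and repeated twice in a row, giving the
#' target of the one-back repetition-detection task: a block of `n` unique
#' images becomes `n + 1` trials.
#'
#' @param images Character/integer vector of unique image identifiers.
#' @param seed Optional seed.
#' @return A list: `sequence` (length `length(images) + 1`) and
#'   `target_index` (position of the repeated presentation).
#' @export
insert_oneback <- function(images, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(images)
  if (n < 1) stop("empty block")
  if (anyDuplicated(images)) stop("images within a block must be unique")
  pick <- sample.int(n, 1)
  seq_out <- append(images, images[pick], after = pick)
  list(sequence = seq_out, target_index = pick + 1L)
}

#' Total duration and TR count of a run
#'
#' @param blocks Data frame with a `duration` column in seconds (one row
#'   per block, fixation included).
#' @param TR Repetition time in seconds.
#' @return A list with `seconds` and `TRs`. Errors if the duration is not
#'   an integer number of TRs.
#' @export
compute_run_timing <- function(blocks, TR = 2) {
  secs <- if (nrow(blocks)) sum(blocks$duration) else 0
  trs <- secs / TR
  if (abs(trs - round(trs)) > 1e-9)
    stop(sprintf("run length %.1f s is not a whole number of TRs (TR = %g s)",
                 secs, TR))
  list(seconds = secs, TRs = as.integer(round(trs)))
}

block_table <- function(labels, durations) {
  data.frame(onset = cumsum(c(0, utils::head(durations, -1))),
             duration = durations,
             trial_type = labels,
             stringsAsFactors = FALSE)
}

#' Wide-field retinotopy run
#'
#' 7 conditions (horizontal and vertical meridians plus five eccentricity
#' bands), 7 six-second blocks each, with seven 6-s fixation blocks
#' interleaved (one after every seven condition blocks) and 6-s fixation at
#' both ends: 348 s = 174 TRs at TR 2 s.
#'
#' @param seed Optional seed for the block order.
#' @param TR Repetition time (s).
#' @return A list of class `ff_run`: `blocks` (onset/duration/trial_type),
#'   `timing`, `protocol`, `conditions`.
#' @export
protocol_retinotopy <- function(seed = NULL, TR = 2) {
  conds <- c("horizontal", "vertical", paste0("ecc", 1:5))
  order <- randomize_block_order(conds, epochs = 7, seed = seed)
  labels <- c("fixation")
  for (e in seq_len(7)) {
    labels <- c(labels, order[(e - 1) * 7 + 1:7], "fixation")
  }
  labels <- c(labels, "fixation")   # lead-out, beyond the interleaved blocks
  blocks <- block_table(labels, rep(6, length(labels)))
  run <- structure(list(blocks = blocks,
                        timing = compute_run_timing(blocks, TR),
                        protocol = "retinotopy",
                        conditions = conds, TR = TR),
                   class = "ff_run")
  run
}

#' Full-field / postcard scene run
#'
#' 7 conditions x 3 epochs of 12-s blocks, each block followed by 6 s of
#' fixation, with 6-s lead-in and lead-out fixation: 390 s = 195 TRs. Each
#' block holds 6 trials (1.5 s stimulus + 0.5 s blank): 5 unique images of
#' the 15 per condition (split across the condition's three blocks) plus a
#' one-back repeat.
#'
#' @param seed Optional seed.
#' @param TR Repetition time (s).
#' @param images_per_condition Unique images available per condition.
#' @return A list of class `ff_run`, with `trials` (one row per stimulus
#'   presentation) alongside `blocks`.
#' @export
protocol_exp2 <- function(seed = NULL, TR = 2, images_per_condition = 15) {
  if (!is.null(seed)) set.seed(seed)
  conds <- c("fullfield_scene", "fullfield_scrambled", "postcard_scene",
             "postcard_scrambled", "face", "big_object", "small_object")
  epochs <- 3
  order <- randomize_block_order(conds, epochs = epochs)
  per_block <- images_per_condition / epochs
  assignment <- lapply(conds, function(cn) {
    ids <- sample(sprintf("%s_%02d", cn, seq_len(images_per_condition)))
    split(ids, rep(seq_len(epochs), each = per_block))
  })
  names(assignment) <- conds
  seen <- stats::setNames(rep(0L, length(conds)), conds)

  labels <- c("fixation")
  durs <- c(6)
  trials <- list()
  t0 <- 6
  for (b in seq_along(order)) {
    cn <- order[b]
    seen[cn] <- seen[cn] + 1L
    ob <- insert_oneback(assignment[[cn]][[seen[cn]]])
    n_tr <- length(ob$sequence)
    trials[[b]] <- data.frame(
      onset = t0 + (seq_len(n_tr) - 1) * 2.0,
      duration = 1.5,
      trial_type = cn,
      stim_file = ob$sequence,
      is_target = seq_len(n_tr) == ob$target_index,
      stringsAsFactors = FALSE)
    labels <- c(labels, cn, "fixation")
    durs <- c(durs, 12, 6)
    t0 <- t0 + 18
  }
  labels <- c(labels, "fixation"); durs <- c(durs, 6)   # lead-out
  blocks <- block_table(labels, durs)
  structure(list(blocks = blocks, trials = do.call(rbind, trials),
                 timing = compute_run_timing(blocks, TR),
                 protocol = "exp2", conditions = conds, TR = TR),
            class = "ff_run")
}

#' Content x scotoma run
#'
#' 20 conditions (4 content types x 5 scotoma levels) in 2 epochs; each
#' epoch holds one 8-s block per condition plus five 8-s rest blocks,
#' randomised with the no-adjacent-repeat constraint across the epoch
#' boundary, and 8-s fixation at both ends: 416 s = 208 TRs. Blocks hold 5
#' trials (1.1 s + 0.5 s): 4 unique images plus a one-back repeat; each
#' epoch splits a content type's 20 base images across its 5 scotoma
#' levels without reuse.
#'
#' @param seed Optional seed.
#' @param TR Repetition time (s).
#' @param scotoma_deg Scotoma levels (condition factor).
#' @return A list of class `ff_run` with `blocks` and `trials`.
#' @export
protocol_exp3 <- function(seed = NULL, TR = 2,
                          scotoma_deg = c(0, 29, 58, 88, 140)) {
  if (!is.null(seed)) set.seed(seed)
  contents <- c("scene", "scrambled", "face_array", "object_array")
  conds <- as.vector(outer(contents, scotoma_deg,
                           function(c, s) sprintf("%s_scot%03d", c, s)))
  n_scot <- length(scotoma_deg)
  epochs <- 2
  ord <- character(0)
  for (e in seq_len(epochs)) {
    repeat {
      perm <- sample(c(conds, rep("rest", 5)))
            boundary_ok <- !length(ord) ||
        !identical(ord[length(ord)], perm[1]) || perm[1] == "rest"
      adjacent_ok <- !any(perm[-1] == perm[-length(perm)] & perm[-1] != "rest")
      if (boundary_ok && adjacent_ok) break
    }
    ord <- c(ord, perm)
  }

  labels <- c("fixation", ord, "fixation")
  blocks <- block_table(labels, rep(8, length(labels)))

  trials <- list()
  for (e in seq_len(epochs)) {
    # split each content's 20 base images across the 5 scotoma levels
    assign_epoch <- list()
    for (cn in contents) {
      ids <- sample(20)
      for (k in seq_len(n_scot)) {
        cond <- sprintf("%s_scot%03d", cn, scotoma_deg[k])
        assign_epoch[[cond]] <- sprintf("%s_base%02d_scot%03d.png", cn,
                                        ids[(k - 1) * 4 + 1:4],
                                        scotoma_deg[k])
      }
    }
    epoch_rows <- which(blocks$trial_type != "fixation" &
                          blocks$trial_type != "rest")
    epoch_rows <- epoch_rows[((e - 1) * 20 + 1):(e * 20)]
    for (b in epoch_rows) {
      cn <- blocks$trial_type[b]
      ob <- insert_oneback(assign_epoch[[cn]])
      n_tr <- length(ob$sequence)
      trials[[length(trials) + 1]] <- data.frame(
        onset = blocks$onset[b] + (seq_len(n_tr) - 1) * 1.6,
        duration = 1.1,
        trial_type = cn,
        stim_file = ob$sequence,
        is_target = seq_len(n_tr) == ob$target_index,
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, trials)
  trials <- trials[order(trials$onset), ]
  structure(list(blocks = blocks, trials = trials,
                 timing = compute_run_timing(blocks, TR),
                 protocol = "exp3", conditions = conds, TR = TR),
            class = "ff_run")
}

#' @export
print.ff_run <- function(x, ...) {
  cat(sprintf("%s run: %d blocks, %.0f s (%d TRs at TR %g s)\n",
              x$protocol, nrow(x$blocks), x$timing$seconds, x$timing$TRs,
              x$TR))
  invisible(x)
}

#' Write a run's events to a BIDS-style events.tsv
#'
#' One row per block (or per trial when the run has a trial table), with
#' columns `onset`, `duration`, `trial_type` and, for trials, `stim_file`
#' and `is_target`. Onsets must be sorted and non-overlapping.
#'
#' @param run An `ff_run` object (or a data frame of events).
#' @param path Output file path.
#' @param what `"blocks"` or `"trials"`.
#' @return The path, invisibly.
#' @export
write_events <- function(run, path, what = c("blocks", "trials")) {
  what <- match.arg(what)
  ev <- if (is.data.frame(run)) run else run[[what]]
  if (is.null(ev)) stop("run has no ", what, " table")
  if (is.unsorted(ev$onset)) stop("onsets must be sorted")
  if (any(diff(ev$onset) < utils::head(ev$duration, -1) - 1e-9))
    stop("overlapping events")
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
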