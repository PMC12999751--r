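# Tautomer-group-aware train/validation/test splitting.
#
# The unit of assignment is the tautomer group (a parent compound plus all of
# its enumerated spellings), so no molecule of a compound can appear in more
# than one partition of any repeat: the leakage guard at the heart of honest
# augmented-dataset evaluation.

# Largest-remainder allocation of n items to the target fractions; keeps every
# realized partition within one group of its target.
allocate_sizes <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    order_rem <- order(raw - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(left)]] <- sizes[order_rem[seq_len(left)]] + 1L
  }
  as.integer(sizes)
}

#' Group-aware repeated train/validation/test splits
#'
#' Draws \code{nRepeats} independent random assignments of tautomer groups to
#' the train, validation and test partitions by shuffled-group allocation with
#' largest-remainder rounding (realized partition sizes stay within one group
#' of the target fractions). Optionally stratifies by the group label when
#' both classes are large enough. Deterministic under \code{seed}.
#'
#' @param groups what to split: a character vector of group ids, a list of
#'   \linkS4class{TautomerGroup}s, or a \linkS4class{GraphDataset}.
#' @param fractions numeric length 3 (train, validation, test), positive,
#'   summing to 1. Default 0.8/0.1/0.1.
#' @param nRepeats number of independent random splits (default 5).
#' @param seed integer seed.
#' @param stratified stratify the allocation by group label (requires labels;
#'   off by default).
#' @return a \linkS4class{SplitPlan}.
#' @examples
#' plan <- makeGroupSplits(sprintf("g%02d", 1:10), nRepeats = 2, seed = 1)
#' table(assignments(plan, 1))
#' @export
makeGroupSplits <- function(groups, fractions = c(0.8, 0.1, 0.1),
                            nRepeats = 5L, seed = 1L, stratified = FALSE) {
  if (is(groups, "GraphDataset")) {
    ids <- unique(groups@groupIds)
    glabels <- groups@labels[match(ids, groups@groupIds)]
  } else if (is.list(groups) && all(vapply(groups, is, logical(1), "TautomerGroup"))) {
    ids <- vapply(groups, parentId, character(1))
    glabels <- vapply(groups, function(g) g@label, integer(1))
  } else {
    ids <- as.character(groups)
    glabels <- rep(NA_integer_, length(ids))
  }
  if (anyDuplicated(ids)) stop("group ids must be unique")
  n <- length(ids)
  if (n < 3) stop("need at least 3 groups (one per partition)")
  if (length(fractions) != 3 || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 positive numbers summing to 1")
  }
  if (stratified && any(is.na(glabels))) {
    stop("stratified splitting requires group labels")
  }

  parts <- c("train", "validation", "test")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  assign_once <- function(ids_sub) {
    sizes <- allocate_sizes(length(ids_sub), fractions)
    shuffled <- sample(ids_sub)
    stats::setNames(rep(parts, times = sizes), shuffled)
  }
  assignments <- lapply(seq_len(nRepeats), function(r) {
    if (stratified) {
      a <- unlist(lapply(split(ids, glabels), assign_once))
      names(a) <- sub("^[01]\\.", "", names(a))
      a[ids]
    } else {
      a <- assign_once(ids)
      a[ids]
    }
  })
  new("SplitPlan", fractions = stats::setNames(fractions, parts),
      nRepeats = as.integer(nRepeats), seed = as.integer(seed),
      assignments = assignments)
}

#' Serialize a split plan to JSON
#'
#' Writes the repeat-by-group partition map (repeat -> group id -> partition)
#' so splits can be shared across training runs and audited for leakage.
#'
#' @param plan a \linkS4class{SplitPlan}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSplitPlan <- function(plan, path) {
  stopifnot(is(plan, "SplitPlan"))
  obj <- list(
    fractions = as.list(plan@fractions),
    n_repeats = plan@nRepeats,
    seed = plan@seed,
    assignments = lapply(plan@assignments, as.list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
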