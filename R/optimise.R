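#' Optimiser configuration
#'
#' @param starting_anchors participant indices seeding the greedy searches
#'   (default: the first two participants).
#' @param max_subset_size largest training subset per side (`Inf` = grow
#'   until no strict improvement).
#' @return list of class `dd_optcfg`.
#' @export
optimiser_config <- function(starting_anchors = c(1L, 2L),
                             max_subset_size = Inf) {
  stop_if_not(!anyDuplicated(starting_anchors) && all(starting_anchors >= 1),
              "anchors must be distinct positive indices")
  stop_if_not(max_subset_size >= 2, "max_subset_size must be >= 2")
  structure(list(starting_anchors = as.integer(starting_anchors),
                 max_subset_size = max_subset_size),
            class = "dd_optcfg")
}

#' Error rate of a candidate training split
#'
#' Fits PCA (half the non-trivial scores retained) and the two-axis LDA on
#' the concatenated training columns, then classifies *all* participants of
#' both conditions with the centroid distance-ratio rule.  The returned
#' error is the percentage misclassified over the full cohort — training
#' samples included, which is the validation convention the optimiser is
#' defined against.
#'
#' @param train_A,train_B column indices of the training participants.
#' @param all_A,all_B full condition feature matrices
#'   (features x participants).
#' @return percentage error over all samples, with attribute `report`.
#' @export
evaluate_training <- function(train_A, train_B, all_A, all_B) {
  stop_if_not(length(train_A) >= 2 && length(train_B) >= 2,
              "each training side needs >= 2 participants for LDA")
  Xtr <- t(cbind(all_A[, train_A, drop = FALSE], all_B[, train_B, drop = FALSE]))
  lab_tr <- rep(c("A", "B"), c(length(train_A), length(train_B)))
  pca <- fit_pca(Xtr)
  n_avail <- ncol(pca$loadings)
  pca$n_keep <- min(max(2L, pca$n_keep), n_avail)
  pad <- function(S) if (ncol(S) < 2) cbind(S, 0) else S  # rank-1 training data
  lda <- fit_lda(pad(predict(pca, Xtr)), lab_tr)
  Xall <- t(cbind(all_A, all_B))
  truth <- rep(c("A", "B"), c(ncol(all_A), ncol(all_B)))
  rep <- classify(lda, pad(predict(pca, Xall)), truth)
  structure(rep$error_rate, report = rep)
}

## Ordering of candidate solutions: lower error, then smaller subset, then
## lexicographically smallest index set.  Returns TRUE if (e1, s1) is
## strictly better than (e2, s2).
better_subset <- function(e1, s1, e2, s2) {
  if (is.null(e2)) return(TRUE)
  if (e1 != e2) return(e1 < e2)
  if (length(s1) != length(s2)) return(length(s1) < length(s2))
  d <- which(s1 != s2)
  length(d) > 0 && s1[d[1]] < s2[d[1]]
}

## One-sided greedy search.  `side` is "A" or "B": subsets of that side are
## grown while the other side's training set stays fixed.
greedy_side <- function(all_A, all_B, side, fixed_other, cfg) {
  n <- if (side == "A") ncol(all_A) else ncol(all_B)
  stop_if_not(n >= 3, "cohort must have >= 3 participants per condition")
  anchors <- cfg$starting_anchors
  stop_if_not(all(anchors <= n), "anchors outside the cohort")

  n_evals <- 0L
  trace <- list()
  eval_subset <- function(subset) {
    n_evals <<- n_evals + 1L
    if (side == "A") {
      as.numeric(evaluate_training(subset, fixed_other, all_A, all_B))
    } else {
      as.numeric(evaluate_training(fixed_other, subset, all_A, all_B))
    }
  }
  log_step <- function(anchor, step, subset, error, accepted) {
    trace[[length(trace) + 1L]] <<- data.frame(
      anchor = anchor, step = step,
      subset = paste(subset, collapse = "+"),
      size = length(subset), error = error, accepted = accepted)
  }

  best_sub <- NULL
  best_err <- NULL
  for (a in anchors) {
    ## seed: best pair {a, i} over all i != a
    cand <- setdiff(seq_len(n), a)
    pair_err <- vapply(cand, function(i) eval_subset(sort(c(a, i))), numeric(1))
    j <- cand[which.min(pair_err)]
    cur <- sort(c(a, j))
    cur_err <- min(pair_err)
    log_step(a, 0L, cur, cur_err, TRUE)

    ## grow: add the single participant that lowers the error most,
    ## while the improvement is strict
    step <- 0L
    repeat {
      if (length(cur) >= min(n, cfg$max_subset_size)) break
      rest <- setdiff(seq_len(n), cur)
      if (length(rest) == 0) break
      add_err <- vapply(rest, function(i) eval_subset(sort(c(cur, i))), numeric(1))
      i_best <- rest[which.min(add_err)]
      step <- step + 1L
      if (min(add_err) < cur_err) {
        cur <- sort(c(cur, i_best))
        cur_err <- min(add_err)
        log_step(a, step, cur, cur_err, TRUE)
      } else {
        log_step(a, step, sort(c(cur, i_best)), min(add_err), FALSE)
        break
      }
    }
    if (better_subset(cur_err, cur, best_err, best_sub)) {
      best_sub <- cur
      best_err <- cur_err
    }
  }

  ## the train-on-everything incumbent competes with the greedy result
  full <- seq_len(n)
  full_err <- eval_subset(full)
  log_step(NA_integer_, NA_integer_, full, full_err, FALSE)
  if (better_subset(full_err, full, best_err, best_sub)) {
    best_sub <- full
    best_err <- full_err
  }

  list(subset = best_sub, error = best_err,
       trace = do.call(rbind, trace), n_evals = n_evals)
}

#' Greedy search for the ideal training participants of condition A
#'
#' Two anchored greedy runs (anchors: the first and second participant by
#' default): each starts from the best pair containing its anchor, with the
#' full condition-B cohort as the B-side training set, then repeatedly adds
#' the single participant whose inclusion lowers the all-sample
#' distance-ratio error the most, stopping when no addition strictly
#' improves (or `max_subset_size` is reached).  The best result over both
#' anchors — competing against the train-on-all incumbent — is returned;
#' ties break to the smaller, then lexicographically smallest subset.
#'
#' @param all_A,all_B condition feature matrices (features x participants).
#' @param cfg an [optimiser_config()].
#' @return list: `subset` (A-side training indices), `error` (%), `trace`
#'   (per-evaluation record) and `n_evals`.
#' @export
greedy_stage_A <- function(all_A, all_B, cfg = optimiser_config()) {
  greedy_side(all_A, all_B, "A", fixed_other = seq_len(ncol(all_B)), cfg = cfg)
}

#' Greedy search for the ideal training participants of condition B
#'
#' Identical procedure to [greedy_stage_A()], run on the B side with the
#' A-side training set fixed to the stage-A result.  Because the full-B
#' incumbent (i.e. the stage-A configuration) competes with the greedy
#' subsets, stage B can only keep or improve the stage-A error.
#'
#' @param all_A,all_B condition feature matrices.
#' @param best_A A-side training indices from stage A.
#' @param cfg an [optimiser_config()].
#' @return as [greedy_stage_A()], for the B side.
#' @export
greedy_stage_B <- function(all_A, all_B, best_A, cfg = optimiser_config()) {
  stop_if_not(length(best_A) >= 2, "best_A must hold >= 2 participants")
  greedy_side(all_A, all_B, "B", fixed_other = best_A, cfg = cfg)
}

#' Two-stage training-subset optimisation
#'
#' Stage A selects the training participants of the first condition with
#' the full second-condition cohort fixed; stage B re-runs the same search
#' on the second condition with the stage-A choice fixed.  The pair of
#' subsets defines the optimised training split; its all-sample error is
#' the optimised discrimination error.  The whole search costs O(n^2)
#' evaluations per anchor instead of the combinatorial `choose(n, k)` of an
#' exhaustive scan.
#'
#' @param all_A,all_B condition feature matrices (features x participants).
#' @param cfg an [optimiser_config()].
#' @return list of class `dd_opt`: `subset_A`, `subset_B`, `error` (%),
#'   `stage_A`, `stage_B` (the per-stage results), `n_evals`, `report`
#'   (the final [classify()] report).
#' @export
optimise_training <- function(all_A, all_B, cfg = optimiser_config()) {
  sA <- greedy_stage_A(all_A, all_B, cfg)
  sB <- greedy_stage_B(all_A, all_B, sA$subset, cfg)
  final <- evaluate_training(sA$subset, sB$subset, all_A, all_B)
  structure(list(subset_A = sA$subset, subset_B = sB$subset,
                 error = as.numeric(final),
                 stage_A = sA, stage_B = sB,
                 n_evals = sA$n_evals + sB$n_evals + 1L,
                 report = attr(final, "report")),
            class = "dd_opt")
}

#' Number of k-subsets of an n-cohort
#'
#' The size of the search space an exhaustive training-subset scan would
#' face per condition (e.g. `choose(30, 20)` = 30,045,015).
#'
#' @param n cohort size.
#' @param k training subset size.
#' @return `choose(n, k)`.
#' @export
search_space_size <- function(n, k) choose(n, k)

#' Exhaustive training-subset search (test oracle)
#'
#' Evaluates every pair of k-subsets (A-side x B-side) and returns the
#' global optimum under the same (error, size, lexicographic) ordering as
#' the greedy search.  Guarded by a budget: if `choose(n, k)` on either
#' side exceeds it, the search is rejected with a condition of class
#' `dd_budget_error` carrying the offending count — exhaustive enumeration
#' is only ever feasible as an oracle on tiny cohorts.
#'
#' @param all_A,all_B condition feature matrices.
#' @param k_A,k_B subset sizes per side.
#' @param budget largest admissible `choose(n, k)` per side.
#' @return list: `subset_A`, `subset_B`, `error`, `n_evaluated`.
#' @export
exhaustive_oracle <- function(all_A, all_B, k_A, k_B = k_A, budget = 1e5) {
  for (side in list(c(ncol(all_A), k_A), c(ncol(all_B), k_B))) {
    cnt <- search_space_size(side[1], side[2])
    if (cnt > budget) {
      cond <- structure(
        class = c("dd_budget_error", "error", "condition"),
        list(message = sprintf(
               "search space choose(%d, %d) = %s exceeds the budget of %s",
               side[1], side[2], format(cnt, scientific = FALSE, big.mark = ","),
               format(budget, scientific = FALSE)),
             call = sys.call(-1), count = cnt))
      stop(cond)
    }
  }
  subs_A <- utils::combn(ncol(all_A), k_A, simplify = FALSE)
  subs_B <- utils::combn(ncol(all_B), k_B, simplify = FALSE)
  best <- NULL
  n_eval <- 0L
  for (sa in subs_A) {
    for (sb in subs_B) {
      e <- as.numeric(evaluate_training(sa, sb, all_A, all_B))
      n_eval <- n_eval + 1L
      key <- c(sa, sb)
      if (is.null(best) || better_subset(e, key, best$error, c(best$subset_A, best$subset_B))) {
        best <- list(subset_A = sa, subset_B = sb, error = e)
      }
    }
  }
  c(best, list(n_evaluated = n_eval))
}

#' Exhaustive search over all subset sizes (test oracle)
#'
#' Runs [exhaustive_oracle()] for every admissible pair of subset sizes
#' (>= 2 per side) and returns the global optimum — the reference the
#' greedy two-stage search is compared against on tiny cohorts.
#'
#' @inheritParams exhaustive_oracle
#' @return as [exhaustive_oracle()].
#' @export
exhaustive_best_over_sizes <- function(all_A, all_B, budget = 1e5) {
  best <- NULL
  n_eval <- 0L
  for (kA in 2:ncol(all_A)) {
    for (kB in 2:ncol(all_B)) {
      r <- exhaustive_oracle(all_A, all_B, kA, kB, budget = budget)
      n_eval <- n_eval + r$n_evaluated
      if (is.null(best) || better_subset(r$error, c(r$subset_A, r$subset_B),
                                         best$error, c(best$subset_A, best$subset_B))) {
        best <- r[c("subset_A", "subset_B", "error")]
      }
    }
  }
  c(best, list(n_evaluated = n_eval))
}
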