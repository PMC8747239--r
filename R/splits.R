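# Train/test division schemes with k-fold cross-validation. Units are gait
# cycles for the within-one-subject and intra-subject schemes and whole
# subjects for the inter-subject scheme.

#' Build a cross-validation split plan
#'
#' Three schemes:
#' \describe{
#'   \item{within_one_subject}{each subject's cycles are partitioned into k
#'     folds (about 80/20 train/test per fold at k = 5); one plan per
#'     subject.}
#'   \item{intra_subject}{all cycles pooled over subjects are shuffled with
#'     the split seed and partitioned into k folds.}
#'   \item{inter_subject}{subjects are shuffled and partitioned into k
#'     disjoint groups (30 subjects at k = 5 gives 6 test subjects per
#'     fold); test subjects are never seen in training.}
#' }
#' Fold construction is deterministic given the seed, which is independent
#' of the model seed.
#'
#' @param cycles List of `gait_cycle` objects (the whole cohort).
#' @param scheme One of `"within_one_subject"`, `"intra_subject"`,
#'   `"inter_subject"`.
#' @param k Number of folds (default 5).
#' @param seed Split seed.
#' @return A `split_plan`: for intra/inter, list of k folds each with
#'   `train` and `test` integer indices into `cycles`; for
#'   within_one_subject, a named list of per-subject plans of the same
#'   shape. Attributes record scheme, k and seed.
#' @export
make_splits <- function(cycles, scheme = c("within_one_subject",
                                           "intra_subject",
                                           "inter_subject"),
                        k = 5, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(length(cycles) >= 1, k >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  subj <- vapply(cycles, function(cy) cy$subject_id, integer(1))

  part <- function(ids, k) {
    # shuffle then deal into k nearly equal folds
    ids <- sample(ids)
    unname(split(ids, cut(seq_along(ids), k, labels = FALSE)))
  }

  plan <- switch(scheme,
    within_one_subject = {
      per_subject <- lapply(unique(subj), function(s) {
        idx <- which(subj == s)
        if (length(idx) < k) {
          stop(sprintf(
            "subject %d has %d cycles, fewer than k = %d folds",
            s, length(idx), k))
        }
        folds <- part(idx, k)
        lapply(folds, function(te) list(train = sort(setdiff(idx, te)),
                                        test = sort(te)))
      })
      names(per_subject) <- as.character(unique(subj))
      per_subject
    },
    intra_subject = {
      folds <- part(seq_along(cycles), k)
      lapply(folds, function(te) {
        list(train = sort(setdiff(seq_along(cycles), te)),
             test = sort(te))
      })
    },
    inter_subject = {
      subjects <- unique(subj)
      if (length(subjects) < k) {
        stop(sprintf("inter_subject needs at least k = %d subjects", k))
      }
      if (length(subjects) %% k != 0) {
        stop(sprintf(
          "inter_subject needs the %d subjects divisible into %d equal groups",
          length(subjects), k))
      }
      groups <- part(subjects, k)
      lapply(groups, function(te_subj) {
        list(train = which(!(subj %in% te_subj)),
             test = which(subj %in% te_subj))
      })
    })
  structure(plan, scheme = scheme, k = k, seed = seed,
            class = "split_plan")
}
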