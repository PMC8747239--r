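# Filter feature selection: absolute Pearson correlation of each IMU
# channel with each joint's angle, normalised per joint by the maximum, and
# a relative-importance threshold with a cross-joint union.

#' Channel importance for one joint
#'
#' Pools all (feature, label) sample pairs over the training cycles and
#' scores each of the nine IMU channels by the absolute Pearson correlation
#' with the joint's angle. Relative importance is the raw score divided by
#' the joint's maximum raw score, so the top channel scores exactly 1.
#' Pearson correlation is affine-invariant, so the scores are computed on
#' preprocessed but unnormalised features.
#'
#' @param train_cycles List of `gait_cycle` objects.
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`.
#' @return Data frame (class `importance_table`) with columns `joint`,
#'   `feature`, `raw_r`, `rel_importance`, one row per channel in
#'   [imu_channels()] order.
#' @export
joint_importance <- function(train_cycles, joint) {
  joint <- match.arg(joint, joint_names())
  if (length(train_cycles) == 0) stop("empty training set")
  X <- do.call(rbind, lapply(train_cycles, function(cy) cy$features))
  y <- unlist(lapply(train_cycles, function(cy) cy$labels[, joint]),
              use.names = FALSE)
  if (nrow(X) < 2) stop("need at least 2 pooled samples")
  raw <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (stats::sd(v) == 0) {
      warning(sprintf("feature %s has zero variance; importance set to 0",
                      colnames(X)[j]))
      return(0)
    }
    abs(stats::cor(v, y))
  }, numeric(1))
  if (all(raw == 0)) stop("all features have zero importance")
  tab <- data.frame(joint = joint, feature = colnames(X), raw_r = raw,
                    rel_importance = raw / max(raw),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(tab) <- c("importance_table", "data.frame")
  tab
}

#' Select features by relative importance across joints
#'
#' Applies the relative-importance rule per joint — keep channels whose
#' importance exceeds `threshold` (strictly, "more than 30 percent" at the
#' default) — and returns the union over the three joints so one model can
#' regress all joints in a single pass. The union is ordered by the
#' canonical channel order for reproducible column layouts.
#'
#' @param tables List of per-joint [joint_importance()] tables (all three
#'   joints required).
#' @param threshold Relative-importance cut in (0, 1), default 0.30.
#' @return Character vector of selected channel names, with attribute
#'   `per_joint` (named list of each joint's own selection).
#' @export
select_features <- function(tables, threshold = 0.30) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  joints <- vapply(tables, function(tb) tb$joint[1], character(1))
  if (!setequal(joints, joint_names())) {
    stop("need one importance table per joint (hip, knee, ankle)")
  }
  per_joint <- lapply(tables, function(tb) {
    tb$feature[tb$rel_importance > threshold]
  })
  names(per_joint) <- joints
  union_set <- imu_channels()[imu_channels() %in%
                                unique(unlist(per_joint))]
  attr(union_set, "per_joint") <- per_joint[joint_names()]
  union_set
}
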