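#' ROC area under the curve for abnormal-gait detection
#'
#' AUC with the abnormal class positive and higher score = more likely
#' abnormal. Computed as the normalized Mann-Whitney statistic with
#' midrank tie handling: `(#\{a > n\} + 0.5 #\{a = n\}) / (|A| |N|)`.
#'
#' @param scores_normal,scores_abnormal Numeric score vectors of the two
#'   classes (both non-empty).
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.1, 0.2), c(0.8, 0.9))  # 1: perfect separation
#' @export
roc_auc <- function(scores_normal, scores_abnormal) {
  nN <- length(scores_normal); nA <- length(scores_abnormal)
  if (nN == 0 || nA == 0)
    stop_gait("insufficient", "both score classes must be non-empty")
  if (any(!is.finite(c(scores_normal, scores_abnormal))))
    stop_gait("parameter", "scores must be finite")
  r <- rank(c(scores_abnormal, scores_normal))  # midranks
  (sum(r[seq_len(nA)]) - nA * (nA + 1) / 2) / (nA * nN)
}

# population variance (divide by n, not n - 1)
pop_var <- function(x) mean((x - mean(x))^2)

#' Score every sequence of a synthetic benchmark
#'
#' Materializes each benchmark sequence with [simulate_walk()], extracts
#' features, and scores it under all 12 processing-flow variants.
#'
#' @param bench A `gait_benchmark` from [make_benchmark()].
#' @param radius Normal-estimation radius in metres.
#' @param verbose Print one line per sequence.
#' @return Data frame with columns `sequence_id`, `subject`, `label`,
#'   `family`, `scheme`, `plane`, `body`, `value` (class
#'   `gait_score_table`).
#' @export
score_benchmark <- function(bench, radius = 0.03, verbose = FALSE) {
  stopifnot(inherits(bench, "gait_benchmark"))
  rows <- lapply(bench$sequences, function(sq) {
    feats <- extract_features(simulate_walk(sq$config), radius = radius)
    sc <- score_sequence(feats)
    if (verbose)
      message(sprintf("%s  %-8s  n=%d", sq$sequence_id, sq$label, nrow(feats)))
    cbind(data.frame(sequence_id = sq$sequence_id, subject = sq$subject,
                     label = sq$label, family = sq$family), sc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gait_score_table", class(out))
  out
}

check_benchmark_structure <- function(scores) {
  for (s in unique(scores$subject)) {
    labs <- scores$label[scores$subject == s]
    if (!any(labs == "normal"))
      stop_gait("evaluation", sprintf("subject %s has no normal sequence", s))
    if (!any(labs == "abnormal"))
      stop_gait("evaluation", sprintf("subject %s has no abnormal sequence", s))
  }
}

auc_from_scores <- function(value, label) {
  roc_auc(value[label == "normal"], value[label == "abnormal"])
}

# variance-based plane weights from one scheme/body slice of a score table,
# using only the named subjects' NORMAL sequences
weights_from_scores <- function(scores, subjects, scheme, body, use) {
  sel <- scores$scheme == scheme & scores$body == body &
         scores$label == "normal" & scores$subject %in% subjects
  w <- vapply(c("transverse", "sagittal", "coronal"), function(p)
    pop_var(scores$value[sel & scores$plane == p]), numeric(1))
  w * use
}

combined_scores <- function(scores, w, scheme, body) {
  planes <- c("transverse", "sagittal", "coronal")
  base <- scores[scores$scheme == scheme & scores$body == body &
                 scores$plane == planes[1],
                 c("sequence_id", "subject", "label")]
  val <- 0
  for (i in seq_along(planes)) {
    sel <- scores$scheme == scheme & scores$body == body &
           scores$plane == planes[i]
    val <- val + w[i] * scores$value[sel]
  }
  base$value <- val
  base
}

#' AUC evaluation of all processing-flow variants
#'
#' From a benchmark (or an already computed score table) computes, for each
#' of the 12 variants {frame, segment} x {transverse, sagittal, coronal} x
#' {full, lower} and for the segment-based weighted combinations
#' (pairwise and all-three, full body):
#' \describe{
#'   \item{`auc_all`}{AUC pooling every sequence, abnormal vs normal. For
#'     combined variants the plane weights are the variances of the
#'     normal-gait indices over all subjects.}
#'   \item{`auc_loo`}{leave-one-subject-out: for each held-out subject the
#'     combination weights are fitted on the *other* subjects' normal
#'     sequences only, and that subject's own 1-normal-vs-rest AUC is
#'     computed; `auc_loo` is the mean over subjects. With a single normal
#'     sequence per subject the per-subject AUC is high-variance.}
#' }
#'
#' @param x A `gait_benchmark` or a score table from [score_benchmark()].
#' @param radius Normal-estimation radius (when scoring a benchmark).
#' @param verbose Passed to [score_benchmark()].
#' @return Data frame with columns `scheme`, `plane`, `body`, `auc_all`,
#'   `auc_loo`; attribute `per_subject` holds the per-subject AUC table and
#'   attribute `scores` the sequence score table.
#' @export
evaluate_all <- function(x, radius = 0.03, verbose = FALSE) {
  scores <- if (inherits(x, "gait_benchmark"))
    score_benchmark(x, radius = radius, verbose = verbose) else x
  check_benchmark_structure(scores)
  subjects <- sort(unique(scores$subject))

  variants <- expand.grid(scheme = c("frame", "segment"),
                          plane = c("transverse", "sagittal", "coronal"),
                          body = c("full", "lower"),
                          stringsAsFactors = FALSE)
  combos <- list("transverse+sagittal" = c(1, 1, 0),
                 "transverse+coronal"  = c(1, 0, 1),
                 "sagittal+coronal"    = c(0, 1, 1),
                 "combined"            = c(1, 1, 1))

  res <- list(); per_subject <- list()
  eval_variant <- function(tbl, scheme, plane, body) {
    ps <- vapply(subjects, function(s)
      auc_from_scores(tbl$value[tbl$subject == s],
                      tbl$label[tbl$subject == s]), numeric(1))
    per_subject[[length(per_subject) + 1L]] <<-
      data.frame(scheme = scheme, plane = plane, body = body,
                 subject = subjects, auc = ps)
    data.frame(scheme = scheme, plane = plane, body = body,
               auc_all = auc_from_scores(tbl$value, tbl$label),
               auc_loo = mean(ps))
  }

  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    tbl <- scores[scores$scheme == v$scheme & scores$plane == v$plane &
                  scores$body == v$body, ]
    res[[length(res) + 1L]] <- eval_variant(tbl, v$scheme, v$plane, v$body)
  }

  for (nm in names(combos)) {
    use <- combos[[nm]]
    # pooled: weights from every subject's normal sequences
    w_all <- weights_from_scores(scores, subjects, "segment", "full", use)
    tbl_all <- combined_scores(scores, w_all, "segment", "full")
    # leave-one-out: per-fold weights exclude the held-out subject
    ps <- vapply(subjects, function(s) {
      w <- weights_from_scores(scores, setdiff(subjects, s),
                               "segment", "full", use)
      tbl <- combined_scores(scores, w, "segment", "full")
      auc_from_scores(tbl$value[tbl$subject == s],
                      tbl$label[tbl$subject == s])
    }, numeric(1))
    per_subject[[length(per_subject) + 1L]] <-
      data.frame(scheme = "segment", plane = nm, body = "full",
                 subject = subjects, auc = ps)
    res[[length(res) + 1L]] <-
      data.frame(scheme = "segment", plane = nm, body = "full",
                 auc_all = auc_from_scores(tbl_all$value, tbl_all$label),
                 auc_loo = mean(ps))
  }

  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "per_subject") <- do.call(rbind, per_subject)
  attr(out, "scores") <- scores
  out
}
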