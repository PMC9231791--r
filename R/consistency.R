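#' Consistency of a global ranking with the original submissions
#'
#' After GLEPO aggregation, the global list should preserve each user's
#' within-submission order as far as the data allow. These functions
#' quantify the residual disagreement: the positional loss L(r,w) per
#' submission, the total loss L(R,w) over the collection, the fraction of
#' preserved ordered pairs (the headline consistency percentage), and
#' Kendall's tau per submission.
#'
#' @name consistency
NULL

# positions of node ids in a ranking; accepts a glepo_ranking or a plain
# ordered id vector
ranking_positions <- function(ranking) {
  ids <- if (inherits(ranking, "glepo_ranking")) ranking$node_id
         else as.character(ranking)
  setNames(seq_along(ids), ids)
}

induced_ranks <- function(sub, ranking) {
  pos <- ranking_positions(ranking)
  missing <- setdiff(sub, names(pos))
  if (length(missing))
    stopf("node(s) %s not present in the ranking", paste(missing, collapse = ", "))
  rank(pos[sub], ties.method = "first")
}

#' Positional loss of one submission
#'
#' L(r,w) = sum over the submission's 5 nodes of |o_i^r - o_i^w|, where
#' o_i^r is the user-submitted rank (1..5) and o_i^w the rank induced by
#' the nodes' relative order in the global list. Always even; at most 12
#' for 5-node submissions (full reversal).
#'
#' @param sub character vector: one submission in submitted order.
#' @param ranking a `glepo_ranking` or ordered node-id vector.
#' @return non-negative even integer
#' @export
submission_loss <- function(sub, ranking) {
  o_w <- induced_ranks(sub, ranking)
  sum(abs(seq_along(sub) - o_w))
}

#' Total loss over a submission set
#'
#' L(R,w) = sum of [submission_loss()] over all submissions; the mean
#' aggregate is reported alongside.
#'
#' @param subs a `submission_set`
#' @param ranking a `glepo_ranking` or ordered node-id vector.
#' @return list with `total`, `mean` and `per_submission` (numeric vector)
#' @export
total_loss <- function(subs, ranking) {
  per <- vapply(subs$nodes, submission_loss, numeric(1), ranking = ranking)
  list(total = sum(per), mean = mean(per), per_submission = per)
}

#' Preserved-pair consistency percentage
#'
#' The percentage of within-submission ordered pairs whose order the global
#' list preserves: 100 means every submission's internal order survived
#' aggregation intact. For submissions of 5 nodes each submission
#' contributes 10 pairs.
#'
#' @param subs a `submission_set`
#' @param ranking a `glepo_ranking` or ordered node-id vector.
#' @return percentage in \[0, 100\]
#' @export
consistency_pct <- function(subs, ranking) {
  pos <- ranking_positions(ranking)
  preserved <- 0L; total <- 0L
  for (sub in subs$nodes) {
    missing <- setdiff(sub, names(pos))
    if (length(missing))
      stopf("node(s) %s not present in the ranking", paste(missing, collapse = ", "))
    p <- pos[sub]
    g <- length(sub)
    for (i in seq_len(g - 1L)) {
      preserved <- preserved + sum(p[i] < p[(i + 1L):g])
      total <- total + (g - i)
    }
  }
  100 * preserved / total
}

#' Kendall rank correlation of one submission with the global list
#'
#' Standard Kendall tau between the submitted order (1..5) and the order
#' induced by the global list, i.e. (concordant - discordant) / 10 for
#' 5-node submissions.
#'
#' @param sub character vector: one submission in submitted order.
#' @param ranking a `glepo_ranking` or ordered node-id vector.
#' @return tau in \[-1, 1\]
#' @export
kendall_tau <- function(sub, ranking) {
  o_w <- induced_ranks(sub, ranking)
  cor(seq_along(sub), o_w, method = "kendall")
}

#' Full loss / consistency report
#'
#' Per-submission positional loss, out-of-order node counts, preserved-pair
#' fractions and Kendall tau, with collection-level summaries.
#'
#' @param subs a `submission_set`
#' @param ranking a `glepo_ranking` or ordered node-id vector.
#' @return object of class `loss_report`: list with `per_submission`
#'   (data.frame: `user_id`, `loss`, `out_of_order`, `preserved_pairs`,
#'   `kendall_tau`) and `summary` (list: `total_loss`, `mean_loss`,
#'   `consistency_pct`, `mean_kendall_tau`, `n_submissions`)
#' @export
consistency_report <- function(subs, ranking) {
  pos <- ranking_positions(ranking)
  g <- lengths(subs$nodes)
  per <- data.frame(
    user_id = subs$user_ids,
    loss = vapply(subs$nodes, submission_loss, numeric(1), ranking = ranking),
    out_of_order = vapply(subs$nodes, function(s)
      sum(induced_ranks(s, ranking) != seq_along(s)), numeric(1)),
    preserved_pairs = vapply(subs$nodes, function(s) {
      p <- pos[s]; n <- length(s)
      sum(vapply(seq_len(n - 1L), function(i)
        sum(p[i] < p[(i + 1L):n]), numeric(1))) / choose(n, 2)
    }, numeric(1)),
    kendall_tau = vapply(subs$nodes, kendall_tau, numeric(1), ranking = ranking),
    stringsAsFactors = FALSE)
  structure(list(
    per_submission = per,
    summary = list(total_loss = sum(per$loss),
                   mean_loss = mean(per$loss),
                   consistency_pct = consistency_pct(subs, ranking),
                   mean_kendall_tau = mean(per$kendall_tau),
                   n_submissions = nrow(per))),
    class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<loss_report> %d submissions | total loss %g (mean %.3g) | consistency %.2f%% | mean tau %.3f\n",
              s$n_submissions, s$total_loss, s$mean_loss,
              s$consistency_pct, s$mean_kendall_tau))
  invisible(x)
}

#' Write a loss report (per-submission CSV + JSON summary)
#' @param report a `loss_report`
#' @param csv_file per-submission CSV path (optional)
#' @param json_file summary JSON path (optional)
#' @return invisibly, the report
#' @export
write_loss_report <- function(report, csv_file = NULL, json_file = NULL) {
  if (!is.null(csv_file))
    write.csv(report$per_submission, csv_file, row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(report$summary, json_file, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
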