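#' Construct a submission set
#'
#' A submission is one user's ordered ranking of exactly 5 distinct road
#' nodes. The fixed direction convention throughout the package is
#' *ascending walkability*: the first node is the one the user judged least
#' walkable and the last the most walkable.
#'
#' @param nodes list of character vectors, each of length 5 with distinct
#'   node ids, ordered by ascending walkability.
#' @param user_ids optional character vector of user ids (recycled if
#'   length 1); defaults to `"u1"` for all.
#' @param group_size expected submission length (default 5).
#' @return object of class `submission_set`: a list with elements `nodes`
#'   (list of id vectors) and `user_ids`.
#' @export
submission_set <- function(nodes, user_ids = NULL, group_size = 5L) {
  if (!is.list(nodes) || !length(nodes))
    stopf("`nodes` must be a non-empty list of id vectors")
  nodes <- lapply(nodes, as.character)
  bad_len <- which(lengths(nodes) != group_size)
  if (length(bad_len))
    stopf("submission %d has %d nodes; expected %d",
          bad_len[1], length(nodes[[bad_len[1]]]), group_size)
  dup <- which(vapply(nodes, anyDuplicated, integer(1)) > 0L)
  if (length(dup))
    stopf("submission %d contains duplicate node ids", dup[1])
  if (is.null(user_ids)) user_ids <- "u1"
  user_ids <- rep_len(as.character(user_ids), length(nodes))
  structure(list(nodes = nodes, user_ids = user_ids), class = "submission_set")
}

#' @export
print.submission_set <- function(x, ...) {
  cat(sprintf("<submission_set> %d submissions (%d slots, %d unique nodes, %d users)\n",
              length(x$nodes), sum(lengths(x$nodes)),
              length(unique(unlist(x$nodes))), length(unique(x$user_ids))))
  invisible(x)
}

#' @export
length.submission_set <- function(x) length(x$nodes)

#' Unique node ids appearing in a submission set
#' @param subs a `submission_set`
#' @return character vector, in first-appearance order
#' @export
submitted_nodes <- function(subs) unique(unlist(subs$nodes))

#' Read submissions from a JSON-lines file
#'
#' One JSON object per line: `{"user_id": ..., "nodes": [id1..id5]}`.
#'
#' @param file path to a JSONL file
#' @return a `submission_set`
#' @export
read_submissions <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("'%s' contains no submissions", file)
  parsed <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e) stopf("malformed JSON on line %d of '%s'", i, file))
  })
  submission_set(lapply(parsed, function(p) as.character(p$nodes)),
                 vapply(parsed, function(p) as.character(p$user_id %||% "u1"),
                        character(1)))
}

#' Write submissions as JSON lines
#' @param subs a `submission_set`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_submissions <- function(subs, file) {
  lines <- vapply(seq_along(subs$nodes), function(j) {
    jsonlite::toJSON(list(user_id = subs$user_ids[j], nodes = subs$nodes[[j]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
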