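#' Autism Behavior Checklist item weight table
#'
#' The ABC instrument has 57 yes/no items, each carrying a fixed integer
#' weight of 1-4 and belonging to one of five behavioral areas (sensory;
#' relating; body and object use; language; social and self-help). The
#' per-item weights of the published instrument are proprietary and not
#' reproduced here: this table is a synthetic stand-in that preserves the
#' instrument's structure -- the published per-area item counts
#' (9/12/12/13/11) and the 1-4 weight range -- with weights assigned by a
#' fixed repeating pattern. All scoring in the package is defined relative
#' to this table; the maximum attainable total is `sum(weights) = 140`.
#'
#' @return data.frame with columns `item` (1-57), `area` (factor, five
#'   levels), `weight` (integer 1-4).
#' @export
abc_weight_table <- function() {
  areas <- c("sensory", "relating", "body_object_use", "language",
             "social_self_help")
  counts <- c(sensory = 9L, relating = 12L, body_object_use = 12L,
              language = 13L, social_self_help = 11L)
  pattern <- c(2L, 1L, 3L, 4L)
  weight <- unlist(lapply(counts, function(k) rep_len(pattern, k)),
                   use.names = FALSE)
  data.frame(item = seq_len(57L),
             area = factor(rep(areas, counts), levels = areas),
             weight = weight)
}

#' Score an ABC record
#'
#' Adds the item weights of all "yes" responses within each behavioral
#' area (subscale scores) and over the whole questionnaire (total score).
#'
#' @param rec an `abc_record` (see [generate_abc_items()]) or a logical
#'   vector of 57 responses, scored against [abc_weight_table()].
#' @return list of class `abc_scores`: `subscale` (named numeric, five
#'   areas) and `total`.
#' @export
score_abc <- function(rec) {
  if (inherits(rec, "abc_record")) {
    responses <- rec$responses
    table <- rec$table
  } else {
    responses <- as.logical(rec)
    table <- abc_weight_table()
  }
  if (length(responses) != 57L || anyNA(responses))
    stop("an ABC record must have exactly 57 yes/no responses")
  yes_w <- ifelse(responses, table$weight, 0L)
  subscale <- tapply(yes_w, table$area, sum)
  structure(list(subscale = c(subscale), total = sum(yes_w)),
            class = "abc_scores")
}

#' Generate ABC item responses hitting a target total score
#'
#' Produces a random 57-item yes/no response pattern whose weighted total
#' equals `target_total` exactly whenever that total is attainable under
#' the package weight table (with weights 1-4 and multiple weight-1 items
#' every integer total in `[0, 140]` is attainable). Selection is a
#' seeded randomized greedy pass over a permutation of the items, with a
#' single-swap repair step.
#'
#' @param target_total desired weighted total score, `0 <= target <= 140`.
#' @param seed optional integer seed.
#' @return list of class `abc_record`: `responses` (logical 57), `table`
#'   (the weight table), `target_total`.
#' @export
generate_abc_items <- function(target_total, seed = NULL) {
  table <- abc_weight_table()
  max_total <- sum(table$weight)
  if (!is.numeric(target_total) || length(target_total) != 1L ||
      is.na(target_total) || target_total < 0)
    stop("target_total must be a single non-negative number")
  if (target_total > max_total)
    stop(sprintf("target_total exceeds the maximum attainable total (%d)",
                 max_total))
  target_total <- round(target_total)
  if (!is.null(seed)) set.seed(seed)
  order_idx <- sample.int(57L)
  responses <- rep(FALSE, 57L)
  remaining <- target_total
  for (i in order_idx) {
    if (table$weight[i] <= remaining) {
      responses[i] <- TRUE
      remaining <- remaining - table$weight[i]
    }
  }
  if (remaining > 0) {
    # swap one included item for an excluded one weighing `remaining` more
    for (j in which(!responses)) {
      k <- which(responses & table$weight == table$weight[j] - remaining)
      if (length(k)) {
        responses[k[1]] <- FALSE
        responses[j] <- TRUE
        remaining <- 0
        break
      }
    }
  }
  structure(list(responses = responses, table = table,
                 target_total = target_total),
            class = "abc_record")
}
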