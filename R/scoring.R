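# Scoring: raw item responses -> the nine analysis variables.

#' Apply the attention-check exclusion
#'
#' Participants who failed the attention check before the speech-gesture
#' matching task are removed, mirroring the exclusion of task data from
#' inattentive responders in online studies.
#'
#' @param responses Data frame with a logical `attention_pass` column.
#' @return List with `retained` (the filtered data frame) and `report`
#'   (list: `n_total`, `n_removed`, `prop_removed`).
#' @export
apply_attention_filter <- function(responses) {
  if (is.null(responses$attention_pass)) {
    stop("responses must carry an attention_pass column", call. = FALSE)
  }
  keep <- responses$attention_pass %in% TRUE
  report <- list(
    n_total = nrow(responses),
    n_removed = sum(!keep),
    prop_removed = if (nrow(responses)) sum(!keep) / nrow(responses) else 0
  )
  if (report$n_removed == report$n_total && report$n_total > 0) {
    warning("all participants failed the attention check; retained set is empty",
            call. = FALSE)
  }
  list(retained = responses[keep, , drop = FALSE], report = report)
}

#' Score the SPQ-B
#'
#' Sums the 22 binary items into the three subscales and the total score.
#' Rows with a missing item get NA on the affected subscale (complete-case
#' per variable).
#'
#' @param responses Data frame with columns `spq_01`..`spq_22` (0/1).
#' @param item_map Partition of items 1-22 into the three subscales; see
#'   [spq_item_map()].
#' @return Data frame with `CogPerc`, `Interp`, `Disorg`, `SPQ_total`.
#' @export
score_spq <- function(responses, item_map = spq_item_map()) {
  check_item_map(item_map, 22L, "SPQ-B",
                 required = c("CogPerc", "Interp", "Disorg"))
  cols <- sprintf("spq_%02d", 1:22)
  if (!all(cols %in% names(responses))) {
    stop("responses must contain columns spq_01..spq_22", call. = FALSE)
  }
  items <- as.matrix(responses[, cols])
  ok <- items %in% c(0, 1) | is.na(items)
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(items)), arr.ind = TRUE)[1, ]
    stop(sprintf("SPQ-B item %d of row %d is not binary", bad[2], bad[1]),
         call. = FALSE)
  }
  out <- data.frame(
    CogPerc = rowSums(items[, item_map$CogPerc, drop = FALSE]),
    Interp  = rowSums(items[, item_map$Interp, drop = FALSE]),
    Disorg  = rowSums(items[, item_map$Disorg, drop = FALSE])
  )
  out$SPQ_total <- out$CogPerc + out$Interp + out$Disorg
  out
}

#' Score the BAG scale
#'
#' Recodes reverse-keyed items as `6 - response`, then sums the 12 items
#' (1-5) into the four 3-item subscales.
#'
#' @param responses Data frame with columns `bag_01`..`bag_12`.
#' @param item_map Partition of items 1-12 into four subscales; see
#'   [bag_item_map()].
#' @param reverse_keyed Item indices recoded before summation; see
#'   [bag_reverse_keyed()].
#' @return Data frame with `Perc`, `Prod`, `SocPerc`, `SocProd`.
#' @export
score_bag <- function(responses, item_map = bag_item_map(),
                      reverse_keyed = bag_reverse_keyed()) {
  check_item_map(item_map, 12L, "BAG",
                 required = c("Perc", "Prod", "SocPerc", "SocProd"))
  cols <- sprintf("bag_%02d", 1:12)
  if (!all(cols %in% names(responses))) {
    stop("responses must contain columns bag_01..bag_12", call. = FALSE)
  }
  items <- as.matrix(responses[, cols])
  bad <- which(!(items %in% 1:5 | is.na(items)))
  if (length(bad)) {
    pos <- arrayInd(bad[1], dim(items))
    stop(sprintf("BAG response out of range 1-5 at row %d, item %d",
                 pos[1], pos[2]), call. = FALSE)
  }
  if (length(reverse_keyed)) {
    items[, reverse_keyed] <- 6 - items[, reverse_keyed]
  }
  out <- lapply(item_map, function(idx) rowSums(items[, idx, drop = FALSE]))
  as.data.frame(out)
}

#' Score the speech-gesture matching task
#'
#' Congruence-sensitivity indices from the eight 7-point relatedness
#' ratings: `Icon` = mean(concrete-related) - mean(concrete-unrelated),
#' `Metaph` = mean(abstract-related) - mean(abstract-unrelated). Higher
#' values mean better discrimination of related from unrelated gestures;
#' both indices are bounded in \[-6, 6\].
#'
#' @param ratings Data frame or matrix with columns `vid_AR1`..`vid_CU2`
#'   (bare condition names `AR1`.. are also accepted).
#' @return Data frame with `Icon` and `Metaph`.
#' @export
score_gesture_task <- function(ratings) {
  ratings <- as.data.frame(ratings)
  want <- paste0("vid_", video_conditions())
  if (!all(want %in% names(ratings))) {
    alt <- video_conditions()
    if (all(alt %in% names(ratings))) {
      names(ratings)[match(alt, names(ratings))] <- want
    } else {
      stop("ratings must contain all eight conditions: ",
           paste(video_conditions(), collapse = ", "), call. = FALSE)
    }
  }
  m <- as.matrix(ratings[, want])
  bad <- which(!(m %in% 1:7 | is.na(m)))
  if (length(bad)) {
    pos <- arrayInd(bad[1], dim(m))
    stop(sprintf("video rating out of range 1-7 at row %d, column %s",
                 pos[1], want[pos[2]]), call. = FALSE)
  }
  cond_mean <- function(cond) {
    rowMeans(m[, paste0("vid_", cond, 1:2), drop = FALSE])
  }
  data.frame(
    Icon   = cond_mean("CR") - cond_mean("CU"),
    Metaph = cond_mean("AR") - cond_mean("AU")
  )
}

#' Score a full response table into the subscale table
#'
#' Applies the attention filter, then scores SPQ-B, BAG and the
#' speech-gesture matching task into the nine analysis variables plus the
#' SPQ-B total.
#'
#' @param responses Raw response data frame (see
#'   [simulate_item_responses()] for the column layout).
#' @param spq_map,bag_map,reverse_keyed Scoring configuration; see
#'   [spq_item_map()], [bag_item_map()], [bag_reverse_keyed()].
#' @param apply_filter If TRUE (default) drop participants failing the
#'   attention check before scoring.
#' @return List with `subscales` (data frame: `participant_id`, the nine
#'   node columns and `SPQ_total`) and `exclusion_report`.
#' @export
score_responses <- function(responses,
                            spq_map = spq_item_map(),
                            bag_map = bag_item_map(),
                            reverse_keyed = bag_reverse_keyed(),
                            apply_filter = TRUE) {
  if (apply_filter && !is.null(responses$attention_pass)) {
    flt <- apply_attention_filter(responses)
    responses <- flt$retained
    report <- flt$report
  } else {
    report <- list(n_total = nrow(responses), n_removed = 0L,
                   prop_removed = 0)
  }
  subscales <- cbind(
    data.frame(participant_id = responses$participant_id,
               stringsAsFactors = FALSE),
    score_spq(responses, spq_map)[, c("CogPerc", "Interp", "Disorg",
                                      "SPQ_total")],
    score_bag(responses, bag_map, reverse_keyed),
    score_gesture_task(responses)
  )
  rownames(subscales) <- NULL
  list(subscales = subscales, exclusion_report = report)
}
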