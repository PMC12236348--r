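# Instrument configuration: node labels, block membership, item maps and
# discretization thresholds. These are data, not code, so that alternative
# scoring conventions can be swapped in without touching the estimators.

#' Node labels of the nine-variable network
#'
#' Three SPQ-B subscales (cognitive-perceptual, interpersonal,
#' disorganization), four BAG subscales (perception, production, social
#' perception, social production) and the two speech-gesture matching indices
#' (iconic, metaphoric), in the canonical column order used throughout the
#' package.
#'
#' @return Character vector of length 9.
#' @export
node_labels <- function() {
  c("CogPerc", "Interp", "Disorg",
    "Perc", "Prod", "SocPerc", "SocProd",
    "Icon", "Metaph")
}

#' Instrument blocks of the nine network variables
#'
#' @return Named integer vector mapping each node to its instrument block:
#'   1 = schizotypal traits (SPQ-B), 2 = self-reported gesture processing
#'   (BAG), 3 = speech-gesture matching task.
#' @export
instrument_blocks <- function() {
  stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L), node_labels())
}

#' Default SPQ-B item-to-subscale map
#'
#' The SPQ-B has 22 yes/no items partitioned into cognitive-perceptual (8
#' items), interpersonal (8 items) and disorganization (6 items) subscales.
#' The default uses contiguous blocks; studies with the published item keys
#' can pass their own partition.
#'
#' @return Named list of integer item indices (1-22), one element per
#'   subscale.
#' @export
spq_item_map <- function() {
  list(CogPerc = 1:8, Interp = 9:16, Disorg = 17:22)
}

#' Default BAG item-to-subscale map
#'
#' Twelve items (1-5 agreement ratings) in four 3-item subscales:
#' perception, production, social perception, social production.
#'
#' @return Named list of integer item indices (1-12).
#' @export
bag_item_map <- function() {
  list(Perc = 1:3, Prod = 4:6, SocPerc = 7:9, SocProd = 10:12)
}

#' Default BAG reverse-keyed item set
#'
#' The perception subscale's anchor item is worded negatively (gesturing by
#' a speaker described as distracting), so item 1 defaults to reverse-keyed;
#' responses x on reverse-keyed items are recoded to 6 - x before summation.
#'
#' @return Integer vector of item indices in 1-12.
#' @export
bag_reverse_keyed <- function() 1L

#' Video condition labels of the speech-gesture matching task
#'
#' Eight videos: 2 x abstract-related (AR), 2 x abstract-unrelated (AU),
#' 2 x concrete-related (CR), 2 x concrete-unrelated (CU), each rated for
#' speech-gesture relatedness on a 7-point scale.
#'
#' @return Character vector of the eight condition-numbered labels.
#' @export
video_conditions <- function() {
  c("AR1", "AR2", "AU1", "AU2", "CR1", "CR2", "CU1", "CU2")
}

#' Default discretization thresholds for item simulation
#'
#' Quantile-style cutpoints on the standard-normal item latents: one cut for
#' the binary SPQ-B items (endorsement rate ~30%), four cuts for the 5-point
#' BAG items, six cuts for the 7-point video ratings.
#'
#' @return Named list with elements `spq`, `bag`, `video`.
#' @export
default_thresholds <- function() {
  list(
    spq   = qnorm(0.70),
    bag   = qnorm(c(0.10, 0.35, 0.65, 0.90)),
    video = qnorm(c(0.05, 0.17, 0.36, 0.64, 0.83, 0.95))
  )
}

# Internal: validate a map partitions 1:n_items into the named subscales.
check_item_map <- function(item_map, n_items, what, required = NULL) {
  if (!is.null(required) && !setequal(names(item_map), required)) {
    stop(what, " item map must name the subscales ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  idx <- sort(unlist(item_map, use.names = FALSE))
  if (anyDuplicated(idx)) {
    stop(what, " item map assigns some items to more than one subscale",
         call. = FALSE)
  }
  if (!identical(as.integer(idx), seq_len(n_items))) {
    stop(what, " item map must partition items 1..", n_items, call. = FALSE)
  }
  invisible(TRUE)
}
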