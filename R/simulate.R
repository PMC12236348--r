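# Latent-Gaussian simulation of subscale scores and item-level responses.

#' Simulate subscale-level observations from a ground-truth network
#'
#' Draws `n` participants from the multivariate Gaussian whose covariance is
#' implied by the ground-truth partial-correlation matrix
#' ([pcor_to_covariance()]). These standardized draws play the role of the
#' nine derived subscale variables entering the network model.
#'
#' @param gt A `ground_truth_network`.
#' @param n Number of participants (at least 10).
#' @param seed Integer seed.
#' @return Data frame with `participant_id` and one column per node, in
#'   [node_labels()] order.
#' @export
simulate_subscales <- function(gt, n, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth_network"))
  n <- as.integer(n)
  if (n < 10L) {
    stop("n must be at least 10; downstream estimation is undefined below that",
         call. = FALSE)
  }
  sigma <- pcor_to_covariance(gt)
  p <- ncol(sigma)
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  colnames(z) <- gt$node_labels
  out <- data.frame(participant_id = paste0("P", seq_len(n)), z,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Latent item scores for one subscale: equicorrelated items loading
# `loading` on the subscale factor, unit total variance.
item_latents <- function(factor_scores, n_items, loading, signs = NULL) {
  n <- length(factor_scores)
  if (is.null(signs)) signs <- rep(1, n_items)
  eps <- matrix(rnorm(n * n_items), n, n_items)
  outer(factor_scores, signs * loading) + eps * sqrt(1 - loading^2)
}

# Discretize a latent column by strictly increasing cutpoints into
# categories first_cat, first_cat+1, ...
cut_latent <- function(z, cuts, first_cat = 1L) {
  findInterval(z, cuts) + first_cat
}

#' Simulate item-level responses from a ground-truth network
#'
#' Disaggregates latent subscale draws into correlated item-level latents
#' (equicorrelated within subscale, default loading 0.7) and discretizes
#' them by quantile-style thresholds into the instruments' response ranges:
#' 22 binary SPQ-B items, 12 five-point BAG items and 8 seven-point video
#' relatedness ratings. Video items in Related conditions load positively
#' and Unrelated conditions negatively on the corresponding task latent,
#' with a mean shift so related gestures are rated as more aligned.
#' Reverse-keyed BAG items are generated with negative loadings so that the
#' scoring recode restores a positive relation to the latent. The attention
#' check is an independent Bernoulli flag.
#'
#' @param gt A `ground_truth_network`.
#' @param n Number of participants (at least 10).
#' @param thresholds Named list of cutpoints (`spq`: 1, `bag`: 4,
#'   `video`: 6), on the standard-normal latent scale; see
#'   [default_thresholds()].
#' @param attention_fail_rate Probability in `[0, 1)` that a participant
#'   fails the attention check.
#' @param loading Item-factor loading in (0, 1); default 0.7.
#' @param related_shift Mean shift applied to the video item latents,
#'   positive for Related and negative for Unrelated conditions; default 1.
#' @param seed Integer seed.
#' @param return_latents If TRUE, attach the generating subscale latents as
#'   attribute `"latents"`.
#' @return Data frame with `participant_id`, `spq_01`..`spq_22`,
#'   `bag_01`..`bag_12`, `vid_AR1`..`vid_CU2` and `attention_pass`.
#' @export
simulate_item_responses <- function(gt, n,
                                    thresholds = default_thresholds(),
                                    attention_fail_rate = 0.04,
                                    loading = 0.7,
                                    related_shift = 1,
                                    seed = 1L,
                                    return_latents = FALSE) {
  stopifnot(inherits(gt, "ground_truth_network"))
  n <- as.integer(n)
  if (n < 10L) stop("n must be at least 10", call. = FALSE)
  if (attention_fail_rate < 0 || attention_fail_rate >= 1) {
    stop("attention_fail_rate must be in [0, 1)", call. = FALSE)
  }
  if (loading <= 0 || loading >= 1) stop("loading must be in (0, 1)",
                                         call. = FALSE)
  for (nm in c("spq", "bag", "video")) {
    cuts <- thresholds[[nm]]
    need <- c(spq = 1L, bag = 4L, video = 6L)[[nm]]
    if (is.null(cuts) || length(cuts) != need) {
      stop(sprintf("thresholds$%s must have %d cutpoint(s) for the item range",
                   nm, need), call. = FALSE)
    }
    if (need > 1L && any(diff(cuts) <= 0)) {
      stop(sprintf("thresholds$%s must be strictly increasing", nm),
           call. = FALSE)
    }
  }

  subs <- simulate_subscales(gt, n, seed = seed)
  lat <- subscale_matrix(subs)
  # simulate_subscales consumed the stream deterministically; continue from
  # a derived state for the item-level noise.
  set.seed(as.integer(seed) + 1L)

  out <- data.frame(participant_id = subs$participant_id,
                    stringsAsFactors = FALSE)

  spq_map <- spq_item_map()
  spq <- matrix(NA_integer_, n, 22L,
                dimnames = list(NULL, sprintf("spq_%02d", 1:22)))
  for (sub in names(spq_map)) {
    items <- spq_map[[sub]]
    z <- item_latents(lat[, sub], length(items), loading)
    spq[, items] <- cut_latent(z, thresholds$spq, first_cat = 0L)
  }
  out <- cbind(out, as.data.frame(spq))

  bag_map <- bag_item_map()
  rev_items <- bag_reverse_keyed()
  bag <- matrix(NA_integer_, n, 12L,
                dimnames = list(NULL, sprintf("bag_%02d", 1:12)))
  for (sub in names(bag_map)) {
    items <- bag_map[[sub]]
    signs <- ifelse(items %in% rev_items, -1, 1)
    z <- item_latents(lat[, sub], length(items), loading, signs = signs)
    bag[, items] <- cut_latent(z, thresholds$bag, first_cat = 1L)
  }
  out <- cbind(out, as.data.frame(bag))

  # Video ratings: AR/AU driven by the metaphoric latent, CR/CU by the
  # iconic latent; Unrelated conditions load negatively.
  vid_spec <- list(
    AR = list(latent = "Metaph", sign = +1), AU = list(latent = "Metaph", sign = -1),
    CR = list(latent = "Icon",   sign = +1), CU = list(latent = "Icon",   sign = -1)
  )
  vid <- matrix(NA_integer_, n, 8L,
                dimnames = list(NULL, paste0("vid_", video_conditions())))
  for (cond in names(vid_spec)) {
    s <- vid_spec[[cond]]
    z <- item_latents(lat[, s$latent], 2L, loading, signs = rep(s$sign, 2L))
    z <- z + s$sign * related_shift
    cols <- paste0("vid_", cond, 1:2)
    vid[, cols] <- cut_latent(z, thresholds$video, first_cat = 1L)
  }
  out <- cbind(out, as.data.frame(vid))

  out$attention_pass <- runif(n) >= attention_fail_rate
  rownames(out) <- NULL
  if (return_latents) attr(out, "latents") <- lat
  out
}
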