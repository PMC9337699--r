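# Task environment and ideal observer: beliefs (log-likelihood ratios),
# rare-ball thresholds, exact response probabilities, trial sampling.

#' Belief increment for a single ball
#'
#' Log-odds update of the ideal observer after observing one ball:
#' \code{log(h_plus/h_minus)} for a rare ball (+1) and
#' \code{log((1-h_plus)/(1-h_minus))} for a common ball (-1). In symmetric
#' blocks the two increments have equal magnitude and opposite sign; in
#' asymmetric blocks the rare-ball increment is larger in magnitude.
#'
#' @param block A [block_config()].
#' @param ball Vector with entries +1 (rare) or -1 (common).
#' @return Numeric vector of log-odds increments (natural log).
#' @export
#' @examples
#' belief_increment(block_config("HA", 0.2, 0.1), c(+1, -1))
belief_increment <- function(block, ball) {
  if (block$h_plus >= 1 || block$h_minus >= 1)
    stop("degenerate jar: a ball colour with probability 0 carries infinite evidence",
         call. = FALSE)
  if (!all(ball %in% c(-1, 1))) stop("balls must be +1 or -1", call. = FALSE)
  inc_plus <- log(block$h_plus / block$h_minus)
  inc_minus <- log((1 - block$h_plus) / (1 - block$h_minus))
  ifelse(ball == 1, inc_plus, inc_minus)
}

#' Ideal observer belief over a sample
#'
#' Accumulated log-likelihood ratio \eqn{z_n = z_0 + \sum_j \Psi(\xi_j)}
#' comparing the high against the low jar. The sum is order-invariant, so the
#' belief depends on the sample only through the rare-ball count and the
#' sample length.
#'
#' @param block A [block_config()].
#' @param sample Vector of +1/-1 ball observations (may be empty) or an
#'   "R"/"C" character string as stored in trial tables.
#' @param z0 Prior log odds (0 for the equal-prior task).
#' @return Scalar belief \code{z} (natural log).
#' @export
ideal_belief <- function(block, sample, z0 = 0) {
  if (is.character(sample)) sample <- sample_to_signs(sample)
  if (length(sample) == 0L) return(z0)
  z0 + sum(belief_increment(block, sample))
}

# belief for every rare count k = 0..n (names give k)
llr_by_count <- function(block, n, z0 = 0) {
  k <- 0:n
  inc_plus <- log(block$h_plus / block$h_minus)
  inc_minus <- log((1 - block$h_plus) / (1 - block$h_minus))
  z <- z0 + k * inc_plus + (n - k) * inc_minus
  names(z) <- k
  z
}

#' Ideal observer choice rule
#'
#' Chooses "high" for positive belief, "low" for negative belief, and
#' resolves an exactly-zero belief by a fair coin flip.
#'
#' @param z Numeric vector of beliefs.
#' @return Character vector of responses ("high"/"low").
#' @export
ideal_choice <- function(z) {
  stopifnot(all(is.finite(z)))
  r <- ifelse(z > 0, "high", "low")
  tie <- z == 0
  if (any(tie)) r[tie] <- ifelse(stats::runif(sum(tie)) < 0.5, "high", "low")
  r
}

#' Minimum rare-ball count for a high response
#'
#' The smallest number of rare balls \code{B} in a sample of length \code{n}
#' for which the ideal observer's belief is positive. For symmetric blocks
#' and even \code{n} the boundary count \code{n/2} yields a belief of exactly
#' zero; by convention \code{B = n/2} is then reported (the tie is resolved
#' randomly by [ideal_choice()]).
#'
#' @param block A [block_config()].
#' @param n Sample length (>= 1).
#' @return Scalar threshold, possibly the half-integer convention \code{n/2}.
#' @export
rare_ball_threshold <- function(block, n) {
  stopifnot(n >= 1)
  z <- llr_by_count(block, n)
  if (any(abs(z) < 1e-12)) return(n / 2)
  pos <- which(z > 0)
  if (length(pos) == 0L) return(n + 1)  # no count yields a high response
  as.numeric(names(z)[pos[1L]])
}

#' Exact response probabilities of the ideal observer
#'
#' Closed-form response probabilities from the binomial distribution of
#' rare-ball counts. Counts with positive belief map to "high", negative to
#' "low"; a count with exactly zero belief contributes half its binomial mass
#' to each response (random tie resolution). Jar-conditional probabilities
#' are mixed with the block prior to give marginal response probabilities.
#'
#' @param block A [block_config()].
#' @param n Sample length.
#' @return List with \code{p_high_given} (named vector over jars),
#'   \code{p_low_given}, marginal \code{p_high}, \code{p_low}, and the
#'   threshold \code{B}.
#' @export
ideal_response_probabilities <- function(block, n) {
  z <- llr_by_count(block, n)
  k <- 0:n
  w_high <- as.numeric(z > 1e-12) + 0.5 * (abs(z) <= 1e-12)
  p_high_given <- vapply(c(high = block$h_plus, low = block$h_minus),
                         function(h) sum(stats::dbinom(k, n, h) * w_high),
                         numeric(1))
  p_high <- block$prior_high * p_high_given[["high"]] +
    (1 - block$prior_high) * p_high_given[["low"]]
  list(p_high_given = p_high_given,
       p_low_given = 1 - p_high_given,
       p_high = p_high, p_low = 1 - p_high,
       B = rare_ball_threshold(block, n))
}

#' Sample the trials of one block
#'
#' Builds the stimulus set of a block: every (jar, sample length) pair occurs
#' equally often, each trial's balls are drawn independently with the jar's
#' rare-ball probability, and the trial order is shuffled. Responses are left
#' empty.
#'
#' @param block A [block_config()].
#' @param seed Optional integer; when given the trial list is reproducible.
#' @param n_trials Number of trials (defaults to the block's); must respect
#'   the divisibility invariant.
#' @return A data frame of trial records with columns \code{subject_id},
#'   \code{block}, \code{trial_index} (0-based), \code{jar}, \code{n},
#'   \code{sample} ("R"/"C" string), \code{rare_count} and \code{response}
#'   (\code{NA}).
#' @export
sample_block_trials <- function(block, seed = NULL, n_trials = block$n_trials) {
  if (!is.null(seed)) set.seed(seed)
  lens <- block$sample_lengths
  if (n_trials %% (2L * length(lens)) != 0L)
    stop("n_trials must be divisible by 2 * number of sample lengths", call. = FALSE)
  per_cell <- n_trials %/% (2L * length(lens))
  design <- expand.grid(jar = c("high", "low"), n = lens,
                        rep = seq_len(per_cell), stringsAsFactors = FALSE)
  design <- design[sample.int(nrow(design)), , drop = FALSE]
  h <- ifelse(design$jar == "high", block$h_plus, block$h_minus)
  samples <- vapply(seq_len(nrow(design)), function(i) {
    balls <- stats::rbinom(design$n[i], 1L, h[i])
    paste(ifelse(balls == 1L, "R", "C"), collapse = "")
  }, character(1))
  data.frame(subject_id = NA_character_,
             block = block$name,
             trial_index = seq_len(nrow(design)) - 1L,
             jar = design$jar,
             n = design$n,
             sample = samples,
             rare_count = vapply(samples, function(s)
               sum(strsplit(s, "")[[1]] == "R"), integer(1), USE.NAMES = FALSE),
             response = NA_character_,
             stringsAsFactors = FALSE)
}

#' Convert between ball-sample encodings
#'
#' Trial tables store a sample as a string of "R" (rare) and "C" (common)
#' characters; model code works with +1/-1 vectors.
#'
#' @param s A sample string such as "RCCRC".
#' @return \code{sample_to_signs}: integer vector of +1/-1.
#' @export
sample_to_signs <- function(s) {
  stopifnot(length(s) == 1L)
  if (nchar(s) == 0L) return(integer(0))
  ch <- strsplit(s, "")[[1]]
  if (!all(ch %in% c("R", "C"))) stop("sample string may contain only R and C",
                                      call. = FALSE)
  ifelse(ch == "R", 1L, -1L)
}

#' @rdname sample_to_signs
#' @param signs Integer vector of +1/-1.
#' @export
signs_to_sample <- function(signs) {
  paste(ifelse(signs == 1L, "R", "C"), collapse = "")
}
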