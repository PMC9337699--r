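#' Define a block of the jar-discrimination task
#'
#' A block is a task condition: two jars ("high" and "low") that differ in
#' their fraction of rare-coloured balls, a number of trials, and the set of
#' sample lengths shown to the observer. On each trial a jar is chosen with
#' probability \code{prior_high} and \code{n} balls are drawn from it with
#' replacement; the observer reports which jar produced the sample.
#'
#' A block is \emph{symmetric} when \code{h_plus == 1 - h_minus} (the two ball
#' colours carry evidence of equal magnitude) and \emph{asymmetric} when
#' \code{h_plus + h_minus < 1}, in which case rare balls carry more evidence
#' per observation than common balls.
#'
#' @param name Short label for the block (e.g. "HA").
#' @param h_plus Rare-ball fraction of the high jar, in (0, 1].
#' @param h_minus Rare-ball fraction of the low jar, in (0, 1); must be
#'   strictly smaller than \code{h_plus}.
#' @param n_trials Number of trials in the block; must be divisible by
#'   \code{2 * length(sample_lengths)} so that jar and sample length can be
#'   sampled equally often.
#' @param sample_lengths Integer vector of sample lengths used in the block.
#' @param prior_high Prior probability that the high jar is the source.
#' @return An object of class \code{block_config}.
#' @seealso [study_blocks()] for the five conditions of the study design.
#' @export
#' @examples
#' ha <- block_config("HA", 0.2, 0.1)
#' is_symmetric(ha)
#' rho_io(ha)
block_config <- function(name, h_plus, h_minus, n_trials = 42L,
                         sample_lengths = c(2L, 5L, 10L), prior_high = 0.5) {
  stopifnot(is.character(name), length(name) == 1L,
            length(h_plus) == 1L, length(h_minus) == 1L)
  if (!(h_minus > 0 && h_plus > h_minus && h_plus <= 1))
    stop("block requires 0 < h_minus < h_plus <= 1", call. = FALSE)
  if (prior_high <= 0 || prior_high >= 1)
    stop("prior_high must lie in (0, 1)", call. = FALSE)
  n_trials <- as.integer(n_trials)
  sample_lengths <- sort(unique(as.integer(sample_lengths)))
  if (any(sample_lengths < 1L)) stop("sample lengths must be >= 1", call. = FALSE)
  if (n_trials %% (2L * length(sample_lengths)) != 0L)
    stop("n_trials must be divisible by 2 * number of sample lengths ",
         "(equal sampling of jar x length)", call. = FALSE)
  structure(list(name = name, h_plus = h_plus, h_minus = h_minus,
                 n_trials = n_trials, sample_lengths = sample_lengths,
                 prior_high = prior_high),
            class = "block_config")
}

#' @export
print.block_config <- function(x, ...) {
  cat(sprintf("<block %s> h+ = %.3g, h- = %.3g (%s), %d trials, lengths {%s}\n",
              x$name, x$h_plus, x$h_minus,
              if (is_symmetric(x)) "symmetric" else "asymmetric",
              x$n_trials, paste(x$sample_lengths, collapse = ",")))
  invisible(x)
}

#' The five block configurations of the study design
#'
#' Control (0.9/0.1, 60 trials: 24 pre-test plus 3 x 12 interspersed),
#' Hard Asymmetric (0.2/0.1), Hard Symmetric (0.55/0.45),
#' Easy Asymmetric (0.4/0.1) and Easy Symmetric (0.7/0.3), each test block
#' with 42 trials equally sampled over jar and sample length {2, 5, 10}.
#'
#' @return Named list of \code{block_config} objects (CT, HA, HS, EA, ES).
#' @export
study_blocks <- function() {
  list(CT = block_config("CT", 0.90, 0.10, n_trials = 60L),
       HA = block_config("HA", 0.20, 0.10),
       HS = block_config("HS", 0.55, 0.45),
       EA = block_config("EA", 0.40, 0.10),
       ES = block_config("ES", 0.70, 0.30))
}

#' @rdname block_config
#' @param block A \code{block_config}.
#' @export
is_symmetric <- function(block) {
  isTRUE(all.equal(block$h_plus, 1 - block$h_minus))
}

#' Ideal observer's rare-ball weight
#'
#' The rare-ball belief weight of the ideal observer after normalizing the
#' common-ball weight to -1:
#' \deqn{\rho_{IO} = \left|\frac{\log(h_+/h_-)}{\log((1-h_+)/(1-h_-))}\right|.}
#' Equals 1 for symmetric blocks and exceeds 1 when evidence is asymmetric.
#'
#' @param block A \code{block_config}.
#' @return Positive scalar.
#' @export
rho_io <- function(block) {
  if (block$h_plus >= 1)
    stop("rare-ball weight undefined for a degenerate jar (h_plus = 1)",
         call. = FALSE)
  abs(log(block$h_plus / block$h_minus) /
        log((1 - block$h_plus) / (1 - block$h_minus)))
}
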