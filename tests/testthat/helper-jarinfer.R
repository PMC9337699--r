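# Shared fixtures: blocks and small simulated subject-block datasets built
# in code at test time.

blocks <- study_blocks()

# brute-force LLR oracle: product of per-ball probabilities
brute_llr <- function(block, sample, z0 = 0) {
  if (length(sample) == 0L) return(z0)
  p_plus <- prod(ifelse(sample == 1, block$h_plus, 1 - block$h_plus))
  p_minus <- prod(ifelse(sample == 1, block$h_minus, 1 - block$h_minus))
  z0 + log(p_plus / p_minus)
}

# simulated trials for one subject-block
sim_subject <- function(block, params, seed, n_trials = block$n_trials) {
  tr <- sample_block_trials(block, seed = seed, n_trials = n_trials)
  simulate_responses(params, tr, block, seed = seed + 1L)
}

# fast trial table without ball strings (for large-sample MI checks)
sim_class_trials <- function(block, params, n_trials, seed) {
  set.seed(seed)
  n <- sample(block$sample_lengths, n_trials, replace = TRUE)
  jar <- sample(c("high", "low"), n_trials, replace = TRUE)
  h <- ifelse(jar == "high", block$h_plus, block$h_minus)
  k <- stats::rbinom(n_trials, n, h)
  tr <- data.frame(subject_id = "S", block = block$name,
                   trial_index = seq_len(n_trials) - 1L, jar = jar, n = n,
                   sample = NA_character_, rare_count = k,
                   response = NA_character_)
  simulate_responses(params, tr, block)
}
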