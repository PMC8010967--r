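# Shared tiny fixtures, built in code.

random_fragment <- function(seed = 1) {
  set.seed(seed)
  chars <- sample(lysgan:::AA_ALPHABET, 17, replace = TRUE)
  chars[9] <- "K"
  paste(chars, collapse = "")
}

# A 17-mer differing from `base` at exactly `k` non-central positions.
mutate_fragment <- function(base, k, seed = 1) {
  set.seed(seed)
  chars <- strsplit(base, "")[[1]]
  pos <- sample(setdiff(1:17, 9), k)
  for (p in pos) chars[p] <- setdiff(lysgan:::AA_ALPHABET, chars[p])[1]
  paste(chars, collapse = "")
}

toy_proteins <- function() {
  c(P1 = "AAAAAAAAAAAKAAAAAAAAAAAAA",   # length 25, K at 12
    P2 = "AAAAKAAAAAAAAAAAAAAA",        # K at 5: only 4 upstream
    P3 = "AKA")
}

small_fixture <- function(counts = c(A = 40, B = 40, C = 40),
                          motif_strength = 0.9, seed = 5) {
  fx <- generate_fixture(fixture_spec(counts = counts,
                                      motif_strength = motif_strength,
                                      seed = seed))
  frags <- extract_fragments(fx$proteins, fx$sites)
  ds <- filter_classes(merge_labels(frags), min_count = 5)
  list(fixture = fx, dataset = ds,
       data = list(dataset = ds, structure = fx$structure))
}

toy_gaussians <- function(n = 150, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n * 2, mean = 3), ncol = 2),
             matrix(stats::rnorm(n * 2, mean = -3), ncol = 2))
  list(X = X, labels = factor(rep(c("a", "b"), each = n)))
}

small_gan_config <- function(iterations = 300, seed = 11) {
  gan_config(iterations = iterations, gen_hidden = c(32, 32),
             critic_hidden = c(32, 32), noise_dim = 8, batch_size = 32,
             seed = seed)
}
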