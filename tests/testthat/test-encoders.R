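BLOCK_DIMS <- c(AAindex = 238, CKSAAP = 1200, PWM = 17, ReducedAlphabet = 136,
                FoldAmyloid = 17, BE = 340, "PC-PseAAC" = 36, "SC-PseAAC" = 52,
                Structure = 323)

test_that("each scheme emits its closed-form dimension and tags cover columns", {
  fx <- small_fixture(counts = c(A = 10, B = 10), seed = 41)
  fr <- fx$dataset$fragments
  pwm <- fit_pwm(fr$sequence)
  s <- fr$sequence[1]
  blocks <- list(encode_aaindex(s), encode_cksaap(s), encode_pwm(s, pwm),
                 encode_reduced_alphabet(s), encode_foldamyloid(s),
                 encode_binary(s), encode_pc_pseaac(s), encode_sc_pseaac(s),
                 encode_structure(fr$protein_id[1], fr$site[1], fx$fixture$structure))
  for (b in blocks) {
    expect_equal(length(b$values), unname(BLOCK_DIMS[b$scheme]), info = b$scheme)
    expect_equal(length(b$tags), length(b$values), info = b$scheme)
  }
  full <- encode_all(s, pwm, fr$protein_id[1], fr$site[1], fx$fixture$structure)
  expect_equal(length(full$values), 2359)
  expect_equal(nrow(full$provenance), 2359)
  expect_equal(unclass(table(full$provenance$scheme))[names(BLOCK_DIMS)],
               BLOCK_DIMS, ignore_attr = TRUE)
  no_struct <- encode_all(s, pwm)
  expect_equal(length(no_struct$values), 2359 - 323)
})

test_that("AAindex block is position-major and homopolymer blocks repeat", {
  s <- strrep("A", 17)
  b <- encode_aaindex(s)
  m <- matrix(b$values, nrow = 14)
  expect_true(all(apply(m, 1, function(r) all(r == r[1]))))
  # first 14 entries are residue 1's property values
  props <- aaindex_properties()
  expect_equal(b$values[1:14], unname(props["A", ]))
  expect_error(encode_aaindex("AAAAAAAAXAAAAAAAA"), "non-canonical")
})

test_that("CKSAAP counts k-spaced pairs and normalises per gap", {
  s <- paste0(strrep("A", 8), "K", strrep("A", 8))
  b <- encode_cksaap(s)
  k0 <- b$values[1:400]; k1 <- b$values[401:800]; k2 <- b$values[801:1200]
  tag0 <- b$tags[1:400]
  expect_equal(k0[tag0 == "AA"], 14 / 16)
  expect_equal(k0[tag0 == "AK"], 1 / 16)
  expect_equal(k0[tag0 == "KA"], 1 / 16)
  expect_equal(k1[b$tags[401:800] == "A*A"], 13 / 15)
  # each k-block sums to 1
  expect_equal(sum(k0), 1)
  expect_equal(sum(k1), 1)
  expect_equal(sum(k2), 1)
  expect_error(encode_cksaap("AKA", k_set = 2), "k must be")
})

test_that("PWM frequencies fit on training fragments and bound encodings", {
  f1 <- random_fragment(51)
  # identical training set: fragment encodes to all ones
  pwm1 <- fit_pwm(rep(f1, 5))
  expect_equal(encode_pwm(f1, pwm1)$values, rep(1, 17))
  # two fragments differing at every non-central position: 0.5 everywhere
  chars <- strsplit(f1, "")[[1]]
  f2 <- vapply(seq_along(chars), function(i)
    if (i == 9) "K" else setdiff(lysgan:::AA_ALPHABET, chars[i])[1], character(1))
  f2 <- paste(f2, collapse = "")
  pwm2 <- fit_pwm(c(f1, f2))
  expect_equal(encode_pwm(f1, pwm2)$values,
               c(rep(0.5, 8), 1, rep(0.5, 8)))
  # columns sum to 1; encodings lie in [0, 1]
  seqs <- vapply(1:20, function(i) random_fragment(60 + i), character(1))
  pwm <- fit_pwm(seqs)
  expect_equal(colSums(pwm), rep(1, 17), ignore_attr = TRUE)
  v <- encode_pwm(seqs[3], pwm)$values
  expect_true(all(v >= 0 & v <= 1))
  expect_error(fit_pwm(character(0)), "empty")
})

test_that("reduced alphabet and binary encodings are one-hot per residue", {
  s <- random_fragment(71)
  ra <- encode_reduced_alphabet(s)
  be <- encode_binary(s)
  expect_true(all(ra$values %in% c(0, 1)))
  expect_equal(sum(ra$values), 17)
  expect_true(all(be$values %in% c(0, 1)))
  expect_equal(sum(be$values), 17)
  # D maps to the acid group; K and R share the basic group
  d <- encode_reduced_alphabet(paste0("D", substr(s, 2, 17)))
  expect_equal(d$values[1:8], c(1, 0, 0, 0, 0, 0, 0, 0))
  k_pos <- which(matrix(encode_reduced_alphabet(strrep("K", 17))$values, 8)[, 1] == 1)
  r_pos <- which(matrix(encode_reduced_alphabet(strrep("R", 17))$values, 8)[, 1] == 1)
  expect_equal(k_pos, r_pos)
  # BE: alanine sets the first coordinate; one substitution flips 2 coords
  a_first <- encode_binary(paste0("A", substr(s, 2, 17)))
  expect_equal(a_first$values[1], 1)
  s2 <- mutate_fragment(s, 1, seed = 8)
  expect_equal(sum(encode_binary(s)$values != encode_binary(s2)$values), 2)
})

test_that("packing-density profile averages a centred window", {
  s <- strrep("A", 17)
  b <- encode_foldamyloid(s)
  expect_equal(length(b$values), 17)
  expect_true(all(abs(b$values - b$values[1]) < 1e-12))
  # window 1 reproduces the raw scale
  s3 <- random_fragment(81)
  raw <- encode_foldamyloid(s3, window = 1)
  expect_equal(raw$values, unname(foldamyloid_scale()[strsplit(s3, "")[[1]]]))
  bin <- encode_foldamyloid(s3, mode = "binary")
  expect_true(all(bin$values %in% c(0, 1)))
})

test_that("PseAAC vectors are unit-sum with the stated dimensions", {
  s <- random_fragment(91)
  pc <- encode_pc_pseaac(s)
  sc <- encode_sc_pseaac(s)
  expect_equal(length(pc$values), 36)  # 20 + (L - 1)
  expect_equal(length(sc$values), 52)  # 20 + 2(L - 1)
  expect_equal(sum(pc$values), 1)
  expect_equal(sum(sc$values), 1)
  # homopolymer: zero correlation factors, unit mass on one composition entry
  hp <- encode_pc_pseaac(strrep("A", 17))
  expect_equal(hp$values[1], 1)
  expect_equal(hp$values[21:36], rep(0, 16))
  # omega = 0 recovers pure composition
  sc0 <- encode_sc_pseaac(s, w = 0)
  expect_equal(sc0$values[21:52], rep(0, 32))
  expect_equal(sum(sc0$values[1:20]), 1)
  expect_error(encode_pc_pseaac(s, lambda = 17), "lambda")
})

test_that("structural block concatenates 19 channels per residue in order", {
  fx <- small_fixture(counts = c(A = 5, B = 5), seed = 43)
  fr <- fx$dataset$fragments
  b <- encode_structure(fr$protein_id[1], fr$site[1], fx$fixture$structure)
  expect_equal(length(b$values), 323)
  expect_equal(b$tags[1], "ASA@-8")
  expect_equal(b$tags[19], "CN@-8")
  # missing residue rows error with the protein named
  expect_error(encode_structure("NOPE", 19, fx$fixture$structure), "NOPE")
  # all-zero rows give a zero vector
  zero_tab <- fx$fixture$structure
  zero_tab[, lysgan:::STRUCT_CHANNELS] <- 0
  bz <- encode_structure(fr$protein_id[1], fr$site[1], zero_tab)
  expect_equal(bz$values, rep(0, 323))
})

test_that("encoding is a pure function of fragment and fitted context", {
  fx <- small_fixture(counts = c(A = 8, B = 8), seed = 44)
  fr <- fx$dataset$fragments
  pwm <- fit_pwm(fr$sequence)
  v1 <- encode_all(fr$sequence[2], pwm, fr$protein_id[2], fr$site[2],
                   fx$fixture$structure)$values
  v2 <- encode_all(fr$sequence[2], pwm, fr$protein_id[2], fr$site[2],
                   fx$fixture$structure)$values
  expect_identical(v1, v2)
})
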