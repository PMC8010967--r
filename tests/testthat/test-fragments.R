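test_that("window extraction covers the annotated lysine and drops short flanks", {
  proteins <- toy_proteins()
  sites <- data.frame(protein_id = c("P1", "P2"), position = c(12, 5),
                      modification = "Ace")
  frags <- extract_fragments(proteins, sites, xi = 8)
  # K at position 12 in a 25-mer: window covers 4..20, length 17
  expect_equal(nrow(frags), 1)
  expect_equal(frags$sequence, substr(proteins[["P1"]], 4, 20))
  expect_equal(nchar(frags$sequence), 17)
  expect_equal(substr(frags$sequence, 9, 9), "K")
  # K at position 5 has only 4 upstream residues: dropped, no padding
  expect_false("P2" %in% frags$protein_id)
})

test_that("minimal window, bad annotations and non-canonical residues are handled", {
  proteins <- c(toy_proteins(), PX = "AAAAAAAAAAAXAAAKAAAAAAAAA")
  sites <- data.frame(protein_id = c("P3", "P1", "P9", "PX"),
                      position = c(2, 13, 4, 16),
                      modification = "Ubiq")
  expect_warning(expect_warning(
    frags <- extract_fragments(proteins, sites, xi = 1),
    "not lysine"), "unknown protein")
  # xi = 1 on "AKA" gives the whole protein
  expect_equal(frags$sequence[frags$protein_id == "P3"], "AKA")
  # P1 position 13 is not K; P9 unknown; both rejected
  expect_false(any(frags$protein_id %in% c("P1", "P9")))
  # window with an X is dropped with a warning
  sites_x <- data.frame(protein_id = "PX", position = 16, modification = "Ace")
  expect_warning(fx <- extract_fragments(proteins, sites_x, xi = 8),
                 "non-canonical")
  expect_equal(nrow(fx), 0)
})

test_that("pairwise identity counts matching positions", {
  a <- strrep("A", 17)
  expect_equal(pairwise_identity(a, a), 1)
  b <- paste0(strrep("C", 8), "K", strrep("C", 8))
  k_only <- paste0(strrep("A", 8), "K", strrep("A", 8))
  expect_equal(pairwise_identity(b, k_only), 1 / 17)
  base <- random_fragment(2)
  seven <- mutate_fragment(base, 10, seed = 3)  # 17 - 10 = 7 agreements
  expect_equal(pairwise_identity(base, seven), 7 / 17)
  expect_error(pairwise_identity("AKA", a), "length")
})

test_that("redundancy removal is a greedy keep-first scan at the 40% bound", {
  base <- random_fragment(4)
  at7 <- mutate_fragment(base, 10, seed = 5)   # identity 7/17 >= 0.40: dropped
  at6 <- mutate_fragment(base, 11, seed = 6)   # identity 6/17 < 0.40: kept
  frags <- data.frame(protein_id = "P", site = 9,
                      sequence = c(base, base, at7, at6))
  kept <- remove_redundant(frags, threshold = 0.40)
  expect_equal(kept$sequence, c(base, at6))
  # idempotent
  expect_equal(remove_redundant(kept, threshold = 0.40), kept)
  # empty input passes through
  expect_equal(nrow(remove_redundant(frags[0, ], 0.4)), 0)
})

test_that("label merging unions modification names over identical fragments", {
  f <- random_fragment(8)
  frags <- data.frame(protein_id = c("P1", "P1", "P1", "P2"),
                      site = c(20, 20, 20, 30),
                      sequence = c(f, f, f, random_fragment(9)),
                      modification = c("Ubiq", "Ace", "Meth", "Succ"))
  merged <- merge_labels(frags)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$labels[[1]], c("Ace", "Meth", "Ubiq"))
  expect_equal(merged$labels[[2]], "Succ")
})

test_that("class filtering keeps singleton labels of large-enough classes", {
  set.seed(10)
  seqs <- vapply(1:30, function(i) random_fragment(100 + i), character(1))
  frags <- data.frame(protein_id = paste0("P", 1:30), site = 9,
                      sequence = seqs)
  frags$labels <- c(rep(list("Big"), 12), rep(list("Small"), 11),
                    rep(list(c("Big", "Small")), 7))
  ds <- filter_classes(frags, min_count = 12)
  # class with 11 singleton records is below the bound; multi-label excluded
  expect_equal(ds$classes, "Big")
  expect_equal(ds$counts, 12L)
  expect_true(all(ds$counts >= 12))
  expect_equal(sum(ds$counts), nrow(ds$fragments))
  expect_error(filter_classes(frags, min_count = 1000), "no class")
})

test_that("every emitted fragment is a 17-mer with a central lysine", {
  fx <- small_fixture(counts = c(A = 15, B = 15), seed = 31)
  fr <- fx$dataset$fragments
  expect_true(all(nchar(fr$sequence) == 17))
  expect_true(all(substr(fr$sequence, 9, 9) == "K"))
})

test_that("dataset TSV writer and reader round-trip", {
  fx <- small_fixture(counts = c(A = 10, B = 10), seed = 32)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(fx$dataset, path)
  back <- read_dataset(path)
  expect_equal(back$fragments$sequence, fx$dataset$fragments$sequence)
  expect_equal(as.integer(back$fragments$class),
               as.integer(fx$dataset$fragments$class))
})
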