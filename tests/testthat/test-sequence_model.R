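test_that("region masks match their structural definitions", {
  expect_identical(build_region_mask("bw4", 183)$positions,
                   c(76L, 77L, 80L, 81L, 82L, 83L))
  hel <- build_region_mask("helices", 183)$positions
  expect_length(hel, 64)
  expect_identical(hel, sort(unique(c(57:85, 141:175))))
  loops <- c(16:19, 39:44, 49:56, 86:90, 106:107, 128:131, 137:140,
             151:152, 176:179, 180:183)
  expect_length(intersect(build_region_mask("no_loops", 183)$positions, loops), 0)
  expect_identical(build_region_mask("all", 183)$positions, 1:183)
  # clipping to short alignments
  expect_identical(build_region_mask("bw4", 80)$positions, c(76L, 77L, 80L))
  expect_error(build_region_mask("bw5", 183), "unknown mask")
})

test_that("one-hot encoding follows the R1/A2 rule with invariant removal", {
  # position 2 invariant -> removed; only features (1,R), (1,S)
  enc <- one_hot_encode(tiny_panel(c("RA", "SA")),
                        build_region_mask("all", 2))
  expect_identical(enc$feature_labels$label, c("R1", "S1"))
  expect_equal(unname(enc$matrix[1, ]), c(1, 0))
  expect_equal(unname(enc$matrix[2, ]), c(0, 1))

  enc3 <- one_hot_encode(tiny_panel(c("RA", "RG", "SG")),
                         build_region_mask("all", 2))
  expect_identical(enc3$feature_labels$label, c("R1", "S1", "A2", "G2"))
  expect_equal(unname(enc3$matrix),
               rbind(c(1, 0, 1, 0), c(1, 0, 0, 1), c(0, 1, 0, 1)))

  # degenerate single-allele panel: every position invariant
  expect_equal(ncol(one_hot_encode(tiny_panel("RAK"))$matrix), 0)
  expect_error(allele_panel(character(0), character(0)), "empty")
  expect_error(allele_panel(c("a", "b"), c("RA", "RAK")), "length")
})

test_that("encoding satisfies the partition and order invariants", {
  panel <- generate_panel(30, seed = 7)
  # plant an unknown residue
  seqs <- panel$sequence
  substr(seqs[3], 62, 62) <- "*"
  panel2 <- allele_panel(panel$name, seqs, panel$locus)
  enc <- one_hot_encode(panel2)
  for (p in unique(enc$feature_labels$position)) {
    cols <- enc$feature_labels$position == p
    sums <- rowSums(enc$matrix[, cols, drop = FALSE])
    known <- substr(panel2$sequence, p, p) != "*"
    expect_equal(unname(sums), as.numeric(known))
  }
  # permutation of the panel permutes rows, identical feature set
  ord <- rev(seq_len(nrow(panel2)))
  encp <- one_hot_encode(allele_panel(panel2$name[ord], panel2$sequence[ord],
                                      panel2$locus[ord]))
  expect_identical(encp$feature_labels, enc$feature_labels)
  expect_equal(encp$matrix[panel2$name, ], enc$matrix)
})

test_that("hamming distance matches a brute-force oracle and the triangle inequality", {
  expect_equal(hamming_distance("RAK", "RAK"), 0)
  expect_equal(hamming_distance("RAK", "RGK"), 1)
  expect_error(hamming_distance("RA", "RAK"), "aligned")
  set.seed(5)
  rand_seq <- function() paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      50, replace = TRUE), collapse = "")
  for (i in 1:20) {
    a <- rand_seq(); b <- rand_seq(); c <- rand_seq()
    oracle <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_identical(hamming_distance(a, b), oracle)
    expect_identical(hamming_distance(a, b), hamming_distance(b, a))
    expect_lte(hamming_distance(a, c),
               hamming_distance(a, b) + hamming_distance(b, c))
  }
  hm <- hamming_matrix(generate_panel(8, seed = 2))
  expect_true(isSymmetric(hm))
  expect_true(all(diag(hm) == 0))
})

test_that("FASTA and TSV panel io round-trips", {
  panel <- generate_panel(10, seed = 3)
  fa <- tempfile(fileext = ".fasta")
  write_allele_fasta(panel, fa)
  back <- read_allele_fasta(fa)
  expect_identical(back$name, panel$name)
  expect_identical(back$sequence, panel$sequence)

  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(allele = panel$name, locus = panel$locus,
                                sequence = panel$sequence),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_allele_tsv(tsv)
  expect_identical(back2$sequence, panel$sequence)
  expect_identical(back2$locus, panel$locus)
})

test_that("80/83 motif lookup maps the classical epitopes", {
  tpl <- strrep("A", 183)
  put <- function(s, p, r) { substr(s, p, p) <- r; s }
  seqs <- c(put(put(tpl, 80, "I"), 83, "R"),   # Bw4
            put(put(tpl, 80, "T"), 83, "R"),   # Bw4
            put(put(tpl, 80, "N"), 83, "G"),   # C1
            put(put(tpl, 80, "K"), 83, "G"),   # C2
            put(put(tpl, 80, "T"), 83, "G"))   # bulk HLA-A
  m <- motif_80_83(tiny_panel(seqs))
  expect_identical(m$epitope, c("Bw4", "Bw4", "C1", "C2", NA))
  expect_identical(m$combo[1], "I80/R83")
  # rare-combination cutoff
  m2 <- motif_80_83(tiny_panel(seqs), min_count = 2)
  expect_true(all(is.na(m2$combo)))
})
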