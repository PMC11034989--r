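# Gapped pattern graph construction: counting, normalization, binning.

test_that("k-mer indexing is a bijection with A<C<G<T lexicographic order", {
  for (k in 1:3) {
    km <- all_kmers(k)
    expect_equal(length(km), 4^k)
    expect_equal(km, sort(km))                      # lexicographic
    expect_equal(kmer_to_index(km), 0:(4^k - 1))    # index round trip
    expect_equal(index_to_kmer(kmer_to_index(km), k), km)
  }
  expect_equal(kmer_to_index(c("A", "C", "G", "T")), 0:3)
  expect_true(is.na(kmer_to_index("AN")))
})

test_that("pattern graph of ATGATGC matches the worked example", {
  cnt <- count_kmers("ATGATGC", 3)
  expect_equal(sum(cnt > 0), 4)
  expect_equal(cnt[["ATG"]], 2)
  expect_equal(cnt[["TGA"]], 1)
  expect_equal(cnt[["GAT"]], 1)
  expect_equal(cnt[["TGC"]], 1)

  arr <- count_gapped_pairs("ATGATGC", 3, 0)
  expect_equal(sum(arr > 0), 2)
  expect_equal(arr["ATG", "ATG", "0"], 1)
  expect_equal(arr["TGA", "TGC", "0"], 1)

  g <- build_gpg("ATGATGC", k = 3, d = 0, normalize = FALSE)
  expect_equal(sum(g$vertex > 0), 4)
  expect_equal(sum(g$pair > 0), 2)

  # normalized vertex count: 2 occurrences / (L - k + 1) = 2/5
  gn <- build_gpg("ATGATGC", k = 3, d = 0)
  expect_equal(gn$vertex[["ATG"]], 0.4)
})

test_that("counting edge cases behave as documented", {
  expect_equal(count_kmers("AAAA", 3)[["AAA"]], 2)
  expect_equal(sum(count_kmers("AAAA", 3)), 2)
  expect_equal(sum(count_kmers("", 3)), 0)         # empty -> all zero
  expect_equal(sum(count_kmers("AT", 3)), 0)       # L < k -> all zero
  expect_equal(sum(count_gapped_pairs("AAAA", 3, 2)), 0)  # no window fits
  expect_error(count_kmers("ACGT", 0), "positive integer")
  expect_error(count_gapped_pairs("ACGT", 3, -1), "non-negative")
  expect_error(count_kmers("ACGT", 9), "not supported")
})

test_that("windows overlapping ambiguity characters are skipped", {
  expect_equal(sum(count_kmers("ACGNACG", 3)), 2)  # only the two clean ACGs
  expect_equal(count_kmers("ACGNACG", 3)[["ACG"]], 2)
  # the whole s.x.t span must be clean: an N in the spacer kills the window
  expect_equal(sum(count_gapped_pairs("ACGNACG", 3, 1)), 0)
  arr <- count_gapped_pairs("ACGTACG", 3, 1)
  expect_equal(arr["ACG", "ACG", "1"], 1)          # spacer T, gap 1
  # lower-case input counts the same as upper-case
  expect_equal(count_kmers("acgtacgt", 2), count_kmers("ACGTACGT", 2))
})

test_that("counts match brute-force enumeration across k, d and lengths", {
  set.seed(401)
  for (k in 1:3) for (d in 0:2) {
    for (rep in 1:12) {
      L <- sample(50:500, 1)
      alpha <- if (rep %% 4 == 0) c("A", "C", "G", "T", "N")
               else c("A", "C", "G", "T")
      s <- rand_dna(L, alpha)
      expect_equal(unname(count_kmers(s, k)), unname(oracle_count_kmers(s, k)))
      expect_equal(unname(count_gapped_pairs(s, k, d)),
                   unname(oracle_count_pairs(s, k, d)))
    }
  }
})

test_that("absolute counts satisfy the conservation identities", {
  set.seed(402)
  for (L in c(7, 30, 211)) {
    s <- rand_dna(L)
    k <- 3; d <- 2
    g <- build_gpg(s, k, d, normalize = FALSE)
    expect_equal(sum(g$vertex), L - k + 1)
    for (gap in 0:d)
      expect_equal(sum(g$pair[, gap + 1]), max(0, L - 2 * k - gap + 1))
  }
})

test_that("normalization divides by window counts and conserves unit mass", {
  set.seed(403)
  s <- rand_dna(300)
  g <- build_gpg(s, 3, 2)
  expect_equal(sum(g$vertex), 1, tolerance = 1e-12)
  for (gap in 0:2)
    expect_equal(sum(g$pair[, gap + 1]), 1, tolerance = 1e-12)
  # explicit normalize op on an absolute graph
  ga <- build_gpg(s, 3, 2, normalize = FALSE)
  gn <- normalize_gpg(ga)
  expect_equal(gn$vertex, g$vertex)
  expect_equal(gn$pair, g$pair)
  # all-zero features stay zero and the mode flag flips
  gz <- normalize_gpg(build_gpg("NNNNNNNNNN", 3, 2, normalize = FALSE))
  expect_true(all(gz$vertex == 0) && all(gz$pair == 0))
  expect_true(gz$normalized)
})

test_that("re-normalizing is flagged, not silently applied", {
  g <- build_gpg("ACGTACGTAC", 3, 1)
  expect_error(normalize_gpg(g), "already normalized")
})

test_that("gap binning validates its partition and conserves mass", {
  expect_equal(gap_binning(2)$B, 3)                 # identity default
  b <- gap_binning(4, list(0:2, 3:4))
  expect_equal(b$B, 2)
  expect_error(gap_binning(2, list(0, 2)), "cover exactly")
  expect_error(gap_binning(2, list(0:2, 1:2)), "cover exactly")
  expect_error(gap_binning(3, list(c(0, 2), c(1, 3))), "contiguous")

  set.seed(404)
  arr <- count_gapped_pairs(rand_dna(200), 2, 4)
  binned <- bin_gaps(arr, b)
  expect_equal(dim(binned)[3], 2)
  expect_equal(sum(binned), sum(arr))               # mass conserved
  expect_equal(binned[, , 1], arr[, , 1] + arr[, , 2] + arr[, , 3],
               ignore_attr = TRUE)
  expect_identical(bin_gaps(arr, gap_binning(4)), arr)   # identity no-op
  expect_error(bin_gaps(arr, gap_binning(2)), "tensor has gaps")
})

test_that("binned normalized features are sums of per-gap frequencies", {
  set.seed(405)
  s <- rand_dna(240)
  ident <- build_gpg(s, 2, 2)
  coarse <- build_gpg(s, 2, 2, binning = gap_binning(2, list(0, 1:2)))
  expect_equal(coarse$pair[, 1], ident$pair[, 1])
  expect_equal(coarse$pair[, 2], ident$pair[, 2] + ident$pair[, 3])
})

test_that("graph construction is deterministic and d=0 matches the pattern graph", {
  set.seed(406)
  s <- rand_dna(150)
  expect_identical(build_gpg(s, 3, 2), build_gpg(s, 3, 2))
  g0 <- build_gpg(s, 3, 0, normalize = FALSE)
  g2 <- build_gpg(s, 3, 2, normalize = FALSE)
  expect_equal(g0$pair[, 1], g2$pair[, 1])   # gap-0 edges coincide
})

test_that("empty input yields the all-zero graph of full shape", {
  g <- build_gpg("", 3, 2, normalize = FALSE)
  expect_equal(length(g$vertex), 64)
  expect_equal(dim(g$pair), c(4096, 3))
  expect_true(all(g$vertex == 0) && all(g$pair == 0))
})

test_that("long-format export lists exactly the nonzero entries", {
  df <- as.data.frame(build_gpg("ATGATGC", 3, 0, normalize = FALSE))
  expect_equal(sum(df$type == "vertex"), 4)
  expect_equal(sum(df$type == "edge"), 2)
  edges <- df[df$type == "edge", ]
  expect_setequal(paste(edges$kmer_s, edges$kmer_t), c("ATG ATG", "TGA TGC"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gpg_tsv(build_gpg("ATGATGC", 3, 0), path)
  back <- read.delim(path)
  expect_equal(nrow(back), 6)
})
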