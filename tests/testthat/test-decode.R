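# Deconvolution of selection reads under the reprogrammed genetic code.

test_that("a reverse-translated winner decodes to its reported peptide", {
  set.seed(101)
  dna <- reverse_translate("yLD2HYSSKLY")
  rec <- decode_read(dna)
  expect_identical(rec$peptide, "yLD2HYSSKLYCGSGSGS")
  expect_true(rec$has_warhead)
  expect_true(rec$valid)
  expect_identical(rec$random_region_length, 10L)
  expect_false(rec$linker_lost)
})

test_that("warhead flag reflects internal Met codons only", {
  set.seed(102)
  no_wh <- reverse_translate("yLDAHYSSKLY")   # no internal warhead
  rec <- decode_read(no_wh)
  expect_false(rec$has_warhead)
  expect_true(rec$valid)
  # the initiator ATG itself never counts as a warhead
  expect_identical(substr(no_wh, 1, 3), "ATG")
})

test_that("flags flip under targeted single-codon mutations", {
  set.seed(103)
  dna <- reverse_translate("yVYS2KEWKY")
  rec <- decode_read(dna)
  expect_true(rec$valid)
  # mutate the first linker codon (TGT, Cys) into GCT (Ala)
  lk_start <- 3 + 3 * 9 + 1
  mut <- paste0(substr(dna, 1, lk_start - 1), "GCT",
                substr(dna, lk_start + 3, nchar(dna)))
  rec2 <- decode_read(mut)
  expect_true(rec2$linker_lost)
  expect_false(rec2$valid)
  # mutate a random-region codon to amber TAG
  mut3 <- paste0(substr(dna, 1, 3), "TAG", substr(dna, 7, nchar(dna)))
  rec3 <- decode_read(mut3)
  expect_true(rec3$premature_stop)
  expect_false(rec3$valid)
  # knock the warhead codon out (ATG at random-region codon 4 -> GCG)
  wh_start <- 3 + 3 * 3 + 1
  expect_identical(substr(dna, wh_start, wh_start + 2), "ATG")
  mut4 <- paste0(substr(dna, 1, wh_start - 1), "GCG",
                 substr(dna, wh_start + 3, nchar(dna)))
  expect_false(decode_read(mut4)$has_warhead)
})

test_that("reads without the expected initiator are invalid records, not errors", {
  rec <- decode_read("CCCTTTAAAGGGCCCTTTAAAGGGCCCTTTAAAGGGCCCTTTAAA")
  expect_false(rec$valid)
  expect_true(is.na(rec$peptide))
})

test_that("NNK validation checks the third base of every codon", {
  expect_true(validate_nnk("ATGCTG"))
  expect_false(validate_nnk("ATACTG"))
  expect_error(validate_nnk("ATGC"), "divisible")
  # sampled NNK regions always validate
  set.seed(104)
  lib <- sample_library(n = 200, seed = 104)
  regions <- substr(lib, 4, nchar(lib) - 21)
  expect_true(all(validate_nnk(regions)))
})

test_that("decode/encode round trip holds over random NNK-encodable peptides of every length", {
  # the reprogrammed alphabet: 19 canonical residues (Met codons encode
  # the warhead, so 'M' cannot appear) plus the warhead symbol
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), c("*", "M"))
  set.seed(105)
  for (len in 6:10) {
    peps <- vapply(1:40, function(i)
      paste0(c("y", sample(c(aas, "2"), len, replace = TRUE)),
             collapse = ""), character(1L))
    dna <- reverse_translate(peps)
    rec <- decode_reads(dna)
    expect_identical(rec$peptide, paste0(peps, "CGSGSGS"))
    expect_identical(rec$random_region_length, rep(len, 40L))
  }
})

test_that("round tabulation counts peptides exactly with deterministic ranking", {
  set.seed(106)
  a <- reverse_translate("yLD2HYSSKLY", deterministic = TRUE)
  b <- reverse_translate("yWY2NWDFNKR", deterministic = TRUE)
  cnt <- tabulate_rounds(list(c(rep(a, 3), b)))
  df <- cnt$rounds[[1L]]
  expect_identical(df$count, c(3L, 1L))
  expect_identical(df$peptide[1L], "yLD2HYSSKLYCGSGSGS")
  expect_identical(df$rank, 1:2)
  expect_equal(sum(df$frequency), 1)
  # tie counts break lexicographically
  cnt2 <- tabulate_rounds(list(c(a, b)))
  expect_identical(cnt2$rounds[[1L]]$peptide,
                   sort(c("yLD2HYSSKLYCGSGSGS", "yWY2NWDFNKRCGSGSGS")))
  # identical inputs give identical tables
  expect_identical(tabulate_rounds(list(c(rep(a, 3), b))), cnt)
})

test_that("warhead-missing fraction is exact read-weighted arithmetic", {
  set.seed(107)
  wh <- reverse_translate("yLD2HYSSKLY", deterministic = TRUE)
  free <- reverse_translate("yLDAHYSSKLY", deterministic = TRUE)
  cnt <- tabulate_rounds(list(c(rep(wh, 7), rep(free, 3))))
  expect_equal(warhead_missing_fraction(cnt, 1), 30)
  expect_equal(warhead_missing_fraction(cnt, 1, weight = "unique"), 50)
  cnt_all <- tabulate_rounds(list(rep(wh, 5)))
  expect_equal(warhead_missing_fraction(cnt_all, 1), 0)
  expect_error(warhead_missing_fraction(cnt, 3), "no such round")
})

test_that("enrichment trajectories normalize per round and smooth zero counts", {
  set.seed(108)
  a <- reverse_translate("yLD2HYSSKLY", deterministic = TRUE)
  b <- reverse_translate("yWY2NWDFNKR", deterministic = TRUE)
  cnt <- tabulate_rounds(list(c(rep(a, 2), rep(b, 8)),
                              c(rep(a, 6), rep(b, 4))))
  pa <- "yLD2HYSSKLYCGSGSGS"
  enr <- enrichment_trajectory(cnt, c(pa, "yABSENTPEPTIDE"))
  ea <- enr[enr$peptide == pa, ]
  expect_equal(ea$frequency, c(0.2, 0.6))
  expect_equal(ea$fold_change[2L], 3)
  absent <- enr[enr$peptide == "yABSENTPEPTIDE", ]
  expect_true(all(absent$frequency == 0))
  # add-one smoothing keeps the fold change finite for zero counts
  expect_true(is.finite(absent$fold_change[2L]))
  # per-round frequencies over all sequences sum to 1
  expect_equal(sum(cnt$rounds[[1L]]$frequency), 1, tolerance = 1e-12)
})

test_that("greedy family clustering equals brute-force connected components", {
  # toy set engineered with chained similarity and an outlier pair
  peps <- c("yAAAAAA", "yAAAAAC", "yAAAACC", "yWWWWWW", "yWWWWWV",
            "yHHHHHH")
  counts <- c(50, 30, 20, 40, 10, 5)
  fam <- cluster_families(peps, counts, max_dist = 2)
  want <- components_oracle(peps, 2)
  expect_true(same_partition(fam$family, want))
  # identical sequences form one family; distant ones split
  expect_identical(length(unique(cluster_families(rep("yAAA", 3))$family)), 1L)
  expect_identical(length(unique(
    cluster_families(c("yAAAAAA", "yWWWWWW"), max_dist = 2)$family)), 2L)
  # randomized sets agree with the oracle too
  set.seed(109)
  for (i in 1:5) {
    rp <- vapply(1:12, function(j) paste0(
      sample(c("A", "C", "D", "W"), 8, replace = TRUE), collapse = ""),
      character(1L))
    fam_i <- cluster_families(rp, max_dist = 2)
    expect_true(same_partition(fam_i$family, components_oracle(rp, 2)))
  }
})

test_that("recovery percentage is exact and guards its domain", {
  expect_equal(recovery_percent(100, 100), 100)
  expect_equal(recovery_percent(0, 50), 0)
  expect_equal(recovery_percent(25, 200), 12.5)
  expect_error(recovery_percent(1, 0), "positive")
})
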