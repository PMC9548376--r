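# Allele classification, heterozygosity census, premature-stop detection.

make_ref <- function(n = 120, seed = 150) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

test_that("identical sequence classifies as wt for any window", {
  ref <- make_ref()
  for (w in c(10L, 20L, 50L)) {
    call <- classify_allele(ref, ref, cut_site = 60, window_bp = w)
    expect_equal(call$class, "wt")
    expect_equal(call$n, 0L)
  }
})

test_that("single-base insertion at the cut site is called insertion(+1)", {
  ref <- make_ref()
  mut <- fuccitrack:::apply_variant(ref, list(type = "insertion", pos = 60,
                                              seq = "C"))
  call <- classify_allele(mut, ref, cut_site = 60)
  expect_equal(call$class, "insertion")
  expect_equal(call$n, 1L)
  expect_lte(abs(call$offset), 3L)   # alignment may slide within a repeat
})

test_that("1-bp deletion 5 bp from the cut site is called deletion(-1) nearby", {
  ref <- "ACGTACGGTACCTGATCGATCGGCTAGCTAAGGCTTACGGATCCGGAACCTTGGAACGT"
  mut <- fuccitrack:::apply_variant(ref, list(type = "deletion", pos = 25,
                                              len = 1))
  call <- classify_allele(mut, ref, cut_site = 30, window_bp = 10)
  expect_equal(call$class, "deletion")
  expect_equal(call$n, 1L)
  expect_lte(abs(call$offset - (-5L)), 2L)
})

test_that("an indel far outside the window classifies as complex", {
  ref <- make_ref(200)
  mut <- fuccitrack:::apply_variant(ref, list(type = "insertion", pos = 10,
                                              seq = "C"))
  call <- classify_allele(mut, ref, cut_site = 150, window_bp = 20)
  expect_equal(call$class, "complex")
  expect_error(classify_allele("", ref, 10), "empty")
})

test_that("allele census matches the exact binomial oracle", {
  calls <- c(replicate(15, list(class = "wt"), simplify = FALSE),
             replicate(19, list(class = "insertion"), simplify = FALSE))
  cen <- allele_census(calls)
  expect_equal(cen$n_wt, 15L)
  expect_equal(cen$n_mut, 19L)
  ref_p <- stats::binom.test(19, 34, 0.5)$p.value
  expect_equal(cen$p_value, ref_p, tolerance = 1e-12)
  expect_gt(cen$p_value, 0.05)
  expect_true(cen$consistent_heterozygous)

  even <- allele_census(c(replicate(17, list(class = "wt"), simplify = FALSE),
                          replicate(17, list(class = "deletion"),
                                    simplify = FALSE)))
  expect_equal(even$p_value, 1)

  all_mut <- allele_census(replicate(34, list(class = "insertion"),
                                     simplify = FALSE))
  expect_equal(all_mut$p_value, 2 * 0.5^34, tolerance = 1e-9)
  expect_false(all_mut$consistent_heterozygous)
})

test_that("census is permutation-invariant and the exact p matches Monte Carlo", {
  calls <- c(replicate(15, list(class = "wt"), simplify = FALSE),
             replicate(19, list(class = "insertion"), simplify = FALSE))
  set.seed(151)
  shuffled <- sample(calls)
  expect_equal(allele_census(shuffled)$p_value, allele_census(calls)$p_value)
  # Monte-Carlo oracle: fraction of Binomial(34, .5) draws no more likely
  # than the observed count
  draws <- stats::rbinom(1e6, 34, 0.5)
  p_mc <- mean(stats::dbinom(draws, 34, 0.5) <=
                 stats::dbinom(19, 34, 0.5) * (1 + 1e-7))
  p_exact <- allele_census(calls)$p_value
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 1e6)
  expect_lt(abs(p_exact - p_mc), 3 * mc_sd)
})

test_that("full fixture pipeline: 34 alleles at the heterozygous composition", {
  ref <- make_ref(150, seed = 152)
  v <- list(type = "insertion", pos = 75, seq = "C")
  set <- simulate_alleles(ref, v, n_wt = 15, n_mut = 19, seed = 153)
  calls <- lapply(as.character(set), classify_allele, ref = ref,
                  cut_site = 75)
  cen <- allele_census(calls)
  expect_equal(cen$n_mut, 19L)
  expect_equal(cen$n_wt, 15L)
  expect_true(cen$consistent_heterozygous)
  ins <- vapply(calls, function(x) x$class == "insertion", logical(1))
  expect_equal(sum(ins), 19L)
})

test_that("a deletion fixture classifies as deletion(-1) throughout", {
  ref <- make_ref(150, seed = 154)
  v <- list(type = "deletion", pos = 75, len = 1)
  set <- simulate_alleles(ref, v, n_wt = 0, n_mut = 10, seed = 155)
  calls <- lapply(as.character(set), classify_allele, ref = ref,
                  cut_site = 75)
  expect_true(all(vapply(calls, function(x)
    x$class == "deletion" && x$n == 1L, logical(1))))
})

test_that("premature stop: immediate stop, no novel stop, and frame handling", {
  #                 1iiii....     codons (frame 0): ATG GCC TAA ...
  edited <- "ATGGCCTAAGGCGGC"
  ref <- "ATGGCCAAAGGCGGC"        # AAA instead of TAA: no stop
  rep <- find_premature_stop(edited, ref, cds_frame_offset = 0, edit_pos = 7)
  expect_true(rep$found)
  expect_equal(rep$distance_bp, 0L)
  expect_equal(rep$codon_index, 3L)

  none <- find_premature_stop(ref, ref, cds_frame_offset = 0, edit_pos = 7)
  expect_false(none$found)
  expect_true(is.na(none$distance_bp))
})

test_that("the +1 frameshift fixture puts its first novel stop 8 bp downstream", {
  # frame 0; insertion of C at position 11 shifts downstream codons; the
  # first novel in-frame stop (TGA) then starts 8 bp after the edit site
  ref    <- "ATGGCTGCAGCACCGCATGACGGTCATGCC"
  edited <- fuccitrack:::apply_variant(ref, list(type = "insertion",
                                                 pos = 10, seq = "C"))
  edit_pos <- 11L                  # the inserted base sits at position 11
  # independent oracle: translate codon-by-codon from the codon holding the
  # edit and find the first stop
  oracle_first_stop <- function(s, from_codon_start) {
    p <- from_codon_start
    while (p + 2 <= nchar(s)) {
      if (substr(s, p, p + 2) %in% c("TAA", "TAG", "TGA")) return(p)
      p <- p + 3
    }
    NA_integer_
  }
  codon_start <- 3 * ((edit_pos - 1) %/% 3) + 1
  oracle_stop <- oracle_first_stop(edited, codon_start)
  expect_equal(oracle_stop - edit_pos, 8L)
  rep <- find_premature_stop(edited, ref, cds_frame_offset = 0,
                             edit_pos = edit_pos)
  expect_true(rep$found)
  expect_equal(rep$distance_bp, 8L)
})
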