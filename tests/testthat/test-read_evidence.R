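# A fixed 60-nt precursor for micro-stacks; mature [6, 26], star [35, 56].
micro_hp <- make_hairpin(mature_len = 21, flank5 = 5, flank3 = 2, loop = 8,
                         seed = 99)
micro_seq <- micro_hp$precursor$sequence
mat <- micro_hp$mature
str_iv <- micro_hp$star
mat_seq <- substr(micro_seq, mat[1], mat[2])
star_seq <- substr(micro_seq, str_iv[1], str_iv[2])

mk_stack <- function(...) {
  rows <- list(...)
  df <- if (length(rows) == 0L)
    data.frame(library_id = character(0), start = integer(0),
               sequence = character(0), count = integer(0))
  else do.call(rbind, lapply(rows, function(r)
    data.frame(library_id = r[[1]], start = as.integer(r[[2]]),
               sequence = r[[3]], count = as.integer(r[[4]]),
               stringsAsFactors = FALSE)))
  read_stack("micro", df)
}

test_that("arm_exact_counts counts exact 5'-anchored reads only", {
  # single exact mature read at the magnitude of the least-supported
  # published miRNA (285 reads)
  st <- mk_stack(list("l1", mat[1], mat_seq, 285))
  expect_equal(arm_exact_counts(st, micro_seq, mat, str_iv),
               c(mature = 285L, star = 0L))

  empty <- mk_stack()[0, ]
  expect_equal(arm_exact_counts(read_stack("micro", empty), micro_seq, mat, str_iv),
               c(mature = 0L, star = 0L))

  # one internal mismatch at mature coords -> excluded
  mut <- mat_seq
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "U"),
                                 substr(mat_seq, 10, 10))[1]
  st <- mk_stack(list("l1", mat[1], mut, 50), list("l1", mat[1], mat_seq, 7))
  expect_equal(arm_exact_counts(st, micro_seq, mat, str_iv),
               c(mature = 7L, star = 0L))

  # shifted 5' end -> excluded even with zero mismatches
  st <- mk_stack(list("l1", mat[1] + 1L, substr(micro_seq, mat[1] + 1L, mat[2]), 9))
  expect_equal(arm_exact_counts(st, micro_seq, mat, str_iv)[["mature"]], 0L)
})

test_that("excision_fraction is the windowed-containment count ratio", {
  loop_read <- substr(micro_seq, mat[2] - 8L, mat[2] + 9L)  # spans the loop
  st <- mk_stack(list("l1", mat[1], mat_seq, 80),
                 list("l1", mat[2] - 8L, loop_read, 20))
  expect_equal(excision_fraction(st, mat, str_iv), 0.80)
  st <- mk_stack(list("l1", mat[1], mat_seq, 10))
  expect_equal(excision_fraction(st, mat, str_iv), 1.0)
  st <- mk_stack(list("l1", mat[2] - 8L, loop_read, 10))
  expect_equal(excision_fraction(st, mat, str_iv), 0.0)
  expect_error(
    excision_fraction(mk_stack(), mat, str_iv),
    class = "undefined_evidence_error")
})

test_that("five_prime_homogeneity uses modal start with leftmost tie-break", {
  sh <- substr(micro_seq, mat[1] + 1L, mat[2])
  st <- mk_stack(list("l1", mat[1], mat_seq, 80), list("l1", mat[1] + 1L, sh, 20))
  expect_equal(five_prime_homogeneity(st, mat), 0.8)
  st <- mk_stack(list("l1", mat[1], mat_seq, 1))
  expect_equal(five_prime_homogeneity(st, mat), 1.0)
  # exact tie: modal start is the 5'-most, fraction 0.5
  st <- mk_stack(list("l1", mat[1], mat_seq, 50), list("l1", mat[1] + 1L, sh, 50))
  expect_equal(five_prime_homogeneity(st, mat), 0.5)
  expect_error(five_prime_homogeneity(st, str_iv),
               class = "undefined_evidence_error")
})

test_that("libraries_detected counts libraries with windowed mature reads", {
  rows <- lapply(sprintf("lib%02d", 1:9), function(l)
    list(l, mat[1], mat_seq, 5))
  st <- do.call(mk_stack, rows)
  expect_equal(libraries_detected(st, mat), 9L)
  # absent from two libraries
  st7 <- do.call(mk_stack, rows[1:7])
  expect_equal(libraries_detected(st7, mat), 7L)
  expect_equal(libraries_detected(mk_stack(), mat), 0L)
  # star-only reads do not count as mature detection
  st <- mk_stack(list("l1", str_iv[1], star_seq, 5))
  expect_equal(libraries_detected(st, mat), 0L)
})

test_that("dominance is the mature share of all counts", {
  st <- mk_stack(list("l1", mat[1], mat_seq, 100))
  expect_equal(dominance(st, mat, str_iv), 1.0)
  st <- mk_stack(list("l1", mat[1], mat_seq, 50),
                 list("l1", str_iv[1], star_seq, 50))
  expect_equal(dominance(st, mat, str_iv), 0.5)
  expect_error(dominance(mk_stack(), mat, str_iv),
               class = "undefined_evidence_error")
})

test_that("count conservation and scale invariance hold on micro-stacks", {
  loop_read <- substr(micro_seq, mat[2] - 8L, mat[2] + 9L)
  st <- mk_stack(list("l1", mat[1], mat_seq, 60),
                 list("l2", str_iv[1], star_seq, 25),
                 list("l1", mat[2] - 8L, loop_read, 15))
  ef <- excision_fraction(st, mat, str_iv)
  dom <- dominance(st, mat, str_iv)
  star_share <- ef - dom
  unassigned <- 1 - ef
  total <- sum(st$count)
  expect_equal(dom * total + star_share * total + unassigned * total, total)

  st10 <- st; st10$count <- st10$count * 10L
  expect_equal(excision_fraction(st10, mat, str_iv), ef)
  expect_equal(dominance(st10, mat, str_iv), dom)
  expect_equal(five_prime_homogeneity(st10, mat),
               five_prime_homogeneity(st, mat))
})

test_that("evidence metrics equal brute-force per-read predicates on micro-stacks", {
  # every metric recomputed by literal per-read predicates
  win <- function(s, e, iv) s >= iv[1] - 2 & e <= iv[2] + 5
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    rows <- lapply(seq_len(n), function(i) {
      start <- sample(seq_len(nchar(micro_seq) - 18L), 1)
      len <- sample(18:min(24, nchar(micro_seq) - start + 1L), 1)
      sq <- substr(micro_seq, start, start + len - 1L)
      if (runif(1) < 0.3) {  # plant one mismatch
        k <- sample(len, 1)
        substr(sq, k, k) <- setdiff(c("A", "C", "G", "U"),
                                    substr(sq, k, k))[1]
      }
      list(sprintf("l%d", sample(1:3, 1)), start, sq, sample(1:50, 1))
    })
    st <- do.call(mk_stack, rows)
    s <- st$start; e <- st$start + nchar(st$sequence) - 1L
    in_m <- win(s, e, mat); in_s <- win(s, e, str_iv) & !in_m
    expect_equal(excision_fraction(st, mat, str_iv),
                 sum(st$count[in_m | in_s]) / sum(st$count))
    expect_equal(dominance(st, mat, str_iv),
                 sum(st$count[in_m]) / sum(st$count))
    expect_equal(libraries_detected(st, mat),
                 length(unique(st$library_id[in_m])))
  }
})
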