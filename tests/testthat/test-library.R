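toy_path <- system.file("extdata", "toy_library_synthetic.tsv", package = "ssir")

test_that("the toy table reads as a 9x5 three-level library", {
  lib <- read_ssir_library(toy_path)
  expect_equal(dim(lib), c(9L, 5L))
  expect_equal(n_samples(lib), 9)
  expect_equal(n_interest(lib), 5)
  expect_true(all(lengths(lib$alphabets) == 3))
  fix <- toy_library()  # same content as the in-code fixture
  expect_identical(lib$x, fix$x)
  expect_identical(lib$y, fix$y)
})

test_that("read -> write -> read round trip preserves everything", {
  lib <- toy_library()
  lib$x[3, 2] <- NA  # include a missing cell
  tmp <- tempfile(fileext = ".tsv")
  write_ssir_library(lib, tmp)
  back <- read_ssir_library(tmp, missing_token = "?",
                            alphabets = lib$alphabets)
  expect_identical(back$x, lib$x)
  expect_identical(back$y, lib$y)
  expect_identical(back$alphabets, lib$alphabets)
  # CSV dialect auto-detects too
  tmp2 <- tempfile(fileext = ".csv")
  write_ssir_library(toy_library(), tmp2, sep = ",")
  expect_identical(read_ssir_library(tmp2)$x, toy_library()$x)
})

test_that("transposed input with a separate label file reads correctly", {
  lib <- toy_library()
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(descriptor = colnames(lib$x), t(lib$x),
                   check.names = FALSE)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  lf <- tempfile(fileext = ".tsv")
  write.table(data.frame(names(lib$y), as.integer(lib$y)), lf, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  back <- read_ssir_library(tmp, orient = "genes-in-rows", label_file = lf)
  expect_identical(back$x, lib$x)
  expect_identical(back$y, lib$y)
})

test_that("malformed inputs are rejected", {
  lib <- toy_library()
  tmp <- tempfile(fileext = ".tsv")
  # duplicate sample ids
  txt <- readLines(toy_path)
  writeLines(c(txt, sub("^I9", "I1", txt[10])), tmp)
  expect_error(read_ssir_library(tmp), "duplicate")
  # token outside a declared alphabet
  expect_error(read_ssir_library(toy_path,
                                 alphabets = rep(list(c("L", "M")), 5)),
               "absent from its declared alphabet")
  # label count mismatch / single sample trains later
  expect_error(ssir_library(lib$x, lib$y[-1]), "label")
  one <- ssir_library(lib$x[1, , drop = FALSE], TRUE)
  expect_equal(n_samples(one), 1)
  expect_error(ssir_train(one, p_c = 0.1), "both classes")
})

test_that("constant descriptors are dropped, idempotently", {
  set.seed(42)
  x <- sapply(1:10, function(j) sample(c("A", "B"), 20, replace = TRUE))
  x[, 4] <- "A"
  lib <- ssir_library(x, rep(c(TRUE, FALSE), 10))
  out <- drop_constant_descriptors(lib)
  expect_equal(n_descriptors(out), 9)
  expect_false("D4" %in% colnames(out$x))
  expect_identical(drop_constant_descriptors(out), out)
  # untouched original, invariant samples/labels
  expect_equal(n_descriptors(lib), 10)
  expect_identical(out$y, lib$y)
  expect_identical(drop_constant_descriptors(toy_library())$x, toy_library()$x)
})

test_that("level merging recodes cells and alphabets", {
  lib <- toy_library()
  merged <- merge_levels(lib, c(M = "A"))
  expect_false(any(merged$x == "M"))
  expect_true(all(vapply(merged$alphabets, function(a)
    setequal(a, c("L", "A", "H")), logical(1))))
  # a three-level {A,M,P} descriptor becomes two-level {A,P}
  x <- cbind(calls = c("A", "M", "P", "A", "M", "P"))
  l2 <- ssir_library(x, rep(c(TRUE, FALSE), 3))
  m2 <- merge_levels(l2, c(M = "A"))
  expect_setequal(m2$alphabets[[1]], c("A", "P"))
  # identity mapping and idempotence
  expect_identical(merge_levels(lib, c(Z = "Q"))$x, lib$x)
  expect_identical(merge_levels(merged, c(M = "A")), merged)
  # collapsing everything then dropping constants leaves zero descriptors
  allone <- merge_levels(l2, c(A = "A", M = "A", P = "A"))
  expect_equal(n_descriptors(drop_constant_descriptors(allone)), 0)
  expect_identical(merged$y, lib$y)
})

test_that("entropy preselection keeps the most balanced descriptors", {
  # 50/50 binary: 1 bit; 90/10: ~0.469 bits
  x <- cbind(even = rep(c("A", "B"), 10),
             skew = c(rep("A", 18), "B", "B"))
  lib <- ssir_library(x, rep(c(TRUE, FALSE), 10))
  h <- descriptor_entropy(lib)
  expect_equal(h[[1]], 1)
  expect_equal(h[[2]], 0.469, tolerance = 1e-3)
  expect_equal(colnames(select_balanced_descriptors(lib, 1)$x), "even")
  # brute-force sort oracle over 20 descriptors with known level counts
  set.seed(7)
  counts <- sample(1:19, 20, replace = TRUE)
  xx <- sapply(counts, function(k) sample(rep(c("A", "B"), c(k, 20 - k))))
  lib20 <- ssir_library(xx, rep(c(TRUE, FALSE), 10))
  hh <- vapply(counts / 20, function(p) {
    q <- c(p, 1 - p); -sum(q * log2(q))
  }, numeric(1))
  top5 <- sort(order(-hh, seq_along(hh))[1:5])
  expect_equal(colnames(select_balanced_descriptors(lib20, 5)$x),
               colnames(xx <- lib20$x)[top5])
  # identity at k = descriptor count; bad k rejected
  expect_identical(select_balanced_descriptors(lib, 2)$x, lib$x)
  expect_error(select_balanced_descriptors(lib, 0), "positive")
  expect_error(select_balanced_descriptors(lib, 3), "exceeds")
})
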