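# a = 100, b = 20 library realizing the worked coverage patterns:
# descriptor D1 level "A" covers 10 samples (9 of interest),
# descriptor D2 level "A" covers 30 samples (2 of interest)
worked_library <- function() {
  y <- rep(c(TRUE, FALSE), c(20, 80))
  d1 <- rep("B", 100); d1[c(1:9, 21)] <- "A"
  d2 <- rep("B", 100); d2[c(1:2, 21:48)] <- "A"
  ssir_library(cbind(D1 = d1, D2 = d2), y)
}

test_that("rule evaluation reproduces the worked p-values", {
  lib <- worked_library()
  e1 <- evaluate_rule(ssir_rule(1, "A"), lib)
  expect_equal(c(e1$a, e1$b, e1$c, e1$d), c(100, 20, 10, 9))
  expect_equal(signif(e1$p_plus, 3), 7.87e-7)
  e2 <- evaluate_rule(ssir_rule(2, "A"), lib)
  expect_equal(c(e2$c, e2$d), c(30, 2))
  expect_equal(round(e2$p_plus, 3), 0.996)
  expect_equal(round(e2$p_minus, 3), 0.023)
  toy <- evaluate_rule(ssir_rule(c(2, 4), c("L", "H")), toy_library())
  expect_equal(c(toy$c, toy$d), c(4, 3))
  expect_equal(toy$p_plus, 45 / 126, tolerance = 1e-14)
  expect_error(evaluate_rule(ssir_rule(1, "Z"), lib), "absent")
})

test_that("training admits exactly the rules passing the cutoff", {
  lib <- toy_library()
  m <- ssir_train(lib, p_c = 0.40, orders = 2)
  row <- m$rules[m$rules$rule == "2:L & 4:H", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$vote, 1L)
  expect_equal(row$p_value, 45 / 126, tolerance = 1e-14)
  # every stored rule satisfies its vote's tail condition and only that one
  expect_true(all(ifelse(m$rules$vote > 0, m$rules$p_plus, m$rules$p_minus)
                  <= 0.40))
  expect_false(any(m$rules$p_plus <= 0.40 & m$rules$p_minus <= 0.40))
  # p_plus + p_minus = 1 + pmf(d)
  pm <- mapply(function(cc, dd) hyper_pmf(9, 5, cc, dd), m$rules$c, m$rules$d)
  expect_equal(m$rules$p_plus + m$rules$p_minus, 1 + pm, tolerance = 1e-12)
  # cutoff below the minimum achievable p-value gives an empty model
  expect_warning(m0 <- ssir_train(lib, p_c = 0.001, orders = 2), "empty")
  expect_equal(nrow(m0$rules), 0)
  expect_error(ssir_train(lib, p_c = 0.7), "p_c")
})

test_that("negative-vote rules carry their dual's significance", {
  for (lib in list(toy_library(), random_library(21, a = 14, n = 5))) {
    m <- suppressWarnings(ssir_train(lib, p_c = 0.3, orders = 1:2))
    neg <- m$rules[m$rules$vote < 0, ]
    a <- m$a; b <- m$b
    for (i in seq_len(nrow(neg)))
      expect_equal(neg$p_minus[i],
                   hyper_upper_tail(a, b, a - neg$c[i], b - neg$d[i]),
                   tolerance = 1e-12)
  }
})

test_that("a planted separating rule earns the minimal p-value and vote +1", {
  lib <- ssir_simulate(ssir_plant_spec(
    40, 10, rules = list(list(positions = c(1, 2), levels = c("A", "A"))),
    seed = 13))
  m <- ssir_train(lib, p_c = 1e-4, orders = 2)
  planted <- m$rules[m$rules$rule == "1:A & 2:A", ]
  expect_equal(planted$vote, 1L)
  expect_equal(planted$p_plus, min(m$rules$p_plus))
  # brute force: no order-2 rule has a smaller upper tail
  rs <- enumerate_rules(lib$alphabets, 2)
  best <- min(vapply(seq_len(length(rs)), function(i) {
    ev <- evaluate_rule(rs[[i]], lib)
    if (ev$c == 0) 1 else ev$p_plus
  }, numeric(1)))
  expect_equal(planted$p_plus, best)
})

test_that("scores superpose votes and rank ties by input order", {
  lib <- toy_library()
  m <- ssir_train(lib, p_c = 0.40, orders = 2)
  rk <- ssir_score(m, lib)
  # manual superposition from the stored rule table
  manual <- integer(9)
  for (i in seq_len(nrow(m$rules))) {
    hit <- rule_matches(parse_ssir_rule(m$rules$rule[i]), lib)
    manual <- manual + m$rules$vote[i] * hit
  }
  expect_identical(as.integer(rk$scores), as.integer(unname(manual)))
  expect_identical(rk$ordering, order(-rk$scores, seq_along(rk$scores)))
  expect_identical(rk$ranks[rk$ordering], seq_len(9))
  # empty model scores everything zero
  m0 <- suppressWarnings(ssir_train(lib, p_c = 0.001, orders = 2))
  expect_true(all(ssir_score(m0, lib)$scores == 0))
  expect_error(ssir_score(m, lib$x[, 1:3]), "mismatch")
  # unseen levels fail positive selectors, satisfy negated ones
  ext <- lib$x[1, , drop = FALSE]; ext[1, ] <- "Q"
  mneg <- list(k = 1, positions = matrix(2), levels = matrix("L"),
               negated = matrix(TRUE), vote = 1L)
  m1 <- m; m1$blocks <- list(mneg); m1$rules <- m$rules[0, ]
  expect_equal(unname(ssir_score(m1, ext)$scores), 1L)
  mpos <- mneg; mpos$negated <- matrix(FALSE)
  m1$blocks <- list(mpos)
  expect_equal(unname(ssir_score(m1, ext)$scores), 0L)
})

test_that("swapping the interest class flips votes and reverses the ranking", {
  lib <- toy_library()
  flip <- ssir_library(lib$x, !lib$y, alphabets = lib$alphabets)
  m <- ssir_train(lib, p_c = 0.40, orders = 2)
  mf <- ssir_train(flip, p_c = 0.40, orders = 2)
  expect_setequal(m$rules$rule, mf$rules$rule)
  merged <- merge(m$rules, mf$rules, by = "rule")
  expect_true(all(merged$vote.x == -merged$vote.y))
  expect_identical(as.integer(ssir_score(mf, lib)$scores),
                   as.integer(-ssir_score(m, lib)$scores))
})

test_that("shrinking the cutoff only removes rules", {
  lib <- random_library(31, a = 16, n = 6)
  pcs <- c(0.3, 0.1, 0.03, 0.01, 0.003)
  sets <- lapply(pcs, function(pc)
    suppressWarnings(ssir_train(lib, p_c = pc, orders = 1:2))$rules$rule)
  for (i in seq_along(pcs)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
    expect_lte(length(sets[[i]]), length(sets[[i - 1]]))
  }
})

test_that("descriptor tallies point at the rule-bearing descriptors", {
  lib <- toy_library()
  m <- ssir_train(lib, p_c = 0.40, orders = 2)
  dv <- descriptor_votes(m)
  expect_setequal(dv$descriptor[1:2], c("D2", "D4"))
  expect_equal(dv$total, sort(dv$total, decreasing = TRUE))
  # a model reduced to the single toy rule tallies D2 and D4 once each
  keep <- m$rules$rule == "2:L & 4:H"
  m1 <- m
  m1$rules <- m$rules[keep, ]
  m1$blocks <- list(list(k = 2, positions = matrix(c(2L, 4L), 1),
                         levels = matrix(c("L", "H"), 1),
                         negated = matrix(c(FALSE, FALSE), 1), vote = 1L))
  dv1 <- descriptor_votes(m1)
  expect_identical(dv1$descriptor, c("D2", "D4"))
  expect_identical(dv1$plus, c(1L, 1L))
  # empty model gives an empty tally
  m0 <- suppressWarnings(ssir_train(lib, p_c = 0.001, orders = 2))
  expect_equal(nrow(descriptor_votes(m0)), 0)
  # planted two-gene fixture: the planted genes top the tally
  plib <- ssir_simulate(ssir_plant_spec(
    40, 12, rules = list(list(positions = c(3, 7), levels = c("A", "A"))),
    seed = 2))
  pm <- ssir_train(plib, p_c = 1e-5, orders = 1:2)
  expect_setequal(descriptor_votes(pm)$descriptor[1:2], c("D3", "D7"))
})

test_that("models persist to text and reload with bit-identical scores", {
  lib <- random_library(51, a = 18, n = 6)
  m <- suppressWarnings(ssir_train(lib, p_c = 0.2, orders = 1:2))
  tmp <- tempfile(fileext = ".tsv")
  write_ssir_model(m, tmp)
  back <- read_ssir_model(tmp)
  expect_identical(back$rules$rule, m$rules$rule)
  expect_identical(back$rules$vote, m$rules$vote)
  expect_identical(back$rules$p_value, m$rules$p_value)
  expect_equal(back$p_c, m$p_c)
  expect_identical(ssir_score(back, lib)$scores, ssir_score(m, lib)$scores)
  ext <- random_library(52, a = 9, n = 6)
  expect_identical(ssir_score(back, ext)$scores, ssir_score(m, ext)$scores)
})
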