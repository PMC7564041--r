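# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: draws are enumerated, AUC is counted pairwise,
# rule spaces are generated raw and deduplicated by coverage signature.

# exact distribution of d by enumerating all choose(a, c) draws
enum_d_distribution <- function(a, b, c) {
  draws <- utils::combn(a, c)
  interest <- seq_len(b)                      # first b samples are of interest
  apply(draws, 2, function(dr) sum(dr %in% interest))
}

# O(n^2) pairwise AUC: concordant + half ties over positive/negative pairs
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# a small random library with mixed alphabets, independent of ssir_simulate
random_library <- function(seed, a = 12, n = 6, sizes = NULL) {
  set.seed(seed)
  if (is.null(sizes)) sizes <- sample(2:3, n, replace = TRUE)
  alph <- lapply(sizes, function(m) LETTERS[seq_len(m)])
  x <- sapply(seq_len(n), function(j) sample(alph[[j]], a, replace = TRUE))
  rownames(x) <- paste0("s", seq_len(a))
  y <- rep(FALSE, a)
  y[sample(a, max(2, round(a / 2)))] <- TRUE
  if (sum(!y) < 2) y[sample(which(y), 2)] <- FALSE
  ssir_library(x, y, alphabets = alph)
}

# every possible fingerprint over the alphabets (small n only)
all_fingerprints <- function(alphabets) {
  g <- rev(expand.grid(rev(alphabets), stringsAsFactors = FALSE))
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, NULL)
  m
}

# raw rule generation (positions x level variations x 2^k negation flags),
# canonicalized and deduplicated by coverage signature over all fingerprints
raw_rule_signatures <- function(alphabets, k) {
  n <- length(alphabets)
  fps <- all_fingerprints(alphabets)
  combos <- utils::combn(n, k)
  sigs <- character(0)
  for (ci in seq_len(ncol(combos))) {
    pos <- combos[, ci]
    levs <- rev(expand.grid(rev(lapply(pos, function(p) alphabets[[p]])),
                            stringsAsFactors = FALSE))
    for (li in seq_len(nrow(levs))) {
      for (flags in 0:(2^k - 1)) {
        neg <- as.logical(bitwAnd(flags, 2^(seq_len(k) - 1)))
        r <- canonicalize_rule(
          ssir_rule(pos, unlist(levs[li, ]), neg), alphabets)
        sigs <- c(sigs, paste(as.integer(rule_matches(r, fps)), collapse = ""))
      }
    }
  }
  sort(unique(sigs))
}

ruleset_signatures <- function(rs, alphabets) {
  fps <- all_fingerprints(alphabets)
  sigs <- vapply(seq_len(length(rs)), function(i)
    paste(as.integer(rule_matches(rs[[i]], fps)), collapse = ""), "")
  sort(sigs)
}

frac_equal <- function(f, num, den) {
  expect_s3_class(f, "ssir_fraction")
  expect_true(f$num * den == num * f$den)
}
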