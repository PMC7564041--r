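#' Conjunction rules over fingerprint positions
#'
#' An SSIR rule of order `k` fixes the level at `k` descriptor positions (all
#' other positions are wildcards); each fixed level may be negated, meaning
#' "any level but this one". A rule acts as an extractor: the samples
#' satisfying every selector are the rule's coverage.
#'
#' Canonical form: selectors are sorted by position and, on a two-level
#' position, a negated selector is rewritten as the positive selector of the
#' other level, so no negations remain on binary positions.
#'
#' @param positions integer vector of 1-based descriptor positions, pairwise
#'   distinct.
#' @param levels character vector of levels, one per position.
#' @param negated logical vector (recycled), `TRUE` for "not this level".
#' @return Object of class `ssir_rule`.
#' @examples
#' ssir_rule(c(2, 4), c("L", "H"))           # D2:L & D4:H
#' ssir_rule(1, "A", negated = TRUE)         # 1:!A
#' @export
ssir_rule <- function(positions, levels, negated = FALSE) {
  positions <- as.integer(positions)
  levels <- as.character(levels)
  negated <- rep_len(as.logical(negated), length(positions))
  if (length(positions) == 0) stop("a rule needs at least one selector", call. = FALSE)
  if (length(levels) != length(positions))
    stop("'levels' and 'positions' lengths differ", call. = FALSE)
  if (anyDuplicated(positions)) stop("duplicate positions in rule", call. = FALSE)
  if (any(positions < 1)) stop("positions are 1-based", call. = FALSE)
  o <- order(positions)
  structure(list(positions = positions[o], levels = levels[o],
                 negated = negated[o]),
            class = "ssir_rule")
}

#' @export
format.ssir_rule <- function(x, ...) {
  paste(sprintf("%d:%s%s", x$positions, ifelse(x$negated, "!", ""), x$levels),
        collapse = " & ")
}

#' @export
print.ssir_rule <- function(x, ...) {
  cat("<rule>", format(x), "\n")
  invisible(x)
}

#' Parse the rule text format
#'
#' Inverse of `format()` on an `ssir_rule`: selectors `pos:LEVEL` or
#' `pos:!LEVEL` (1-based positions) joined by `&`.
#'
#' @param text a single rule string, e.g. `"2:L & 4:H"`.
#' @return An [ssir_rule].
#' @export
parse_ssir_rule <- function(text) {
  parts <- strsplit(trimws(text), "\\s*&\\s*")[[1]]
  m <- regmatches(parts, regexec("^([0-9]+):(!?)(.+)$", parts))
  if (any(lengths(m) != 4)) stop("malformed rule text: ", text, call. = FALSE)
  ssir_rule(vapply(m, function(p) as.integer(p[2]), integer(1)),
            vapply(m, `[`, "", 4),
            vapply(m, function(p) p[3] == "!", logical(1)))
}

#' Rewrite a rule into canonical form
#'
#' Sorts selectors by position and removes negations on two-level positions
#' by naming the other level instead. Idempotent; canonical equivalents match
#' identical sample sets on every library over the same alphabets.
#'
#' @param rule an [ssir_rule].
#' @param alphabets named or unnamed list of per-position level alphabets
#'   (e.g. `lib$alphabets`).
#' @return The canonical [ssir_rule].
#' @export
canonicalize_rule <- function(rule, alphabets) {
  lev <- rule$levels
  neg <- rule$negated
  for (i in seq_along(rule$positions)) {
    a <- alphabets[[rule$positions[i]]]
    if (!lev[i] %in% a)
      stop(sprintf("level '%s' absent from the alphabet of position %d",
                   lev[i], rule$positions[i]), call. = FALSE)
    if (neg[i] && length(a) == 2) {
      lev[i] <- setdiff(a, lev[i])
      neg[i] <- FALSE
    }
  }
  ssir_rule(rule$positions, lev, neg)
}

#' Which samples does a rule cover?
#'
#' A positive selector requires the cell to equal its level; a negated
#' selector requires it to differ. Missing cells satisfy no selector of
#' either kind, so missing data never contributes evidence to a rule.
#'
#' @param rule an [ssir_rule].
#' @param lib an [ssir_library], or a character matrix of fingerprints with
#'   the same descriptor count the rule was built for.
#' @return Logical vector, one entry per sample.
#' @export
rule_matches <- function(rule, lib) {
  x <- if (inherits(lib, "ssir_library")) lib$x else lib
  if (max(rule$positions) > ncol(x))
    stop("rule position ", max(rule$positions),
         " out of range for ", ncol(x), " descriptors", call. = FALSE)
  hit <- rep(TRUE, nrow(x))
  for (i in seq_along(rule$positions)) {
    v <- x[, rule$positions[i]]
    s <- if (rule$negated[i]) !is.na(v) & v != rule$levels[i]
         else                 !is.na(v) & v == rule$levels[i]
    hit <- hit & s
  }
  hit
}

## ---- canonical selector table ---------------------------------------------

## Per position: a two-level alphabet contributes its m = 2 positive
## selectors (negation is redundant); any other size contributes level and
## negated-level pairs, 2m selectors. Order: position, then alphabet order,
## then positive before negated.
.selector_table <- function(alphabets) {
  pos <- integer(0); lev <- character(0); neg <- logical(0)
  for (j in seq_along(alphabets)) {
    a <- as.character(alphabets[[j]])
    if (length(a) == 2) {
      pos <- c(pos, j, j); lev <- c(lev, a); neg <- c(neg, FALSE, FALSE)
    } else {
      for (l in a) {
        pos <- c(pos, j, j); lev <- c(lev, l, l); neg <- c(neg, FALSE, TRUE)
      }
    }
  }
  data.frame(position = pos, level = lev, negated = neg,
             stringsAsFactors = FALSE)
}

.selector_weights <- function(alphabets) {
  m <- lengths(alphabets)
  ifelse(m == 2, 2, 2 * m)
}

#' Enumerate every canonical rule of a given order
#'
#' Systematic generation nests position combinations, level variations and
#' negation flags, emitting each distinct canonical rule exactly once in a
#' fixed lexicographic order (positions, then levels, then negation).
#'
#' @param alphabets list of per-position level alphabets.
#' @param k rule order, `1 <= k <= length(alphabets)`.
#' @param max_rules guard against accidental combinatorial explosions; raise
#'   it deliberately for big enumerations.
#' @return An `ssir_ruleset`: a compact set of canonical rules supporting
#'   `length()` and `[[` (which yields an [ssir_rule]).
#' @seealso [count_rules()] for counting without materializing,
#'   [sample_rules()] for Monte Carlo rule selection.
#' @export
enumerate_rules <- function(alphabets, k, max_rules = 2e6) {
  n <- length(alphabets)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > n)
    stop("'k' must be an integer in 1..", n, call. = FALSE)
  total <- count_rules(alphabets, k)
  if (total > max_rules)
    stop(sprintf("enumeration would yield %.0f rules (max_rules = %.0f)",
                 total, max_rules), call. = FALSE)
  sel <- .selector_table(alphabets)
  by_pos <- split(seq_len(nrow(sel)), sel$position)
  combos <- utils::combn(n, k)
  blocks <- vector("list", ncol(combos))
  for (ci in seq_len(ncol(combos))) {
    idx_lists <- lapply(combos[, ci], function(p) by_pos[[as.character(p)]])
    # odometer: last position varies fastest
    g <- rev(expand.grid(rev(idx_lists), KEEP.OUT.ATTRS = FALSE))
    blocks[[ci]] <- as.matrix(g)
  }
  idx <- do.call(rbind, blocks)
  dimnames(idx) <- NULL
  structure(list(k = k, n = n, sel = sel, idx = idx, alphabets = alphabets),
            class = "ssir_ruleset")
}

#' @export
length.ssir_ruleset <- function(x) nrow(x$idx)

#' @export
`[[.ssir_ruleset` <- function(x, i) {
  s <- x$idx[i, ]
  ssir_rule(x$sel$position[s], x$sel$level[s], x$sel$negated[s])
}

#' @export
print.ssir_ruleset <- function(x, ...) {
  cat(sprintf("ssir_ruleset: %d canonical rules of order %d over %d positions\n",
              nrow(x$idx), x$k, x$n))
  invisible(x)
}

#' Count canonical rules of a given order
#'
#' Each position with a two-level alphabet offers 2 canonical selectors; an
#' m-level position (m != 2) offers 2m (each level, plain and negated). The
#' order-k rule count is the sum over position k-subsets of the product of
#' their selector counts — the k-th elementary symmetric polynomial of the
#' per-position counts, which for all-binary alphabets collapses to
#' `choose(n, k) * 2^k`.
#'
#' @param alphabets list of per-position alphabets, or an integer vector of
#'   alphabet sizes.
#' @param k rule order.
#' @param method `"closed-form"` evaluates the symmetric polynomial by
#'   dynamic programming; `"stream"` walks the position combinations
#'   (vectorized over the innermost position) and accumulates per-combination
#'   counts, an independent cross-check of the closed form.
#' @return The rule count as a double (counts can exceed integer range).
#' @examples
#' count_rules(rep(2, 3645), 2)  # 26564760
#' @export
count_rules <- function(alphabets, k, method = c("closed-form", "stream")) {
  method <- match.arg(method)
  w <- if (is.list(alphabets)) .selector_weights(alphabets)
       else ifelse(alphabets == 2, 2, 2 * as.numeric(alphabets))
  n <- length(w)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > n)
    stop("'k' must be an integer in 1..", n, call. = FALSE)
  if (method == "closed-form") {
    e <- c(1, rep(0, k))
    for (wi in w) for (j in seq(k, 1)) e[j + 1] <- e[j + 1] + e[j] * wi
    return(e[k + 1])
  }
  # stream: recurse over ordered position prefixes, vectorizing the last slot
  rec <- function(start, depth, acc) {
    if (depth == k - 1) return(acc * sum(w[start:n]))
    tot <- 0
    for (i in start:(n - (k - depth - 1)))
      tot <- tot + rec(i + 1, depth + 1, acc * w[i])
    tot
  }
  if (k == 1) sum(w) else rec(1, 0, 1)
}

#' Draw rules uniformly from the canonical rule space
#'
#' Monte Carlo alternative to exhaustive enumeration for large rule spaces:
#' draws `n_rules` canonical rules of order `k` uniformly with replacement.
#' Position subsets are sampled with probability proportional to the product
#' of their selector counts (via suffix elementary symmetric polynomials),
#' then a selector is drawn uniformly at each chosen position, which makes
#' every canonical rule equally likely.
#'
#' @inheritParams enumerate_rules
#' @param n_rules number of rules to draw.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return An `ssir_ruleset` (with possible repeats).
#' @export
sample_rules <- function(alphabets, k, n_rules, seed) {
  n <- length(alphabets)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > n)
    stop("'k' must be an integer in 1..", n, call. = FALSE)
  if (n_rules < 1) stop("'n_rules' must be >= 1", call. = FALSE)
  w <- .selector_weights(alphabets)
  if (all(w == 0)) stop("empty rule space", call. = FALSE)
  sel <- .selector_table(alphabets)
  by_pos <- split(seq_len(nrow(sel)), sel$position)
  # E[j + 1, i] = e_j(w_i, ..., w_n)
  E <- matrix(0, k + 1, n + 2)
  E[1, ] <- 1
  for (i in seq(n, 1)) for (j in seq_len(k))
    E[j + 1, i] <- E[j + 1, i + 1] + w[i] * E[j, i + 1]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  idx <- matrix(0L, n_rules, k)
  for (r in seq_len(n_rules)) {
    i <- 1
    for (j in seq(k, 1)) {        # j selectors still to place
      repeat {
        pr <- w[i] * E[j, i + 1] / E[j + 1, i]
        if (stats::runif(1) < pr) break
        i <- i + 1
      }
      slots <- by_pos[[as.character(i)]]
      idx[r, k - j + 1] <- slots[sample.int(length(slots), 1)]
      i <- i + 1
    }
  }
  structure(list(k = k, n = n, sel = sel, idx = idx, alphabets = alphabets),
            class = "ssir_ruleset")
}
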