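#' @title Consensus voting models of significant rules
#' @description Training evaluates every candidate rule against the library,
#'   keeps those whose hypergeometric tail p-value passes the cutoff `p_c`,
#'   and superposes their unit votes: a rule enriched in the interest class
#'   (`p(d+) <= p_c`) votes +1 for every sample it covers, a rule depleted in
#'   it (`p(d-) <= p_c`) votes -1. A sample's score is the sum of votes of
#'   all covering rules and defines the ranking.
#' @name ssir-model
#' @keywords internal
NULL

## ---- shared evaluation core -------------------------------------------------

## Match matrices for all canonical rules of each requested order.
## Coverage does not depend on labels, so leave-one-out folds and label
## shuffles can reuse this cache and remain exactly equivalent to
## from-scratch retraining.
.eval_core <- function(lib, orders, mode = "exhaustive", n_rules = NULL,
                       seed = NULL, max_rules = 2e6) {
  blocks <- lapply(orders, function(k) {
    rs <- if (mode == "exhaustive") enumerate_rules(lib$alphabets, k, max_rules)
          else sample_rules(lib$alphabets, k, n_rules, seed + k)
    M <- .match_matrix(rs, lib$x)
    list(k = k, ruleset = rs, M = M, c = colSums(M))
  })
  names(blocks) <- paste0("order", orders)
  blocks
}

.match_matrix <- function(ruleset, x) {
  sel <- ruleset$sel
  S <- matrix(FALSE, nrow(x), nrow(sel))
  for (s in seq_len(nrow(sel))) {
    v <- x[, sel$position[s]]
    S[, s] <- if (sel$negated[s]) !is.na(v) & v != sel$level[s]
              else                !is.na(v) & v == sel$level[s]
  }
  idx <- ruleset$idx
  M <- S[, idx[, 1], drop = FALSE]
  if (ncol(idx) > 1) for (j in 2:ncol(idx))
    M <- M & S[, idx[, j], drop = FALSE]
  M
}

## Both tail p-values for many (c, d) pairs under fixed (a, b), via a
## unique-pair lookup.
.tails_cd <- function(a, b, cvec, dvec) {
  key <- paste(cvec, dvec)
  uk <- !duplicated(key)
  up <- vapply(which(uk), function(i) hyper_upper_tail(a, b, cvec[i], dvec[i]),
               numeric(1))
  lo <- vapply(which(uk), function(i) hyper_lower_tail(a, b, cvec[i], dvec[i]),
               numeric(1))
  pos <- match(key, key[uk])
  list(p_plus = up[pos], p_minus = lo[pos])
}

## Vote selection for one block under labels y (logical, length a).
## Returns indices into the block's rules plus vote signs and p-values.
.select_block <- function(block, y, p_c, positive_only = FALSE) {
  a <- length(y); b <- sum(y)
  live <- which(block$c >= 1)
  d <- colSums(block$M[y, live, drop = FALSE])
  tails <- .tails_cd(a, b, block$c[live], d)
  plus <- tails$p_plus <= p_c
  minus <- !positive_only & tails$p_minus <= p_c
  sel <- plus | minus
  list(rule = live[sel],
       c = block$c[live][sel], d = d[sel],
       p_plus = tails$p_plus[sel], p_minus = tails$p_minus[sel],
       vote = ifelse(plus[sel], 1L, -1L))
}

## ---- user-facing operations -------------------------------------------------

#' Evaluate a single rule against a library
#'
#' Computes the rule's coverage counts and both hypergeometric tail p-values:
#' `p_plus` is the chance a random draw of the same size contains at least as
#' many interest samples, `p_minus` at most as many.
#'
#' @param rule an [ssir_rule].
#' @param lib an [ssir_library] with both classes present.
#' @return List of class `ssir_rule_eval`: `rule`, `a`, `b`, `c`, `d`,
#'   `p_plus`, `p_minus`, `matched` (logical vector).
#' @examples
#' lib <- toy_library()
#' evaluate_rule(ssir_rule(c(2, 4), c("L", "H")), lib)
#' @export
evaluate_rule <- function(rule, lib) {
  stopifnot(inherits(lib, "ssir_library"))
  a <- n_samples(lib); b <- n_interest(lib)
  if (b == 0 || b == a) stop("both classes must be present", call. = FALSE)
  for (i in seq_along(rule$positions)) {
    p <- rule$positions[i]
    if (p > ncol(lib$x))
      stop("rule position ", p, " out of range", call. = FALSE)
    if (!rule$levels[i] %in% lib$alphabets[[p]])
      stop(sprintf("level '%s' absent from descriptor '%s'",
                   rule$levels[i], colnames(lib$x)[p]), call. = FALSE)
  }
  m <- rule_matches(rule, lib)
  cc <- sum(m); dd <- sum(m & lib$y)
  structure(list(rule = rule, a = a, b = b, c = cc, d = dd,
                 p_plus = hyper_upper_tail(a, b, cc, dd),
                 p_minus = hyper_lower_tail(a, b, cc, dd),
                 matched = m),
            class = "ssir_rule_eval")
}

#' @export
print.ssir_rule_eval <- function(x, ...) {
  cat(sprintf("<rule eval> %s\n  a=%d b=%d c=%d d=%d  p(d+)=%.4g  p(d-)=%.4g\n",
              format(x$rule), x$a, x$b, x$c, x$d, x$p_plus, x$p_minus))
  invisible(x)
}

#' Train an SSIR voting model
#'
#' Enumerates (or samples) every canonical rule of the requested orders,
#' scores each against the training library, and admits into the voting pool
#' each rule with `p(d+) <= p_c` (vote +1) or `p(d-) <= p_c` (vote -1).
#' Rules covering zero samples are skipped. For `p_c < 0.5` no rule can earn
#' both votes since `p(d+) + p(d-) >= 1`.
#'
#' @param lib training [ssir_library]; both classes must be present.
#' @param p_c significance cutoff, `0 < p_c < 0.5`.
#' @param orders rule orders to evaluate, a subset of 1..4 typically.
#' @param mode `"exhaustive"` enumeration or Monte Carlo `"sample"`.
#' @param n_rules,seed number of sampled rules per order and seed
#'   (`mode = "sample"` only).
#' @param positive_only admit only +1 rules.
#' @param max_rules guard for exhaustive enumeration size.
#' @return An `ssir_model`: selected rules with counts, tails and votes, plus
#'   training metadata (`a`, `b`, `p_c`, `orders`, `mode`, `seed`).
#' @examples
#' lib <- toy_library()
#' m <- ssir_train(lib, p_c = 0.40, orders = 2)
#' m$rules[m$rules$rule == "2:L & 4:H", ]
#' @export
ssir_train <- function(lib, p_c, orders = 2L, mode = c("exhaustive", "sample"),
                       n_rules = NULL, seed = NULL, positive_only = FALSE,
                       max_rules = 2e6) {
  stopifnot(inherits(lib, "ssir_library"))
  mode <- match.arg(mode)
  a <- n_samples(lib); b <- n_interest(lib)
  if (b == 0 || b == a)
    stop("training needs samples of both classes (0 < b < a)", call. = FALSE)
  if (!is.numeric(p_c) || p_c <= 0 || p_c >= 0.5)
    stop("'p_c' must satisfy 0 < p_c < 0.5", call. = FALSE)
  orders <- sort(unique(as.integer(orders)))
  if (any(orders < 1 | orders > ncol(lib$x)))
    stop("orders out of range", call. = FALSE)
  if (mode == "sample" && (is.null(n_rules) || is.null(seed)))
    stop("mode = 'sample' needs 'n_rules' and 'seed'", call. = FALSE)
  core <- .eval_core(lib, orders, mode, n_rules, seed, max_rules)
  rows <- list(); blocks <- list()
  for (bl in core) {
    s <- .select_block(bl, lib$y, p_c, positive_only)
    if (!length(s$rule)) next
    idx <- bl$ruleset$idx[s$rule, , drop = FALSE]
    sel <- bl$ruleset$sel
    txt <- vapply(seq_len(nrow(idx)), function(i) {
      j <- idx[i, ]
      paste(sprintf("%d:%s%s", sel$position[j],
                    ifelse(sel$negated[j], "!", ""), sel$level[j]),
            collapse = " & ")
    }, "")
    rows[[length(rows) + 1]] <- data.frame(
      order = bl$k, rule = txt, c = s$c, d = s$d,
      p_plus = s$p_plus, p_minus = s$p_minus,
      p_value = ifelse(s$vote > 0, s$p_plus, s$p_minus),
      vote = s$vote, stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1]] <- list(
      k = bl$k,
      positions = matrix(sel$position[idx], nrow(idx)),
      levels = matrix(sel$level[idx], nrow(idx)),
      negated = matrix(sel$negated[idx], nrow(idx)),
      vote = s$vote)
  }
  rules <- if (length(rows)) do.call(rbind, rows)
           else data.frame(order = integer(), rule = character(),
                           c = integer(), d = integer(), p_plus = numeric(),
                           p_minus = numeric(), p_value = numeric(),
                           vote = integer(), stringsAsFactors = FALSE)
  if (!nrow(rules)) warning("no rule passed the cutoff; model is empty")
  structure(list(rules = rules, blocks = blocks, a = a, b = b, p_c = p_c,
                 orders = orders, mode = mode, seed = seed,
                 positive_only = positive_only,
                 descriptors = colnames(lib$x), alphabets = lib$alphabets),
            class = "ssir_model")
}

#' @export
print.ssir_model <- function(x, ...) {
  cat(sprintf(
    "ssir_model: %d rules (%d +1 / %d -1), p_c = %g, orders = %s, a = %d, b = %d\n",
    nrow(x$rules), sum(x$rules$vote > 0), sum(x$rules$vote < 0), x$p_c,
    paste(x$orders, collapse = ","), x$a, x$b))
  invisible(x)
}

#' Score and rank samples with a voting model
#'
#' Each sample accumulates the votes of every pool rule that covers it; the
#' summed score ranks the samples (descending, ties by input order). Works
#' identically for training and external samples; levels never seen in
#' training simply fail positive selectors and satisfy negated ones.
#'
#' @param model an `ssir_model`.
#' @param newdata an [ssir_library] or character matrix with the same
#'   descriptor count as the training library.
#' @return An `ssir_ranking`: `scores` (named integer), `ordering`
#'   (sample indices best-first), `ranks` (rank of each sample).
#' @export
ssir_score <- function(model, newdata) {
  x <- if (inherits(newdata, "ssir_library")) newdata$x else newdata
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$descriptors))
    stop("descriptor count mismatch: model has ", length(model$descriptors),
         ", data has ", ncol(x), call. = FALSE)
  scores <- integer(nrow(x))
  for (bl in model$blocks) {
    if (!length(bl$vote)) next
    for (r in seq_along(bl$vote)) {
      hit <- rep(TRUE, nrow(x))
      for (j in seq_len(ncol(bl$positions))) {
        v <- x[, bl$positions[r, j]]
        s <- if (bl$negated[r, j]) !is.na(v) & v != bl$levels[r, j]
             else                  !is.na(v) & v == bl$levels[r, j]
        hit <- hit & s
      }
      scores <- scores + bl$vote[r] * hit
    }
  }
  names(scores) <- rownames(x)
  ordering <- order(-scores, seq_along(scores))
  ranks <- integer(length(scores))
  ranks[ordering] <- seq_along(scores)
  structure(list(scores = scores, ordering = ordering, ranks = ranks),
            class = "ssir_ranking")
}

#' @rdname ssir_score
#' @param object an `ssir_model`.
#' @param ... passed on.
#' @export
predict.ssir_model <- function(object, newdata, ...) ssir_score(object, newdata)

#' @export
print.ssir_ranking <- function(x, ...) {
  cat("ssir_ranking of", length(x$scores), "samples\n")
  df <- as.data.frame(x)
  print(utils::head(df[x$ordering, ], 10))
  if (length(x$scores) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.ssir_ranking <- function(x, ...) {
  data.frame(sample = names(x$scores) %||% seq_along(x$scores),
             score = as.integer(x$scores), rank = x$ranks,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Descriptor vote tally
#'
#' How often each descriptor appears in the pool's +1 and -1 rules. The most
#' used descriptors are the ones the rule selection found informative, so
#' the tally doubles as a variable-selection readout.
#'
#' @param model an `ssir_model`.
#' @return data frame (descriptor, plus, minus, total), sorted by total
#'   descending, ties by descriptor input order; empty model gives zero rows.
#' @export
descriptor_votes <- function(model) {
  p <- length(model$descriptors)
  plus <- integer(p); minus <- integer(p)
  for (bl in model$blocks) for (r in seq_along(bl$vote)) {
    pos <- bl$positions[r, ]
    if (bl$vote[r] > 0) plus[pos] <- plus[pos] + 1L
    else minus[pos] <- minus[pos] + 1L
  }
  df <- data.frame(descriptor = model$descriptors, plus = plus, minus = minus,
                   total = plus + minus, stringsAsFactors = FALSE)
  df <- df[df$total > 0, , drop = FALSE]
  df <- df[order(-df$total, seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## ---- persistence ------------------------------------------------------------

#' Save / load a voting model
#'
#' Text format: a JSON header line (training metadata and descriptor schema)
#' followed by a TSV rule table — rule text (1-based positions), descriptor
#' names, order, c, d, both tails and the vote. Reloading reproduces scores
#' bit-exactly since votes are integers and rules round-trip verbatim.
#'
#' @param model an `ssir_model`.
#' @param path file path.
#' @return `write_ssir_model` returns `path` invisibly; `read_ssir_model`
#'   the reconstructed `ssir_model`.
#' @export
write_ssir_model <- function(model, path) {
  hdr <- jsonlite::toJSON(list(
    a = model$a, b = model$b, p_c = model$p_c, orders = model$orders,
    mode = model$mode, seed = model$seed,
    positive_only = model$positive_only,
    descriptors = model$descriptors,
    alphabets = model$alphabets), auto_unbox = TRUE, digits = NA)
  rules <- model$rules
  rules$descriptors <- vapply(strsplit(rules$rule, " & "), function(sels) {
    pos <- as.integer(sub(":.*", "", sels))
    paste(model$descriptors[pos], collapse = ",")
  }, "")
  for (col in c("p_plus", "p_minus", "p_value"))
    rules[[col]] <- sprintf("%.17g", rules[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#ssir-model ", hdr), con)
  utils::write.table(rules, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ssir_model
#' @export
read_ssir_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#ssir-model "))
    stop("not an ssir model file", call. = FALSE)
  hdr <- jsonlite::fromJSON(sub("^#ssir-model ", "", lines[1]),
                            simplifyVector = TRUE)
  rules <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                             colClasses = "character", quote = "")
  rules$order <- as.integer(rules$order)
  rules$c <- as.integer(rules$c); rules$d <- as.integer(rules$d)
  rules$p_plus <- as.numeric(rules$p_plus)
  rules$p_minus <- as.numeric(rules$p_minus)
  rules$p_value <- as.numeric(rules$p_value)
  rules$vote <- as.integer(rules$vote)
  rules$descriptors <- NULL
  blocks <- list()
  for (k in sort(unique(rules$order))) {
    sub <- rules[rules$order == k, , drop = FALSE]
    parsed <- lapply(sub$rule, parse_ssir_rule)
    blocks[[length(blocks) + 1]] <- list(
      k = k,
      positions = do.call(rbind, lapply(parsed, `[[`, "positions")),
      levels = do.call(rbind, lapply(parsed, `[[`, "levels")),
      negated = do.call(rbind, lapply(parsed, `[[`, "negated")),
      vote = sub$vote)
  }
  alph <- hdr$alphabets
  if (!is.list(alph)) alph <- as.list(alph)
  structure(list(rules = rules, blocks = blocks, a = hdr$a, b = hdr$b,
                 p_c = hdr$p_c, orders = hdr$orders, mode = hdr$mode,
                 seed = hdr$seed, positive_only = isTRUE(hdr$positive_only),
                 descriptors = hdr$descriptors, alphabets = alph),
            class = "ssir_model")
}
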