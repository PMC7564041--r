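#' Seeded synthetic libraries with planted rules
#'
#' Generates two-class fingerprint libraries in which chosen conjunction
#' rules are "planted": interest-class samples receive the rule's level
#' pattern with a given penetrance, all other cells are drawn i.i.d. from a
#' background distribution. Every pipeline stage can thus be exercised with
#' known ground truth and no external downloads.
#'
#' By default the background at planted positions excludes the planted
#' level, so the pattern occurs if and only if it was imposed: at penetrance
#' 1 the planted rule separates the classes perfectly, and at penetrance 0
#' the planted level never appears and the library is pure noise. Set
#' `background_excludes_planted = FALSE` to let the pattern also arise by
#' background chance in either class.
#'
#' @param n_samples number of samples.
#' @param n_descriptors number of descriptors.
#' @param alphabet level alphabet shared by all descriptors (character
#'   vector), or a list of per-descriptor alphabets.
#' @param rules list of planted rules, each a list with `positions`,
#'   `levels`, optional `class` (`TRUE` = plant in the interest class,
#'   default) and `penetrance` in `[0, 1]` (default 1). Two rules fixing
#'   different levels at the same position are contradictory and rejected.
#' @param balance fraction of interest-class samples (default 0.5).
#' @param background per-level background probabilities (named numeric,
#'   recycled over descriptors); default uniform.
#' @param background_excludes_planted see Details.
#' @param seed integer seed; the same spec and seed give byte-identical
#'   libraries.
#' @return Object of class `ssir_plant_spec`.
#' @examples
#' spec <- ssir_plant_spec(40, 30, rules = list(list(positions = c(1, 2),
#'                                                   levels = c("A", "A"))),
#'                         seed = 1)
#' lib <- ssir_simulate(spec)
#' attr(lib, "manifest")$rules
#' @export
ssir_plant_spec <- function(n_samples = 40, n_descriptors = 30,
                            alphabet = c("A", "P"),
                            rules = list(list(positions = c(1, 2),
                                              levels = c("A", "A"),
                                              penetrance = 1)),
                            balance = 0.5, background = NULL,
                            background_excludes_planted = TRUE, seed = 1) {
  stopifnot(n_samples >= 2, n_descriptors >= 1,
            balance > 0, balance < 1)
  alphabets <- if (is.list(alphabet)) lapply(alphabet, as.character)
               else rep(list(as.character(alphabet)), n_descriptors)
  if (length(alphabets) != n_descriptors)
    stop("one alphabet per descriptor required", call. = FALSE)
  fixed <- list()   # position -> (level, class)
  for (r in rules) {
    r$class <- if (is.null(r$class)) TRUE else isTRUE(r$class)
    r$penetrance <- if (is.null(r$penetrance)) 1 else r$penetrance
    if (r$penetrance < 0 || r$penetrance > 1)
      stop("penetrance must lie in [0, 1]", call. = FALSE)
    if (length(r$positions) != length(r$levels))
      stop("planted rule positions/levels lengths differ", call. = FALSE)
    for (i in seq_along(r$positions)) {
      p <- r$positions[i]
      if (p < 1 || p > n_descriptors)
        stop("planted rule position ", p, " out of range", call. = FALSE)
      if (!r$levels[i] %in% alphabets[[p]])
        stop("planted level '", r$levels[i],
             "' absent from the alphabet of position ", p, call. = FALSE)
      key <- as.character(p)
      if (!is.null(fixed[[key]]) && fixed[[key]] != r$levels[i])
        stop("contradictory planted rules at position ", p, call. = FALSE)
      fixed[[key]] <- r$levels[i]
    }
  }
  rules <- lapply(rules, function(r) {
    list(positions = as.integer(r$positions), levels = as.character(r$levels),
         class = if (is.null(r$class)) TRUE else isTRUE(r$class),
         penetrance = if (is.null(r$penetrance)) 1 else r$penetrance)
  })
  structure(list(n_samples = as.integer(n_samples),
                 n_descriptors = as.integer(n_descriptors),
                 alphabets = alphabets, rules = rules, balance = balance,
                 background = background,
                 background_excludes_planted = background_excludes_planted,
                 seed = as.integer(seed)),
            class = "ssir_plant_spec")
}

#' Generate a library from a plant specification
#'
#' @param spec an [ssir_plant_spec].
#' @param dir optional directory; when given, writes `library.tsv` (the
#'   [write_ssir_library()] dialect) and a ground-truth `manifest.json`.
#' @return An [ssir_library] with a `"manifest"` attribute recording the
#'   planted rules, seed and balance.
#' @export
ssir_simulate <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "ssir_plant_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_descriptors
  n_pos <- max(1, min(n - 1, round(spec$balance * n)))
  y <- sample(rep(c(TRUE, FALSE), c(n_pos, n - n_pos)))
  planted_at <- lapply(seq_len(p), function(j) {
    levs <- unique(unlist(lapply(spec$rules, function(r)
      r$levels[r$positions == j])))
    levs
  })
  x <- matrix(NA_character_, n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("D%d", seq_len(p))))
  for (j in seq_len(p)) {
    a <- spec$alphabets[[j]]
    pr <- if (is.null(spec$background)) stats::setNames(rep(1, length(a)), a)
          else spec$background[a]
    if (spec$background_excludes_planted && length(planted_at[[j]])) {
      pr[names(pr) %in% planted_at[[j]]] <- 0
      if (all(pr == 0))
        stop("background excludes every level at position ", j, call. = FALSE)
    }
    x[, j] <- sample(a, n, replace = TRUE, prob = pr)
  }
  for (r in spec$rules) {
    targets <- which(y == r$class)
    impose <- targets[stats::runif(length(targets)) < r$penetrance]
    for (i in impose) x[i, r$positions] <- r$levels
  }
  lib <- ssir_library(x, y, alphabets = spec$alphabets)
  attr(lib, "manifest") <- list(
    rules = lapply(spec$rules, function(r)
      list(rule = format(ssir_rule(r$positions, r$levels)),
           class = r$class, penetrance = r$penetrance)),
    seed = spec$seed, balance = spec$balance,
    n_samples = n, n_descriptors = p)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_ssir_library(lib, file.path(dir, "library.tsv"))
    jsonlite::write_json(attr(lib, "manifest"),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  lib
}

#' Toy nine-individual library
#'
#' A synthetic stand-in for the classic nine-individual, five-descriptor
#' illustration with three levels (L/M/H): it reproduces every stated fact of
#' that example — 9 individuals of which 5 are of interest, and the order-2
#' rule `2:L & 4:H` covers exactly I2, I3, I6 and I9, three of them of
#' interest (so its upper tail is 45/126). The remaining cells are arbitrary
#' fixed values. The same table ships as
#' `inst/extdata/toy_library_synthetic.tsv`.
#'
#' @return An [ssir_library] with `a = 9`, `b = 5`.
#' @examples
#' evaluate_rule(ssir_rule(c(2, 4), c("L", "H")), toy_library())
#' @export
toy_library <- function() {
  x <- matrix(c(
    # D1   D2   D3   D4   D5
    "L",  "M", "H", "L", "M",   # I1 interest
    "M",  "L", "L", "H", "H",   # I2 interest  rule hit
    "H",  "L", "M", "H", "L",   # I3 interest  rule hit
    "L",  "H", "L", "M", "H",   # I4
    "M",  "M", "H", "L", "L",   # I5 interest
    "H",  "L", "M", "H", "M",   # I6           rule hit
    "L",  "H", "L", "M", "H",   # I7
    "M",  "M", "H", "L", "L",   # I8
    "L",  "L", "M", "H", "H"    # I9 interest  rule hit
  ), nrow = 9, byrow = TRUE,
  dimnames = list(paste0("I", 1:9), paste0("D", 1:5)))
  ssir_library(x, labels = c(TRUE, TRUE, TRUE, FALSE, TRUE,
                             FALSE, FALSE, FALSE, TRUE),
               alphabets = rep(list(c("L", "M", "H")), 5))
}
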