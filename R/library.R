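#' Two-class categorical fingerprint libraries
#'
#' An `ssir_library` holds a matrix of symbolic levels (samples in rows,
#' descriptors in columns), a binary class label per sample, and the ordered
#' alphabet of observed levels for every descriptor. It is the universe the
#' urn experiment draws from: `a` samples of which `b` are of the interest
#' class.
#'
#' Missing values are represented internally as `NA` and match no rule
#' selector, positive or negated.
#'
#' @param x character matrix or data frame of levels, samples in rows;
#'   row names (or `sample_ids`) identify samples, column names the
#'   descriptors.
#' @param labels logical vector (or coercible 0/1), `TRUE` for the interest
#'   class, one entry per sample.
#' @param sample_ids optional character vector of unique sample identifiers;
#'   defaults to row names or `S1..Sa`.
#' @param alphabets optional named list of per-descriptor level alphabets;
#'   inferred from the observed tokens (in order of first appearance down
#'   the column) when omitted. Observed tokens outside a declared alphabet
#'   are an error.
#' @param missing_token token(s) in `x` to treat as missing, in addition to
#'   `NA`.
#' @return Object of class `ssir_library` with fields `x` (character
#'   matrix), `y` (logical labels), `alphabets` (named list).
#' @examples
#' lib <- ssir_library(
#'   matrix(c("A", "P", "A", "P"), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("g1", "g2"))),
#'   labels = c(TRUE, FALSE))
#' lib
#' @export
ssir_library <- function(x, labels, sample_ids = NULL, alphabets = NULL,
                         missing_token = character()) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("'x' must be a matrix or data frame", call. = FALSE)
  storage.mode(x) <- "character"
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty matrix", call. = FALSE)
  if (length(missing_token)) x[x %in% missing_token] <- NA_character_
  if (is.null(sample_ids)) sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(x)))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  rownames(x) <- sample_ids
  if (length(labels) != nrow(x))
    stop("label missing for a sample: ", length(labels), " labels for ",
         nrow(x), " samples", call. = FALSE)
  if (anyNA(labels)) stop("label missing for a sample", call. = FALSE)
  y <- as.logical(labels)
  if (anyNA(y)) stop("labels must be logical or 0/1", call. = FALSE)
  names(y) <- sample_ids
  observed <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    unique(v[!is.na(v)])
  })
  names(observed) <- colnames(x)
  if (is.null(alphabets)) {
    alphabets <- observed
  } else {
    if (is.null(names(alphabets)) && length(alphabets) == ncol(x))
      names(alphabets) <- colnames(x)
    if (!all(colnames(x) %in% names(alphabets)))
      stop("alphabets must cover every descriptor", call. = FALSE)
    alphabets <- lapply(alphabets[colnames(x)], as.character)
    for (j in seq_len(ncol(x))) {
      bad <- setdiff(observed[[j]], alphabets[[j]])
      if (length(bad))
        stop(sprintf("token '%s' in descriptor '%s' absent from its declared alphabet",
                     bad[1], colnames(x)[j]), call. = FALSE)
    }
  }
  structure(list(x = x, y = y, alphabets = alphabets),
            class = "ssir_library")
}

#' @export
print.ssir_library <- function(x, ...) {
  cat(sprintf(
    "ssir_library: %d samples (%d of interest), %d descriptors\n",
    nrow(x$x), sum(x$y), ncol(x$x)))
  sizes <- lengths(x$alphabets)
  cat("alphabet sizes: ", paste(names(table(sizes)), "levels x",
                                as.integer(table(sizes)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.ssir_library <- function(x) dim(x$x)

n_samples    <- function(lib) nrow(lib$x)
n_interest   <- function(lib) sum(lib$y)
n_descriptors <- function(lib) ncol(lib$x)

## subset samples, keeping the descriptor schema (alphabets) fixed
subset_samples <- function(lib, keep) {
  structure(list(x = lib$x[keep, , drop = FALSE], y = lib$y[keep],
                 alphabets = lib$alphabets),
            class = "ssir_library")
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a fingerprint library from delimited text
#'
#' Reads a TSV/CSV table of symbolic levels plus a binary class label, either
#' with samples in rows (default) or descriptors in rows (transposed input,
#' common for gene-expression call matrices).
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` auto-detects tab vs comma from the
#'   first line.
#' @param orient `"samples-in-rows"` or `"genes-in-rows"`.
#' @param label_col name (or index) of the label column; ignored when
#'   `label_file` is given. With `orient = "genes-in-rows"` the labels must
#'   come from `label_file`.
#' @param positive_label token in the label column denoting the interest
#'   class; alternatively the column may already be 0/1 or TRUE/FALSE
#'   (then `positive_label` is ignored if `NULL`).
#' @param label_file optional two-column file (sample id, label) supplying
#'   labels separately.
#' @inheritParams ssir_library
#' @return An [ssir_library].
#' @export
read_ssir_library <- function(path, sep = NULL,
                              orient = c("samples-in-rows", "genes-in-rows"),
                              label_col = "class", positive_label = NULL,
                              label_file = NULL, alphabets = NULL,
                              missing_token = character()) {
  orient <- match.arg(orient)
  if (is.null(sep)) sep <- .detect_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           row.names = 1, colClasses = "character",
                           check.names = FALSE, quote = "")
  if (nrow(tab) == 0 || ncol(tab) == 0) stop("empty matrix", call. = FALSE)
  labels <- NULL
  if (!is.null(label_file)) {
    lt <- utils::read.table(label_file, sep = .detect_sep(label_file),
                            header = FALSE, colClasses = "character",
                            quote = "")
    labels_raw <- stats::setNames(lt[[2]], lt[[1]])
  } else {
    if (orient == "genes-in-rows")
      stop("genes-in-rows input needs a separate 'label_file'", call. = FALSE)
    if (is.numeric(label_col)) label_col <- colnames(tab)[label_col]
    if (!label_col %in% colnames(tab))
      stop("label column '", label_col, "' not found", call. = FALSE)
    labels_raw <- stats::setNames(tab[[label_col]], rownames(tab))
    tab <- tab[, setdiff(colnames(tab), label_col), drop = FALSE]
  }
  m <- as.matrix(tab)
  if (orient == "genes-in-rows") m <- t(m)
  ids <- rownames(m)
  if (!all(ids %in% names(labels_raw)))
    stop("label missing for a sample: ",
         paste(setdiff(ids, names(labels_raw)), collapse = ", "),
         call. = FALSE)
  raw <- labels_raw[ids]
  labels <- if (is.null(positive_label)) {
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v)) stop("non-numeric labels need 'positive_label'", call. = FALSE)
    v != 0
  } else raw == positive_label
  ssir_library(m, labels, sample_ids = ids, alphabets = alphabets,
               missing_token = missing_token)
}

#' Write a fingerprint library to delimited text
#'
#' Samples in rows, one `class` column of 0/1 labels appended; the dialect
#' round-trips through [read_ssir_library()].
#'
#' @param lib an [ssir_library].
#' @param path output path.
#' @param sep field delimiter.
#' @param missing_token token written for missing cells.
#' @return `path`, invisibly.
#' @export
write_ssir_library <- function(lib, path, sep = "\t", missing_token = "?") {
  m <- lib$x
  m[is.na(m)] <- missing_token
  df <- data.frame(sample = rownames(m), m, class = as.integer(lib$y),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop descriptors with a single observed level
#'
#' Constant descriptors can never separate the classes: every rule built on
#' them covers all or none of the samples. This mirrors the usual first
#' preprocessing step on call matrices.
#'
#' @param lib an [ssir_library].
#' @return A library keeping only descriptors with at least two distinct
#'   observed (non-missing) levels; may have zero descriptors.
#' @export
drop_constant_descriptors <- function(lib) {
  nlev <- vapply(seq_len(ncol(lib$x)), function(j) {
    v <- lib$x[, j]
    length(unique(v[!is.na(v)]))
  }, integer(1))
  keep <- nlev >= 2
  structure(list(x = lib$x[, keep, drop = FALSE], y = lib$y,
                 alphabets = lib$alphabets[keep]),
            class = "ssir_library")
}

#' Merge descriptor levels
#'
#' Recode levels, e.g. collapse marginal calls into absent (`c(M = "A")`) to
#' binarize three-level call matrices. Descriptors that become constant are
#' not dropped automatically; chain [drop_constant_descriptors()].
#'
#' @param lib an [ssir_library].
#' @param mapping named character vector (`c(old = "new", ...)`) applied to
#'   every descriptor, or a named list of such vectors applied per
#'   descriptor.
#' @return The recoded library with recomputed alphabets.
#' @export
merge_levels <- function(lib, mapping) {
  per_desc <- is.list(mapping)
  x <- lib$x
  alph <- lib$alphabets
  for (j in seq_len(ncol(x))) {
    map <- if (per_desc) mapping[[colnames(x)[j]]] else mapping
    if (is.null(map) || !length(map)) next
    v <- x[, j]
    hit <- !is.na(v) & v %in% names(map)
    v[hit] <- unname(map[v[hit]])
    x[, j] <- v
    a <- alph[[j]]
    a[a %in% names(map)] <- unname(map[a[a %in% names(map)]])
    a <- unique(a[!is.na(a)])
    if (!length(a))
      stop("mapping creates an empty alphabet for descriptor '",
           colnames(x)[j], "'", call. = FALSE)
    alph[[j]] <- a
  }
  structure(list(x = x, y = lib$y, alphabets = alph), class = "ssir_library")
}

#' Shannon entropy of each descriptor's level distribution
#'
#' @param lib an [ssir_library].
#' @return Numeric vector (bits), one entry per descriptor; missing cells are
#'   excluded from the frequencies.
#' @export
descriptor_entropy <- function(lib) {
  vapply(seq_len(ncol(lib$x)), function(j) {
    v <- lib$x[, j]
    p <- table(v[!is.na(v)])
    p <- p / sum(p)
    -sum(p * log2(p))
  }, numeric(1))
}

#' Keep the k most level-balanced descriptors
#'
#' Scores every descriptor by the Shannon entropy of its level frequencies
#' across all samples (not class-conditional) and keeps the `k` highest, so
#' descriptors showing each level about equally often are preferred — a
#' maximum-entropy preselection. Ties break by input order.
#'
#' @param lib an [ssir_library].
#' @param k number of descriptors to keep, `1 <= k <=` descriptor count.
#' @return A library with the `k` selected descriptors, in input order.
#' @export
select_balanced_descriptors <- function(lib, k) {
  p <- ncol(lib$x)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k <= 0)
    stop("'k' must be a positive integer", call. = FALSE)
  if (k > p) stop("'k' exceeds the descriptor count", call. = FALSE)
  h <- descriptor_entropy(lib)
  keep <- sort(order(-h, seq_len(p))[seq_len(k)])
  structure(list(x = lib$x[, keep, drop = FALSE], y = lib$y,
                 alphabets = lib$alphabets[keep]),
            class = "ssir_library")
}

#' Descriptor manifest
#'
#' @param lib an [ssir_library].
#' @return data frame with one row per descriptor: name, alphabet
#'   (comma-joined), entropy in bits.
#' @export
descriptor_manifest <- function(lib) {
  data.frame(descriptor = colnames(lib$x),
             alphabet = vapply(lib$alphabets, paste, "", collapse = ","),
             entropy = descriptor_entropy(lib),
             row.names = NULL, stringsAsFactors = FALSE)
}
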