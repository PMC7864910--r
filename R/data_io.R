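#' Read a multilabel label table
#'
#' Parses a label CSV in the chest-radiograph dialect: one row per image, an
#' image-identifier column and a pipe-separated findings column where the
#' literal string `"No Finding"` marks a healthy image. Every finding is
#' validated against `vocabulary`; `"No Finding"` maps to an empty finding
#' set, never to a class of its own.
#'
#' @param path Path to a CSV file with a header row.
#' @param vocabulary Character vector of allowed class names.
#' @param id_col,labels_col Column names; defaults follow the NIH convention.
#' @param healthy_label String standing for the empty finding set.
#'
#' @return A tibble of class `cbf_labels` with columns `image_id` (character)
#'   and `findings` (list column of character vectors, `character(0)` for a
#'   healthy image). The vocabulary is kept in the `"vocabulary"` attribute.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("Image Index,Finding Labels",
#'              "a.png,Hernia|Pneumonia", "b.png,No Finding"), tf)
#' read_label_table(tf, c("Hernia", "Pneumonia"))
read_label_table <- function(path, vocabulary,
                             id_col = "Image Index",
                             labels_col = "Finding Labels",
                             healthy_label = "No Finding") {
  if (!file.exists(path)) abort(paste0("label table not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (col in c(id_col, labels_col)) {
    if (!col %in% names(raw)) {
      abort(paste0("column '", col, "' missing from ", path))
    }
  }
  ids <- raw[[id_col]]
  if (anyNA(ids) || any(!nzchar(ids))) abort("empty image id in label table")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    abort(paste0("duplicate image_id '", dup, "' in label table"))
  }
  findings <- purrr::map(strsplit(raw[[labels_col]], "|", fixed = TRUE),
                         function(f) {
                           f <- trimws(f[nzchar(trimws(f))])
                           f[f != healthy_label]
                         })
  bad <- purrr::map_lgl(findings, ~ any(!.x %in% vocabulary))
  if (any(bad)) {
    row <- which(bad)[1L]
    offender <- setdiff(findings[[row]], vocabulary)[1L]
    abort(paste0("unknown label '", offender, "' in row ", row,
                 " (image_id '", ids[row], "')"))
  }
  new_label_table(tibble::tibble(image_id = ids, findings = findings),
                  vocabulary)
}

new_label_table <- function(tbl, vocabulary) {
  structure(tbl, vocabulary = vocabulary,
            class = c("cbf_labels", class(tbl)))
}

#' Write a label table in the chest-radiograph dialect
#'
#' Inverse of [read_label_table()]: findings are pipe-joined and an empty
#' finding set is written as the healthy marker, so a write/read round trip
#' reproduces the records exactly.
#'
#' @param labels A `cbf_labels` tibble.
#' @param path Output CSV path.
#' @inheritParams read_label_table
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path,
                              id_col = "Image Index",
                              labels_col = "Finding Labels",
                              healthy_label = "No Finding") {
  out <- tibble::tibble(
    !!id_col := labels$image_id,
    !!labels_col := purrr::map_chr(labels$findings, function(f) {
      if (length(f) == 0L) healthy_label else paste(f, collapse = "|")
    })
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-class positive/negative counts
#'
#' Tallies how many records carry each class. A multilabel record increments
#' every class it carries, so the positives column may sum to more than the
#' number of records.
#'
#' @param labels A `cbf_labels` tibble (or any tibble with a `findings` list
#'   column).
#' @param vocabulary Class names; defaults to the table's vocabulary.
#' @return A `cbf_counts` tibble with columns `class`, `positives`,
#'   `negatives`, `total`; `negatives` is always derived as
#'   `total - positives`.
#' @export
count_classes <- function(labels, vocabulary = attr(labels, "vocabulary")) {
  if (nrow(labels) == 0L) abort("cannot count classes of an empty record set")
  if (is.null(vocabulary)) abort("no class vocabulary supplied")
  total <- nrow(labels)
  seen <- unlist(labels$findings, use.names = FALSE)
  pos <- as.integer(table(factor(seen, levels = vocabulary)))
  new_class_counts(vocabulary, pos, total)
}

#' Construct a per-class count table
#'
#' @param classes Ordered class names.
#' @param positives Per-class positive counts P_k.
#' @param total Total number of records n; negatives are N_k = n - P_k.
#' @return A `cbf_counts` tibble.
#' @export
new_class_counts <- function(classes, positives, total) {
  positives <- as.integer(positives)
  total <- as.integer(total[1L])
  if (length(classes) < 1L) abort("need at least one class")
  if (length(positives) != length(classes)) {
    abort("positives and classes differ in length")
  }
  if (any(positives < 0L) || any(positives > total)) {
    abort("positive counts must satisfy 0 <= P_k <= total")
  }
  structure(
    tibble::tibble(class = as.character(classes), positives = positives,
                   negatives = total - positives, total = total),
    class = c("cbf_counts", class(tibble::tibble()))
  )
}

#' Read / write a per-class count table
#'
#' CSV with columns `class,positives,negatives,total`. On read, `negatives`
#' is recomputed from `total - positives` rather than trusted.
#'
#' @param path CSV path.
#' @return A `cbf_counts` tibble.
#' @export
read_class_counts <- function(path) {
  raw <- readr::read_csv(path, col_types = "ciii", progress = FALSE)
  for (col in c("class", "positives", "total")) {
    if (!col %in% names(raw)) abort(paste0("column '", col, "' missing"))
  }
  if (length(unique(raw$total)) != 1L) abort("total must be constant")
  new_class_counts(raw$class, raw$positives, raw$total[1L])
}

#' @rdname read_class_counts
#' @param counts A `cbf_counts` tibble.
#' @export
write_class_counts <- function(counts, path) {
  readr::write_csv(tibble::as_tibble(counts), path, progress = FALSE)
  invisible(path)
}

#' Combine two count tables over the same vocabulary
#'
#' @param a,b `cbf_counts` tibbles with identical class order.
#' @return A `cbf_counts` tibble with elementwise-summed positives and totals.
#' @export
combine_class_counts <- function(a, b) {
  if (!identical(a$class, b$class)) abort("class vocabularies differ")
  new_class_counts(a$class, a$positives + b$positives, a$total[1L] + b$total[1L])
}

#' Split records into partitions or cross-validation folds
#'
#' Either a train/validation/test split by fractions or a k-fold partition.
#' Deterministic given `seed`; fold sizes differ by at most one. An optional
#' grouping vector (e.g. patient id) keeps all records of a group in one
#' partition.
#'
#' @param labels A `cbf_labels` tibble.
#' @param k Fold count for cross-validation (mutually exclusive with
#'   `fractions`).
#' @param fractions Named numeric vector summing to 1, e.g.
#'   `c(train = .7, val = .1, test = .2)`.
#' @param seed Integer seed.
#' @param group Optional vector, one entry per record, of group ids.
#' @return A tibble with columns `image_id` and `partition` (fold number as
#'   `"fold1"`... for k-fold).
#' @export
make_split <- function(labels, k = NULL,
                       fractions = c(train = 0.7, val = 0.1, test = 0.2),
                       seed = 1L, group = NULL) {
  n <- nrow(labels)
  units <- if (is.null(group)) labels$image_id else unique(group)
  m <- length(units)
  if (!is.null(k)) {
    if (k < 1L) abort("k must be a positive fold count")
    if (k > m) abort("more folds than records")
    assignment <- withr::with_seed(seed, sample(rep_len(seq_len(k), m)))
    part <- paste0("fold", assignment)
  } else {
    if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
    sizes <- floor(fractions * m)
    # hand leftovers to partitions in declared order
    left <- m - sum(sizes)
    if (left > 0) sizes[seq_len(left)] <- sizes[seq_len(left)] + 1L
    part_units <- rep(names(fractions), times = sizes)
    part <- withr::with_seed(seed, sample(part_units))
  }
  map <- setNames(part, units)
  key <- if (is.null(group)) labels$image_id else group
  tibble::tibble(image_id = labels$image_id, partition = unname(map[key]))
}
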