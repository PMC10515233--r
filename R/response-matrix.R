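#' Construct a response matrix
#'
#' Container for a persons x items matrix of integer category codes
#' (0..m_i per item), with missing responses as `NA`, per-item metadata
#' (id, wording polarity, maximum category, scale-version membership) and
#' optional person covariates.
#'
#' @param data Integer matrix or data frame, persons in rows, items in
#'   columns. Codes must be integers in `0..max_category`; `NA` marks a
#'   missing response.
#' @param item_meta Data frame with one row per item and columns `id`,
#'   `polarity` ("negative"/"positive"), `max_category`, and optionally
#'   `versions` (comma-separated memberships). Defaults to ids from column
#'   names, polarity "negative", and max category taken from the data.
#' @param person_meta Optional data frame of person covariates (e.g.
#'   `gender`, `age`), one row per person.
#' @return An object of class `resp_matrix`: list with elements `data`
#'   (integer matrix), `item_meta`, `person_meta`.
#' @export
response_matrix <- function(data, item_meta = NULL, person_meta = NULL) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 persons and 2 items", call. = FALSE)
  if (any(x[!is.na(x)] != round(x[!is.na(x)])))
    stop("response codes must be integers", call. = FALSE)
  storage.mode(x) <- "integer"
  if (any(x < 0L, na.rm = TRUE))
    stop("response codes must be >= 0", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("q", seq_len(ncol(x)))

  if (is.null(item_meta)) {
    item_meta <- data.frame(id = colnames(x),
                            polarity = "negative",
                            max_category = apply(x, 2L, max, na.rm = TRUE),
                            stringsAsFactors = FALSE)
  }
  item_meta <- as.data.frame(item_meta)
  stopifnot(all(c("id", "polarity", "max_category") %in% names(item_meta)))
  if (nrow(item_meta) != ncol(x))
    stop("item_meta must have one row per item", call. = FALSE)
  if (!all(item_meta$polarity %in% c("negative", "positive")))
    stop("item polarity must be 'negative' or 'positive'", call. = FALSE)
  colnames(x) <- item_meta$id
  for (i in seq_len(ncol(x))) {
    bad <- which(!is.na(x[, i]) & x[, i] > item_meta$max_category[i])
    if (length(bad))
      stop(sprintf("item %s: code %d at row %d exceeds max category %d",
                   item_meta$id[i], x[bad[1L], i], bad[1L],
                   item_meta$max_category[i]), call. = FALSE)
  }
  if (!is.null(person_meta)) {
    person_meta <- as.data.frame(person_meta)
    if (nrow(person_meta) != nrow(x))
      stop("person_meta must have one row per person", call. = FALSE)
  }
  structure(list(data = x, item_meta = item_meta, person_meta = person_meta),
            class = "resp_matrix")
}

#' Read a response matrix from CSV
#'
#' Reads a persons x items CSV of integer category codes (empty cell =
#' missing) and, optionally, an item metadata CSV with columns `id`,
#' `polarity`, `max_category` (and `versions`).
#'
#' @param path Path to the response CSV (one row per person, header row of
#'   item ids).
#' @param meta_path Optional path to the item metadata CSV.
#' @param person_meta Optional person covariate data frame, or a character
#'   vector of column names in the response CSV to split off as covariates.
#' @return A [response_matrix()] object.
#' @export
read_responses <- function(path, meta_path = NULL, person_meta = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty input file: ", path, call. = FALSE)
  if (is.character(person_meta)) {
    pm <- raw[, intersect(person_meta, names(raw)), drop = FALSE]
    raw <- raw[, setdiff(names(raw), person_meta), drop = FALSE]
    person_meta <- pm
  }
  for (j in seq_along(raw)) {
    v <- raw[[j]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(trimws(v)))
    bad <- which(!is.na(raw[[j]]) & raw[[j]] != "" & is.na(v))
    if (length(bad))
      stop(sprintf("non-integer cell at row %d, column %s", bad[1L],
                   names(raw)[j]), call. = FALSE)
    if (any(v[!is.na(v)] != round(v[!is.na(v)])))
      stop(sprintf("non-integer cell in column %s", names(raw)[j]),
           call. = FALSE)
    raw[[j]] <- v
  }
  meta <- if (!is.null(meta_path)) utils::read.csv(meta_path) else NULL
  response_matrix(raw, item_meta = meta, person_meta = person_meta)
}

#' Reverse-code positively worded items
#'
#' Maps codes of the given items through `x -> max_category - x`, so that
#' all items point in the same (distress) direction before a full-scale
#' fit. Subscale analyses typically keep the raw orientation.
#'
#' @param rm A [response_matrix()] object.
#' @param items Items to reverse; default: all items with polarity
#'   "positive" in the metadata.
#' @return The modified `resp_matrix`, with attribute `"reversed"` naming
#'   the reversed items.
#' @export
reverse_code <- function(rm, items = NULL) {
  stopifnot(inherits(rm, "resp_matrix"))
  if (is.null(items)) items <- rm$item_meta$id[rm$item_meta$polarity == "positive"]
  idx <- match(items, rm$item_meta$id)
  if (anyNA(idx)) stop("unknown items: ",
                       paste(items[is.na(idx)], collapse = ", "), call. = FALSE)
  for (i in idx)
    rm$data[, i] <- rm$item_meta$max_category[i] - rm$data[, i]
  attr(rm, "reversed") <- items
  rm
}

#' Subset a response matrix by items
#'
#' @param rm A [response_matrix()] object.
#' @param items Item ids or indices to keep (e.g. a named subset from
#'   [pss_item_subset()]).
#' @return A `resp_matrix` restricted to those items.
#' @export
subset_items <- function(rm, items) {
  stopifnot(inherits(rm, "resp_matrix"))
  idx <- if (is.character(items)) match(items, rm$item_meta$id) else items
  if (anyNA(idx)) stop("unknown items requested", call. = FALSE)
  response_matrix(rm$data[, idx, drop = FALSE],
                  item_meta = rm$item_meta[idx, , drop = FALSE],
                  person_meta = rm$person_meta)
}

#' Perceived Stress Scale item metadata
#'
#' Item ids q1..q14, wording polarity (positively worded: 4, 5, 6, 7, 9,
#' 10, 13), maximum category 4 (five-point scale 0-4), and version
#' membership for the 14-, 10- and 4-item forms. The short-form
#' memberships follow the standard published forms: PSS-10 = items
#' 1, 2, 3, 6, 7, 8, 9, 10, 11, 14; PSS-4 = items 2, 6, 7, 14.
#'
#' @return Data frame usable as `item_meta` in [response_matrix()].
#' @export
pss_item_meta <- function() {
  pos <- c(4, 5, 6, 7, 9, 10, 13)
  p10 <- c(1, 2, 3, 6, 7, 8, 9, 10, 11, 14)
  p4 <- c(2, 6, 7, 14)
  data.frame(
    id = paste0("q", 1:14),
    polarity = ifelse(1:14 %in% pos, "positive", "negative"),
    max_category = 4L,
    versions = vapply(1:14, function(i)
      paste(c("PSS14", if (i %in% p10) "PSS10", if (i %in% p4) "PSS4"),
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' Named Perceived Stress Scale item subsets
#'
#' Hard-coded subsets used throughout the evaluation: full and short scale
#' versions plus the wording subscales.
#'
#' @param name One of `"PSS14"`, `"PSS10"`, `"PSS4"`, `"negative7"`,
#'   `"negative6"` (negative items of the PSS-10), `"positive7"`.
#' @return Character vector of item ids.
#' @export
pss_item_subset <- function(name = c("PSS14", "PSS10", "PSS4", "negative7",
                                     "negative6", "positive7")) {
  name <- match.arg(name)
  q <- function(i) paste0("q", i)
  switch(name,
         PSS14 = q(1:14),
         PSS10 = q(c(1, 2, 3, 6, 7, 8, 9, 10, 11, 14)),
         PSS4 = q(c(2, 6, 7, 14)),
         negative7 = q(c(1, 2, 3, 8, 11, 12, 14)),
         negative6 = q(c(1, 2, 3, 8, 11, 14)),
         positive7 = q(c(4, 5, 6, 7, 9, 10, 13)))
}

#' @export
print.resp_matrix <- function(x, ...) {
  cat("Response matrix: ", nrow(x$data), " persons x ", ncol(x$data),
      " items\n", sep = "")
  nmiss <- sum(is.na(x$data))
  cat("missing cells: ", nmiss, sprintf(" (%.1f%%)", 100 * nmiss /
        length(x$data)), "\n", sep = "")
  pol <- table(x$item_meta$polarity)
  cat("polarity: ", paste(names(pol), pol, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
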