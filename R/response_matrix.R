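#' Construct a response matrix
#'
#' Container for a complete-case person-by-item table of integer responses,
#' together with person covariates and an item-to-subscale map. Responses are
#' stored on the 0-based analysis scale: a five-category rating item
#' ("never" ... "always", coded 1-5 on the questionnaire) is held as 0..4.
#'
#' @param scores integer matrix, persons in rows, items in columns, values
#'   \code{0..max_score[i]} for column \code{i}. No missing entries are
#'   allowed: the analysis operates under a complete-case contract and
#'   incomplete rows must be dropped before construction (see
#'   \code{\link{read_responses_csv}}).
#' @param subscale_map named character vector mapping every item id to a
#'   subscale label, or \code{NULL} for a single unnamed scale.
#' @param person_factors data frame of per-person categorical covariates
#'   (e.g. gender, age_group, country), or \code{NULL}.
#' @param item_ids character vector of stable item names; defaults to
#'   \code{colnames(scores)}.
#' @param max_score integer vector of per-item maximum scores; defaults to
#'   the observed column maxima.
#'
#' @return An object of class \code{response_matrix}: a list with elements
#'   \code{scores}, \code{item_ids}, \code{subscale_map},
#'   \code{person_factors}, \code{max_score}.
#' @export
response_matrix <- function(scores, subscale_map = NULL, person_factors = NULL,
                            item_ids = colnames(scores), max_score = NULL) {
  scores <- as.matrix(scores)
  if (is.null(item_ids)) item_ids <- paste0("I", seq_len(ncol(scores)))
  if (length(item_ids) != ncol(scores))
    stop("item_ids length must equal the number of item columns")
  if (anyDuplicated(item_ids)) stop("item_ids must be unique")
  if (any(!is.finite(scores)))
    stop("response matrix contains missing or non-finite entries; ",
         "complete cases are required")
  if (any(scores != round(scores)) || any(scores < 0))
    stop("responses must be non-negative integers on the 0-based scale")
  storage.mode(scores) <- "integer"
  colnames(scores) <- item_ids
  if (is.null(max_score)) max_score <- apply(scores, 2, max)
  max_score <- as.integer(max_score)
  if (any(max_score < 1)) stop("every item needs a maximum score of at least 1")
  bad <- which(apply(scores, 2, max) > max_score)
  if (length(bad))
    stop("responses exceed max_score for item(s): ",
         paste(item_ids[bad], collapse = ", "))
  if (!is.null(subscale_map)) {
    if (is.null(names(subscale_map))) {
      if (length(subscale_map) != length(item_ids))
        stop("unnamed subscale_map must have one entry per item")
      names(subscale_map) <- item_ids
    }
    missing_items <- setdiff(item_ids, names(subscale_map))
    if (length(missing_items))
      stop("subscale_map lacks item(s): ", paste(missing_items, collapse = ", "))
    subscale_map <- subscale_map[item_ids]
  }
  if (!is.null(person_factors)) {
    person_factors <- as.data.frame(person_factors)
    if (nrow(person_factors) != nrow(scores))
      stop("person_factors must have one row per person")
  }
  structure(
    list(scores = scores, item_ids = item_ids, subscale_map = subscale_map,
         person_factors = person_factors, max_score = stats::setNames(max_score, item_ids)),
    class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix:", nrow(x$scores), "persons x", ncol(x$scores), "items\n")
  if (!is.null(x$subscale_map)) {
    tab <- table(x$subscale_map)
    cat("Subscales:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  cat("Max scores:", paste(unique(x$max_score), collapse = "/"), "\n")
  invisible(x)
}

#' Restrict a response matrix to a subset of items
#'
#' @param resp a \code{\link{response_matrix}}.
#' @param items character vector of item ids to keep (order preserved as given).
#' @return a \code{response_matrix} with only those items.
#' @export
subset_items <- function(resp, items) {
  stopifnot(inherits(resp, "response_matrix"))
  missing_items <- setdiff(items, resp$item_ids)
  if (length(missing_items))
    stop("unknown item(s): ", paste(missing_items, collapse = ", "))
  response_matrix(resp$scores[, items, drop = FALSE],
                  subscale_map = if (!is.null(resp$subscale_map)) resp$subscale_map[items],
                  person_factors = resp$person_factors,
                  item_ids = items,
                  max_score = resp$max_score[items])
}

# category counts per item on 0..m; rows = category, list per item
category_counts <- function(resp) {
  lapply(seq_along(resp$item_ids), function(i) {
    m <- resp$max_score[i]
    tabulate(resp$scores[, i] + 1L, nbins = m + 1L)
  })
}

# error if any item has a never-observed category (CML requirement)
check_null_categories <- function(resp) {
  cc <- category_counts(resp)
  for (i in seq_along(cc)) {
    z <- which(cc[[i]] == 0L) - 1L
    if (length(z))
      stop("item ", resp$item_ids[i], " has null (never observed) categor",
           if (length(z) > 1) "ies " else "y ", paste(z, collapse = ", "),
           "; collapse categories or drop the item", call. = FALSE)
  }
  invisible(TRUE)
}

# collapse never-observed categories by recoding scores to consecutive ranks
# of the observed values; returns list(resp, log) where log records recodes
collapse_null_categories <- function(resp) {
  cc <- category_counts(resp)
  scores <- resp$scores
  max_score <- resp$max_score
  log <- character(0)
  for (i in seq_along(cc)) {
    obs <- which(cc[[i]] > 0L) - 1L
    if (length(obs) == length(cc[[i]])) next
    if (length(obs) < 2L) {
      # degenerate column: nothing to collapse onto; leave it for the
      # fitting step to reject
      log <- c(log, sprintf("item %s: single observed category, left as is",
                            resp$item_ids[i]))
      next
    }
    recode <- match(scores[, i], obs) - 1L
    scores[, i] <- recode
    max_score[i] <- length(obs) - 1L
    log <- c(log, sprintf("item %s: categories %s collapsed to 0..%d",
                          resp$item_ids[i],
                          paste(obs, collapse = ","), max_score[i]))
  }
  out <- response_matrix(scores, subscale_map = resp$subscale_map,
                         person_factors = resp$person_factors,
                         item_ids = resp$item_ids, max_score = max_score)
  list(resp = out, log = log)
}
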