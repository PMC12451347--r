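#' Small-cell disclosure masking
#'
#' Masks count cells with values in `(0, threshold)` for disclosure
#' control, displaying them as `"<10"`. Zero is not masked (it reveals no
#' individual). When a row's cells sum to a published total, a single
#' masked cell could be back-calculated; `mask_small_cells()` therefore
#' additionally masks the next-smallest cell of the row (displayed
#' `"Masked"`) whenever exactly one cell is primary-masked.
#'
#' @param counts Tibble with integer count columns.
#' @param count_cols Character vector of column names holding counts; all
#'   numeric columns by default.
#' @param threshold Masking threshold (default 10).
#' @param co_mask Apply next-smallest co-masking within each row (default
#'   `TRUE`).
#' @return The tibble with the count columns converted to character
#'   display values.
#' @export
#' @examples
#' mask_small_cells(tibble::tibble(a = 146, b = 7, c = 135))
mask_small_cells <- function(counts, count_cols = NULL, threshold = 10,
                             co_mask = TRUE) {
  if (is.null(count_cols)) {
    count_cols <- names(counts)[vapply(counts, is.numeric, TRUE)]
  }
  if (length(count_cols) == 0) return(counts)
  mat <- as.matrix(counts[count_cols])
  disp <- matrix(format_count(mat), nrow = nrow(mat))
  primary <- !is.na(mat) & mat > 0 & mat < threshold
  disp[primary] <- paste0("<", threshold)
  if (co_mask) {
    for (r in seq_len(nrow(mat))) {
      if (sum(primary[r, ]) == 1) {
        candidates <- which(!primary[r, ] & !is.na(mat[r, ]) & mat[r, ] > 0)
        if (length(candidates) > 0) {
          co <- candidates[which.min(mat[r, candidates])]
          disp[r, co] <- "Masked"
        }
      }
    }
  }
  for (k in seq_along(count_cols)) counts[[count_cols[k]]] <- disp[, k]
  counts
}

format_count <- function(x) {
  out <- ifelse(is.na(x), "",
                ifelse(x == round(x), format(x, trim = TRUE,
                                             scientific = FALSE),
                       format(round(x, 2), trim = TRUE,
                              scientific = FALSE)))
  out
}
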