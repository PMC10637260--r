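`%||%` <- function(a, b) if (is.null(a)) b else a

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

.assert_columns <- function(df, cols, what = "metadata") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# rowMeans/colMeans that work for both base and Matrix classes
.row_means <- function(x) {
  if (inherits(x, "Matrix")) Matrix::rowMeans(x) else base::rowMeans(x)
}
.col_means <- function(x) {
  if (inherits(x, "Matrix")) Matrix::colMeans(x) else base::colMeans(x)
}
.col_sums <- function(x) {
  if (inherits(x, "Matrix")) Matrix::colSums(x) else base::colSums(x)
}

# Two-group label resolution: `groups` gives the contrast order
# (first minus second). When NULL the sorted unique labels are used,
# which is only allowed when exactly two are present.
.resolve_groups <- function(labels, groups = NULL) {
  present <- sort(unique(as.character(labels)))
  if (is.null(groups)) {
    if (length(present) != 2L) {
      stop(sprintf("found %d group label(s) (%s); supply `groups` naming the two to contrast",
                   length(present), paste(present, collapse = ", ")), call. = FALSE)
    }
    return(present)
  }
  groups <- as.character(groups)
  if (length(groups) != 2L || anyDuplicated(groups)) {
    stop("`groups` must be two distinct labels", call. = FALSE)
  }
  absent <- setdiff(groups, present)
  if (length(absent)) {
    stop(sprintf("group label(s) not present in the data: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  groups
}
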