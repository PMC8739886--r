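#' Vertex label map
#'
#' An integer label per mesh vertex, with an explicit "unlabeled" code for
#' vertices outside the parcellation (the medial wall, by convention code 0).
#' Class labels run 1..C externally.
#'
#' @param labels integer N-vector.
#' @param num_classes number of classes C; inferred as the maximum positive
#'   code when missing.
#' @param unlabeled_code the code marking unlabeled vertices (default 0).
#' @return a `label_map` object.
#' @export
label_map <- function(labels, num_classes = NULL, unlabeled_code = 0L) {
  labels <- as.integer(labels)
  unlabeled_code <- as.integer(unlabeled_code)
  if (any(is.na(labels))) stop("labels contain NA")
  pos <- labels[labels != unlabeled_code]
  if (any(pos < 0L)) stop("negative label codes are not allowed")
  if (is.null(num_classes)) {
    num_classes <- if (length(pos)) max(pos) else 0L
  }
  num_classes <- as.integer(num_classes)
  if (length(pos) && max(pos) > num_classes) {
    stop(sprintf("label code %d exceeds num_classes = %d", max(pos), num_classes))
  }
  structure(
    list(labels = labels, num_classes = num_classes,
         unlabeled_code = unlabeled_code),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf(
    "<label_map> %d vertices, %d classes, %d unlabeled\n",
    length(x$labels), x$num_classes, sum(x$labels == x$unlabeled_code)
  ))
  invisible(x)
}

is_labeled <- function(lm) lm$labels != lm$unlabeled_code
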