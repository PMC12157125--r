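#' Ground-truth ledger round trip
#'
#' Writes / reads the generative ledger of a simulated dataset
#' (`sample_id, class, phi, time, event, label, max_nodule_size`) as CSV,
#' with numerics serialised at full double precision so the round trip is
#' lossless.
#'
#' @param groundTruth a data frame as produced by [makeNoduleImages()].
#' @param path file path.
#' @export
writeGroundTruthLedger <- function(groundTruth, path) {
  out <- groundTruth
  for (cn in names(out))
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruthLedger
#' @export
readGroundTruthLedger <- function(path) {
  gt <- read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("phi", "time", "max_nodule_size"))
    if (cn %in% names(gt)) gt[[cn]] <- as.numeric(gt[[cn]])
  gt
}

#' Image array container I/O
#'
#' Stores an [ImageSet-class] in a columnar array-container file (Parquet
#' via the arrow package): one row per sample with its identifier and the
#' flattened pixel vector, plus the array shape and per-sample metadata
#' carried as table metadata.
#'
#' @param x an [ImageSet-class].
#' @param path file path (conventionally `.parquet`).
#' @export
writeImageSet <- function(x, path) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for image container I/O")
  d <- dim(x@images)
  n <- d[length(d)]
  shape <- d[-length(d)]
  flat <- matrix(x@images, prod(shape), n)
  tab <- data.frame(sample_id = x@sampleIds, stringsAsFactors = FALSE)
  tab$pixels <- lapply(seq_len(n), function(i) flat[, i])
  attr(tab, "imageShape") <- shape
  attr(tab, "classId") <- x@classId
  attr(tab, "role") <- x@role
  arrow::write_parquet(tab, path)
  invisible(path)
}

#' @rdname writeImageSet
#' @export
readImageSet <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for image container I/O")
  tab <- as.data.frame(arrow::read_parquet(path))
  shape <- attr(tab, "imageShape")
  n <- nrow(tab)
  imgs <- array(unlist(tab$pixels, use.names = FALSE), dim = c(shape, n))
  cid <- attr(tab, "classId")
  role <- attr(tab, "role")
  new("ImageSet", images = imgs, sampleIds = as.character(tab$sample_id),
      classId = if (is.null(cid)) integer(0) else as.integer(cid),
      role = if (is.null(role)) character(0) else as.character(role),
      ledger = list())
}

#' @export
setMethod("imageArray", "ImageSet", function(x) x@images)

#' @export
setMethod("sampleIds", "ImageSet", function(x) x@sampleIds)

#' @export
setMethod("nSamples", "ImageSet", function(x) {
  d <- dim(x@images)
  d[length(d)]
})

#' @export
setMethod("show", "ImageSet", function(object) {
  d <- dim(object@images)
  cat("ImageSet:", d[length(d)], "images of shape",
      paste(d[-length(d)], collapse = "x"), "\n")
  if (length(object@classId))
    cat("  classes:", paste(table(object@classId), collapse = " / "), "\n")
  if (length(object@ledger))
    cat("  nodule ledger present\n")
})

#' @export
setMethod("[", "ImageSet", function(x, i, j, ..., drop = TRUE) {
  d <- dim(x@images)
  nd <- length(d)
  idx <- rep(list(quote(expr = )), nd)
  idx[[nd]] <- i
  imgs <- do.call(`[`, c(list(x@images), idx, list(drop = FALSE)))
  new("ImageSet", images = imgs, sampleIds = x@sampleIds[i],
      classId = if (length(x@classId)) x@classId[i] else integer(0),
      role = if (length(x@role)) x@role[i] else character(0),
      ledger = if (length(x@ledger)) x@ledger[i] else list())
})
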