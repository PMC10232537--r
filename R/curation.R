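# Micrograph stage-position curation: removal of micrographs acquired too
# close to previously exposed regions.

#' Micrograph proximity filter
#'
#' Scans stage positions in acquisition order and removes a micrograph if
#' its position lies closer than `min_distance` to ANY earlier acquisition
#' (retained or removed: every earlier position received exposure). The
#' first position is always retained. Strict inequality: exactly
#' `min_distance` apart is kept.
#'
#' @param positions data.frame with columns `micrograph_id`, `x`, `y` (stage
#'   coordinates in micrometers) and optionally `acquisition_order` (rows
#'   are otherwise taken as already ordered).
#' @param min_distance exclusion radius in micrometers (default 1.5).
#' @return list with `retained` and `removed` character vectors of ids, and
#'   `table`: the input ordered by acquisition with a `retained` column.
#' @export
micrograph_proximity_filter <- function(positions, min_distance = 1.5) {
  req <- c("micrograph_id", "x", "y")
  miss <- setdiff(req, names(positions))
  if (length(miss)) stop("positions is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(positions$micrograph_id))
    stop("duplicate micrograph ids: ",
         paste(unique(positions$micrograph_id[duplicated(positions$micrograph_id)]),
               collapse = ", "))
  if (!is.null(positions$acquisition_order)) {
    if (anyDuplicated(positions$acquisition_order))
      stop("acquisition_order must be a total order")
    positions <- positions[order(positions$acquisition_order), , drop = FALSE]
  }
  n <- nrow(positions)
  keep <- rep(TRUE, n)
  if (n > 1) {
    xs <- positions$x; ys <- positions$y
    for (i in 2:n) {
      prev <- seq_len(i - 1)
      d2 <- (xs[prev] - xs[i])^2 + (ys[prev] - ys[i])^2
      if (any(d2 < min_distance^2)) keep[i] <- FALSE
    }
  }
  positions$retained <- keep
  rownames(positions) <- NULL
  list(retained = positions$micrograph_id[keep],
       removed = positions$micrograph_id[!keep],
       table = positions)
}

#' Read stage positions from SerialEM-style .mdoc metadata files
#'
#' A minimal key-value parser: each file contributes one record, taken from
#' its first `StagePosition = x y` line; the micrograph id is the file name.
#' Acquisition order follows the order of `paths`.
#'
#' @param paths character vector of .mdoc file paths.
#' @return data.frame with `micrograph_id`, `x`, `y`, `acquisition_order`.
#' @export
read_mdoc_positions <- function(paths) {
  rows <- lapply(seq_along(paths), function(i) {
    lines <- readLines(paths[i], warn = FALSE)
    hit <- grep("^\\s*StagePosition\\s*=", lines, value = TRUE)
    if (!length(hit))
      stop("no StagePosition entry in ", paths[i])
    val <- sub("^\\s*StagePosition\\s*=\\s*", "", hit[1])
    xy <- as.numeric(strsplit(trimws(val), "\\s+")[[1]])
    if (length(xy) < 2 || anyNA(xy))
      stop("malformed StagePosition in ", paths[i], ": '", hit[1], "'")
    data.frame(micrograph_id = basename(paths[i]), x = xy[1], y = xy[2],
               acquisition_order = i)
  })
  do.call(rbind, rows)
}

#' Read stage positions from CSV
#'
#' Expects columns `micrograph_id`, `x`, `y` and optionally
#' `acquisition_order`.
#'
#' @param path CSV file path.
#' @return data.frame of stage positions.
#' @export
read_position_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("micrograph_id", "x", "y"), names(df))
  if (length(miss)) stop("CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}
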